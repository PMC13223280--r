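#!/usr/bin/env Rscript
# Generate the default two-assay SGE screen (500 variants, HAP1-like 3
# replicates + ES-like 2 replicates, batch effects, t noise) with known
# ground truth, and write it as TSV fixtures for the downstream steps.
suppressPackageStartupMessages(library(sgemix))

dir.create("results/fixture", recursive = TRUE, showWarnings = FALSE)
scr <- simulate_screen(sim_config(seed = 7L))
print(scr)
write_fixture(scr, "results/fixture")
cat("wrote results/fixture/{variants,scores,truth}.tsv\n")
cat(sprintf("pathogenic fraction among missense: %.3f\n",
            with(merge(scr$variants, scr$truth), 
                 mean(true_status[consequence == "missense"] == "nonfunctional"))))
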