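#!/usr/bin/env Rscript
# Rescale the second assay onto the first assay's scale via the synonymous
# and nonsense control medians, then merge all replicates into one long
# table per variant.
suppressPackageStartupMessages(library(sgemix))

fx <- read_fixture("results/fixture")
harm <- rescale_assay(fx$observations, fx$variants)
print(harm)
long <- merge_replicates(harm)
write.table(long, "results/scores_harmonized.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(anchors = harm$anchors, slope = harm$slope, intercept = harm$intercept),
  "results/harmonize_anchors.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/scores_harmonized.tsv and results/harmonize_anchors.json\n")
cat(sprintf("%d variants observed in a single assay only\n",
            length(unique(long$variant_id[long$single_assay]))))
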