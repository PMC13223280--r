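Package: sgemix
Title: Integration of Saturation Genome Editing Screens for Variant Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines per-replicate functional scores from two saturation
    genome editing (SGE) screens of BRCA2 DNA-binding-domain single
    nucleotide variants into composite functional models: a Bayesian
    hierarchical two-component mixture with replicate-by-exon batch
    random effects and t-distributed errors (VarCall, fit by MCMC via
    JAGS), a two-component Gaussian mixture fit by EM, and concordance
    models over their seven-level functional categories. Provides
    Bayes-factor evidence-strength mapping, sensitivity/specificity
    benchmarking against ClinVar and homology-directed-repair standards,
    a points-based ClinGen/ACMG/AMP classification engine with the
    VUS(discordant) override, pooled case-control burden testing, and a
    synthetic-data generator that emulates the statistical structure of
    multi-assay SGE screens with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
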