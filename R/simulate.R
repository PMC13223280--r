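#' Configuration for a simulated multi-assay SGE screen
#'
#' Defines the generating model for synthetic saturation-genome-editing
#' data: a two-component mixture of latent variant effects (functional vs
#' non-functional, with non-functional variants depleted, i.e. lower
#' scores), replicate-by-exon location and log-scale batch effects,
#' t-distributed residual noise, an affine distortion applied to the second
#' assay, and completely-at-random missingness. Defaults emulate a
#' HAP1-like assay with 3 replicates and an ES-cell-like assay with 2,
#' with control components separated by roughly 6.7 component SDs.
#'
#' @param n_variants number of variants to simulate.
#' @param exon_ids character vector of exon batch labels.
#' @param replicates_per_assay named integer vector, assay id -> replicate
#'   count. The first element is the reference assay.
#' @param frac_missense_pathogenic probability that a missense variant is
#'   non-functional (default 0.227, the AlphaMissense-predicted pathogenic
#'   fraction for the BRCA2 DNA-binding domain).
#' @param consequence_mix named proportions over the consequence classes
#'   `synonymous`, `nonsense`, `missense`, `canonical_splice`; must sum to 1.
#' @param mu_functional,mu_nonfunctional means of the latent effect
#'   components, on the functional-score scale.
#' @param sigma_functional,sigma_nonfunctional SDs of the components.
#' @param batch_location_sd SD of the additive exon-by-replicate batch
#'   offsets.
#' @param batch_logscale_sd SD of the exon-by-replicate log multiplicative
#'   scale effects (generated on the log scale so scales stay positive).
#' @param t_df degrees of freedom of the residual t noise (must exceed 2).
#' @param residual_scale scale of the residual t noise.
#' @param assay_offset,assay_scale affine distortion applied to every
#'   observation of the second assay: `y2 = assay_offset + assay_scale * y`.
#' @param missing_rate probability that any single observation is dropped.
#' @param seed integer seed; the full output is reproducible given it.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_screen()]
#' @export
sim_config <- function(n_variants = 500L,
                       exon_ids = paste0("ex", 15:18),
                       replicates_per_assay = c(A1 = 3L, A2 = 2L),
                       frac_missense_pathogenic = 0.227,
                       consequence_mix = c(synonymous = 0.20, nonsense = 0.05,
                                           missense = 0.70, canonical_splice = 0.05),
                       mu_functional = 0,
                       mu_nonfunctional = -1,
                       sigma_functional = 0.15,
                       sigma_nonfunctional = 0.15,
                       batch_location_sd = 0.05,
                       batch_logscale_sd = 0.05,
                       t_df = 5,
                       residual_scale = 0.10,
                       assay_offset = 0.3,
                       assay_scale = 1.25,
                       missing_rate = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_variants = as.integer(n_variants), exon_ids = as.character(exon_ids),
    replicates_per_assay = replicates_per_assay,
    frac_missense_pathogenic = frac_missense_pathogenic,
    consequence_mix = consequence_mix,
    mu_functional = mu_functional, mu_nonfunctional = mu_nonfunctional,
    sigma_functional = sigma_functional,
    sigma_nonfunctional = sigma_nonfunctional,
    batch_location_sd = batch_location_sd,
    batch_logscale_sd = batch_logscale_sd,
    t_df = t_df, residual_scale = residual_scale,
    assay_offset = assay_offset, assay_scale = assay_scale,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_variants >= 1L, length(cfg$exon_ids) >= 1L)
  req <- c("synonymous", "nonsense", "missense", "canonical_splice")
  if (!setequal(names(cfg$consequence_mix), req)) {
    stop("consequence_mix must name exactly: ", paste(req, collapse = ", "))
  }
  if (abs(sum(cfg$consequence_mix) - 1) > 1e-9) {
    stop("consequence_mix proportions must sum to 1 (within 1e-9)")
  }
  if (any(cfg$consequence_mix < 0)) stop("consequence_mix proportions must be >= 0")
  sds <- c(cfg$sigma_functional, cfg$sigma_nonfunctional, cfg$residual_scale)
  if (any(sds <= 0)) stop("all SDs and residual_scale must be > 0")
  if (any(c(cfg$batch_location_sd, cfg$batch_logscale_sd) < 0)) {
    stop("batch-effect SDs must be >= 0")
  }
  if (cfg$t_df <= 2) stop("t_df must exceed 2 (finite variance)")
  if (is.null(names(cfg$replicates_per_assay)) ||
      any(!nzchar(names(cfg$replicates_per_assay)))) {
    stop("replicates_per_assay must be a named vector (assay -> count)")
  }
  if (any(cfg$replicates_per_assay < 1L)) stop("replicate counts must be >= 1")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  cfg
}

#' Simulate a two-assay SGE screen with known ground truth
#'
#' Draws a latent effect `theta_v` for each variant from the mixture
#' component matching its true functional status, then generates one raw
#' score per (variant, assay, replicate) as
#' `b[e,r] + exp(g[e,r]) * theta_v + residual_scale * t(t_df)`,
#' where `b` and `g` are exon-by-replicate location and log-scale batch
#' effects. Observations of the second assay are additionally passed
#' through the configured affine distortion, and observations are dropped
#' independently at `missing_rate`.
#'
#' Synonymous variants are always functional and nonsense (and
#' canonical-splice) variants always non-functional; missense variants are
#' non-functional with probability `frac_missense_pathogenic`. Annotation
#' columns (BayesDel, filter allele frequency, ClinVar / HDR standard
#' labels, pre-assigned evidence codes) are generated consistently with the
#' true status so the downstream evidence and evaluation modules are
#' exercised end to end.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sge_screen`: a list with data frames
#'   `variants` (one row per variant with annotations), `observations`
#'   (one row per raw score: variant_id, assay, replicate, exon,
#'   raw_score) and `truth` (variant_id, true_status, true_effect).
#' @export
simulate_screen <- function(config) {
  config <- validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n <- config$n_variants
  variant_id <- sprintf("var%05d", seq_len(n))
  consequence <- sample(names(config$consequence_mix), n, replace = TRUE,
                        prob = config$consequence_mix)
  for (cls in names(config$consequence_mix)) {
    if (config$consequence_mix[[cls]] > 0 && !any(consequence == cls)) {
      warning("no variants of requested consequence class '", cls,
              "' were drawn; downstream control-dependent steps may fail")
    }
  }
  exon <- sample(config$exon_ids, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  nonfunctional <- ifelse(
    consequence == "synonymous", FALSE,
    ifelse(consequence %in% c("nonsense", "canonical_splice"), TRUE,
           stats::runif(n) < config$frac_missense_pathogenic)
  )
  true_status <- ifelse(nonfunctional, "nonfunctional", "functional")
  theta <- ifelse(nonfunctional,
                  stats::rnorm(n, config$mu_nonfunctional, config$sigma_nonfunctional),
                  stats::rnorm(n, config$mu_functional, config$sigma_functional))

  # annotations: deleteriousness score tracks status; population frequency is
  # mostly absent (rare variants), occasionally appreciable for benign ones
  bayesdel <- ifelse(nonfunctional,
                     pmin(pmax(stats::rnorm(n, 0.45, 0.10), 0), 1),
                     pmin(pmax(stats::rnorm(n, 0.05, 0.07), 0), 1))
  bayesdel[stats::runif(n) < 0.05] <- NA_real_
  spliceai_flag <- consequence == "canonical_splice"
  faf <- numeric(n)
  has_faf_b <- !nonfunctional & stats::runif(n) < 0.35
  faf[has_faf_b] <- 10^stats::runif(sum(has_faf_b), -6, -2.3)
  has_faf_p <- nonfunctional & stats::runif(n) < 0.02
  faf[has_faf_p] <- 10^stats::runif(sum(has_faf_p), -6, -5)

  is_mis <- consequence == "missense"
  clinvar_standard <- rep("none", n)
  pick_cv <- is_mis & stats::runif(n) < 0.08
  clinvar_standard[pick_cv] <- ifelse(nonfunctional[pick_cv], "P/LP", "B/LB")
  hdr_standard <- rep("none", n)
  pick_hdr <- is_mis & stats::runif(n) < 0.15
  hdr_standard[pick_hdr] <- ifelse(nonfunctional[pick_hdr], "abnormal", "normal")

  preassigned_codes <- rep("", n)
  pick_pm3 <- nonfunctional & is_mis & stats::runif(n) < 0.05
  preassigned_codes[pick_pm3] <- "PM3"
  pick_bs2 <- !nonfunctional & is_mis & stats::runif(n) < 0.05
  preassigned_codes[pick_bs2] <- "BS2"

  variants <- data.frame(
    variant_id = variant_id, chrom = "13",
    pos = 32900000L + seq_len(n), ref = ref, alt = alt,
    exon = exon, consequence = consequence,
    bayesdel = bayesdel, spliceai_flag = spliceai_flag, faf = faf,
    preassigned_codes = preassigned_codes,
    clinvar_standard = clinvar_standard, hdr_standard = hdr_standard,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(variant_id = variant_id, true_status = true_status,
                      true_effect = theta, stringsAsFactors = FALSE)

  assays <- names(config$replicates_per_assay)
  obs <- vector("list", length(assays))
  for (ai in seq_along(assays)) {
    a <- assays[ai]
    reps <- config$replicates_per_assay[[a]]
    blocks <- vector("list", reps)
    for (r in seq_len(reps)) {
      # one location and one log-scale effect per exon within this replicate
      b_er <- stats::rnorm(length(config$exon_ids), 0, config$batch_location_sd)
      g_er <- stats::rnorm(length(config$exon_ids), 0, config$batch_logscale_sd)
      names(b_er) <- names(g_er) <- config$exon_ids
      eps <- config$residual_scale * stats::rt(n, config$t_df)
      y <- b_er[exon] + exp(g_er[exon]) * theta + eps
      if (ai == 2L) y <- config$assay_offset + config$assay_scale * y
      blocks[[r]] <- data.frame(
        variant_id = variant_id, assay = a, replicate = r, exon = exon,
        raw_score = unname(y), stringsAsFactors = FALSE
      )
    }
    obs[[ai]] <- do.call(rbind, blocks)
  }
  observations <- do.call(rbind, obs)
  if (config$missing_rate > 0) {
    keep <- stats::runif(nrow(observations)) >= config$missing_rate
    observations <- observations[keep, , drop = FALSE]
  }
  rownames(observations) <- NULL

  structure(list(variants = variants, observations = observations,
                 truth = truth, config = config),
            class = "sge_screen")
}

#' @export
print.sge_screen <- function(x, ...) {
  cat("Simulated SGE screen:", nrow(x$variants), "variants,",
      nrow(x$observations), "observations,",
      length(unique(x$observations$assay)), "assays\n")
  print(table(x$variants$consequence))
  invisible(x)
}

#' Write a simulated screen to tab-separated fixture files
#'
#' Writes `variants.tsv`, `scores.tsv` and `truth.tsv` into `dir`, in the
#' dialect all downstream readers use. Absent filter allele frequencies are
#' written as 0 and absent annotations as NA.
#'
#' @param screen an `sge_screen` from [simulate_screen()].
#' @param dir output directory; created if needed.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(screen, dir) {
  stopifnot(inherits(screen, "sge_screen") || is.list(screen))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("variants.tsv", "scores.tsv", "truth.tsv"))
  utils::write.table(screen$variants, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(screen$observations, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(screen$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir directory containing `variants.tsv`, `scores.tsv`,
#'   `truth.tsv` (truth optional for real-data layouts).
#' @return a list with `variants`, `observations` and (if present) `truth`.
#' @export
read_fixture <- function(dir) {
  rd <- function(p) utils::read.delim(p, stringsAsFactors = FALSE,
                                      na.strings = "NA")
  out <- list(
    variants = rd(file.path(dir, "variants.tsv")),
    observations = rd(file.path(dir, "scores.tsv"))
  )
  # read.delim drops empty strings to NA only for character NA markers;
  # normalise the optional preassigned-code column
  if (!is.null(out$variants$preassigned_codes)) {
    pc <- out$variants$preassigned_codes
    out$variants$preassigned_codes <- ifelse(is.na(pc), "", as.character(pc))
  }
  tp <- file.path(dir, "truth.tsv")
  if (file.exists(tp)) out$truth <- rd(tp)
  out
}
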