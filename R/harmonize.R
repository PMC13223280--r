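#' Rescale one assay's scores onto a reference assay's scale
#'
#' Computes the pooled medians of the synonymous and nonsense control
#' scores in each assay and applies the unique affine map sending the
#' source assay's two anchors onto the reference assay's. Medians (not
#' means) are used as anchors because the measurement model assumes heavy
#' tails. Reference-assay scores pass through unchanged; replicate-level
#' differences are deliberately left for the hierarchical model's batch
#' random effects to absorb.
#'
#' @param observations data frame with columns `variant_id`, `assay`,
#'   `replicate`, `exon`, `raw_score`.
#' @param variants data frame with `variant_id` and `consequence`.
#' @param source_assay assay id to rescale (default `"A2"`).
#' @param reference_assay assay id defining the target scale (default `"A1"`).
#' @param min_controls minimum number of control variants of each class
#'   with observations required per assay (default 5).
#' @return an object of class `harmonized`: list with `observations`
#'   (input plus a `rescaled_score` column), `anchors` (per-assay control
#'   medians), and the fitted `slope` / `intercept`.
#' @export
rescale_assay <- function(observations, variants,
                          source_assay = "A2", reference_assay = "A1",
                          min_controls = 5L) {
  stopifnot(all(c("variant_id", "assay", "raw_score") %in% names(observations)))
  cons <- variants$consequence[match(observations$variant_id, variants$variant_id)]

  anchor <- function(assay, class) {
    idx <- observations$assay == assay & cons == class
    ids <- unique(observations$variant_id[idx])
    if (length(ids) < min_controls) {
      stop("assay ", assay, " has only ", length(ids), " ", class,
           " control variants with observations; >= ", min_controls, " required")
    }
    stats::median(observations$raw_score[idx])
  }
  anchors <- data.frame(
    assay = rep(c(reference_assay, source_assay), each = 2),
    class = rep(c("synonymous", "nonsense"), 2),
    median = c(anchor(reference_assay, "synonymous"),
               anchor(reference_assay, "nonsense"),
               anchor(source_assay, "synonymous"),
               anchor(source_assay, "nonsense")),
    stringsAsFactors = FALSE
  )
  ref_syn <- anchors$median[1]; ref_non <- anchors$median[2]
  src_syn <- anchors$median[3]; src_non <- anchors$median[4]
  if (abs(src_syn - src_non) < .Machine$double.eps^0.5) {
    stop("degenerate anchors: source-assay synonymous and nonsense medians are equal")
  }
  slope <- (ref_syn - ref_non) / (src_syn - src_non)
  if (slope <= 0) {
    stop("rescaling slope is not positive (", signif(slope, 4),
         "); assays disagree on score direction")
  }
  intercept <- ref_non - slope * src_non

  observations$rescaled_score <- ifelse(
    observations$assay == source_assay,
    intercept + slope * observations$raw_score,
    observations$raw_score
  )
  structure(list(observations = observations, anchors = anchors,
                 slope = slope, intercept = intercept,
                 source_assay = source_assay, reference_assay = reference_assay),
            class = "harmonized")
}

#' @export
print.harmonized <- function(x, ...) {
  cat("Harmonized dataset:", nrow(x$observations), "observations;",
      x$source_assay, "->", x$reference_assay,
      sprintf("(slope %.4f, intercept %.4f)\n", x$slope, x$intercept))
  invisible(x)
}

#' Merge all replicates into one long per-observation table
#'
#' One row per (variant, assay, replicate) observation. Variants observed
#' in only one assay are flagged via `single_assay`, not dropped; an
#' optional filter restricts to variants common to both assays, which is
#' how the integrated analyses are run by default.
#'
#' @param harmonized a `harmonized` object from [rescale_assay()].
#' @param common_only if `TRUE`, keep only variants observed in both assays.
#' @return data frame keyed by (variant_id, assay, replicate) with
#'   `rescaled_score` and logical `single_assay`.
#' @export
merge_replicates <- function(harmonized, common_only = FALSE) {
  obs <- harmonized$observations
  n_assays <- tapply(obs$assay, obs$variant_id, function(a) length(unique(a)))
  obs$single_assay <- unname(n_assays[obs$variant_id] < 2L)
  if (common_only) obs <- obs[!obs$single_assay, , drop = FALSE]
  rownames(obs) <- NULL
  obs
}
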