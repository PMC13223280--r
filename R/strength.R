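#' Seven-level functional strength categories
#'
#' Ordered from strongest pathogenic evidence to strongest benign evidence.
#' Both integrated models (VarCall and GMM) map their evidence ratios onto
#' this common scale.
#'
#' @export
CATEGORY_LEVELS <- c(
  "P_Strong", "P_Moderate", "P_Supporting", "Uncertain",
  "B_Supporting", "B_Moderate", "B_Strong"
)

#' Collapse a functional category to its side
#'
#' Any pathogenic-strength category maps to `"P"`, any benign-strength
#' category to `"B"`, and `Uncertain` to `"VUS"`. Side membership (not exact
#' category) is what the concordance models compare.
#'
#' @param category character vector of categories from [CATEGORY_LEVELS].
#' @return character vector in `{"P","B","VUS"}`; `NA` passes through.
#' @export
category_side <- function(category) {
  bad <- !is.na(category) & !category %in% CATEGORY_LEVELS
  if (any(bad)) {
    stop("unknown category: ", paste(unique(category[bad]), collapse = ", "))
  }
  out <- rep(NA_character_, length(category))
  out[startsWith(category, "P_")] <- "P"
  out[startsWith(category, "B_")] <- "B"
  out[!is.na(category) & category == "Uncertain"] <- "VUS"
  out
}

#' Convert a posterior probability of pathogenicity to a Bayes factor
#'
#' The Bayes factor in favour of pathogenicity is the posterior odds divided
#' by the prior odds. Posterior probabilities of exactly 0 or 1 (as produced
#' for control variants whose pathogenicity indicator is fixed) are clamped
#' to `1/(S+1)` and `S/(S+1)` where `S = n_draws`, so controls receive
#' finite, maximal-strength Bayes factors while the ordering of all other
#' variants is preserved.
#'
#' @param pp numeric vector of posterior probabilities in `[0, 1]`.
#' @param prior prior probability of pathogenicity, in `(0, 1)`.
#' @param n_draws total number of posterior draws behind `pp`; used only for
#'   the clamp. If `NULL`, no clamping is applied and `pp` of 0 or 1 yields
#'   a Bayes factor of 0 or `Inf`.
#' @return numeric vector of Bayes factors.
#' @export
posterior_to_bf <- function(pp, prior, n_draws = NULL) {
  if (!is.numeric(prior) || length(prior) != 1L || is.na(prior) ||
      prior <= 0 || prior >= 1) {
    stop("`prior` must be a single probability strictly inside (0, 1)")
  }
  if (any(pp < 0 | pp > 1, na.rm = TRUE)) {
    stop("`pp` must lie in [0, 1]")
  }
  if (!is.null(n_draws)) {
    lo <- 1 / (n_draws + 1)
    pp <- pmin(pmax(pp, lo), 1 - lo)
  }
  (pp / (1 - pp)) / (prior / (1 - prior))
}

#' Map Bayes factors to the seven functional strength categories
#'
#' Thresholds follow the Bayesian reading of the ACMG/AMP evidence scale:
#' strong, moderate and supporting pathogenic evidence correspond to Bayes
#' factors of at least `odds_constant^(1/2)`, `^(1/4)` and `^(1/8)`
#' respectively, with the reciprocal bounds on the benign side. Bayes
#' factors between the two supporting bounds are `Uncertain`.
#'
#' @param bf numeric vector of Bayes factors (positive; `Inf` allowed).
#' @param odds_constant the canonical odds-of-pathogenicity constant whose
#'   fractional powers define the strength thresholds (default 350).
#' @return character vector of categories.
#' @export
categorize_bf <- function(bf, odds_constant = 350) {
  if (any(bf < 0, na.rm = TRUE)) stop("`bf` must be positive")
  thr <- odds_constant^(1 / c(2, 4, 8))
  out <- rep(NA_character_, length(bf))
  out[!is.na(bf)] <- "Uncertain"
  out[bf >= thr[3]] <- "P_Supporting"
  out[bf >= thr[2]] <- "P_Moderate"
  out[bf >= thr[1]] <- "P_Strong"
  out[bf <= 1 / thr[3]] <- "B_Supporting"
  out[bf <= 1 / thr[2]] <- "B_Moderate"
  out[bf <= 1 / thr[1]] <- "B_Strong"
  out
}
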