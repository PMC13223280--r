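#' Build category pairs from two call tables
#'
#' @param calls_a,calls_b call tables (from [varcall_calls()],
#'   [gmm_calls()], or external category tables with `variant_id` and
#'   `category`).
#' @return data frame with `variant_id`, `category_a`, `category_b`,
#'   `side_a`, `side_b`, restricted to variants present in both tables.
#' @export
category_pairs <- function(calls_a, calls_b) {
  ids <- intersect(calls_a$variant_id, calls_b$variant_id)
  a <- calls_a$category[match(ids, calls_a$variant_id)]
  b <- calls_b$category[match(ids, calls_b$variant_id)]
  data.frame(variant_id = ids, category_a = a, category_b = b,
             side_a = category_side(a), side_b = category_side(b),
             stringsAsFactors = FALSE)
}

#' Split variants into concordant and discordant sets
#'
#' A variant is concordant when both sources place it on the same side:
#' any pathogenic-strength category in both, any benign-strength category
#' in both, or Uncertain in both. Concordant variants carry their
#' consensus side; discordant variants keep both categories for
#' reporting. Variants with a missing category on either side are
#' excluded (and counted in the result).
#'
#' @param pairs data frame from [category_pairs()] (columns `variant_id`,
#'   `category_a`, `category_b`; sides recomputed if absent).
#' @return list with data frames `concordant` (with `side`) and
#'   `discordant`, a `counts` table of concordant variants by side, and
#'   `n_excluded`.
#' @export
concordant_set <- function(pairs) {
  if (is.null(pairs$side_a)) pairs$side_a <- category_side(pairs$category_a)
  if (is.null(pairs$side_b)) pairs$side_b <- category_side(pairs$category_b)
  miss <- is.na(pairs$category_a) | is.na(pairs$category_b)
  if (any(miss)) {
    message(sum(miss), " variant(s) excluded for missing category")
  }
  pairs <- pairs[!miss, , drop = FALSE]
  conc <- pairs$side_a == pairs$side_b
  concordant <- pairs[conc, , drop = FALSE]
  concordant$side <- concordant$side_a
  discordant <- pairs[!conc, , drop = FALSE]
  rownames(concordant) <- rownames(discordant) <- NULL
  list(concordant = concordant, discordant = discordant,
       counts = table(factor(concordant$side, c("P", "B", "VUS"))),
       n_excluded = sum(miss))
}

#' Exact seven-level category agreement and confusion matrix
#'
#' @param pairs data frame from [category_pairs()].
#' @return list with `agreement` (fraction of variants with identical
#'   categories) and `confusion` (7x7 table).
#' @export
category_agreement <- function(pairs) {
  miss <- is.na(pairs$category_a) | is.na(pairs$category_b)
  pairs <- pairs[!miss, , drop = FALSE]
  lv <- CATEGORY_LEVELS
  list(agreement = mean(pairs$category_a == pairs$category_b),
       confusion = table(factor(pairs$category_a, lv),
                         factor(pairs$category_b, lv), dnn = c("a", "b")),
       n = nrow(pairs))
}
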