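#' Sensitivity and specificity of functional calls against truth standards
#'
#' Benchmarks a call table against ClinVar (P/LP vs B/LB) or
#' homology-directed-repair (abnormal vs normal) standards. Two
#' definitions are supported. `conservative`: sensitivity is the fraction
#' of pathogenic/abnormal standards called `P_Strong`, specificity the
#' fraction of benign/normal standards called `B_Strong` or `B_Moderate`
#' — the high-confidence categories only. `all_categories`: any
#' pathogenic-side category counts towards sensitivity and any benign-side
#' category towards specificity. Standards with an `Uncertain` call count
#' in the denominator either way; only standards with an opposite-side
#' call are listed as discrepant.
#'
#' @param calls call table with `variant_id` and `category`.
#' @param standards data frame with `variant_id` and truth columns
#'   `clinvar_standard` (`P/LP`, `B/LB`, `none`) and/or `hdr_standard`
#'   (`abnormal`, `normal`, `none`); a variants table works directly.
#' @param truth_source `"clinvar"` or `"hdr"`.
#' @param definition `"conservative"` or `"all_categories"`.
#' @return an object of class `performance_report`: list with
#'   `n_standards_evaluated`, `sensitivity`, `specificity` (`NA` when no
#'   standard of that polarity exists), `discrepant` (data frame), and the
#'   definition/truth source used.
#' @export
evaluate_calls <- function(calls, standards,
                           truth_source = c("clinvar", "hdr"),
                           definition = c("conservative", "all_categories")) {
  truth_source <- match.arg(truth_source)
  definition <- match.arg(definition)
  col <- paste0(truth_source, "_standard")
  if (is.null(standards[[col]])) stop("standards table lacks column ", col)
  lab <- standards[[col]][match(calls$variant_id, standards$variant_id)]
  path_lab <- if (truth_source == "clinvar") "P/LP" else "abnormal"
  ben_lab <- if (truth_source == "clinvar") "B/LB" else "normal"

  keep <- !is.na(lab) & lab %in% c(path_lab, ben_lab)
  cat <- calls$category[keep]
  id <- calls$variant_id[keep]
  truth_path <- lab[keep] == path_lab
  side <- category_side(cat)

  hit_path <- if (definition == "conservative") cat == "P_Strong" else side == "P"
  hit_ben <- if (definition == "conservative") {
    cat %in% c("B_Strong", "B_Moderate")
  } else side == "B"

  sens <- if (any(truth_path)) mean(hit_path[truth_path]) else NA_real_
  spec <- if (any(!truth_path)) mean(hit_ben[!truth_path]) else NA_real_

  opp <- (truth_path & side == "B") | (!truth_path & side == "P")
  discrepant <- data.frame(variant_id = id[opp], category = cat[opp],
                           standard = lab[keep][opp], stringsAsFactors = FALSE)
  structure(list(n_standards_evaluated = sum(keep),
                 n_pathogenic = sum(truth_path), n_benign = sum(!truth_path),
                 sensitivity = sens, specificity = spec,
                 discrepant = discrepant,
                 definition = definition, truth_source = truth_source),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    "Performance vs %s standards (%s definition): n = %d (%d pathogenic-side, %d benign-side)\n",
    x$truth_source, x$definition, x$n_standards_evaluated,
    x$n_pathogenic, x$n_benign))
  cat(sprintf("  sensitivity %.3f, specificity %.3f; %d discrepant variant(s)\n",
              x$sensitivity, x$specificity, nrow(x$discrepant)))
  invisible(x)
}

#' Pooled case-control burden test on a 2x2 table
#'
#' Odds ratio `ad/bc` for a pooled carriers/non-carriers by cases/controls
#' table, with a Haldane continuity correction (+0.5 to every cell) when
#' any cell is zero; a two-sided Fisher exact p-value; and a Wald
#' confidence interval on the log odds ratio. If both cells of a row or
#' column are zero the odds ratio is undefined and reported as `NA`.
#'
#' @param a,b,c_,d counts: carriers in cases, non-carriers in cases,
#'   carriers in controls, non-carriers in controls. Alternatively pass a
#'   length-4 vector or 2x2 matrix as `a`.
#' @param conf_level confidence level for the Wald interval (default 0.95).
#' @return list with `or`, `p`, `ci` (length 2), `table` and `corrected`.
#' @export
pooled_burden_or <- function(a, b = NULL, c_ = NULL, d = NULL,
                             conf_level = 0.95) {
  if (is.null(b)) {
    x <- as.numeric(a)
    stopifnot(length(x) == 4L)
  } else {
    x <- as.numeric(c(a, b, c_, d))
  }
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  tab <- matrix(x, 2, 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("carrier", "noncarrier")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value

  undefined <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (undefined) {
    return(list(or = NA_real_, p = p, ci = c(NA_real_, NA_real_),
                table = tab, corrected = FALSE))
  }
  corrected <- any(tab == 0)
  tc <- if (corrected) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  se <- sqrt(sum(1 / tc))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * zq * se)
  list(or = or, p = p, ci = ci, table = tab, corrected = corrected)
}
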