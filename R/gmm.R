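#' Fit the integrated two-component Gaussian mixture model
#'
#' Summarises each variant's harmonized replicate scores into one function
#' score (mean by default) and fits a two-component univariate Gaussian
#' mixture by EM with random restarts. Components are labelled by control
#' calibration: the component with the higher mean responsibility among
#' nonsense controls is the non-functional one (synonymous variants are
#' treated as functional, nonsense as non-functional).
#'
#' @param harmonized a `harmonized` object (or list with an `observations`
#'   data frame carrying `rescaled_score`).
#' @param variants variant table with `variant_id` and `consequence`.
#' @param seed integer seed for the random restarts.
#' @param summary_fn replicate combiner, `mean` (default) or `median`.
#' @param n_restarts number of EM restarts; the best log-likelihood wins.
#' @param tol EM stops when the log-likelihood gain drops below this.
#' @param max_iter maximum EM iterations per restart.
#' @param var_floor variance floor applied when a component collapses.
#' @return an object of class `gmm_fit` with component means `m_F`, `m_N`,
#'   SDs `s_F`, `s_N`, non-functional weight `w_N`, per-variant summary
#'   scores, responsibilities, and the log-likelihood trace of the winning
#'   restart.
#' @export
fit_gmm <- function(harmonized, variants, seed = 1L, summary_fn = mean,
                    n_restarts = 10L, tol = 1e-8, max_iter = 500L,
                    var_floor = 1e-6) {
  obs <- harmonized$observations
  stopifnot(!is.null(obs$rescaled_score))
  ids <- intersect(variants$variant_id, unique(obs$variant_id))
  score <- vapply(split(obs$rescaled_score[obs$variant_id %in% ids],
                        factor(obs$variant_id[obs$variant_id %in% ids], ids)),
                  summary_fn, numeric(1))
  y <- unname(score)
  cons <- variants$consequence[match(ids, variants$variant_id)]
  if (stats::sd(y) < sqrt(var_floor)) {
    stop("degenerate input: all per-variant summary scores are (nearly) identical")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1L) {
      # anchor the first restart on the control medians when available
      m1 <- if (any(cons == "synonymous")) stats::median(y[cons == "synonymous"]) else stats::quantile(y, 0.75)
      m2 <- if (any(cons == "nonsense")) stats::median(y[cons == "nonsense"]) else stats::quantile(y, 0.25)
      list(m = c(m1, m2), s2 = rep(stats::var(y) / 4, 2), w = c(0.5, 0.5))
    } else {
      list(m = sample(y, 2), s2 = rep(stats::var(y) / stats::runif(1, 2, 8), 2),
           w = { w1 <- stats::runif(1, 0.2, 0.8); c(w1, 1 - w1) })
    }
    res <- tryCatch(em_two_gaussian(y, init, tol, max_iter, var_floor),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best)) stop("all EM restarts degenerated; cannot fit mixture")

  # control calibration: which component is non-functional?
  resp2 <- best$resp[, 2]
  idx_non <- if (any(cons == "nonsense")) {
    mean_r2_non <- mean(resp2[cons == "nonsense"])
    mean_r2_syn <- if (any(cons == "synonymous")) mean(resp2[cons == "synonymous"]) else 1 - mean_r2_non
    if (mean_r2_non >= mean_r2_syn) 2L else 1L
  } else {
    which.min(best$m)  # fall back to score direction: depleted = lower
  }
  idx_fun <- 3L - idx_non

  fit <- structure(list(
    m_F = best$m[idx_fun], m_N = best$m[idx_non],
    s_F = sqrt(best$s2[idx_fun]), s_N = sqrt(best$s2[idx_non]),
    w_N = best$w[idx_non],
    variant_id = ids, score = unname(y), consequence = cons,
    resp_N = best$resp[, idx_non],
    loglik = best$loglik, ll_trace = best$ll_trace,
    n_iter = best$n_iter, seed = seed
  ), class = "gmm_fit")
  if (fit$m_N >= fit$m_F) {
    warning("control calibration labelled the higher-mean component ",
            "non-functional; check score direction")
  }
  fit
}

# EM for a univariate two-component Gaussian mixture. Log-likelihood is
# non-decreasing by construction; a collapsing component gets its variance
# floored and the iteration continues.
em_two_gaussian <- function(y, init, tol, max_iter, var_floor) {
  m <- init$m; s2 <- pmax(init$s2, var_floor); w <- init$w
  n <- length(y)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  resp <- NULL
  for (it in seq_len(max_iter)) {
    ld <- cbind(log(w[1]) + stats::dnorm(y, m[1], sqrt(s2[1]), log = TRUE),
                log(w[2]) + stats::dnorm(y, m[2], sqrt(s2[2]), log = TRUE))
    mx <- pmax(ld[, 1], ld[, 2])
    lse <- mx + log(exp(ld[, 1] - mx) + exp(ld[, 2] - mx))
    ll <- sum(lse)
    resp <- exp(ld - lse)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    nk <- colSums(resp)
    if (any(nk < 1e-10)) stop("empty component")
    w <- nk / n
    m <- colSums(resp * y) / nk
    s2 <- pmax(colSums(resp * (outer(y, m, "-")^2)) / nk, var_floor)
  }
  list(m = m, s2 = s2, w = w, resp = resp, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, n_iter = length(ll_trace))
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "Integrated GMM fit: %d variants; m_F = %.3f (s %.3f), m_N = %.3f (s %.3f), w_N = %.3f; logLik %.3f (%d iters)\n",
    length(x$variant_id), x$m_F, x$s_F, x$m_N, x$s_N, x$w_N, x$loglik, x$n_iter))
  invisible(x)
}

#' Probability of impact on function and strength categories from a GMM fit
#'
#' The per-variant evidence is the component likelihood ratio
#' `LR = f_N(y) / f_F(y)` (densities of the non-functional and functional
#' components at the variant's summary score). The probability of impact
#' on function is the posterior under the supplied prior,
#' `PIF = LR * prior / (LR * prior + 1 - prior)`, and the likelihood ratio
#' is compared against the same odds-of-pathogenicity thresholds as the
#' VarCall Bayes factors (see [categorize_bf()]), so both models share one
#' strength scale. The fitted mixture weight is deliberately not used as
#' the prior: evidence and prior stay separable.
#'
#' @param fit a `gmm_fit`.
#' @param prior prior probability of pathogenicity (default 0.2).
#' @param odds_constant passed to [categorize_bf()].
#' @return data frame with `variant_id`, `score`, `pif`, `lr`, `category`,
#'   `model_tag`, plus `pp` and `bf` aliases so GMM calls are
#'   interchangeable with VarCall calls downstream.
#' @export
pif_and_categorize <- function(fit, prior = 0.2, odds_constant = 350) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (prior <= 0 || prior >= 1) stop("prior must lie strictly inside (0, 1)")
  log_lr <- stats::dnorm(fit$score, fit$m_N, fit$s_N, log = TRUE) -
    stats::dnorm(fit$score, fit$m_F, fit$s_F, log = TRUE)
  log_lr <- pmin(pmax(log_lr, -700), 700)
  lr <- exp(log_lr)
  pif <- lr * prior / (lr * prior + 1 - prior)
  data.frame(variant_id = fit$variant_id, score = fit$score,
             pif = pif, lr = lr, pp = pif, bf = lr,
             category = categorize_bf(lr, odds_constant),
             model_tag = "gmm", stringsAsFactors = FALSE)
}

#' Functional calls from a GMM fit
#'
#' Convenience wrapper around [pif_and_categorize()] returning the shared
#' call schema.
#'
#' @inheritParams pif_and_categorize
#' @return data frame with `variant_id`, `pp`, `bf`, `category`, `model_tag`.
#' @export
gmm_calls <- function(fit, prior = 0.2, odds_constant = 350) {
  pif_and_categorize(fit, prior, odds_constant)[
    , c("variant_id", "pp", "bf", "category", "model_tag")]
}
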