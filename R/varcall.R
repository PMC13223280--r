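#' MCMC specification for the integrated VarCall model
#'
#' @param prior_pathogenic prior probability of pathogenicity for variants
#'   whose status is not fixed (default 0.2 for the DNA-binding region,
#'   reflecting the predicted 22.7% pathogenic fraction among missense
#'   variants there; 0.1 is the standard sensitivity alternative).
#' @param n_chains number of MCMC chains (>= 2, for convergence checks).
#' @param n_adapt adaptation iterations for the sampler.
#' @param n_warmup burn-in iterations discarded after adaptation.
#' @param n_samples retained iterations per chain.
#' @param seed integer seed; each chain gets a deterministic RNG stream
#'   derived from it.
#' @param rhat_max convergence bound on the potential scale reduction
#'   factor of every hyperparameter (default 1.05).
#' @param ess_min minimum chain-pooled effective sample size per
#'   hyperparameter (default 400).
#' @return an object of class `varcall_spec`.
#' @export
varcall_spec <- function(prior_pathogenic = 0.2, n_chains = 2L,
                         n_adapt = 500L, n_warmup = 500L, n_samples = 2000L,
                         seed = 20260409L, rhat_max = 1.05, ess_min = 400) {
  if (prior_pathogenic <= 0 || prior_pathogenic >= 1) {
    stop("prior_pathogenic must lie strictly inside (0, 1)")
  }
  if (n_chains < 2L) stop("n_chains must be >= 2")
  structure(list(prior_pathogenic = prior_pathogenic,
                 n_chains = as.integer(n_chains),
                 n_adapt = as.integer(n_adapt),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 rhat_max = rhat_max, ess_min = ess_min),
            class = "varcall_spec")
}

# Assemble the JAGS model text. Two switches: replicate-by-exon batch
# effects on/off, and hyperparameters free vs fixed at supplied values
# (fixed mode with infinite nu uses a plain Gaussian likelihood; used for
# closed-form cross-checks).
varcall_model_text <- function(include_batch, fixed_hyper, gaussian_errors) {
  mean_expr <- if (include_batch) {
    "b[batch[i]] + exp(g[batch[i]]) * theta[v[i]]"
  } else {
    "theta[v[i]]"
  }
  lik <- if (gaussian_errors) {
    sprintf("    y[i] ~ dnorm(%s, prec_res)", mean_expr)
  } else {
    sprintf("    y[i] ~ dt(%s, prec_res, nu)", mean_expr)
  }
  batch_block <- if (include_batch) "
  for (j in 1:B) {
    b[j] ~ dnorm(0, prec_b)
    g[j] ~ dnorm(0, prec_g)
  }
  sd_b ~ dnorm(0, prec_hn) T(0,)
  prec_b <- pow(sd_b, -2)
  sd_g ~ dnorm(0, 4) T(0,)
  prec_g <- pow(sd_g, -2)" else ""
  hyper_block <- if (fixed_hyper) "
  mu_comp[1] <- mu_F
  mu_comp[2] <- mu_N
  prec_comp[1] <- pow(sigma_F, -2)
  prec_comp[2] <- pow(sigma_N, -2)
  prec_res <- pow(tau, -2)" else "
  mu_comp[1] <- mu_F
  mu_comp[2] <- mu_N
  prec_comp[1] <- pow(sigma_F, -2)
  prec_comp[2] <- pow(sigma_N, -2)
  mu_F ~ dnorm(m0F, prec0)
  delta ~ dnorm(d0, prec0) T(0,)
  mu_N <- mu_F - delta
  sigma_F ~ dnorm(0, prec_hn) T(0,)
  sigma_N ~ dnorm(0, prec_hn) T(0,)
  tau ~ dnorm(0, prec_hn) T(0,)
  prec_res <- pow(tau, -2)"
  nu_block <- if (gaussian_errors || fixed_hyper) "" else "
  nu ~ dgamma(2, 0.1) T(2,)"
  paste0("model {
  for (i in 1:N) {
", lik, "
  }", batch_block, "
  for (k in 1:V) {
    z[k] ~ dbern(prior_p)
    theta[k] ~ dnorm(mu_comp[z[k] + 1], prec_comp[z[k] + 1])
  }", hyper_block, nu_block, "
}")
}

#' Fit the integrated VarCall model
#'
#' A Bayesian hierarchical model over harmonized per-replicate scores: each
#' variant carries a binary pathogenicity indicator `z_v` — fixed at 0 for
#' synonymous and 1 for nonsense controls, Bernoulli(`prior_pathogenic`)
#' otherwise — and a latent effect `theta_v` drawn from the mixture
#' component selected by `z_v` (non-functional component constrained below
#' the functional one). The measurement model is
#' `y = b[e,r] + exp(g[e,r]) * theta_v + t-noise`, with replicate-by-exon
#' location (`b`) and log-scale (`g`) random effects and t-distributed
#' errors to absorb outliers. Fit by MCMC with JAGS; hyperpriors are
#' weakly informative and centred on the control medians.
#'
#' @param harmonized a `harmonized` object from [rescale_assay()] (or any
#'   list with an `observations` data frame carrying `rescaled_score`).
#' @param variants variant table with `variant_id` and `consequence`.
#' @param spec a [varcall_spec()].
#' @param include_batch include the batch random effects (default `TRUE`).
#'   Switch off for data known to be batch-free.
#' @param fixed_hyper optional named list fixing `mu_F`, `mu_N`,
#'   `sigma_F`, `sigma_N`, `tau` (and optionally `nu`; `Inf` selects
#'   Gaussian errors) at known values, so only `z` and `theta` are
#'   sampled. Used for validation against closed-form posteriors.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `varcall_fit`: posterior summaries of the
#'   component parameters, batch effects, per-variant `pp` (posterior
#'   probability of pathogenicity), `theta` summaries, convergence
#'   diagnostics (`rhat`, `ess`, `converged`) and the spec used.
#' @export
fit_varcall <- function(harmonized, variants, spec = varcall_spec(),
                        include_batch = TRUE, fixed_hyper = NULL,
                        quiet = TRUE) {
  obs <- harmonized$observations
  stopifnot(!is.null(obs$rescaled_score))
  ids <- intersect(variants$variant_id, unique(obs$variant_id))
  if (length(ids) == 0L) stop("no variants with observations")
  obs <- obs[obs$variant_id %in% ids, , drop = FALSE]
  cons <- variants$consequence[match(ids, variants$variant_id)]
  if (!any(cons == "synonymous")) stop("no synonymous (silent) controls in the data")
  if (!any(cons == "nonsense")) stop("no nonsense controls in the data")

  v <- match(obs$variant_id, ids)
  y <- obs$rescaled_score
  z_data <- ifelse(cons == "synonymous", 0L,
                   ifelse(cons == "nonsense", 1L, NA_integer_))

  m0F <- stats::median(y[cons[v] == "synonymous"])
  m0N <- stats::median(y[cons[v] == "nonsense"])
  s_all <- stats::sd(y)

  fixed <- !is.null(fixed_hyper)
  gaussian <- fixed && !is.null(fixed_hyper$nu) && is.infinite(fixed_hyper$nu)
  data <- list(y = y, v = v, N = length(y), V = length(ids),
               prior_p = spec$prior_pathogenic, z = z_data)
  if (include_batch) {
    batch <- factor(paste(obs$assay, obs$replicate, obs$exon, sep = ":"))
    data$batch <- as.integer(batch)
    data$B <- nlevels(batch)
  }
  if (fixed) {
    need <- c("mu_F", "mu_N", "sigma_F", "sigma_N", "tau")
    miss <- setdiff(need, names(fixed_hyper))
    if (length(miss)) stop("fixed_hyper must supply: ", paste(miss, collapse = ", "))
    data$mu_F <- fixed_hyper$mu_F; data$mu_N <- fixed_hyper$mu_N
    data$sigma_F <- fixed_hyper$sigma_F; data$sigma_N <- fixed_hyper$sigma_N
    data$tau <- fixed_hyper$tau
    if (!gaussian && !is.null(fixed_hyper$nu)) data$nu <- fixed_hyper$nu
    if (!gaussian && is.null(fixed_hyper$nu)) stop("fixed_hyper must supply nu (Inf for Gaussian errors)")
  } else {
    data$m0F <- m0F
    data$d0 <- max(m0F - m0N, 0.1)
    data$prec0 <- (2 * s_all)^-2
    data$prec_hn <- s_all^-2
  }

  # deterministic inits; chains differ through their RNG streams
  ybar <- tapply(y, v, mean)
  theta0 <- as.numeric(ybar[as.character(seq_along(ids))])
  mid <- (m0F + m0N) / 2
  z0 <- ifelse(is.na(z_data), as.integer(theta0 < mid), NA_integer_)
  inits <- lapply(seq_len(spec$n_chains), function(ch) {
    ini <- list(theta = theta0, z = z0,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = spec$seed + ch)
    if (!fixed) {
      ini$mu_F <- m0F
      ini$delta <- max(m0F - m0N, 0.1)
      ini$sigma_F <- max(s_all / 4, 1e-3)
      ini$sigma_N <- max(s_all / 4, 1e-3)
      ini$tau <- max(s_all / 4, 1e-3)
    }
    ini
  })

  model_txt <- varcall_model_text(include_batch, fixed, gaussian)
  hyper_pars <- if (fixed) character(0) else {
    c("mu_F", "mu_N", "sigma_F", "sigma_N", "tau",
      if (!gaussian) "nu", if (include_batch) c("sd_b", "sd_g"))
  }
  monitors <- c("z", "theta", hyper_pars, if (include_batch) c("b", "g"))

  run <- function() {
    jm <- rjags::jags.model(textConnection(model_txt), data = data,
                            inits = inits, n.chains = spec$n_chains,
                            n.adapt = spec$n_adapt, quiet = quiet)
    update(jm, spec$n_warmup, progress.bar = "none")
    rjags::coda.samples(jm, variable.names = monitors, n.iter = spec$n_samples,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()

  all_mat <- do.call(rbind, lapply(samples, as.matrix))
  cols <- colnames(all_mat)
  pick <- function(prefix) {
    idx <- grep(paste0("^", prefix, "\\["), cols)
    m <- all_mat[, idx, drop = FALSE]
    ord <- order(as.integer(sub(".*\\[(\\d+)\\]", "\\1", cols[idx])))
    m[, ord, drop = FALSE]
  }
  z_mat <- pick("z")
  theta_mat <- pick("theta")
  pp <- colMeans(z_mat)
  names(pp) <- ids

  hyper <- NULL; rhat <- numeric(0); ess <- numeric(0)
  if (length(hyper_pars)) {
    hs <- lapply(samples, function(s) s[, hyper_pars, drop = FALSE])
    hs <- coda::as.mcmc.list(lapply(hs, coda::as.mcmc))
    gd <- coda::gelman.diag(hs, multivariate = FALSE, autoburnin = FALSE)
    rhat <- gd$psrf[, 1]; names(rhat) <- hyper_pars
    ess <- coda::effectiveSize(hs)[hyper_pars]
    hm <- all_mat[, hyper_pars, drop = FALSE]
    hyper <- data.frame(param = hyper_pars, mean = colMeans(hm),
                        median = apply(hm, 2, stats::median),
                        sd = apply(hm, 2, stats::sd),
                        rhat = unname(rhat), ess = unname(ess),
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  converged <- !length(rhat) ||
    (all(rhat <= spec$rhat_max, na.rm = TRUE) && all(ess >= spec$ess_min))

  batch_eff <- NULL
  if (include_batch) {
    b_mat <- pick("b"); g_mat <- pick("g")
    batch_eff <- data.frame(batch = levels(batch),
                            b_mean = colMeans(b_mat), g_mean = colMeans(g_mat),
                            row.names = NULL, stringsAsFactors = FALSE)
  }

  structure(list(
    variant_id = ids, pp = pp,
    theta_mean = stats::setNames(colMeans(theta_mat), ids),
    theta_sd = stats::setNames(apply(theta_mat, 2, stats::sd), ids),
    hyper = hyper, batch = batch_eff,
    consequence = cons,
    diagnostics = list(rhat = rhat, ess = ess, converged = converged,
                       n_draws = nrow(all_mat)),
    prior = spec$prior_pathogenic, spec = spec,
    include_batch = include_batch, fixed_hyper = fixed_hyper
  ), class = "varcall_fit")
}

#' @export
print.varcall_fit <- function(x, ...) {
  cat("Integrated VarCall fit:", length(x$pp), "variants,",
      x$diagnostics$n_draws, "posterior draws; converged:",
      x$diagnostics$converged, "\n")
  if (!is.null(x$hyper)) print(x$hyper, digits = 3)
  invisible(x)
}

#' Functional calls from a VarCall fit
#'
#' Converts per-variant posterior probabilities to Bayes factors (clamped
#' for fixed-indicator controls, see [posterior_to_bf()]) and assigns the
#' seven-level strength category.
#'
#' @param fit a `varcall_fit`.
#' @param odds_constant passed to [categorize_bf()].
#' @return data frame with `variant_id`, `pp`, `bf`, `category`, `model_tag`.
#' @export
varcall_calls <- function(fit, odds_constant = 350) {
  bf <- posterior_to_bf(fit$pp, fit$prior, n_draws = fit$diagnostics$n_draws)
  data.frame(variant_id = fit$variant_id, pp = unname(fit$pp),
             bf = unname(bf), category = categorize_bf(bf, odds_constant),
             model_tag = "varcall", stringsAsFactors = FALSE)
}

#' Prior-sensitivity analysis of the VarCall categories
#'
#' Refits the model under each prior with the same seed and reports the
#' fraction of variants whose seven-level category is identical.
#'
#' @param harmonized,variants,spec as in [fit_varcall()].
#' @param priors two prior probabilities of pathogenicity (default 0.2, 0.1).
#' @param ... passed to [fit_varcall()].
#' @return list with `concordance` (fraction identical), `table`
#'   (cross-tabulation of categories), and the two call tables.
#' @export
prior_sensitivity <- function(harmonized, variants, spec = varcall_spec(),
                              priors = c(0.2, 0.1), ...) {
  stopifnot(length(priors) == 2L)
  fits <- lapply(priors, function(p) {
    s <- spec; s$prior_pathogenic <- p
    fit_varcall(harmonized, variants, s, ...)
  })
  calls <- lapply(fits, varcall_calls)
  stopifnot(identical(calls[[1]]$variant_id, calls[[2]]$variant_id))
  same <- calls[[1]]$category == calls[[2]]$category
  lv <- CATEGORY_LEVELS
  list(concordance = mean(same),
       table = table(factor(calls[[1]]$category, lv),
                     factor(calls[[2]]$category, lv),
                     dnn = paste0("prior_", priors)),
       calls = calls, priors = priors)
}

#' Write VarCall convergence diagnostics to JSON
#'
#' @param fit a `varcall_fit`.
#' @param path output path (e.g. `varcall_diagnostics.json`).
#' @return invisibly, `path`.
#' @export
write_varcall_diagnostics <- function(fit, path) {
  d <- fit$diagnostics
  jsonlite::write_json(
    list(rhat = as.list(d$rhat), ess = as.list(d$ess),
         converged = d$converged, n_draws = d$n_draws),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
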