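quick_spec <- function(...) {
  varcall_spec(n_adapt = 300L, n_warmup = 300L, n_samples = 800L, ...)
}

test_that("spec validation rejects bad priors and chain counts", {
  expect_error(varcall_spec(prior_pathogenic = 0), "inside")
  expect_error(varcall_spec(prior_pathogenic = 1), "inside")
  expect_error(varcall_spec(n_chains = 1L), "n_chains")
})

test_that("control variants keep their fixed pathogenicity indicators", {
  scr <- simulate_screen(sim_config(n_variants = 80L, seed = 5L))
  h <- rescale_assay(scr$observations, scr$variants)
  fit <- fit_varcall(h, scr$variants, quick_spec())
  cons <- scr$variants$consequence[match(fit$variant_id, scr$variants$variant_id)]
  expect_true(all(fit$pp[cons == "synonymous"] == 0))
  expect_true(all(fit$pp[cons == "nonsense"] == 1))
  # and their categories are the extreme ones after BF capping
  calls <- varcall_calls(fit)
  expect_true(all(calls$category[cons == "synonymous"] == "B_Strong"))
  expect_true(all(calls$category[cons == "nonsense"] == "P_Strong"))
})

test_that("fitting requires both control classes", {
  scr <- simulate_screen(sim_config(n_variants = 80L, seed = 5L))
  h <- rescale_assay(scr$observations, scr$variants)
  keep <- scr$variants$consequence != "nonsense"
  expect_error(fit_varcall(h, scr$variants[keep, ], quick_spec()), "nonsense")
})

test_that("MCMC posterior matches the closed-form mixture responsibility", {
  # batch effects off, Gaussian errors, hyperparameters fixed at truth:
  # P(z=1 | y) has a closed form from the replicate-mean likelihood
  inst <- oracle_instance()
  fit <- oracle_varcall_fit()
  cfg <- inst$screen$config
  obs <- inst$harm$observations
  cons <- inst$screen$variants$consequence[
    match(fit$variant_id, inst$screen$variants$variant_id)]
  free <- !cons %in% c("synonymous", "nonsense")
  ybar <- tapply(obs$rescaled_score, factor(obs$variant_id, fit$variant_id), mean)
  nrep <- tapply(obs$rescaled_score, factor(obs$variant_id, fit$variant_id), length)
  oracle <- responsibility_oracle(
    as.numeric(ybar), as.numeric(nrep), fit$prior,
    cfg$mu_functional, cfg$mu_nonfunctional,
    cfg$sigma_functional, cfg$sigma_nonfunctional, cfg$residual_scale)
  expect_lt(max(abs(fit$pp[free] - oracle[free])), 0.02)
})

test_that("posterior pathogenicity is non-increasing in the mean rescaled score", {
  inst <- oracle_instance()
  fit <- oracle_varcall_fit()
  obs <- inst$harm$observations
  cons <- inst$screen$variants$consequence[
    match(fit$variant_id, inst$screen$variants$variant_id)]
  free <- !cons %in% c("synonymous", "nonsense")
  ybar <- as.numeric(tapply(obs$rescaled_score,
                            factor(obs$variant_id, fit$variant_id), mean))
  ord <- order(ybar[free])
  pp <- fit$pp[free][ord]
  # allow Monte Carlo jitter of the sampled probabilities
  expect_true(all(diff(pp) <= 0.02))
})

test_that("batch-effect SDs shrink towards zero when the data are batch-free", {
  cfg <- sim_config(n_variants = 300L, exon_ids = c("exA", "exB"), seed = 17L,
                    batch_location_sd = 0, batch_logscale_sd = 0,
                    missing_rate = 0)
  scr <- simulate_screen(cfg)
  h <- rescale_assay(scr$observations, scr$variants)
  fit <- fit_varcall(h, scr$variants, quick_spec())
  hy <- fit$hyper
  sd_b <- hy$median[hy$param == "sd_b"]
  tau <- hy$mean[hy$param == "tau"]
  expect_lt(sd_b, 0.1 * tau)
})

test_that("functional categories are stable across priors 0.2 and 0.1", {
  scr <- simulate_screen(sim_config(n_variants = 160L, seed = 23L))
  h <- rescale_assay(scr$observations, scr$variants)
  ps <- prior_sensitivity(h, scr$variants, quick_spec(), priors = c(0.2, 0.1))
  expect_gte(ps$concordance, 0.95)
  # identical priors are trivially fully concordant
  ps0 <- prior_sensitivity(h, scr$variants,
                           varcall_spec(n_adapt = 100L, n_warmup = 100L,
                                        n_samples = 200L),
                           priors = c(0.2, 0.2))
  expect_equal(ps0$concordance, 1.0)
})

test_that("diagnostics are attached and serialisable", {
  fit <- oracle_varcall_fit()
  expect_true(is.list(fit$diagnostics))
  expect_true(fit$diagnostics$converged)  # no free hyperparameters
  path <- withr::local_tempfile(fileext = ".json")
  write_varcall_diagnostics(fit, path)
  d <- jsonlite::read_json(path)
  expect_true(d$converged)
  expect_equal(d$n_draws, fit$diagnostics$n_draws)
})
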