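# Shared fixtures, computed lazily and cached for the whole test run so the
# expensive MCMC fits happen once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default well-separated 500-variant screen, seed-pinned
default_screen <- function() {
  memo("screen", simulate_screen(sim_config(seed = 7L)))
}

default_harmonized <- function() {
  memo("harm", {
    s <- default_screen()
    rescale_assay(s$observations, s$variants)
  })
}

default_varcall_fit <- function() {
  memo("vfit", fit_varcall(default_harmonized(), default_screen()$variants,
                           varcall_spec()))
}

default_varcall_calls <- function() {
  memo("vcalls", varcall_calls(default_varcall_fit()))
}

default_gmm_fit <- function() {
  memo("gfit", fit_gmm(default_harmonized(), default_screen()$variants,
                       seed = 7L))
}

default_gmm_calls <- function() {
  memo("gcalls", gmm_calls(default_gmm_fit()))
}

# control-enriched consequence mix for small fixtures, so both anchor
# classes carry enough variants at n = 25-50
small_mix <- c(synonymous = 0.3, nonsense = 0.2, missense = 0.5,
               canonical_splice = 0)

# a batch-free, distortion-free, near-Gaussian instance where the
# two-component posterior has a closed form
oracle_config <- function(n_variants = 50L) {
  sim_config(
    n_variants = n_variants, seed = 11L,
    consequence_mix = small_mix,
    batch_location_sd = 0, batch_logscale_sd = 0,
    assay_offset = 0, assay_scale = 1,
    t_df = 1e6, missing_rate = 0
  )
}

oracle_instance <- function() {
  memo("oracle", {
    scr <- simulate_screen(oracle_config())
    harm <- rescale_assay(scr$observations, scr$variants)
    list(screen = scr, harm = harm)
  })
}

oracle_varcall_fit <- function() {
  memo("oracle_fit", {
    inst <- oracle_instance()
    cfg <- inst$screen$config
    fit_varcall(
      inst$harm, inst$screen$variants,
      varcall_spec(n_adapt = 300L, n_warmup = 500L, n_samples = 3000L),
      include_batch = FALSE,
      fixed_hyper = list(mu_F = cfg$mu_functional, mu_N = cfg$mu_nonfunctional,
                         sigma_F = cfg$sigma_functional,
                         sigma_N = cfg$sigma_nonfunctional,
                         tau = cfg$residual_scale, nu = Inf)
    )
  })
}

# independent closed-form oracle: posterior responsibility of the
# non-functional component given the replicate mean, marginalising the
# latent effect analytically
responsibility_oracle <- function(ybar, n_rep, prior, mu_F, mu_N,
                                  sigma_F, sigma_N, tau) {
  dN <- stats::dnorm(ybar, mu_N, sqrt(sigma_N^2 + tau^2 / n_rep))
  dF <- stats::dnorm(ybar, mu_F, sqrt(sigma_F^2 + tau^2 / n_rep))
  prior * dN / (prior * dN + (1 - prior) * dF)
}

# EM vs exhaustive grid search on a small instance (memoized: used by both
# the module test and the acceptance suite)
gmm_grid_oracle <- function() {
  memo("grid", {
    scr <- simulate_screen(sim_config(n_variants = 25L, seed = 19L,
                                      consequence_mix = small_mix,
                                      missing_rate = 0))
    h <- rescale_assay(scr$observations, scr$variants)
    fit <- fit_gmm(h, scr$variants, seed = 19L)
    y <- fit$score
    ms <- seq(floor(min(y) * 20) / 20, ceiling(max(y) * 20) / 20, by = 0.05)
    ss <- seq(0.05, 0.5, by = 0.05)
    ws <- seq(0.05, 0.95, by = 0.05)
    comb <- expand.grid(m = ms, s = ss)
    dens <- vapply(seq_len(nrow(comb)),
                   function(i) stats::dnorm(y, comb$m[i], comb$s[i]),
                   numeric(length(y)))
    best_ll <- -Inf
    for (w in ws) {
      for (i in seq_len(nrow(comb))) {
        mix <- w * dens[, i] + (1 - w) * dens
        best_ll <- max(best_ll, max(colSums(log(mix))))
      }
    }
    list(fit_loglik = fit$loglik, grid_loglik = best_ll)
  })
}

# truth lookup helper
true_status_of <- function(screen, ids) {
  screen$truth$true_status[match(ids, screen$truth$variant_id)]
}

# Standard error for recovering a component mean from harmonized summary
# scores, from generator constants alone. Two contributions: sampling of
# the latent effects (sigma/sqrt(n)), and the common shift induced on the
# rescaled assay by anchor-median noise, which does not average out over
# variants. Residual/batch noise per observation (non-theta, since the
# same latent effects underlie both assays and cancel from the anchor
# contrast): tau^2 * nu/(nu-2) + batch_location_sd^2 + (|mu| * batch_logscale_sd)^2.
recovery_se <- function(screen, harm, component = c("nonfunctional", "functional")) {
  component <- match.arg(component)
  cfg <- screen$config
  mu <- if (component == "functional") cfg$mu_functional else cfg$mu_nonfunctional
  sigma <- if (component == "functional") cfg$sigma_functional else cfg$sigma_nonfunctional
  ctrl_class <- if (component == "functional") "synonymous" else "nonsense"
  n_comp <- sum(true_status_of(screen, screen$variants$variant_id) == component)

  obs <- harm$observations
  cons <- screen$variants$consequence[match(obs$variant_id, screen$variants$variant_id)]
  n_ref <- sum(cons == ctrl_class & obs$assay == harm$reference_assay)
  n_src <- sum(cons == ctrl_class & obs$assay == harm$source_assay)
  s_noise2 <- cfg$residual_scale^2 * cfg$t_df / (cfg$t_df - 2) +
    cfg$batch_location_sd^2 + (mu * cfg$batch_logscale_sd)^2
  anchor_var <- (pi / 2) * s_noise2 * (1 / n_ref + 1 / n_src)  # median efficiency
  tr <- true_status_of(screen, obs$variant_id)
  w_src <- mean(obs$assay[tr == component] == harm$source_assay)
  sqrt(sigma^2 / n_comp + w_src^2 * anchor_var)
}
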