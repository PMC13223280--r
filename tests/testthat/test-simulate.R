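test_that("config invariants are enforced", {
  expect_error(sim_config(consequence_mix = c(synonymous = 0.5, nonsense = 0.4,
                                              missense = 0.2, canonical_splice = 0)),
               "sum to 1")
  expect_error(sim_config(t_df = 2), "t_df")
  expect_error(sim_config(sigma_functional = 0), "SD")
  expect_error(sim_config(replicates_per_assay = c(A1 = 0L, A2 = 2L)), ">= 1")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("no dropout yields exactly sum-of-replicates observations per variant", {
  scr <- simulate_screen(sim_config(n_variants = 40L, missing_rate = 0, seed = 2L))
  counts <- table(scr$observations$variant_id)
  expect_length(counts, 40L)
  expect_true(all(counts == 5L))  # 3 + 2 replicates
})

test_that("a fixed seed makes the generator byte-identical across runs", {
  a <- simulate_screen(sim_config(n_variants = 60L, seed = 42L))
  b <- simulate_screen(sim_config(n_variants = 60L, seed = 42L))
  expect_identical(a$variants, b$variants)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99); before <- .Random.seed
  invisible(simulate_screen(sim_config(n_variants = 10L, seed = 5L)))
  expect_identical(.Random.seed, before)
})

test_that("control classes carry their known status and effects match components", {
  scr <- simulate_screen(sim_config(seed = 7L))
  tr <- scr$truth$true_status[match(scr$variants$variant_id, scr$truth$variant_id)]
  expect_true(all(tr[scr$variants$consequence == "synonymous"] == "functional"))
  expect_true(all(tr[scr$variants$consequence == "nonsense"] == "nonfunctional"))
})

test_that("with pure measurement noise the observation mean recovers theta", {
  # batch effects off, identity distortion, near-Gaussian noise, 50+50 replicates
  cfg <- sim_config(n_variants = 10L, seed = 31L,
                    replicates_per_assay = c(A1 = 50L, A2 = 50L),
                    batch_location_sd = 0, batch_logscale_sd = 0,
                    assay_offset = 0, assay_scale = 1, t_df = 1e6,
                    missing_rate = 0)
  scr <- suppressWarnings(simulate_screen(cfg))  # tiny n: some classes absent
  for (id in scr$variants$variant_id) {
    y <- scr$observations$raw_score[scr$observations$variant_id == id]
    se <- cfg$residual_scale / sqrt(length(y))
    theta <- scr$truth$true_effect[scr$truth$variant_id == id]
    expect_lt(abs(mean(y) - theta), 3 * se)
  }
})

test_that("pathogenic fraction among missense converges to the configured value", {
  cfg <- sim_config(n_variants = 4000L, seed = 13L)
  scr <- simulate_screen(cfg)
  mis <- scr$variants$consequence == "missense"
  tr <- true_status_of(scr, scr$variants$variant_id[mis])
  phat <- mean(tr == "nonfunctional")
  n <- sum(mis)
  ci <- cfg$frac_missense_pathogenic +
    c(-1, 1) * stats::qnorm(0.995) * sqrt(0.227 * 0.773 / n)
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})

test_that("fixture files round-trip all fields", {
  scr <- suppressWarnings(simulate_screen(sim_config(n_variants = 30L, seed = 3L)))
  dir <- withr::local_tempdir()
  write_fixture(scr, dir)
  back <- read_fixture(dir)
  expect_equal(back$variants$variant_id, scr$variants$variant_id)
  expect_equal(back$variants$bayesdel, scr$variants$bayesdel)
  expect_equal(back$variants$preassigned_codes, scr$variants$preassigned_codes)
  expect_equal(back$observations$raw_score, scr$observations$raw_score)
  expect_equal(back$truth$true_effect, scr$truth$true_effect)
})

test_that("a missing requested consequence class warns instead of failing", {
  w <- capture_warnings(simulate_screen(sim_config(n_variants = 5L, seed = 1L)))
  expect_true(any(grepl("consequence class", w)))
})

test_that("an empty variant set writes valid header-only files", {
  scr <- suppressWarnings(simulate_screen(sim_config(n_variants = 5L, seed = 1L)))
  empty <- list(variants = scr$variants[0, ],
                observations = scr$observations[0, ],
                truth = scr$truth[0, ])
  dir <- withr::local_tempdir()
  write_fixture(empty, dir)
  back <- read_fixture(dir)
  expect_equal(nrow(back$variants), 0L)
  expect_named(back$observations,
               c("variant_id", "assay", "replicate", "exon", "raw_score"))
})
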