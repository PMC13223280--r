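variant_row <- function(variant_id = "v1", consequence = "missense",
                        faf = NA_real_, bayesdel = NA_real_,
                        spliceai_flag = FALSE, preassigned_codes = "",
                        clinvar_standard = "none", hdr_standard = "none") {
  data.frame(variant_id = variant_id, consequence = consequence, faf = faf,
             bayesdel = bayesdel, spliceai_flag = spliceai_flag,
             preassigned_codes = preassigned_codes,
             clinvar_standard = clinvar_standard, hdr_standard = hdr_standard,
             stringsAsFactors = FALSE)
}

test_that("strength-to-points table and code parsing are consistent", {
  expect_equal(evidence_code("PVS1")$points, 8L)
  expect_equal(evidence_code("PS1")$points, 4L)
  expect_equal(evidence_code("PM3")$points, 2L)
  expect_equal(evidence_code("PP4")$points, 1L)
  expect_equal(evidence_code("BA1")$points, -8L)
  expect_equal(evidence_code("BS2")$points, -4L)
  expect_equal(evidence_code("BP7")$points, -1L)
  # suffix modulation overrides the prefix default
  expect_equal(evidence_code("PM2_Supporting")$points, 1L)
  expect_equal(evidence_code("BS1_Supporting")$points, -1L)
  expect_equal(evidence_code("PP4_Moderate")$points, 2L)
  expect_equal(evidence_code("BP7_Strong")$points, -4L)
  expect_error(evidence_code("XYZ1"), "unrecognised")
  pre <- parse_preassigned("PS1;PP4_Moderate")
  expect_equal(pre$points, c(4L, 2L))
  expect_true(all(pre$source == "preassigned"))
  expect_null(parse_preassigned(""))
})

test_that("functional categories map to PS3/BS3 capped at strong", {
  expect_equal(functional_evidence("P_Strong")$points, 4L)
  expect_equal(functional_evidence("P_Moderate")$points, 2L)
  expect_equal(functional_evidence("P_Supporting")$points, 1L)
  expect_equal(functional_evidence("B_Supporting")$points, -1L)
  expect_equal(functional_evidence("B_Moderate")$points, -2L)
  expect_equal(functional_evidence("B_Strong")$points, -4L)
  expect_null(functional_evidence("Uncertain"))
  expect_null(functional_evidence(NA))
  # the cap is structural: no category reaches +/-8
  for (cat in setdiff(CATEGORY_LEVELS, "Uncertain")) {
    expect_lte(abs(functional_evidence(cat)$points), 4L)
  }
})

test_that("frequency evidence follows the FAF thresholds", {
  expect_equal(frequency_evidence(0.002)$code, "BA1")
  expect_equal(frequency_evidence(0.0005)$code, "BS1")
  expect_equal(frequency_evidence(0.00005)$code, "BS1_Supporting")
  expect_null(frequency_evidence(0.00001))
  expect_equal(frequency_evidence(NA)$code, "PM2_Supporting")
  expect_equal(frequency_evidence(0)$code, "PM2_Supporting")
  expect_error(frequency_evidence(1.5), "0, 1")
})

test_that("in-silico evidence follows the BayesDel and splice rules", {
  expect_equal(insilico_evidence(0.35)$code, "PP3_Moderate")
  expect_equal(insilico_evidence(0.2, TRUE)$code, "PP3")
  expect_null(insilico_evidence(0.2, FALSE))     # between cutoffs
  expect_equal(insilico_evidence(0.05)$code, "BP4")
  expect_null(insilico_evidence(NA, FALSE))
})

test_that("point bands partition the integers at the printed boundaries", {
  expect_equal(classify_points(10), "P")
  expect_equal(classify_points(9), "LP")
  expect_equal(classify_points(6), "LP")
  expect_equal(classify_points(5), "VUS")
  expect_equal(classify_points(-1), "VUS")
  expect_equal(classify_points(-2), "LB")
  expect_equal(classify_points(-6), "LB")
  expect_equal(classify_points(-7), "B")
  cls <- classify_points(-30:30)
  expect_true(all(cls %in% c("B", "LB", "VUS", "LP", "P")))
  # bands are contiguous: class index is non-decreasing in points
  idx <- match(cls, c("B", "LB", "VUS", "LP", "P"))
  expect_true(all(diff(idx) >= 0))
})

test_that("brute force over code subsets agrees with the profile classifier", {
  # archetype codes, one per family plus preassigned extras
  pool <- c("PVS1", "PS3", "PM2_Supporting", "PP3_Moderate", "BS2", "BP5")
  pts <- c(8L, 4L, 1L, 2L, -4L, -1L)  # independent point table
  band <- function(total) {
    if (total >= 10) "P" else if (total >= 6) "LP" else if (total >= -1) "VUS"
    else if (total >= -6) "LB" else "B"
  }
  for (mask in 0:(2^6 - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:5)))
    expected_total <- sum(pts[sel])
    v <- variant_row(
      consequence = if (sel[1]) "nonsense" else "missense",
      faf = if (sel[3]) NA_real_ else 0.00001,
      bayesdel = if (sel[4]) 0.4 else NA_real_,
      preassigned_codes = paste(pool[c(FALSE, FALSE, FALSE, FALSE, sel[5:6])],
                                collapse = ";"))
    cat <- if (sel[2]) "P_Strong" else NA
    prof <- build_evidence_profile(v, cat)
    expect_equal(prof$total_points, expected_total)
    expect_equal(classify_variant(prof, cat)$class, band(expected_total))
  }
})

test_that("adding evidence moves the class monotonically in its polarity", {
  order_cls <- c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)
  for (base_pts in -12:12) {
    base_cls <- order_cls[[classify_points(base_pts)]]
    expect_gte(order_cls[[classify_points(base_pts + 2)]], base_cls)
    expect_lte(order_cls[[classify_points(base_pts - 2)]], base_cls)
  }
})

test_that("mutually exclusive codes raise an error naming the clash", {
  v <- variant_row(faf = NA_real_, preassigned_codes = "BA1")
  expect_error(build_evidence_profile(v, NA), "PM2_Supporting.*BA1")
})

test_that("the sample LP arithmetic holds: PVS1 + PM2_Supporting = 9 points", {
  v <- variant_row(consequence = "nonsense", faf = NA_real_)
  prof <- build_evidence_profile(v, NA, include_functional = FALSE)
  expect_equal(prof$total_points, 9L)
  expect_equal(classify_variant(prof)$class, "LP")
})

test_that("the discordance override fires only on opposite-side standards", {
  v <- variant_row(faf = NA_real_, bayesdel = 0.4, clinvar_standard = "B/LB")
  prof <- build_evidence_profile(v, "P_Strong")
  expect_equal(classify_variant(prof, "P_Strong", "B/LB", "none")$class,
               "VUS_discordant")
  # same evidence, no standard: points decide
  expect_equal(classify_variant(prof, "P_Strong", "none", "none")$class,
               classify_points(prof$total_points))
  # agreeing standard: no override
  expect_equal(classify_variant(prof, "P_Strong", "P/LP", "none")$class,
               classify_points(prof$total_points))
  # an Uncertain call never triggers it
  prof_u <- build_evidence_profile(v, NA)
  expect_false(classify_variant(prof_u, NA, "B/LB", "none")$class ==
                 "VUS_discordant")
  # HDR conflicts too
  expect_equal(classify_variant(prof, "P_Strong", "none", "normal")$class,
               "VUS_discordant")
})

test_that("run_classification emits both runs and sensible summaries", {
  # functional evidence only: the without-functional run is all VUS
  ids <- sprintf("v%02d", 1:6)
  vs <- do.call(rbind, lapply(ids, function(i)
    variant_row(variant_id = i, faf = 0.00001, bayesdel = 0.2)))
  calls <- data.frame(variant_id = ids,
                      category = rep(c("P_Strong", "B_Strong"), 3),
                      stringsAsFactors = FALSE)
  rc <- run_classification(vs, calls)
  expect_true(all(rc$classifications$class_without_functional == "VUS"))

  # BA1 everywhere: benign in both runs
  vs_ba1 <- do.call(rbind, lapply(ids, function(i)
    variant_row(variant_id = i, faf = 0.01)))
  rc2 <- run_classification(vs_ba1, calls[0, ])
  expect_true(all(rc2$classifications$class_with_functional == "B"))
  expect_true(all(rc2$classifications$class_without_functional == "B"))

  # mixed fixture: functional data strictly increases the classified fraction
  vs_mix <- do.call(rbind, lapply(ids, function(i)
    variant_row(variant_id = i, faf = NA_real_, bayesdel = 0.4)))
  calls_mix <- data.frame(variant_id = ids, category = "P_Strong",
                          stringsAsFactors = FALSE)
  rc3 <- run_classification(vs_mix, calls_mix)
  expect_gt(rc3$summary$classified_fraction_with,
            rc3$summary$classified_fraction_without)
})
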