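test_that("skew correction follows odds algebra and fixes its landmarks", {
  # identity calibration: a 50-reading standard changes nothing
  expect_equal(skew_correct(73, 50), 73)
  # the standard itself maps to exactly 50
  expect_equal(skew_correct(200 / 3, 200 / 3), 50)
  # 2x skewed standard (reads 66.667), raw 75: odds 3 / 2 = 1.5 -> 60
  expect_equal(skew_correct(75, 200 / 3), 60)
  # endpoints pass through unchanged
  expect_equal(skew_correct(c(0, 100), 70), c(0, 100))

  expect_error(skew_correct(50, 0), class = "methtrace_calibration_error")
  expect_error(skew_correct(50, 100), class = "methtrace_calibration_error")
  expect_error(skew_correct(120, 50), "0, 100")
})

test_that("skew correction is strictly increasing and inverts the generator", {
  std <- 65
  x <- seq(0, 100, by = 0.5)
  y <- skew_correct(x, std)
  expect_true(all(diff(y) > 0))

  # composing correction with the generative odds skew recovers the true
  # fraction exactly at zero noise, over a grid of fractions and skews
  for (s in c(0.25, 0.5, 1, 2, 4)) {
    f <- seq(0.01, 0.99, by = 0.01)
    cfg <- allelotype_config(seed = 1, snp_ids = sprintf("s%02d", seq_along(f)),
                             true_maternal_fraction = f, skew_ratio = s,
                             noise_sd = 0, n_replicates = 1)
    sim <- simulate_allelotypes(cfg)
    het <- sim$standards$observed_maternal_pct[sim$standards$kind == "het_dna"]
    corrected <- skew_correct(sim$measurements$raw_maternal_pct, het)
    expect_equal(corrected, 100 * f, tolerance = 1e-9)
  }
})

test_that("mixing-series linearity is exact for clean and skew-corrected series", {
  pts <- c(0, 10, 30, 50, 70, 90, 100)
  # noise-free, skew-free series
  lin <- linearity_check(pts, pts)
  expect_equal(lin$slope, 1)
  expect_equal(lin$intercept, 0, tolerance = 1e-12)
  expect_equal(lin$r_squared, 1)
  expect_true(lin$qc_pass)

  # 2x skew then correction: closed-form odds transform at the 7 points
  cfg <- allelotype_config(seed = 1, skew_ratio = 2, noise_sd = 0)
  sim <- simulate_allelotypes(cfg)
  std <- sim$standards
  mix <- std[std$kind == "mixing_point", ]
  het <- std$observed_maternal_pct[std$kind == "het_dna"]
  corrected <- skew_correct(mix$observed_maternal_pct, het)
  lin2 <- linearity_check(mix$true_maternal_pct, corrected)
  expect_equal(lin2$r_squared, 1, tolerance = 1e-12)
  expect_gt(lin2$slope, 0.9)
  expect_lt(lin2$slope, 1.1)

  # constant observations: undefined R^2, QC failure
  lin3 <- linearity_check(pts, rep(42, 7))
  expect_true(is.na(lin3$r_squared))
  expect_false(lin3$qc_pass)

  expect_error(linearity_check(c(0, 100), c(0, 100)), "3 distinct")
})

test_that("Bonferroni thresholds reproduce the published families", {
  expect_equal(bonferroni_alpha(0.05, 28)$threshold, 0.0018)
  expect_equal(bonferroni_alpha(0.05, 56)$threshold, 0.0009)
  expect_equal(bonferroni_alpha(0.05, 33)$threshold, 0.0015)
  expect_equal(bonferroni_alpha(0.05, 1)$threshold, 0.05)
  # identity before rounding
  for (m in c(1, 7, 28, 33, 56, 101)) {
    expect_equal(bonferroni_alpha(0.05, m)$exact * m, 0.05)
  }
  expect_error(bonferroni_alpha(0.05, 0), class = "methtrace_config_error")
})

test_that("baseline classification partitions [0, 100] with inclusive cutoffs", {
  expect_identical(classify_baseline(c(100, 5, 73)), c("MAT", "PAT", "NO"))
  expect_identical(classify_baseline(c(80, 20)), c("MAT", "PAT"))
  expect_identical(classify_baseline(c(79.99, 20.01)), c("NO", "NO"))
  # no gaps, no overlaps over a fine grid
  grid <- seq(0, 100, by = 0.25)
  cls <- classify_baseline(grid)
  expect_true(all(cls %in% c("MAT", "PAT", "NO")))
  expect_identical(cls, ifelse(grid >= 80, "MAT",
                               ifelse(grid <= 20, "PAT", "NO")))
  expect_error(classify_baseline(101), "0, 100")
})

test_that("compare_groups reproduces published table logic", {
  rows <- dplyr::bind_rows(
    # strongly affected, maternally imprinted at baseline (oil 100 -> 77)
    tibble::tibble(snp_id = "Peg10", organ = "placenta",
                   treatment = rep(c("oil", "VZ"), each = 3),
                   maternal_pct = c(100, 100, 100, reps_with_mean(76.6))),
    # paternally imprinted baseline, small but significant gain (5 -> 10.1)
    tibble::tibble(snp_id = "IG-DMR", organ = "lung",
                   treatment = rep(c("oil", "VZ"), each = 3),
                   maternal_pct = c(reps_with_mean(5, 0.5),
                                    reps_with_mean(10.1, 0.5))),
    # no baseline imprint (oil 73), moderate significant decrease
    tibble::tibble(snp_id = "Zac1", organ = "placenta",
                   treatment = rep(c("oil", "VZ"), each = 3),
                   maternal_pct = c(reps_with_mean(73, 0.5),
                                    reps_with_mean(67.1, 0.5)))
  )
  rows$replicate <- rep(1:3, 6)
  res <- compare_groups(rows, family_size = 28)
  res <- res[order(res$snp_id), ]

  peg10 <- res[res$snp_id == "Peg10", ]
  expect_identical(peg10$baseline, "MAT")
  expect_identical(peg10$flag, "gt10")
  expect_equal(peg10$difference_pct, -23.4)
  expect_identical(peg10$mean_control, 100)

  igdmr <- res[res$snp_id == "IG-DMR", ]
  expect_identical(igdmr$baseline, "PAT")
  expect_identical(igdmr$flag, "gt5")
  expect_equal(igdmr$difference_pct, 5.1)

  zac1 <- res[res$snp_id == "Zac1", ]
  expect_identical(zac1$baseline, "NO")
  expect_identical(zac1$flag, "gt5")
  expect_equal(zac1$difference_pct, -5.9, tolerance = 1e-9)

  # none of these single-family rows clears 0.05/28 unless p is tiny
  expect_identical(res$bonferroni_significant, res$p_value < 0.05 / 28)
})

test_that("compare_groups enforces the joint flag condition and design checks", {
  base <- tibble::tibble(
    snp_id = "s1", organ = "liver",
    treatment = rep(c("oil", "BPA"), each = 3),
    replicate = rep(1:3, 2),
    maternal_pct = c(50, 60, 70, 56, 66, 76)
  )
  # difference 6 but p well above 0.05: flag none
  res <- compare_groups(base, family_size = 10)
  expect_equal(res$difference_pct, 6)
  expect_gt(res$p_value, 0.05)
  expect_identical(res$flag, "none")

  # identical replicates: difference 0, flag none, p = 1
  same <- base
  same$maternal_pct <- rep(c(50, 60, 70), 2)
  res2 <- compare_groups(same, family_size = 10)
  expect_equal(res2$difference_pct, 0)
  expect_identical(res2$flag, "none")

  # missing control stratum errors
  no_oil <- base[base$treatment != "oil", ]
  expect_error(compare_groups(no_oil, family_size = 10), "control")
})
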