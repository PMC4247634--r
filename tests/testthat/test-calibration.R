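test_that("equal-width bands use half-open intervals with a closed final band", {
  pairs <- data.frame(risk = c(0.05, 0.15, 0.95), outcome = c(0, 0, 1))
  b <- band_equal_width(pairs, 10)
  expect_equal(nrow(b), 10)
  expect_equal(b$n_patients, c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1))
  # boundary value 0.10 belongs to [0.10, 0.20)
  b2 <- band_equal_width(data.frame(risk = 0.10, outcome = 0), 10)
  expect_equal(which(b2$n_patients == 1), 2L)
  expect_error(band_equal_width(pairs, 1), "k must be")
})

test_that("both banding schemes conserve episodes and deaths exactly", {
  set.seed(23)
  ch <- generate_cohort(cohort_spec(n = 800, lambda = 0.5, seed = 23))
  pairs <- score_cohort(possum_model(), ch)
  for (b in list(band_equal_width(pairs, 10),
                 band_equal_expected(pairs, 10))) {
    expect_equal(sum(b$n_patients), nrow(pairs))
    expect_equal(sum(b$observed_deaths), sum(pairs$outcome))
    expect_equal(sum(b$expected_deaths), sum(pairs$risk), tolerance = 1e-12)
  }
})

test_that("equal-expected banding splits at cumulative thresholds, never ties", {
  pairs <- data.frame(risk = c(0.1, 0.1, 0.4, 0.4), outcome = c(0, 0, 1, 1))
  expect_warning(b <- band_equal_expected(pairs, 2), "below 5")
  expect_equal(b$n_patients, c(2, 2))
  expect_equal(b$expected_deaths, c(0.2, 0.8))
  expect_error(band_equal_expected(pairs, 1), "k must be")
  # k cannot exceed the number of distinct risks
  expect_error(suppressWarnings(band_equal_expected(pairs, 3)), "distinct")
  # near-identical distinct risks -> band sizes equal to within one episode
  u <- data.frame(risk = 0.3 + (1:12) * 1e-6, outcome = 0)
  expect_warning(bu <- band_equal_expected(u, 4), "below 5")
  expect_equal(sum(bu$n_patients), 12)
  expect_true(all(abs(bu$n_patients - 3) <= 1))
})

test_that("HL component matches printed band cells and its simplified form", {
  # stable rows of the published POSSUM / P-POSSUM decile tables
  expect_equal(round(hl_component(1501, 15, 71.96), 2), 47.36)
  expect_equal(round(hl_component(216, 16, 52.36), 2), 33.33)
  expect_equal(round(hl_component(133, 9, 45.64), 2), 44.78)
  expect_equal(round(hl_component(203, 19, 28.64), 2), 3.78)
  # perfectly calibrated band contributes nothing
  expect_equal(hl_component(100, 10, 10), 0)
  # two-cell form == simplified form
  set.seed(9)
  for (i in 1:50) {
    n <- sample(20:2000, 1); e <- runif(1, 0.5, n - 0.5); o <- sample(0:n, 1)
    expect_equal(hl_component(n, o, e), (o - e)^2 / (e * (1 - e / n)),
                 tolerance = 1e-10)
  }
  expect_error(hl_component(10, 5, 0), "degenerate")
  expect_error(hl_component(10, 5, 10), "degenerate")
})

test_that("HL test sums components, uses g-2 df and the chi-square upper tail", {
  b <- fake_bands(rep(0.4503, 10))
  res <- hl_test(b)
  expect_equal(res$statistic, 4.503)
  expect_equal(res$df, 8L)
  expect_equal(round(res$p_value, 2), 0.81)
  expect_false(res$poor_fit)
  # zero statistic -> p = 1; df convention unchanged
  res0 <- hl_test(fake_bands(rep(0, 10)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$df, 8L)
  # external reference keeps all g degrees of freedom
  expect_equal(hl_test(b, df = "external")$df, 10L)
  # empty bands drop out of statistic and df
  b2 <- fake_bands(c(rep(1, 9), 0))
  b2$n_patients[10] <- 0; b2$expected_deaths[10] <- 0
  b2$hl_component[10] <- NA
  res2 <- hl_test(b2)
  expect_equal(res2$statistic, 9)
  expect_equal(res2$df, 7L)
  expect_error(hl_test(fake_bands(1)[integer(0), ]), "3 non-empty")
})

test_that("O:E ratios reproduce published totals with valid Poisson intervals", {
  ov_possum <- oe_ratio(88, 350.94)
  expect_equal(round(unname(ov_possum["ratio"]), 2), 0.25)
  ov_pposum <- oe_ratio(88, 162.35)
  expect_equal(round(unname(ov_pposum["ratio"]), 2), 0.54)
  expect_equal(round(unname(oe_ratio(15, 71.96)["ratio"]), 2), 0.21)
  expect_equal(round(unname(oe_ratio(19, 28.64)["ratio"]), 2), 0.66)
  # interval brackets the point estimate; lower bound 0 when o = 0
  expect_true(ov_possum["low"] < ov_possum["ratio"] &&
                ov_possum["ratio"] < ov_possum["high"])
  z <- oe_ratio(0, 5)
  expect_equal(unname(z["ratio"]), 0)
  expect_equal(unname(z["low"]), 0)
  expect_gt(z["high"], 0)
  expect_error(oe_ratio(5, 0), "positive")
})

test_that("exact Poisson O:E interval covers a true ratio of 1 at nominal rate", {
  set.seed(77)
  e <- 88
  covered <- vapply(1:1000, function(i) {
    ci <- oe_ratio(rpois(1, e), e)
    ci["low"] <= 1 && 1 <= ci["high"]
  }, TRUE)
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("calibration tables carry all columns, a pooled row and the HL total", {
  ch <- generate_cohort(cohort_spec(n = 1500, lambda = 1, seed = 3))
  tab <- calibration_table(possum_model(), ch, "equal_width", 10)
  expect_s3_class(tab, "calibration_table")
  expect_equal(sum(tab$bands$n_patients), 1500)
  expect_equal(tab$overall$n_patients, 1500)
  expect_equal(tab$overall$observed_deaths, sum(ch$died_30d))
  expect_equal(tab$overall$expected_deaths, sum(tab$bands$expected_deaths),
               tolerance = 1e-9)
  expect_equal(tab$hl$statistic,
               sum(tab$bands$hl_component[tab$bands$n_patients > 0]),
               tolerance = 1e-9)
  expect_error(calibration_table(possum_model(), ch, "equal_width", 1))
  md <- capture.output(print(tab))
  expect_true(any(grepl("0-100", md)))
})

test_that("an identity-distortion cohort is well calibrated; shrunken odds push O:E down", {
  # perfectly calibrated: most band O:E intervals cover 1
  ch <- generate_cohort(cohort_spec(n = 10000, lambda = 1, seed = 8))
  tab <- calibration_table(possum_model(), ch, "equal_width", 10)
  b <- tab$bands[tab$bands$n_patients > 0, ]
  covers <- b$oe_low <= 1 & 1 <= b$oe_high
  expect_gte(sum(covers), nrow(b) - 2)
  # odds halved at generation -> overall O:E significantly below 1
  ch2 <- generate_cohort(cohort_spec(n = 10000, lambda = 0.5, seed = 8))
  ov <- calibration_table(possum_model(), ch2, "equal_width", 10)$overall
  expect_lt(ov$oe_high, 1)
})

test_that("calibration curve rates and exact binomial intervals are consistent", {
  ch <- generate_cohort(cohort_spec(n = 1200, lambda = 1, seed = 14))
  bands <- band_equal_width(score_cohort(possum_model(), ch), 10)
  has_empty <- any(bands$n_patients == 0)
  cc <- if (has_empty) suppressWarnings(calibration_curve(bands))
        else calibration_curve(bands)
  b <- bands[bands$n_patients > 0, ]
  expect_equal(cc$observed_rate, b$observed_deaths / b$n_patients)
  expect_true(all(cc$ci_low <= cc$observed_rate & cc$observed_rate <= cc$ci_high))
  # saturated band: rate 1
  one <- fake_bands(0, n = 5, e = 4.5, o = 5)
  expect_equal(calibration_curve(one)$observed_rate, 1)
  # a published first-decile row: 15 deaths of 1501 is a rate just under 1%
  row <- fake_bands(47.36, n = 1501, e = 71.96, o = 15)
  expect_equal(calibration_curve(row)$observed_rate, 15 / 1501, tolerance = 1e-12)
})
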