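test_that("intercept-only and symmetric fits have closed-form solutions", {
  y <- rep(c(1, 0), c(25, 75))
  fit <- fit_logistic(matrix(nrow = 100, ncol = 0), y)
  expect_equal(unname(fit$coefficients), log(25 / 75), tolerance = 1e-8)
  expect_true(fit$converged)
  # balanced symmetric data: intercept 0, slope by symmetry
  x <- matrix(rep(c(-1, 1), 50), ncol = 1, dimnames = list(NULL, "x"))
  fit2 <- fit_logistic(x, rep(c(0, 1), 50))
  expect_equal(unname(fit2$coefficients["(Intercept)"]), 0, tolerance = 1e-8)
})

test_that("Newton-Raphson fit matches glm() in coefficients and SEs", {
  set.seed(101)
  for (i in 1:5) {
    n <- 400
    x <- cbind(a = rnorm(n), b = runif(n), c = rbinom(n, 1, 0.3))
    eta <- -1 + 0.8 * x[, "a"] - 1.2 * x[, "b"] + 0.5 * x[, "c"]
    y <- rbinom(n, 1, plogis(eta))
    fit <- fit_logistic(x, y)
    oracle <- glm(y ~ a + b + c, data = data.frame(x, y), family = binomial(),
                  control = glm.control(epsilon = 1e-12))
    expect_equal(unname(fit$coefficients[c("(Intercept)", "a", "b", "c")]),
                 unname(coef(oracle)[c("(Intercept)", "a", "b", "c")]),
                 tolerance = 1e-6)
    expect_equal(unname(fit$se),
                 unname(summary(oracle)$coefficients[names(fit$se), "Std. Error"]),
                 tolerance = 1e-6)
    expect_equal(fit$log_likelihood, as.numeric(logLik(oracle)),
                 tolerance = 1e-8)
  }
})

test_that("score equations hold at the optimum (calibrated-in-the-large)", {
  ch <- toy_cohort(300, seed = 41)
  rec <- derive_recalibrated_model(ch)
  x <- cbind(1, ch$ps, ch$os, as.numeric(ch$urgency == "non_elective"))
  resid <- ch$died_30d - rec$fit$fitted
  expect_lt(max(abs(crossprod(x, resid))), 1e-6)
  # hence expected deaths under the refit equal observed deaths: O:E = 1
  pairs <- score_cohort(rec$model, ch)
  expect_equal(sum(pairs$risk), sum(ch$died_30d), tolerance = 1e-6)
})

test_that("separation and degenerate inputs raise explicit errors", {
  x <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1, dimnames = list(NULL, "x"))
  y <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_logistic(x, y), "separat")
  expect_error(fit_logistic(x, rep(0, 20)), "single class")
  expect_error(fit_logistic(cbind(k = rep(2, 20)), y), "constant")
  expect_error(fit_logistic(x[1:20, , drop = FALSE], c(1, 2, rep(0, 18))),
               "binary")
})

test_that("coefficient table satisfies the OR and Wald-CI identities", {
  ch <- toy_cohort(400, seed = 55)
  fit <- derive_recalibrated_model(ch)$fit
  tab <- coefficient_table(fit)
  expect_equal(tab$odds_ratio, exp(tab$b), tolerance = 1e-9)
  z <- qnorm(0.975)
  expect_equal(tab$or_ci_low, exp(tab$b - z * tab$se), tolerance = 1e-9)
  expect_equal(tab$or_ci_high, exp(tab$b + z * tab$se), tolerance = 1e-9)
  expect_equal(tab$p, 2 * pnorm(-abs(tab$b / tab$se)), tolerance = 1e-12)
  # intercept renders last, clinical-report style
  expect_equal(tab$term[nrow(tab)], "(Intercept)")
  # published-style rounding: a log-odds of 0.144 is an OR of 1.155
  fake <- structure(list(coefficients = c(PScore = 0.144, OScore = 0.030,
                                          Emergency = -1.057),
                         se = c(PScore = 0.014, OScore = 0.021,
                                Emergency = 0.244),
                         converged = TRUE),
                    class = "logistic_fit")
  ft <- coefficient_table(fake)
  expect_true(all(abs(ft$odds_ratio - c(1.155, 1.031, 0.348)) <= 0.00101))
  expect_lte(abs(ft$or_ci_low[3] - 0.215), 0.00101)
  expect_lte(abs(ft$or_ci_high[3] - 0.561), 0.00101)
  # b = 0: OR 1, CI symmetric about 1 on the log scale
  f0 <- structure(list(coefficients = c(x = 0), se = c(x = 0.2),
                       converged = TRUE), class = "logistic_fit")
  t0 <- coefficient_table(f0)
  expect_equal(t0$odds_ratio, 1)
  expect_equal(t0$or_ci_low * t0$or_ci_high, 1, tolerance = 1e-12)
})

test_that("recalibration recovers the generating coefficients", {
  truth <- sposum_model()
  for (n in c(5000, 50000)) {
    ch <- generate_cohort(cohort_spec(n = n, truth_model = truth,
                                      lambda = 1, slope = 1, seed = 90125))
    rec <- derive_recalibrated_model(ch)
    b <- rec$fit$coefficients
    se <- rec$fit$se
    target <- c(`(Intercept)` = -6.505, PScore = 0.144, OScore = 0.03,
                Emergency = 1.057)
    expect_true(all(abs(b[names(target)] - target) <= 3 * se[names(target)]),
                label = sprintf("coefficients within 3 SE at n = %d", n))
  }
  # and the refit shows no lack of fit on its own training data
  expect_gt(rec$hl$p_value, 0.05)
})

test_that("reverse urgency coding flips the sign but yields the same risks", {
  ch <- toy_cohort(500, seed = 67)
  fwd <- derive_recalibrated_model(ch)
  rev <- derive_recalibrated_model(ch, reverse_urgency = TRUE)
  expect_equal(rev$coefficients$b[rev$coefficients$term == "Elective"],
               -fwd$coefficients$b[fwd$coefficients$term == "Emergency"],
               tolerance = 1e-6)
  # both parameterisations describe the same model
  expect_equal(score_cohort(rev$model, ch)$risk,
               score_cohort(fwd$model, ch)$risk, tolerance = 1e-6)
})

test_that("single-class cohorts cannot be recalibrated", {
  ch <- cohort(make_episodes(30, ps = 15:44, died = 0))
  expect_error(derive_recalibrated_model(ch), "single class")
})
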