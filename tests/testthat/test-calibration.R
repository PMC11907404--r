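test_that("fit_calibration recovers exact and flat lines", {
  cv <- fit_calibration(c(1, 2, 3), c(2, 4, 6))
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$r, 1)
  expect_true(cv$quantitative)

  expect_warning(flat <- fit_calibration(c(0, 1, 2), c(1, 1, 1)),
                 "non-quantitative")
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 1)
  expect_true(is.na(flat$r))
  expect_false(flat$quantitative)
})

test_that("fit_calibration rejects degenerate designs", {
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "degenerate")
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(fit_calibration(c(-1, 0, 1), c(1, 2, 3)), ">= 0")
})

test_that("fit_calibration matches the normal-equations oracle on random designs", {
  set.seed(41)
  for (i in 1:100) {
    x <- sort(runif(7, 0.25, 100))
    y <- 0.01 * x + 0.002 + rnorm(7, 0, 0.01)
    got <- fit_calibration(x, y)
    ref <- ols_oracle(x, y)
    expect_equal(got$slope, ref$slope, tolerance = 1e-10)
    expect_equal(got$intercept, ref$intercept, tolerance = 1e-10)
    expect_equal(got$r, ref$r, tolerance = 1e-10)
  }
})

test_that("predict_concentration inverts the line and flags zero slope", {
  cv <- fit_calibration(c(1, 2, 3), c(2, 4, 6))
  expect_equal(predict_concentration(cv, 4), 2)
  cv1 <- fit_calibration(c(0, 1, 2), c(1, 2, 3))
  expect_equal(predict_concentration(cv1, 1), 0)
  suppressWarnings(flat <- fit_calibration(c(0, 1, 2), c(1, 1, 1)))
  expect_error(predict_concentration(flat, 2), "zero slope")
})

test_that("detection limits follow the blank + k SD rule and its monotonicities", {
  cv <- fit_calibration(c(0, 5, 10), c(0, 5, 10)) # b = 1, a = 0
  lims <- detection_limits(cv, blank_stats(mean = 0, sd = 1, n = 10))
  expect_equal(unname(lims), c(3, 10))

  cv2 <- fit_calibration(c(0, 1, 2), c(0.5, 2.5, 4.5)) # b = 2, a = 0.5
  lims2 <- detection_limits(cv2, blank_stats(mean = 0.5, sd = 0, n = 5))
  expect_equal(unname(lims2), c(0, 0))

  # random inputs match the direct formula; lod <= loq throughout;
  # monotone in blank sd, antitone in slope
  set.seed(7)
  for (i in 1:50) {
    b <- runif(1, 0.5, 5); a <- runif(1, -0.1, 0.3)
    m <- runif(1, 0.3, 1); s <- runif(1, 0, 0.5)
    crv <- fit_calibration(c(0, 1, 2), a + b * c(0, 1, 2))
    got <- detection_limits(crv, blank_stats(mean = m, sd = s, n = 8))
    expect_equal(got[["lod"]], max(0, (m + 3 * s - a) / b), tolerance = 1e-9)
    expect_equal(got[["loq"]], max(0, (m + 10 * s - a) / b), tolerance = 1e-9)
    expect_lte(got[["lod"]], got[["loq"]])
    worse <- detection_limits(crv, blank_stats(mean = m, sd = s + 0.1, n = 8))
    expect_gte(worse[["lod"]], got[["lod"]])
    steeper <- fit_calibration(c(0, 1, 2), a + 2 * b * c(0, 1, 2))
    expect_lte(detection_limits(steeper, blank_stats(mean = m, sd = s, n = 8))[["lod"]],
               got[["lod"]])
  }
})

test_that("precision CV range and repeatability CV use sample SD over mean", {
  expect_equal(unname(precision_cv(list(c(10, 10), c(20, 20)))), c(0, 0))
  expect_equal(unname(precision_cv(list(c(9, 10, 11)))),
               rep(100 * sd(c(9, 10, 11)) / 10, 2))
  expect_error(precision_cv(list(c(-1, 1))), "zero mean")

  expect_equal(repeatability_cv(rep(5, 15)), 0)
  expect_equal(repeatability_cv(c(90, 100, 110)), 10)
  expect_error(repeatability_cv(c(-1, 1)), "zero mean")
  # day-mean variant collapses replicates first
  vals <- c(98, 100, 102, 109, 110, 111)
  day <- rep(1:2, each = 3)
  md <- tapply(vals, day, mean)
  expect_equal(repeatability_cv(vals, day, method = "day_means"),
               100 * sd(md) / mean(md))
})

test_that("simulated precision at CV 5 percent matches a sampling-theory oracle", {
  # Monte-Carlo calibration of precision_cv as an estimator at n = 3 over 7
  # levels, against an independent oracle built from the sampling
  # distributions directly: s ~ sigma * sqrt(chisq_2 / 2), xbar ~ N(mu,
  # sigma^2/3). Both the mean per-level estimate and the coverage of the
  # max-CV inside [2, 9] % must agree with the oracle within MC error.
  n_runs <- 1000
  set.seed(11)
  got_max <- replicate(n_runs, {
    precision_cv(lapply(1:7, function(l) rnorm(3, 100, 5)))[["max"]]
  })
  set.seed(12)
  oracle_max <- replicate(n_runs, {
    max(100 * (5 * sqrt(rchisq(7, 2) / 2)) / rnorm(7, 100, 5 / sqrt(3)))
  })
  expect_lt(abs(mean(got_max) - mean(oracle_max)), 0.5)
  cover_got <- mean(got_max >= 2 & got_max <= 9)
  cover_oracle <- mean(oracle_max >= 2 & oracle_max <= 9)
  expect_lt(abs(cover_got - cover_oracle), 0.06)
  # and the per-level estimate is centred near the true 5 % CV
  set.seed(13)
  all_cv <- replicate(200, precision_cv(lapply(1:7, function(l) rnorm(3, 100, 5))))
  expect_gt(mean(all_cv), 3.5)
  expect_lt(mean(all_cv), 5.5)
})

test_that("recovery and trueness t-test behave as the validation protocol", {
  crm <- crm_reference("Cr", 1.69, 0.13)
  expect_equal(recovery(1.69, crm), 100)
  expect_equal(recovery(1.521, crm), 90)
  expect_equal(recovery(0, crm), 0)
  expect_error(crm_reference("Cr", 0), "positive")

  expect_equal(trueness_t_test(c(100, 100, 100))$t_calc, 0)
  expect_true(trueness_t_test(c(98, 100, 102))$pass)
  r <- c(95, 97, 99)
  tt <- trueness_t_test(r)
  expect_equal(tt$t_calc, (mean(r) - 100) / (sd(r) / sqrt(3)))
  # zero-SD off-reference recoveries are an automatic fail
  expect_false(trueness_t_test(c(90, 90, 90))$pass)
})

test_that("uncertainty budget is the k-expanded root sum of squares", {
  expect_equal(uncertainty_budget(3, 4), 10)
  expect_equal(uncertainty_budget(5, 0), 10)
  expect_equal(uncertainty_budget(2.1, 6.1), 2 * sqrt(2.1^2 + 6.1^2))
})

test_that("censoring keeps the numeric value but labels below-LOQ cells", {
  out <- censor_below_loq(c(0.1, 5), loq = 1)
  expect_equal(out$censored, c(TRUE, FALSE))
  expect_equal(out$value, c(0.1, 5))
  expect_equal(out$label[1], "<LOQ")
})

test_that("validation_report assembles a coherent per-element table", {
  cfg <- generator_config(seed = 302)
  st <- generate_study(cfg)
  crm_vals <- setNames(crm_certified_values()$certified,
                       crm_certified_values()$element)
  vr <- validation_report(st$observed$calibration, st$observed$blanks,
                          st$observed$crm[, c("element", "content")], crm_vals)
  expect_equal(nrow(vr), nrow(st$config$instrument))
  expect_true(all(vr$lod_ng_mL <= vr$loq_ng_mL))
  expect_true(all(vr$r > 0.99))
  expect_true(all(vr$recovery_mean > 80 & vr$recovery_mean < 120))
  expect_true(all(vr$expanded_U >= 0))
})
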