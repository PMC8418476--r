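test_that("fit_increment_model recovers an exact line", {
  hi <- c(6, 10, 25, 80, 200)
  fit <- fit_increment_model(hi, 2 * hi + 1)
  expect_equal(coef(fit), c(intercept = 1, slope = 2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 5L)
  expect_equal(predict(fit, hi = 11), 23)
})

test_that("least squares agrees with the normal-equations oracle", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- runif(n, 6, 400)
    y <- 0.3 * x + rnorm(n, 0, 5)
    fit <- fit_increment_model(x, y, hi_filter = -Inf)
    expect_equal(unname(coef(fit)), unname(ols_oracle(x, y)),
                 tolerance = 1e-9)
  }
})

test_that("HI filtering and degenerate designs are handled", {
  # points at or below the filter are excluded
  fit <- fit_increment_model(c(2, 5, 10, 20), c(99, 99, 3.9, 6.8),
                             hi_filter = 5)
  expect_equal(fit$n_points, 2L)
  expect_equal(unname(coef(fit)), c(1, 0.29), tolerance = 1e-9)

  expect_error(fit_increment_model(c(10, 10), c(1, 2)), "degenerate")
  expect_error(fit_increment_model(c(2, 3, 10), c(1, 1, 1), hi_filter = 5),
               "fewer than 2")
  expect_error(fit_increment_model(c(10, NA), c(1, 2)), "finite")
})

test_that("personalization rescales and round-trips the generic equation", {
  gen <- increment_model(slope = 0.2757, intercept = 0.9793)
  per <- personalize(gen, donor_r = 0.31)

  # reported coefficients at printed precision
  expect_equal(signif(per$slope_per_r, 3), 0.889)
  expect_equal(signif(per$intercept_per_r, 4), 3.159)

  # multiplying back recovers the generic coefficients
  expect_equal(per$slope_per_r * 0.31, 0.2757, tolerance = 1e-9)
  expect_equal(per$intercept_per_r * 0.31, 0.9793, tolerance = 1e-9)

  # identity at R = 1
  id <- personalize(increment_model(1.7, -0.2), donor_r = 1)
  expect_equal(c(id$slope_per_r, id$intercept_per_r), c(1.7, -0.2))

  # evaluated at r = donor R the personalized model reproduces the line
  hi <- seq(6, 500, length.out = 40)
  expect_equal(predict(per, hi = hi, r = 0.31), predict(gen, hi = hi),
               tolerance = 1e-9)

  expect_error(personalize(gen, donor_r = 0), "not personalizable")
})

test_that("measure_ratio divides lysate NSE by HI and is dilution invariant", {
  expect_equal(measure_ratio(155, 500), 0.31)
  expect_equal(measure_ratio(0, 100), 0)
  expect_equal(measure_ratio(155 / 2, 500 / 2), measure_ratio(155, 500))
  expect_error(measure_ratio(10, 0), "positive")
  expect_error(measure_ratio(400, 500), "re-dilute")
})

test_that("correct_nse subtracts the personalized increment and clamps", {
  per <- reported_model()
  res <- correct_nse(20.0, 11, r = 0.31, model = per)
  expect_equal(round(res$increment, 1), 4.0)  # false elevation at HI 11
  expect_equal(res$nse_corr, 20.0 - res$increment)
  expect_false(res$clamped)

  # r = 0: red cells contribute nothing
  res0 <- correct_nse(20.0, 11, r = 0, model = per)
  expect_equal(res0$increment, 0)
  expect_equal(res0$nse_corr, 20.0)

  # floor clamp with the reported personalized coefficients
  lit <- personalize(increment_model(0.889, 3.159), donor_r = 1)
  resf <- correct_nse(1.0, 100, r = 0.4, model = lit)
  expect_equal(round(resf$increment, 2), 36.82)
  expect_equal(resf$nse_corr, 0.05)
  expect_true(resf$clamped)

  expect_error(correct_nse(-1, 10, 0.3, per), "negative")
  expect_error(correct_nse(10, 10, NA, per), "required")
})

test_that("corrected NSE is monotone nonincreasing in HI and in R", {
  per <- reported_model()
  hi <- seq(6, 300, by = 7)
  corr_hi <- correct_nse(300, hi, r = 0.3, model = per)$nse_corr
  expect_true(all(diff(corr_hi) <= 0))
  r <- seq(0, 0.467, length.out = 30)
  corr_r <- correct_nse(300, 50, r = r, model = per)$nse_corr
  expect_true(all(diff(corr_r) <= 0))
})

test_that("model JSON serialization round-trips the coefficients", {
  f <- withr::local_tempfile(fileext = ".json")
  fit <- fit_increment_model(c(6, 10, 25, 80), c(2.9, 4.1, 8.6, 25.3))
  per <- personalize(fit, donor_r = 0.31)
  write_model_json(per, f, fit = fit)
  back <- read_model_json(f)
  expect_equal(back$slope_per_r, per$slope_per_r)
  expect_equal(back$intercept_per_r, per$intercept_per_r)
  expect_equal(back$donor_r, per$donor_r)
})

test_that("spiking CSV reader computes increments in both x modes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pool_id,aliquot,hi_meas,nse_meas,baseline_hi,baseline_nse",
               "p1,2,52,25.5,2,10.0",
               "p1,3,27,18.1,2,10.0"), f)
  tab <- read_spiking_csv(f)
  expect_equal(tab$hi, c(52, 27))
  expect_equal(tab$increment, c(15.5, 8.1))
  tab2 <- read_spiking_csv(f, x = "delta_hi")
  expect_equal(tab2$hi, c(50, 25))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pool,hi,nse", "p1,1,2"), f2)
  expect_error(read_spiking_csv(f2), "expected header")
})
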