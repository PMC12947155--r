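test_that("published coefficients evaluate exactly as printed", {
  pub <- published_models()
  expect_equal(predict_hct(pub$literature, 50), 0.51 * 50 + 17.4)
  expect_equal(predict_hct(pub$baseline, 48.7), 0.864 * 48.7 - 2.09)
  expect_identical(pub$literature$slope, 0.51)
  expect_identical(pub$literature$intercept, 17.4)
  expect_identical(pub$baseline$slope, 0.864)
  expect_identical(pub$baseline$intercept, -2.09)
  expect_identical(pub$male_low_bmi$slope, 1.16)
  expect_identical(pub$male_high_bmi$intercept, 8.38)
  expect_identical(pub$female_high_bmi$intercept, 8.19)
  expect_length(pub$combined$routes, 3)

  flat <- linear_hct_model(0, 40)
  expect_equal(predict_hct(flat, c(-100, 0, 500)), c(40, 40, 40))
  expect_error(predict_hct(flat, NaN), "finite")
})

test_that("fit_linear recovers exact lines and rejects degenerate designs", {
  x <- c(1, 2, 5, 9)
  fit <- fit_linear(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_fit, 4L)

  two <- fit_linear(c(40, 60), c(38, 46))
  expect_equal(two$slope, 0.4, tolerance = 1e-12)
  expect_equal(two$r_squared, 1)

  expect_error(fit_linear(c(5, 5, 5), c(1, 2, 3)), "constant")
  expect_error(fit_linear(3, 1), "3 points")
  expect_error(fit_linear(1:3, 1:4), "equal length")
})

test_that("fit_linear agrees with a grid-refinement least-squares oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(4:20, 1)
      x <- rnorm(n, 50, 5)
      y <- 0.9 * x - 5 + rnorm(n, 0, 3)
    })
    fit <- fit_linear(x, y)
    oracle <- ols_grid_oracle(x, y)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-6)
    expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-6)
  }
})

test_that("parameter recovery is unbiased under calibrated noise", {
  cohort <- generate_cohort(cohort_spec(n_male = 5000, n_female = 0), seed = 13)
  lo <- dplyr::filter(cohort, bmi < 30.7)
  fit <- stats::lm(I(hct * 100) ~ hu_blood, data = lo)
  se <- summary(fit)$coefficients["hu_blood", "Std. Error"]
  expect_lt(abs(coef(fit)[["hu_blood"]] - 1.16), 3 * se)
})

test_that("routing is deterministic, total, and boundary values go to the upper stratum", {
  combined <- published_models()$combined
  expect_identical(route(combined, "male", 25)$label, "male_low_bmi")
  expect_identical(route(combined, "male", 30.7)$label, "male_high_bmi")
  expect_identical(route(combined, "female", 22.4)$label, "female_high_bmi")
  expect_null(route(combined, "female", 20))

  with_fallback <- published_models(fallback = "baseline_model")$combined
  expect_identical(route(with_fallback, "female", 20)$label, "baseline")

  # total over a dense grid: exactly one outcome per (sex, bmi) pair
  for (sx in c("male", "female")) {
    for (b in seq(10, 60, by = 0.5)) {
      hits <- sum(vapply(combined$routes,
                         function(r) synecv:::predicate_matches(r[[1]], sx, b),
                         TRUE))
      expect_lte(hits, 1L)
      expect_identical(is.null(route(combined, sx, b)),
                       hits == 0L)
    }
  }

  expect_error(
    stratified_hct_model(list(
      list(model_predicate("male", -Inf, 31), linear_hct_model(1, 0)),
      list(model_predicate("male", 30, Inf), linear_hct_model(1, 0))
    )),
    "Overlapping"
  )
})

test_that("stratified prediction flags uncovered records as missing", {
  combined <- published_models()$combined
  pred <- predict_hct(combined, c(50, 50, 50),
                      sex = c("male", "female", "female"),
                      bmi = c(25, 30, 20))
  expect_equal(pred[1], 1.16 * 50 - 17.2)
  expect_equal(pred[2], 0.669 * 50 + 8.19)
  expect_true(is.na(pred[3]))
})

test_that("models round-trip through JSON with bit-exact coefficients", {
  pub <- published_models()
  for (nm in c("literature", "baseline", "male_low_bmi")) {
    path <- withr::local_tempfile(fileext = ".json")
    write_hct_model(pub[[nm]], path)
    back <- read_hct_model(path)
    expect_identical(back$slope, pub[[nm]]$slope)
    expect_identical(back$intercept, pub[[nm]]$intercept)
    expect_identical(back$label, pub[[nm]]$label)
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_hct_model(pub$combined, path)
  back <- read_hct_model(path)
  expect_identical(length(back$routes), 3L)
  for (i in 1:3) {
    expect_identical(back$routes[[i]][[2]]$slope, pub$combined$routes[[i]][[2]]$slope)
    expect_identical(back$routes[[i]][[1]]$bmi_low, pub$combined$routes[[i]][[1]]$bmi_low)
    expect_identical(back$routes[[i]][[1]]$bmi_high, pub$combined$routes[[i]][[1]]$bmi_high)
  }
  expect_identical(back$fallback, "flag_missing")
})

test_that("tidiers expose coefficients and diagnostics as tibbles", {
  fit <- fit_linear(c(45, 50, 55, 60), c(36, 40, 45, 49), label = "demo")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(glance(fit)$nobs, 4L)
  routes <- tidy(published_models()$combined)
  expect_equal(nrow(routes), 3)
  expect_named(routes, c("sex", "bmi_low", "bmi_high", "slope", "intercept",
                         "label", "n_fit", "r_squared"))
})
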