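test_that("the sex interaction term is exact under identical noise-free models", {
  sg <- tibble::tibble(
    sex = c("male", "female"), bmi_low = -Inf, bmi_high = Inf,
    slope = 0.9, intercept = -3, hct_mean = 40, hct_sd = 5, r_squared = 1
  )
  cohort <- generate_cohort(cohort_spec(100, 100, subgroups = sg), seed = 1)
  fit <- fit_interaction(cohort, "sex")
  expect_equal(fit$beta3_hat, 0, tolerance = 1e-10)
  expect_equal(fit$beta1_hat, 0.9, tolerance = 1e-10)
})

test_that("the sex interaction is detected with high power at the generator's effect size", {
  cohort <- generate_cohort(cohort_spec(n_male = 3500, n_female = 1500),
                            seed = 21)
  fit <- fit_interaction(cohort, "sex")
  expect_lt(fit$p_beta3, 0.001)
  expect_equal(fit$n, 5000L)
})

test_that("the interaction test holds its nominal type-I error under the null", {
  # both sexes share one true model: beta3 = 0 by construction
  spec <- cohort_spec(
    n_male = 70, n_female = 38,
    subgroups = tibble::tibble(
      sex = c("male", "female"), bmi_low = -Inf, bmi_high = Inf,
      slope = 0.864, intercept = -2.09, hct_mean = 40, hct_sd = 5,
      r_squared = 0.5
    )
  )
  n_rep <- 1000
  rejections <- sum(vapply(seq_len(n_rep), function(i) {
    fit_interaction(generate_cohort(spec, seed = 20000 + i), "sex")$p_beta3 < 0.05
  }, TRUE))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rejections / n_rep - 0.05), 2 * se + 1e-12)
})

test_that("degenerate interaction designs are rejected", {
  males <- generate_cohort(cohort_spec(n_male = 50, n_female = 0), seed = 1)
  expect_error(fit_interaction(males, "sex"), "does not vary")
  expect_error(fit_interaction(males[1:5, ], "sex"), "10 records")
})

test_that("bin search recovers the injected male BMI break as a two-bin split", {
  males <- generate_cohort(cohort_spec(n_male = 2000, n_female = 0), seed = 1)
  result <- bin_search(males, "bmi")
  expect_s3_class(result, "bin_search_result")
  expect_length(result$edges, 1)
  expect_lt(abs(result$edges - 30.7), 1.5)
  expect_equal(result$per_bin$slope[1], 1.16, tolerance = 0.1)
  expect_equal(result$per_bin$slope[2], 0.669, tolerance = 0.1)
  # gates hold on the returned configuration
  expect_true(all(result$per_bin$p_cor < result$alpha))
  expect_true(all(result$boundary_p < result$alpha))
})

test_that("bin search output is invariant to record order", {
  males <- generate_cohort(cohort_spec(n_male = 600, n_female = 0), seed = 4)
  shuffled <- males[withr::with_seed(1, sample(nrow(males))), ]
  a <- bin_search(males, "bmi")
  b <- bin_search(shuffled, "bmi")
  expect_equal(a$edges, b$edges)
  expect_equal(a$score, b$score)
  expect_equal(a$per_bin$slope, b$per_bin$slope)
})

test_that("bin search matches an independent lm/cor.test re-implementation", {
  males <- generate_cohort(cohort_spec(n_male = 200, n_female = 0), seed = 9)
  got <- bin_search(males, "bmi")
  oracle <- bin_search_oracle(males, "bmi")
  if (is.null(oracle)) {
    expect_null(got)
  } else {
    expect_equal(got$edges, oracle$edges, tolerance = 1e-12)
    expect_equal(got$score, oracle$score, tolerance = 1e-9)
  }
})

test_that("homogeneous data yields no split or one agreeing with the global fit", {
  cohort <- generate_cohort(single_line_spec(n_male = 800), seed = 6)
  result <- bin_search(cohort, "bmi")
  if (!is.null(result)) {
    global <- fit_linear(cohort$hu_blood, cohort$hct * 100)
    expect_true(all(abs(result$per_bin$slope - global$slope) < 0.2))
  } else {
    succeed()
  }
})

test_that("pure-noise haematocrit never yields a stratification", {
  for (seed in 1:5) {
    cohort <- noise_cohort(300, seed)
    expect_null(bin_search(cohort, "bmi"))
    expect_null(window_search(cohort, "bmi"))
  }
})

test_that("noise covariates are not retained on the default male cohort", {
  males <- generate_cohort(cohort_spec(n_male = 800, n_female = 0), seed = 15)
  for (cov in c("age", "egfr", "creatinine")) {
    expect_null(bin_search(males, cov))
  }
})

test_that("window search restricts females to the covered BMI range", {
  females <- generate_cohort(cohort_spec(n_male = 0, n_female = 1000),
                             seed = 101)
  result <- window_search(females, "bmi")
  expect_s3_class(result, "window_search_result")
  expect_lt(abs(result$low - 22.4), 1.5)
  expect_gt(result$high, quantile(females$bmi, 0.9))
  expect_lt(result$correlation_p, result$alpha)
  expect_equal(result$model$slope, 0.669, tolerance = 0.15)
})

test_that("a window over a clean linear cohort reproduces the global fit", {
  cohort <- generate_cohort(single_line_spec(n_male = 500), seed = 31)
  result <- window_search(cohort, "bmi")
  expect_s3_class(result, "window_search_result")
  global <- fit_linear(cohort$hu_blood, cohort$hct * 100)
  se <- 3 * sqrt(1 - 0.5) * 5 / (sd(cohort$hu_blood) * sqrt(result$n))
  expect_lt(abs(result$model$slope - global$slope), 3 * se + 0.05)
  expect_error(window_search(cohort, "bmi", width_fracs = numeric(0)),
               "non-empty")
})

test_that("search results serialize to JSON with their grid settings", {
  males <- generate_cohort(cohort_spec(n_male = 400, n_female = 0), seed = 2)
  result <- bin_search(males, "bmi")
  path <- withr::local_tempfile(fileext = ".json")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_search_result(result, path, report = txt)
  js <- jsonlite::read_json(path)
  if (is.null(result)) {
    expect_false(js$selected)
  } else {
    expect_true(js$selected)
    expect_identical(js$covariate, "bmi")
    expect_length(js$per_bin, nrow(result$per_bin))
    expect_true(file.exists(txt))
  }
  # the explicit no-result record
  path2 <- withr::local_tempfile(fileext = ".json")
  write_search_result(NULL, path2)
  expect_false(jsonlite::read_json(path2)$selected)
})
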