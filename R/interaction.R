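#' Test whether a covariate modifies the attenuation-haematocrit slope
#'
#' Fits the interaction regression
#' `Hct% = alpha + beta1 * HU_blood + beta2 * X + beta3 * (HU_blood * X)`
#' by OLS, where `X` is sex coded as a binary variable (male = 0,
#' female = 1) or a continuous covariate (`bmi`, `age`, `egfr`,
#' `creatinine`). The two-sided t-test P value of `beta3` decides whether
#' the covariate significantly modifies the calibration slope and therefore
#' warrants stratified models.
#'
#' @param cohort Cohort tibble with columns `hct` (fraction), `hu_blood`,
#'   and the covariate.
#' @param covariate One of `"sex"`, `"bmi"`, `"age"`, `"egfr"`,
#'   `"creatinine"`.
#' @return An object of class `interaction_fit` with elements `alpha_hat`,
#'   `beta1_hat`, `beta2_hat`, `beta3_hat`, `p_beta3`, `n`, `covariate`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(), seed = 1)
#' fit_interaction(cohort, "sex")
#' @export
fit_interaction <- function(cohort, covariate = "sex") {
  covariate <- match.arg(covariate, c("sex", "bmi", "age", "egfr", "creatinine"))
  if (nrow(cohort) < 10L) {
    stop("At least 10 records are required for the interaction fit.",
         call. = FALSE)
  }
  x <- if (covariate == "sex") {
    as.numeric(cohort$sex == "female")
  } else {
    cohort[[covariate]]
  }
  if (length(unique(x)) < 2L) {
    stop("Degenerate design: covariate `", covariate, "` does not vary.",
         call. = FALSE)
  }
  hu <- cohort$hu_blood
  y <- cohort$hct * 100
  fit <- stats::lm(y ~ hu * x)
  co <- stats::coef(fit)
  if (any(is.na(co))) {
    stop("Degenerate design: interaction model is rank deficient.",
         call. = FALSE)
  }
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(alpha_hat = co[["(Intercept)"]], beta1_hat = co[["hu"]],
         beta2_hat = co[["x"]], beta3_hat = co[["hu:x"]],
         p_beta3 = sm["hu:x", "Pr(>|t|)"], n = length(y),
         covariate = covariate),
    class = "interaction_fit"
  )
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("<interaction_fit> HU_blood x %s on n = %d\n", x$covariate, x$n))
  cat(sprintf("  beta3 = %.4g (interaction P = %.4g)\n", x$beta3_hat, x$p_beta3))
  invisible(x)
}

#' @method tidy interaction_fit
#' @export
tidy.interaction_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "hu_blood", x$covariate,
             paste0("hu_blood:", x$covariate)),
    estimate = c(x$alpha_hat, x$beta1_hat, x$beta2_hat, x$beta3_hat),
    p.value = c(NA_real_, NA_real_, NA_real_, x$p_beta3)
  )
}

#' @method glance interaction_fit
#' @export
glance.interaction_fit <- function(x, ...) {
  tibble::tibble(covariate = x$covariate, beta3 = x$beta3_hat,
                 p.beta3 = x$p_beta3, nobs = x$n)
}

# two-sided P value of the Pearson correlation between x and y
# (closed-form t test, identical to cor.test)
pearson_p <- function(x, y) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}
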