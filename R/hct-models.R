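#' Linear blood-pool attenuation to haematocrit model
#'
#' Constructs a univariable linear calibration model mapping mean pre-contrast
#' blood-pool attenuation (Hounsfield units) to haematocrit in percent.
#' Published models carry `n_fit = 0` and no fit diagnostics; models produced
#' by [fit_linear()] carry the fit sample size and coefficient of
#' determination.
#'
#' All models in this package work in haematocrit *percent* (a blood-pool
#' attenuation near 50 HU maps to a haematocrit near 40%); serum haematocrit
#' in patient tables is stored as a fraction and converted only at model
#' boundaries.
#'
#' @param slope Slope in Hct-percent per HU.
#' @param intercept Intercept in Hct-percent.
#' @param label Human-readable model label.
#' @param n_fit Number of observations the model was fitted on (0 for
#'   published coefficients).
#' @param r_squared Coefficient of determination of the fit, or `NA` when
#'   unknown.
#' @return An object of class `linear_hct_model`.
#' @examples
#' m <- linear_hct_model(0.51, 17.4, label = "literature")
#' predict_hct(m, 50) # 42.9
#' @export
linear_hct_model <- function(slope, intercept, label = "", n_fit = 0L,
                             r_squared = NA_real_) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("`r_squared` must lie in [0, 1].", call. = FALSE)
  }
  structure(
    list(slope = as.numeric(slope), intercept = as.numeric(intercept),
         label = as.character(label), n_fit = as.integer(n_fit),
         r_squared = as.numeric(r_squared)),
    class = "linear_hct_model"
  )
}

#' @export
print.linear_hct_model <- function(x, ...) {
  cat(sprintf("<linear_hct_model> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  synHct%% = %.4g x HU_blood %+.4g\n", x$slope, x$intercept))
  if (x$n_fit > 0L) {
    cat(sprintf("  fitted on n = %d, R^2 = %.3f\n", x$n_fit, x$r_squared))
  }
  invisible(x)
}

#' Predict synthetic haematocrit (percent) from blood-pool attenuation
#'
#' Evaluates a linear calibration model at the given mean blood-pool
#' attenuation values. Predictions are returned in haematocrit percent and are
#' deliberately not clamped to the physiological range: out-of-range values
#' are the caller's signal that the model was applied outside its calibration
#' domain.
#'
#' For a stratified model, per-record sex and BMI are required so the
#' prediction can be routed; records falling outside every route return `NA`
#' under the `flag_missing` fallback policy.
#'
#' @param model A [linear_hct_model()] or [stratified_hct_model()].
#' @param hu_blood Numeric vector of mean blood-pool attenuation (HU).
#' @param ... Passed to methods.
#' @return Numeric vector of synthetic haematocrit values in percent.
#' @export
predict_hct <- function(model, hu_blood, ...) {
  UseMethod("predict_hct")
}

#' @rdname predict_hct
#' @export
predict_hct.linear_hct_model <- function(model, hu_blood, ...) {
  if (!is.numeric(hu_blood) || any(!is.finite(hu_blood))) {
    stop("`hu_blood` must be finite numeric.", call. = FALSE)
  }
  model$slope * hu_blood + model$intercept
}

#' Fit a univariable haematocrit calibration model by ordinary least squares
#'
#' Fits `hct_percent ~ hu_blood` by OLS via [stats::lm()] and wraps the result
#' as a [linear_hct_model()] with its sample size and R-squared.
#'
#' @param hu_blood Numeric vector of blood-pool attenuation values (HU).
#' @param hct_percent Numeric vector of haematocrit values in percent.
#' @param label Label for the fitted model.
#' @return A [linear_hct_model()].
#' @examples
#' fit_linear(c(48, 50, 52, 55), c(39, 41, 43, 46))
#' @export
fit_linear <- function(hu_blood, hct_percent, label = "fitted") {
  if (length(hu_blood) != length(hct_percent)) {
    stop("`hu_blood` and `hct_percent` must have equal length.", call. = FALSE)
  }
  ok <- is.finite(hu_blood) & is.finite(hct_percent)
  x <- hu_blood[ok]
  y <- hct_percent[ok]
  if (length(x) < 3L) {
    # two points define a line but give no residual df; require 3 except the
    # exact-interpolation case
    if (length(x) == 2L && x[1] != x[2]) {
      slope <- (y[2] - y[1]) / (x[2] - x[1])
      return(linear_hct_model(slope, y[1] - slope * x[1], label = label,
                              n_fit = 2L, r_squared = 1))
    }
    stop("At least 3 points are required to fit a model.", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("Degenerate design: `hu_blood` is constant.", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # summary.lm warns on exact fits (noise-free fixtures); R^2 is still valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  linear_hct_model(co[["x"]], co[["(Intercept)"]], label = label,
                   n_fit = length(x), r_squared = r2)
}

#' @method tidy linear_hct_model
#' @export
tidy.linear_hct_model <- function(x, ...) {
  tibble::tibble(
    term = c("hu_blood", "(Intercept)"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @method glance linear_hct_model
#' @export
glance.linear_hct_model <- function(x, ...) {
  tibble::tibble(label = x$label, r.squared = x$r_squared, nobs = x$n_fit)
}
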