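#' Routing predicate for a stratified haematocrit model
#'
#' A predicate selects records by sex and a half-open BMI interval
#' `[bmi_low, bmi_high)`. A BMI exactly on a stratification threshold
#' therefore routes to the upper interval, keeping the routes a partition.
#'
#' @param sex `"male"`, `"female"` or `"any"`.
#' @param bmi_low,bmi_high BMI bounds in kg/m^2 (`-Inf`/`Inf` for unbounded).
#' @return An object of class `model_predicate`.
#' @export
model_predicate <- function(sex = "any", bmi_low = -Inf, bmi_high = Inf) {
  sex <- match.arg(sex, c("male", "female", "any"))
  stopifnot(is.numeric(bmi_low), is.numeric(bmi_high))
  if (!(bmi_low < bmi_high)) {
    stop("`bmi_low` must be strictly below `bmi_high`.", call. = FALSE)
  }
  structure(list(sex = sex, bmi_low = bmi_low, bmi_high = bmi_high),
            class = "model_predicate")
}

predicate_matches <- function(pred, sex, bmi) {
  (pred$sex == "any" | pred$sex == sex) & bmi >= pred$bmi_low & bmi < pred$bmi_high
}

#' Sex- and BMI-stratified haematocrit model
#'
#' Bundles an ordered list of `(predicate, model)` routes with a fallback
#' policy for records no route covers. The default policy, `"flag_missing"`,
#' refuses to predict (returns `NA`) rather than silently substituting a
#' model: the combined sex- and BMI-specific model deliberately has no
#' prediction for females with BMI below 22.4 kg/m^2.
#'
#' @param routes List of two-element lists `list(predicate, model)` where the
#'   predicate is a [model_predicate()] and the model a [linear_hct_model()].
#' @param fallback One of `"flag_missing"`, `"baseline_model"`,
#'   `"literature_model"`.
#' @param label Model label.
#' @return An object of class `stratified_hct_model`.
#' @export
stratified_hct_model <- function(routes,
                                 fallback = c("flag_missing", "baseline_model",
                                              "literature_model"),
                                 label = "stratified") {
  fallback <- match.arg(fallback)
  stopifnot(length(routes) >= 1L)
  for (r in routes) {
    stopifnot(inherits(r[[1]], "model_predicate"),
              inherits(r[[2]], "linear_hct_model"))
  }
  # routes must not overlap within a sex: dispatch is then order-independent
  for (sx in c("male", "female")) {
    iv <- purrr::keep(routes, ~ .x[[1]]$sex %in% c(sx, "any"))
    if (length(iv) > 1L) {
      for (i in seq_len(length(iv) - 1L)) {
        for (j in seq(i + 1L, length(iv))) {
          a <- iv[[i]][[1]]; b <- iv[[j]][[1]]
          if (max(a$bmi_low, b$bmi_low) < min(a$bmi_high, b$bmi_high)) {
            stop("Overlapping routes for sex '", sx, "'.", call. = FALSE)
          }
        }
      }
    }
  }
  structure(list(routes = routes, fallback = fallback, label = label),
            class = "stratified_hct_model")
}

#' @export
print.stratified_hct_model <- function(x, ...) {
  cat(sprintf("<stratified_hct_model> %s (%d routes, fallback = %s)\n",
              x$label, length(x$routes), x$fallback))
  for (r in x$routes) {
    p <- r[[1]]; m <- r[[2]]
    cat(sprintf("  %s, BMI [%.4g, %.4g): synHct%% = %.4g x HU %+.4g\n",
                p$sex, p$bmi_low, p$bmi_high, m$slope, m$intercept))
  }
  invisible(x)
}

#' Route a record to its stratum-specific model
#'
#' Returns the first route whose predicate matches the record's sex and BMI.
#' Under `fallback = "flag_missing"` an uncovered record returns `NULL`
#' (the missing flag); the other policies return the corresponding published
#' model.
#'
#' @param model A [stratified_hct_model()].
#' @param sex `"male"` or `"female"`.
#' @param bmi BMI in kg/m^2.
#' @return A [linear_hct_model()], or `NULL` when the record is not covered
#'   and the fallback is `flag_missing`.
#' @export
route <- function(model, sex, bmi) {
  stopifnot(inherits(model, "stratified_hct_model"))
  stopifnot(sex %in% c("male", "female"), is.numeric(bmi), length(bmi) == 1L)
  for (r in model$routes) {
    if (predicate_matches(r[[1]], sex, bmi)) return(r[[2]])
  }
  switch(model$fallback,
         flag_missing = NULL,
         baseline_model = published_models()$baseline,
         literature_model = published_models()$literature)
}

#' @rdname predict_hct
#' @param sex,bmi Vectors of record sex (`"male"`/`"female"`) and BMI
#'   (kg/m^2), recycled against `hu_blood`, used to route predictions through
#'   a stratified model.
#' @export
predict_hct.stratified_hct_model <- function(model, hu_blood, sex, bmi, ...) {
  n <- max(length(hu_blood), length(sex), length(bmi))
  hu_blood <- rep_len(hu_blood, n)
  sex <- rep_len(sex, n)
  bmi <- rep_len(bmi, n)
  purrr::map_dbl(seq_len(n), function(i) {
    m <- route(model, sex[i], bmi[i])
    if (is.null(m)) NA_real_ else predict_hct(m, hu_blood[i])
  })
}

#' @method tidy stratified_hct_model
#' @export
tidy.stratified_hct_model <- function(x, ...) {
  purrr::map_dfr(x$routes, function(r) {
    tibble::tibble(
      sex = r[[1]]$sex, bmi_low = r[[1]]$bmi_low, bmi_high = r[[1]]$bmi_high,
      slope = r[[2]]$slope, intercept = r[[2]]$intercept,
      label = r[[2]]$label, n_fit = r[[2]]$n_fit, r_squared = r[[2]]$r_squared
    )
  })
}

#' Published haematocrit calibration models
#'
#' Returns the calibration models with their published coefficients, stored
#' exactly as printed (never re-derived):
#' \describe{
#'   \item{`literature`}{synHct% = 0.51 x HU + 17.4, the model derived from an
#'     earlier 40-patient cardiac CT cohort.}
#'   \item{`baseline`}{synHct% = 0.864 x HU − 2.09, the univariable model
#'     refitted on the 108-patient cohort.}
#'   \item{`male_low_bmi`}{Males, BMI < 30.7: synHct% = 1.16 x HU − 17.2.}
#'   \item{`male_high_bmi`}{Males, BMI ≥ 30.7: synHct% = 0.669 x HU + 8.38.}
#'   \item{`female_high_bmi`}{Females, BMI ≥ 22.4: synHct% = 0.669 x HU + 8.19.}
#'   \item{`combined`}{The sex- and BMI-stratified dispatcher assembled from
#'     the three stratum models, with `flag_missing` fallback (no prediction
#'     for females with BMI < 22.4).}
#' }
#'
#' @param fallback Fallback policy for the combined dispatcher.
#' @return Named list of five [linear_hct_model()]s and one
#'   [stratified_hct_model()].
#' @examples
#' published_models()$literature
#' @export
published_models <- function(fallback = "flag_missing") {
  lit <- linear_hct_model(0.51, 17.4, label = "literature")
  base <- linear_hct_model(0.864, -2.09, label = "baseline")
  m_lo <- linear_hct_model(1.16, -17.2, label = "male_low_bmi")
  m_hi <- linear_hct_model(0.669, 8.38, label = "male_high_bmi")
  f_hi <- linear_hct_model(0.669, 8.19, label = "female_high_bmi")
  combined <- stratified_hct_model(
    routes = list(
      list(model_predicate("male", -Inf, 30.7), m_lo),
      list(model_predicate("male", 30.7, Inf), m_hi),
      list(model_predicate("female", 22.4, Inf), f_hi)
    ),
    fallback = fallback, label = "combined"
  )
  list(literature = lit, baseline = base, male_low_bmi = m_lo,
       male_high_bmi = m_hi, female_high_bmi = f_hi, combined = combined)
}
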