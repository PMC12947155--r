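#' Mean absolute error
#'
#' @param pred,truth Numeric vectors of equal, non-zero length.
#' @return Mean of the absolute differences, in the units of the inputs.
#' @examples
#' mae(c(0.41, 0.39), c(0.40, 0.40)) # 0.01
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    stop("`pred` and `truth` must have equal, non-zero length.", call. = FALSE)
  }
  mean(abs(pred - truth))
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' Transforms the correlation with `atanh`, applies a normal interval with
#' standard error `1 / sqrt(n - 3)`, and back-transforms with `tanh`. With
#' the conventional `z* = 1.96` at the 95% level, this reproduces the
#' printed intervals of the study's model-comparison table exactly (to the
#' 2-decimal display rounding).
#'
#' @param r Pearson correlation, `|r| < 1`.
#' @param n Sample size, at least 4.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`, unrounded.
#' @examples
#' round(pearson_ci(0.68, 108), 2) # 0.56 0.77
#' @export
pearson_ci <- function(r, n, level = 0.95) {
  if (!is.finite(r) || abs(r) >= 1) {
    stop("`r` must satisfy |r| < 1 for the Fisher-z interval.", call. = FALSE)
  }
  if (n < 4L) stop("At least n = 4 is required.", call. = FALSE)
  zstar <- stats::qnorm(1 - (1 - level) / 2)
  z <- atanh(r) + c(-1, 1) * zstar / sqrt(n - 3)
  stats::setNames(tanh(z), c("low", "high"))
}

#' Score a haematocrit model on a cohort
#'
#' Predicts synthetic haematocrit for every routable record and reports
#' mean absolute error (fraction units) and Pearson correlation with
#' Fisher-z confidence intervals, for haematocrit and for the downstream
#' per-record mean-LV ECV. ECV is computed from each record's attenuation
#' change pair (`dhu_myo`, `dhu_blood`): conventional ECV with the measured
#' serum haematocrit, synthetic ECV with the model prediction. Records no
#' route covers (for a stratified model under `flag_missing`) are excluded
#' from the metrics and counted in `n_unroutable`, mirroring a restricted
#' subgroup analysis.
#'
#' @param model A [linear_hct_model()] or [stratified_hct_model()].
#' @param cohort Cohort tibble with `hct`, `hu_blood`, `sex`, `bmi` and
#'   (optionally) `dhu_myo`, `dhu_blood`. Without the attenuation pairs, a
#'   fixed convention is used: `dhu_blood = 60` HU and `dhu_myo` derived
#'   from `ecv_true`.
#' @param label Row label; defaults to the model's own label.
#' @return A one-row tibble of class `hct_model_evaluation` with columns
#'   `label`, `mae_hct`, `r_hct`, `r_hct_low`, `r_hct_high`, `mae_ecv`,
#'   `r_ecv`, `r_ecv_low`, `r_ecv_high`, `n_scored`, `n_unroutable`.
#' @export
evaluate_model <- function(model, cohort, label = NULL) {
  if (nrow(cohort) == 0L) stop("Cohort is empty.", call. = FALSE)
  label <- label %||% model$label
  pred_pct <- if (inherits(model, "stratified_hct_model")) {
    predict_hct(model, cohort$hu_blood, cohort$sex, cohort$bmi)
  } else {
    predict_hct(model, cohort$hu_blood)
  }
  routable <- !is.na(pred_pct)
  if (!any(routable)) {
    stop("No record is routable under this model.", call. = FALSE)
  }
  sub <- cohort[routable, , drop = FALSE]
  pred <- pred_pct[routable] / 100
  truth <- sub$hct

  if (!all(c("dhu_myo", "dhu_blood") %in% names(sub))) {
    if (!"ecv_true" %in% names(sub)) {
      stop("Cohort needs `dhu_myo`/`dhu_blood` columns or `ecv_true` for ECV metrics.",
           call. = FALSE)
    }
    sub$dhu_blood <- 60
    sub$dhu_myo <- sub$ecv_true * sub$dhu_blood / (1 - truth)
  }
  con_ecv <- (1 - truth) * sub$dhu_myo / sub$dhu_blood
  syn_ecv <- (1 - pred) * sub$dhu_myo / sub$dhu_blood

  n <- length(pred)
  cor_with_ci <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      if (mae(a, b) == 0) {
        warning("Zero variance with exact predictions; correlation reported as 1.",
                call. = FALSE)
        return(c(r = 1, low = 1, high = 1))
      }
      warning("Zero variance; correlation undefined.", call. = FALSE)
      return(c(r = NA_real_, low = NA_real_, high = NA_real_))
    }
    r <- stats::cor(a, b)
    if (abs(r) >= 1) return(c(r = r, low = r, high = r))
    ci <- pearson_ci(r, n)
    c(r = r, low = ci[["low"]], high = ci[["high"]])
  }
  ch <- cor_with_ci(pred, truth)
  ce <- cor_with_ci(syn_ecv, con_ecv)

  out <- tibble::tibble(
    label = label,
    mae_hct = mae(pred, truth), r_hct = ch[["r"]],
    r_hct_low = ch[["low"]], r_hct_high = ch[["high"]],
    mae_ecv = mae(syn_ecv, con_ecv), r_ecv = ce[["r"]],
    r_ecv_low = ce[["low"]], r_ecv_high = ce[["high"]],
    n_scored = n, n_unroutable = sum(!routable)
  )
  class(out) <- c("hct_model_evaluation", class(out))
  out
}

#' Fit the full calibration model family on a cohort
#'
#' Reproduces the model-building workflow on a given cohort: the published
#' literature model; a refitted univariable baseline; per-sex models; the
#' male model stratified at a BMI threshold; the female model restricted to
#' BMI above its threshold; and the combined sex- and BMI-stratified
#' dispatcher assembled from the stratum fits.
#'
#' @param cohort Cohort tibble.
#' @param male_bmi_threshold,female_bmi_threshold Stratification thresholds
#'   (kg/m^2); defaults are the thresholds selected on the study cohort.
#' @param fallback Fallback policy for records outside all routes.
#' @return Named list of seven models in comparison-table order:
#'   `literature`, `baseline`, `male`, `male_bmi`, `female`, `female_bmi`,
#'   `combined`.
#' @export
fit_model_family <- function(cohort, male_bmi_threshold = 30.7,
                             female_bmi_threshold = 22.4,
                             fallback = "flag_missing") {
  pub <- published_models()
  males <- dplyr::filter(cohort, .data$sex == "male")
  females <- dplyr::filter(cohort, .data$sex == "female")
  fit_on <- function(d, label) fit_linear(d$hu_blood, d$hct * 100, label)
  wrap <- function(m, sex, lo = -Inf, hi = Inf, label = m$label) {
    stratified_hct_model(list(list(model_predicate(sex, lo, hi), m)),
                         fallback = fallback, label = label)
  }
  m_lo <- fit_on(dplyr::filter(males, .data$bmi < male_bmi_threshold),
                 "male_low_bmi")
  m_hi <- fit_on(dplyr::filter(males, .data$bmi >= male_bmi_threshold),
                 "male_high_bmi")
  f_hi <- fit_on(dplyr::filter(females, .data$bmi >= female_bmi_threshold),
                 "female_high_bmi")
  list(
    literature = pub$literature,
    baseline = fit_on(cohort, "baseline"),
    male = wrap(fit_on(males, "male"), "male"),
    male_bmi = stratified_hct_model(
      list(list(model_predicate("male", -Inf, male_bmi_threshold), m_lo),
           list(model_predicate("male", male_bmi_threshold, Inf), m_hi)),
      fallback = fallback, label = "male_bmi"),
    female = wrap(fit_on(females, "female"), "female"),
    female_bmi = wrap(f_hi, "female", female_bmi_threshold, Inf, "female_bmi"),
    combined = stratified_hct_model(
      list(list(model_predicate("male", -Inf, male_bmi_threshold), m_lo),
           list(model_predicate("male", male_bmi_threshold, Inf), m_hi),
           list(model_predicate("female", female_bmi_threshold, Inf), f_hi)),
      fallback = fallback, label = "combined")
  )
}

#' Model-comparison table across the calibration family
#'
#' Evaluates a named set of models on one cohort and stacks the results in
#' the standard comparison order (literature, baseline, male, male with
#' BMI, female, female with BMI, combined). By default the family is fitted
#' on the cohort itself with [fit_model_family()].
#'
#' @param cohort Cohort tibble.
#' @param models Named list of models; defaults to
#'   `fit_model_family(cohort)`.
#' @return A tibble of class `hct_model_comparison`, one
#'   [evaluate_model()] row per model.
#' @examples
#' cohort <- generate_cohort(cohort_spec(), seed = 1)
#' comparison_table(cohort)
#' @export
comparison_table <- function(cohort, models = NULL) {
  models <- models %||% fit_model_family(cohort)
  if (length(models) == 0L) stop("At least one model is required.", call. = FALSE)
  out <- purrr::imap_dfr(models, function(m, nm) {
    evaluate_model(m, cohort, label = nm)
  })
  class(out) <- c("hct_model_comparison", "hct_model_evaluation", class(out))
  out
}

#' Write a comparison table as CSV and/or JSON
#'
#' @param comparison A tibble from [comparison_table()].
#' @param csv,json Output paths (either may be `NULL`).
#' @return Written paths, invisibly.
#' @export
write_comparison <- function(comparison, csv = NULL, json = NULL) {
  if (!is.null(csv)) readr::write_csv(comparison, csv)
  if (!is.null(json)) {
    jsonlite::write_json(comparison, json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csv, json = json))
}
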