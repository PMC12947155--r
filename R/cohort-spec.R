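#' Specification of a synthetic TAVI-workup cohort
#'
#' Describes the statistical structure of the synthetic patient cohort: sex
#' counts, per-stratum true calibration lines between blood-pool attenuation
#' and haematocrit, target haematocrit moments and fit strength (R-squared)
#' per stratum, and per-sex demographic distributions. The default values
#' reproduce the printed summaries of the study population (108 patients,
#' 75 male / 33 female, cohort haematocrit 0.40 +/- 0.05, median ECV 0.32)
#' and inject the published stratum-specific calibration lines as ground
#' truth.
#'
#' Two quantities per stratum are *solved*, not supplied: the blood-pool HU
#' standard deviation and the residual SD of haematocrit-percent. Given the
#' target haematocrit SD `s_y` and target R-squared `r2`, the generator uses
#' `hu_sd = sqrt(r2) * s_y / |slope|` and `resid_sd = sqrt(1 - r2) * s_y`, so
#' the explained-variance identity `1 - resid_sd^2 / var(Hct%) = r2` holds
#' exactly. The stratum HU mean is found by inverting the stratum line at the
#' target mean haematocrit. Strata with slope 0 (the female low-BMI stratum,
#' where no significant calibration exists) inherit the HU distribution of
#' the same-sex stratum with non-zero slope.
#'
#' @param n_male,n_female Sex counts; assignment is by fixed count, not by
#'   Bernoulli draws, so the counts are exact.
#' @param subgroups Tibble with columns `sex`, `bmi_low`, `bmi_high`,
#'   `slope` (Hct% per HU), `intercept` (Hct%), `hct_mean` (target mean
#'   Hct%), `hct_sd` (target SD of Hct%), `r_squared` (target fit strength).
#'   BMI intervals are half-open `[low, high)` and must partition each sex's
#'   BMI range.
#' @param demographics Tibble with one row per sex and columns `age_median`,
#'   `age_iqr`, `bmi_median`, `bmi_iqr`, `egfr_mean`, `egfr_sd`,
#'   `creat_median`, `creat_iqr`. Ages in years, BMI in kg/m^2, eGFR in
#'   mL/min/1.73 m^2, creatinine in umol/L. Demographics other than BMI are
#'   generated independent of haematocrit, encoding the study's null results
#'   for age, eGFR and creatinine.
#' @param ecv_median,ecv_iqr Median and interquartile range of the
#'   ground-truth extracellular volume fraction.
#' @param dhu_blood_mean,dhu_blood_sd Mean and SD of the per-record
#'   blood-pool attenuation change between baseline and late-enhancement
#'   acquisitions (HU), used to derive per-record myocardial attenuation
#'   changes consistent with the ground-truth ECV.
#' @return An object of class `cohort_spec` with solved calibration columns
#'   `hu_mean`, `hu_sd`, `resid_sd` appended to `subgroups`.
#' @examples
#' spec <- cohort_spec()
#' spec$subgroups
#' @export
cohort_spec <- function(n_male = 75L,
                        n_female = 33L,
                        subgroups = default_subgroups(),
                        demographics = default_demographics(),
                        ecv_median = 0.32,
                        ecv_iqr = 0.05,
                        dhu_blood_mean = 60,
                        dhu_blood_sd = 8) {
  spec <- list(
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    subgroups = tibble::as_tibble(subgroups),
    demographics = tibble::as_tibble(demographics),
    ecv_median = ecv_median, ecv_iqr = ecv_iqr,
    dhu_blood_mean = dhu_blood_mean, dhu_blood_sd = dhu_blood_sd
  )
  spec$subgroups <- solve_calibration(spec$subgroups)
  validate_cohort_spec(structure(spec, class = "cohort_spec"))
}

#' @rdname cohort_spec
#' @export
default_subgroups <- function() {
  tibble::tribble(
    ~sex,     ~bmi_low, ~bmi_high, ~slope, ~intercept, ~hct_mean, ~hct_sd, ~r_squared,
    "male",   -Inf,     30.7,      1.16,   -17.2,      40.2,      5,       0.55,
    "male",   30.7,     Inf,       0.669,  8.38,       40.2,      5,       0.55,
    "female", 22.4,     Inf,       0.669,  8.19,       38.7,      4,       0.33,
    "female", -Inf,     22.4,      0,      38.7,       38.7,      4,       0
  )
}

#' @rdname cohort_spec
#' @export
default_demographics <- function() {
  tibble::tribble(
    ~sex,     ~age_median, ~age_iqr, ~bmi_median, ~bmi_iqr, ~egfr_mean, ~egfr_sd, ~creat_median, ~creat_iqr,
    "male",   80,          10,       27.6,        7.7,      62.7,       20.3,     95,            34,
    "female", 83,          7.5,      25.9,        7.3,      63.4,       17.9,     77,            22
  )
}

# Solve per-stratum HU mean/SD and residual SD from the target moments.
solve_calibration <- function(sg) {
  need <- c("sex", "bmi_low", "bmi_high", "slope", "intercept",
            "hct_mean", "hct_sd", "r_squared")
  miss <- setdiff(need, names(sg))
  if (length(miss)) {
    stop("`subgroups` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sg <- dplyr::mutate(
    sg,
    resid_sd = sqrt(1 - .data$r_squared) * .data$hct_sd,
    hu_mean = ifelse(.data$slope != 0,
                     (.data$hct_mean - .data$intercept) / .data$slope, NA_real_),
    hu_sd = ifelse(.data$slope != 0,
                   sqrt(.data$r_squared) * .data$hct_sd / abs(.data$slope),
                   NA_real_)
  )
  # slope-0 strata inherit the HU distribution of a same-sex sloped stratum
  sg <- dplyr::group_by(sg, .data$sex)
  sg <- dplyr::mutate(
    sg,
    hu_mean = ifelse(is.na(.data$hu_mean),
                     mean(.data$hu_mean, na.rm = TRUE), .data$hu_mean),
    hu_sd = ifelse(is.na(.data$hu_sd),
                   mean(.data$hu_sd, na.rm = TRUE), .data$hu_sd)
  )
  dplyr::ungroup(sg)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_male < 0L || spec$n_female < 0L) {
    stop("Invalid cohort spec: `n_male`/`n_female` must be non-negative.",
         call. = FALSE)
  }
  if (spec$n_male + spec$n_female <= 0L) {
    stop("Invalid cohort spec: `n_male + n_female` must be positive.",
         call. = FALSE)
  }
  sg <- spec$subgroups
  for (col in c("hct_sd", "resid_sd", "hu_sd")) {
    if (any(!is.finite(sg[[col]]) | sg[[col]] < 0)) {
      stop("Invalid cohort spec: `subgroups$", col,
           "` must be finite and non-negative.", call. = FALSE)
    }
  }
  if (any(sg$r_squared < 0 | sg$r_squared > 1)) {
    stop("Invalid cohort spec: `subgroups$r_squared` must lie in [0, 1].",
         call. = FALSE)
  }
  if (any(!(sg$bmi_low < sg$bmi_high))) {
    stop("Invalid cohort spec: each subgroup needs `bmi_low < bmi_high`.",
         call. = FALSE)
  }
  for (sx in unique(sg$sex)) {
    s <- dplyr::arrange(dplyr::filter(sg, .data$sex == sx), .data$bmi_low)
    if (s$bmi_low[1] != -Inf || s$bmi_high[nrow(s)] != Inf ||
        (nrow(s) > 1L && any(s$bmi_high[-nrow(s)] != s$bmi_low[-1L]))) {
      stop("Invalid cohort spec: `subgroups` BMI intervals for sex '", sx,
           "' must partition (-Inf, Inf).", call. = FALSE)
    }
  }
  dm <- spec$demographics
  for (col in c("age_iqr", "bmi_iqr", "egfr_sd", "creat_iqr")) {
    if (any(dm[[col]] < 0)) {
      stop("Invalid cohort spec: `demographics$", col,
           "` must be non-negative.", call. = FALSE)
    }
  }
  if (any(dm$bmi_median <= 0)) {
    stop("Invalid cohort spec: `demographics$bmi_median` must be positive.",
         call. = FALSE)
  }
  if (spec$ecv_iqr < 0 || spec$dhu_blood_sd < 0) {
    stop("Invalid cohort spec: `ecv_iqr` and `dhu_blood_sd` must be non-negative.",
         call. = FALSE)
  }
  if (spec$dhu_blood_mean <= 0) {
    stop("Invalid cohort spec: `dhu_blood_mean` must be positive.",
         call. = FALSE)
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> n = %d (%d male / %d female)\n",
              x$n_male + x$n_female, x$n_male, x$n_female))
  cat("Strata (calibration solved from target moments):\n")
  print(x$subgroups)
  invisible(x)
}

#' Read or write a cohort specification as YAML
#'
#' The packaged default specification lives at
#' `system.file("extdata", "default_cohort_spec.yaml", package = "synecv")`
#' and reproduces the study population's printed summaries.
#'
#' @param path Path to a YAML file.
#' @param spec A [cohort_spec()].
#' @return `read_cohort_spec()` returns a [cohort_spec()];
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) {
    stop("Cohort spec file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  for (f in c("n_male", "n_female", "subgroups", "demographics")) {
    if (is.null(y[[f]])) {
      stop("Cohort spec YAML is missing field `", f, "`.", call. = FALSE)
    }
  }
  inf <- function(v) ifelse(v == ".inf", Inf, ifelse(v == "-.inf", -Inf,
                                                     suppressWarnings(as.numeric(v))))
  sg <- purrr::map_dfr(y$subgroups, function(s) {
    tibble::tibble(sex = s$sex, bmi_low = inf(s$bmi_low),
                   bmi_high = inf(s$bmi_high), slope = s$slope,
                   intercept = s$intercept, hct_mean = s$hct_mean,
                   hct_sd = s$hct_sd, r_squared = s$r_squared)
  })
  dm <- purrr::map_dfr(y$demographics, tibble::as_tibble)
  cohort_spec(n_male = y$n_male, n_female = y$n_female, subgroups = sg,
              demographics = dm,
              ecv_median = y$ecv_median %||% 0.32,
              ecv_iqr = y$ecv_iqr %||% 0.05,
              dhu_blood_mean = y$dhu_blood_mean %||% 60,
              dhu_blood_sd = y$dhu_blood_sd %||% 8)
}

#' @rdname read_cohort_spec
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  fin <- function(v) ifelse(is.finite(v), v,
                            ifelse(v > 0, ".inf", "-.inf"))
  y <- list(
    n_male = spec$n_male, n_female = spec$n_female,
    subgroups = purrr::pmap(spec$subgroups[, c("sex", "bmi_low", "bmi_high",
                                               "slope", "intercept", "hct_mean",
                                               "hct_sd", "r_squared")],
                            function(sex, bmi_low, bmi_high, ...) {
                              c(list(sex = sex, bmi_low = fin(bmi_low),
                                     bmi_high = fin(bmi_high)), list(...))
                            }),
    demographics = purrr::pmap(spec$demographics, function(...) list(...)),
    ecv_median = spec$ecv_median, ecv_iqr = spec$ecv_iqr,
    dhu_blood_mean = spec$dhu_blood_mean, dhu_blood_sd = spec$dhu_blood_sd
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname cohort_spec
#' @export
default_cohort_spec <- function() {
  read_cohort_spec(system.file("extdata", "default_cohort_spec.yaml",
                               package = "synecv"))
}
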