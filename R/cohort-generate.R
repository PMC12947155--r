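#' Generate a synthetic patient cohort
#'
#' Draws a patient table with the statistical structure assumed by the
#' synthetic-haematocrit analysis. Per sex, BMI is drawn log-normal (matched
#' to the printed median and IQR); each record is assigned to its sex/BMI
#' stratum; blood-pool attenuation is drawn normal with the stratum's solved
#' mean and SD; and haematocrit-percent is set to
#' `slope * hu_blood + intercept + rnorm(0, resid_sd)`, i.e. the generator
#' inverts the fitted calibration models. Haematocrit is stored as a
#' fraction (percent / 100). Ages and creatinine are log-normal, eGFR
#' normal, all independent of haematocrit. Ground-truth ECV is drawn normal
#' (median 0.32, IQR 0.05 by default) and each record carries a consistent
#' pair of attenuation changes: `dhu_blood` drawn normal and
#' `dhu_myo = ecv_true * dhu_blood / (1 - hct)`, so the conventional ECV
#' computed from the record equals its ground truth exactly.
#'
#' All randomness flows from `seed` via [withr::with_seed()]; the global RNG
#' state is untouched and two calls with the same spec and seed return
#' identical tables.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed driving all draws.
#' @return A tibble with one row per patient and columns `patient_id`,
#'   `sex`, `age`, `bmi`, `egfr`, `creatinine`, `hct` (fraction),
#'   `hu_blood` (HU), `ecv_true` (fraction), `dhu_myo` (HU), `dhu_blood`
#'   (HU).
#' @examples
#' cohort <- generate_cohort(cohort_spec(), seed = 1)
#' dplyr::count(cohort, sex)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  withr::with_seed(seed, {
    per_sex <- purrr::map(
      c(male = "male", female = "female"),
      function(sx) {
        n <- if (sx == "male") spec$n_male else spec$n_female
        if (n == 0L) return(NULL)
        dm <- dplyr::filter(spec$demographics, .data$sex == sx)
        if (nrow(dm) != 1L) {
          stop("`demographics` must have exactly one row for sex '", sx, "'.",
               call. = FALSE)
        }
        bmi <- rlnorm_median_iqr(n, dm$bmi_median, dm$bmi_iqr)
        age <- rlnorm_median_iqr(n, dm$age_median, dm$age_iqr)
        egfr <- pmax(stats::rnorm(n, dm$egfr_mean, dm$egfr_sd), 1)
        creat <- rlnorm_median_iqr(n, dm$creat_median, dm$creat_iqr)
        sg <- dplyr::filter(spec$subgroups, .data$sex == sx)
        idx <- stratum_index(sg, bmi)
        hu <- stats::rnorm(n, sg$hu_mean[idx], sg$hu_sd[idx])
        hct_pct <- sg$slope[idx] * hu + sg$intercept[idx] +
          stats::rnorm(n, 0, sg$resid_sd[idx])
        tibble::tibble(sex = sx, age = age, bmi = bmi, egfr = egfr,
                       creatinine = creat, hct = hct_pct / 100,
                       hu_blood = hu)
      }
    )
    cohort <- dplyr::bind_rows(per_sex)
    n <- nrow(cohort)
    ecv_sd <- spec$ecv_iqr / (2 * stats::qnorm(0.75))
    ecv <- pmin(pmax(stats::rnorm(n, spec$ecv_median, ecv_sd), 0.01), 0.99)
    dhu_blood <- pmax(stats::rnorm(n, spec$dhu_blood_mean, spec$dhu_blood_sd),
                      spec$dhu_blood_mean / 4)
    dplyr::mutate(
      cohort,
      patient_id = sprintf("P%04d", dplyr::row_number()),
      ecv_true = ecv,
      dhu_blood = dhu_blood,
      dhu_myo = ecv * dhu_blood / (1 - .data$hct),
      .before = 1
    ) |>
      dplyr::relocate("patient_id", "sex", "age", "bmi", "egfr",
                      "creatinine", "hct", "hu_blood", "ecv_true",
                      "dhu_myo", "dhu_blood")
  })
}

# index of the stratum whose half-open [bmi_low, bmi_high) contains each bmi
stratum_index <- function(sg, bmi) {
  idx <- integer(length(bmi))
  for (i in seq_len(nrow(sg))) {
    idx[bmi >= sg$bmi_low[i] & bmi < sg$bmi_high[i]] <- i
  }
  if (any(idx == 0L)) stop("BMI value not covered by any stratum.", call. = FALSE)
  idx
}

# log-normal draws matched to a target median and interquartile range
rlnorm_median_iqr <- function(n, median, iqr) {
  sigma <- asinh(iqr / (2 * median)) / stats::qnorm(0.75)
  stats::rlnorm(n, meanlog = log(median), sdlog = sigma)
}

#' Read and write cohort tables as CSV
#'
#' The on-disk format has a header row and columns `patient_id`, `sex`
#' (`"male"`/`"female"`), `age`, `bmi`, `egfr`, `creatinine`, `hct`
#' (fraction), `hu_blood`, and optionally `ecv_true`, `dhu_myo`,
#' `dhu_blood`.
#'
#' @param cohort A cohort tibble, as from [generate_cohort()].
#' @param path CSV file path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("patient_id", "sex", "bmi", "hct", "hu_blood")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("Cohort CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !cohort$sex %in% c("male", "female")
  if (any(bad)) {
    stop("Cohort CSV: `sex` must be \"male\"/\"female\" (first bad row: ",
         which(bad)[1], ").", call. = FALSE)
  }
  cohort
}
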