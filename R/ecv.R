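#' Extracellular volume from haematocrit and attenuation changes
#'
#' The extracellular volume fraction of myocardium is computed from the
#' contrast-induced attenuation change in tissue relative to blood, scaled by
#' the blood plasma fraction:
#' `ECV = (1 - Hct) * dHU_myo / dHU_blood`.
#' Values outside `[0, 1]` (possible under image noise) are returned, not
#' clipped; use [ecv_flagged()] to identify them.
#'
#' @param hct Haematocrit as a fraction in `[0, 1]`.
#' @param dhu_myo Myocardial attenuation change (HU); may be a vector or
#'   array (voxel-wise use).
#' @param dhu_blood Mean blood-pool attenuation change (HU); non-zero scalar.
#' @return ECV fraction(s), same shape as `dhu_myo`.
#' @examples
#' compute_ecv(0.40, 30, 60) # 0.30
#' @export
compute_ecv <- function(hct, dhu_myo, dhu_blood) {
  if (!is.numeric(hct) || any(hct < 0 | hct > 1)) {
    stop("`hct` must be a fraction in [0, 1].", call. = FALSE)
  }
  if (any(dhu_blood == 0)) {
    stop("`dhu_blood` must be non-zero.", call. = FALSE)
  }
  (1 - hct) * dhu_myo / dhu_blood
}

#' @rdname compute_ecv
#' @param ecv ECV values to check.
#' @return `ecv_flagged()` returns a logical vector/array marking values
#'   outside `[0, 1]`.
#' @export
ecv_flagged <- function(ecv) {
  !is.na(ecv) & (ecv < 0 | ecv > 1)
}

#' Binary erosion of a 3-D mask with a face-adjacent structuring element
#'
#' Erodes a 3-D binary mask using the 6-connected (face-adjacent) structuring
#' element, applied `iterations` times. Voxels outside the array are treated
#' as background, so masks shrink at the array border too. Used to sample a
#' small central region of the blood pool, away from trabeculations,
#' registration error and artefacts.
#'
#' @param mask 3-D logical or 0/1 numeric array.
#' @param iterations Number of erosion passes; 0 is the identity.
#' @return Logical 3-D array. Errors if the mask erodes to empty (reduce
#'   `iterations`).
#' @examples
#' m <- array(TRUE, c(5, 5, 5))
#' sum(erode_mask(m, 1)) # 27: the solid 3^3 interior
#' @export
erode_mask <- function(mask, iterations = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  stopifnot(iterations >= 0)
  m <- mask > 0
  for (it in seq_len(iterations)) {
    out <- m &
      shift3(m, 1L, 1L) & shift3(m, 1L, -1L) &
      shift3(m, 2L, 1L) & shift3(m, 2L, -1L) &
      shift3(m, 3L, 1L) & shift3(m, 3L, -1L)
    if (!any(out)) {
      stop("Mask eroded to empty after ", it,
           " iteration(s); reduce `iterations`.", call. = FALSE)
    }
    m <- out
  }
  m
}

# shift a 3-D logical array by one voxel along `axis`, padding with FALSE
shift3 <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (by > 0) {
    idx_dst[[axis]] <- seq(1L + by, d[axis])
    idx_src[[axis]] <- seq(1L, d[axis] - by)
  } else {
    idx_dst[[axis]] <- seq(1L, d[axis] + by)
    idx_src[[axis]] <- seq(1L - by, d[axis])
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Voxel-wise ECV map from a registered baseline / late-enhancement pair
#'
#' Implements the image-processing pipeline: the blood-pool mask is eroded to
#' sample a central region; the mean attenuation change over that region
#' gives `dhu_blood`; the voxel-wise attenuation change inside the
#' left-ventricular myocardium mask gives `dhu_myo`; and the ECV relation is
#' applied per voxel with the supplied haematocrit.
#'
#' @param pair A [volume_pair()].
#' @param hct Haematocrit fraction to use (serum for conventional ECV, a
#'   model prediction / 100 for synthetic ECV).
#' @param erosion_iterations Blood-pool erosion passes before sampling
#'   (default 2).
#' @param source `"conventional"` or `"synthetic"`, recorded on the result.
#' @return An object of class `ecv_map`: a list with elements `ecv` (3-D
#'   array, `NA` outside the myocardium mask), `mean_lv_ecv`, `dhu_blood`,
#'   `hct_used`, `source`, `erosion_iterations`, and `n_flagged` (voxels
#'   outside `[0, 1]`, kept not clipped).
#' @export
compute_ecv_map <- function(pair, hct, erosion_iterations = 2L,
                            source = c("conventional", "synthetic")) {
  source <- match.arg(source)
  validate_volume_pair(pair)
  if (length(hct) != 1L || is.na(hct) || hct < 0 || hct > 1) {
    stop("`hct` must be a single fraction in [0, 1].", call. = FALSE)
  }
  bp <- erode_mask(pair$bp_mask, erosion_iterations)
  delta <- pair$lie_hu - pair$baseline_hu
  dhu_blood <- mean(delta[bp])
  if (dhu_blood == 0) {
    stop("Mean blood-pool attenuation change is zero.", call. = FALSE)
  }
  lv <- pair$lv_mask > 0
  ecv <- array(NA_real_, dim(delta))
  ecv[lv] <- compute_ecv(hct, delta[lv], dhu_blood)
  structure(
    list(ecv = ecv, mean_lv_ecv = mean(ecv[lv]), dhu_blood = dhu_blood,
         hct_used = hct, source = source,
         erosion_iterations = as.integer(erosion_iterations),
         n_flagged = sum(ecv_flagged(ecv[lv]))),
    class = "ecv_map"
  )
}

#' @export
print.ecv_map <- function(x, ...) {
  cat(sprintf("<ecv_map> %s (Hct %.3f)\n", x$source, x$hct_used))
  cat(sprintf("  mean LV ECV %.4f over %d voxels; dHU_blood %.2f; %d flagged\n",
              x$mean_lv_ecv, sum(!is.na(x$ecv)), x$dhu_blood, x$n_flagged))
  invisible(x)
}

#' Synthetic ECV for a patient record
#'
#' Predicts synthetic haematocrit from the record's mean blood-pool
#' attenuation (routing through a stratified model when given one), converts
#' it from percent to a fraction, and substitutes it into the ECV relation.
#' Returns `NA` (the missing flag) when the record is not covered by any
#' route under the `flag_missing` fallback.
#'
#' @param record A one-row data frame (or list) with `hu_blood` and, for
#'   stratified models, `sex` and `bmi`.
#' @param model A [linear_hct_model()] or [stratified_hct_model()].
#' @param dhu_myo Myocardial attenuation change (HU); scalar or voxel array.
#' @param dhu_blood Mean blood-pool attenuation change (HU).
#' @return Synthetic ECV fraction(s), or `NA` when unroutable.
#' @examples
#' rec <- list(hu_blood = 50, sex = "male", bmi = 25)
#' compute_synecv(rec, published_models()$literature, 30, 60) # 0.2855
#' @export
compute_synecv <- function(record, model, dhu_myo, dhu_blood) {
  if (inherits(model, "stratified_hct_model")) {
    m <- route(model, record$sex, record$bmi)
    if (is.null(m)) return(NA_real_)
    model <- m
  }
  syn_hct <- predict_hct(model, record$hu_blood) / 100
  if (syn_hct < 0 || syn_hct > 1) {
    warning("Predicted synthetic haematocrit ", round(syn_hct, 3),
            " is outside [0, 1]; model applied outside calibration range.",
            call. = FALSE)
    syn_hct <- min(max(syn_hct, 0), 1)
  }
  compute_ecv(syn_hct, dhu_myo, dhu_blood)
}
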