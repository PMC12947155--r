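#' Combined selection score over candidate stratifications
#'
#' Candidate stratifications are ranked on four metrics: mean absolute
#' error and Pearson correlation of predicted haematocrit, and the same two
#' on downstream ECV. Each metric is min-max normalized across the
#' candidate set (errors inverted so lower is better) and the four
#' normalized values averaged with equal weights; higher is better. A
#' metric with zero spread across candidates is neutral (contributes 1 for
#' every candidate), so a single candidate scores exactly 1.
#'
#' @param mae_hct,r_hct,mae_ecv,r_ecv Numeric vectors, one entry per
#'   candidate.
#' @return Numeric vector of scores in `[0, 1]`, one per candidate.
#' @examples
#' combined_score(c(0.03, 0.02), c(0.6, 0.8), c(0.02, 0.015), c(0.8, 0.9))
#' @export
combined_score <- function(mae_hct, r_hct, mae_ecv, r_ecv) {
  k <- length(mae_hct)
  stopifnot(length(r_hct) == k, length(mae_ecv) == k, length(r_ecv) == k)
  if (k == 0L) stop("Candidate set is empty.", call. = FALSE)
  metrics <- list(mae_hct, r_hct, mae_ecv, r_ecv)
  if (any(!purrr::map_lgl(metrics, ~ all(is.finite(.x))))) {
    stop("All metrics must be finite.", call. = FALSE)
  }
  norm_hi <- function(v) { # higher is better
    rng <- range(v)
    if (diff(rng) == 0) rep(1, length(v)) else (v - rng[1]) / diff(rng)
  }
  (norm_hi(-mae_hct) + norm_hi(r_hct) + norm_hi(-mae_ecv) + norm_hi(r_ecv)) / 4
}

# In-sample Hct and ECV metrics for a vector of Hct-percent predictions on a
# cohort subset. ECV metrics use the per-record attenuation-change pair when
# present; otherwise only the Hct metrics are available and the ECV entries
# repeat them (the combined score then effectively weights Hct only).
prediction_metrics <- function(cohort, pred_pct) {
  truth <- cohort$hct
  pred <- pred_pct / 100
  mh <- mean(abs(pred - truth))
  rh <- safe_cor(pred, truth)
  if (all(c("dhu_myo", "dhu_blood") %in% names(cohort))) {
    con <- (1 - truth) * cohort$dhu_myo / cohort$dhu_blood
    syn <- (1 - pred) * cohort$dhu_myo / cohort$dhu_blood
    me <- mean(abs(syn - con))
    re <- safe_cor(syn, con)
  } else {
    me <- mh
    re <- rh
  }
  c(mae_hct = mh, r_hct = rh, mae_ecv = me, r_ecv = re)
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    if (mean(abs(a - b)) == 0) 1 else 0
  } else {
    stats::cor(a, b)
  }
}
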