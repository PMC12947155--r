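#' Significance-gated search for an optimal covariate binning
#'
#' Enumerates partitions of a continuous covariate into 2 to 5 bins with
#' varying widths and retains only configurations in which (i) the
#' attenuation-haematocrit Pearson correlation is significant *within every
#' bin* and (ii) every bin boundary carries a significant change in
#' calibration slope (the per-boundary interaction test; for two bins this
#' is the single HU x bin interaction term). Among retained configurations
#' the one with the highest [combined_score()] of held-out haematocrit and
#' ECV metrics wins; ties go to fewer bins, then to the smaller first edge.
#'
#' Candidate bin edges are drawn from the covariate's empirical percentiles
#' on a 5-percentile lattice (p10 to p90), taking all strictly increasing
#' combinations; when a bin count would exceed `max_candidates`
#' combinations, the lattice is coarsened deterministically (10-, then
#' 20-percentile steps). Percentile edges guarantee occupied bins and a
#' finite, record-order-invariant search space.
#'
#' @param cohort Cohort tibble (columns `hct`, `hu_blood`, the covariate,
#'   and optionally `dhu_myo`/`dhu_blood` for the ECV half of the score).
#' @param covariate `"bmi"`, `"age"`, `"egfr"` or `"creatinine"`.
#' @param k_range Bin counts to consider (default `2:5`).
#' @param alpha Two-sided significance level for both gates (default 0.05).
#' @param bonferroni If `TRUE` (the default), `alpha` is divided by the
#'   number of candidate configurations before gating. The search runs on
#'   the order of a thousand per-candidate tests, so without family-wise
#'   control chance-significant boundaries are retained at a rate far above
#'   `alpha`; set `FALSE` to reproduce the uncorrected single-threshold
#'   gating appropriate for small cohorts and few candidates.
#' @param min_bin_n Minimum records per bin (default 5).
#' @param max_candidates Cap on edge combinations per bin count.
#' @param cv If `TRUE` (the default), candidate metrics are computed on
#'   analytic leave-one-out predictions of the per-bin fits (deterministic
#'   and record-order invariant); this keeps the winner's curse of
#'   in-sample scoring from promoting over-fitted configurations when the
#'   candidate grid is large. `FALSE` scores in sample, as the original
#'   procedure did. With `cv = TRUE` a configuration is additionally kept
#'   only when it beats every one-boundary-removed reduction of itself on
#'   held-out error and correlation.
#' @return A `bin_search_result` (list with `covariate`, `edges`, `per_bin`
#'   tibble, `boundary_p`, `score`, `metrics`, `alpha`, `n_candidates`,
#'   `n_retained`, `grid_settings`), or `NULL` when no configuration
#'   survives the gates.
#' @export
bin_search <- function(cohort, covariate = "bmi", k_range = 2:5,
                       alpha = 0.05, bonferroni = TRUE, min_bin_n = 5L,
                       max_candidates = 2000L, cv = TRUE) {
  covariate <- match.arg(covariate, c("bmi", "age", "egfr", "creatinine"))
  if (nrow(cohort) == 0L) stop("Cohort is empty.", call. = FALSE)
  x <- cohort[[covariate]]
  hu <- cohort$hu_blood
  y <- cohort$hct * 100

  candidates <- purrr::map(k_range, function(k) {
    edge_candidates(x, k, max_candidates)
  })
  candidates <- purrr::flatten(candidates)
  if (length(candidates) == 0L) return(NULL)
  gate_alpha <- if (bonferroni) alpha / length(candidates) else alpha

  evaluated <- purrr::map(candidates, function(edges) {
    evaluate_bin_config(cohort, x, hu, y, edges, gate_alpha, min_bin_n, cv)
  })
  retained <- purrr::compact(evaluated)
  # every boundary must earn its keep out of sample: a configuration is kept
  # only if it beats each of its one-boundary-removed reductions on held-out
  # Hct error and correlation (skipped under in-sample scoring, which
  # reproduces the raw procedure)
  if (cv) {
    retained <- purrr::keep(retained, function(cand) {
      purrr::every(seq_along(cand$edges), function(drop) {
        red <- bin_loo_metrics(cohort, x, hu, y, cand$edges[-drop])
        cand$metrics[["mae_hct"]] < red[["mae_hct"]] &&
          cand$metrics[["r_hct"]] > red[["r_hct"]]
      })
    })
  }
  if (length(retained) == 0L) return(NULL)

  metrics <- purrr::map_dfr(retained, ~ tibble::as_tibble_row(.x$metrics))
  scores <- combined_score(metrics$mae_hct, metrics$r_hct,
                           metrics$mae_ecv, metrics$r_ecv)
  ord <- order(-scores,
               purrr::map_int(retained, ~ length(.x$edges) + 1L),
               purrr::map_dbl(retained, ~ .x$edges[1]))
  best <- retained[[ord[1]]]
  structure(
    list(covariate = covariate, edges = best$edges, per_bin = best$per_bin,
         boundary_p = best$boundary_p, score = scores[ord[1]],
         metrics = best$metrics, alpha = gate_alpha,
         n_candidates = length(candidates), n_retained = length(retained),
         grid_settings = list(k_range = k_range, lattice_step = 0.05,
                              max_candidates = max_candidates,
                              min_bin_n = min_bin_n, cv = cv)),
    class = "bin_search_result"
  )
}

# strictly increasing (k-1)-edge combinations on a percentile lattice,
# coarsening the lattice when the combination count would blow up
edge_candidates <- function(x, k, max_candidates) {
  for (step in c(0.05, 0.10, 0.20)) {
    lattice <- unique(unname(stats::quantile(x, seq(0.10, 0.90, by = step))))
    m <- length(lattice)
    if (k - 1L > m) next
    if (choose(m, k - 1L) <= max_candidates) {
      combos <- utils::combn(lattice, k - 1L, simplify = FALSE)
      return(combos)
    }
  }
  list()
}

# analytic leave-one-out predictions of a simple OLS line fitted to (xs, ys):
# loo_i = y_i - e_i / (1 - h_i) with hat value h_i = 1/n + (x_i - xbar)^2/Sxx.
# Falls back to the in-sample prediction for degenerate fits.
loo_line_predictions <- function(xs, ys) {
  n <- length(xs)
  mx <- mean(xs)
  sxx <- sum((xs - mx)^2)
  if (n < 4L || sxx == 0) {
    if (sxx == 0) return(rep(mean(ys), n))
    b <- sum((xs - mx) * (ys - mean(ys))) / sxx
    return(b * xs + (mean(ys) - b * mx))
  }
  b <- sum((xs - mx) * (ys - mean(ys))) / sxx
  a <- mean(ys) - b * mx
  fit <- a + b * xs
  h <- 1 / n + (xs - mx)^2 / sxx
  h <- pmin(h, 1 - 1e-8)
  ys - (ys - fit) / (1 - h)
}

# held-out (or in-sample) predictions for a binned piecewise-linear model
bin_predictions <- function(bin, hu, y, k, cv) {
  pred <- numeric(length(y))
  for (j in seq_len(k)) {
    sel <- bin == j
    pred[sel] <- if (cv) loo_line_predictions(hu[sel], y[sel]) else {
      xs <- hu[sel]; ys <- y[sel]
      mx <- mean(xs)
      sxx <- sum((xs - mx)^2)
      if (sxx == 0) rep(mean(ys), sum(sel)) else {
        b <- sum((xs - mx) * (ys - mean(ys))) / sxx
        b * xs + (mean(ys) - b * mx)
      }
    }
  }
  pred
}

# ungated leave-one-out metrics for an arbitrary edge set (possibly empty,
# i.e. the single global fit)
bin_loo_metrics <- function(cohort, x, hu, y, edges) {
  bin <- findInterval(x, c(-Inf, edges, Inf), left.open = FALSE)
  pred <- bin_predictions(bin, hu, y, length(edges) + 1L, cv = TRUE)
  prediction_metrics(cohort, pred)
}

# gate a single edge set; NULL when any gate fails
evaluate_bin_config <- function(cohort, x, hu, y, edges, alpha, min_bin_n,
                                cv = TRUE) {
  bin <- findInterval(x, c(-Inf, edges, Inf), left.open = FALSE)
  k <- length(edges) + 1L
  counts <- tabulate(bin, nbins = k)
  if (any(counts < max(min_bin_n, 3L))) return(NULL)

  slopes <- numeric(k); intercepts <- numeric(k); sxx <- numeric(k)
  rss <- numeric(k); p_cor <- numeric(k); r2 <- numeric(k)
  pred <- numeric(length(y))
  for (j in seq_len(k)) {
    sel <- bin == j
    xs <- hu[sel]; ys <- y[sel]
    if (stats::sd(xs) == 0) return(NULL)
    p_cor[j] <- pearson_p(xs, ys)
    if (is.na(p_cor[j]) || p_cor[j] >= alpha) return(NULL)
    mx <- mean(xs); my <- mean(ys)
    sxx[j] <- sum((xs - mx)^2)
    slopes[j] <- sum((xs - mx) * (ys - my)) / sxx[j]
    intercepts[j] <- my - slopes[j] * mx
    res <- ys - (slopes[j] * xs + intercepts[j])
    rss[j] <- sum(res^2)
    tss <- sum((ys - my)^2)
    r2[j] <- if (tss > 0) 1 - rss[j] / tss else 1
    pred[sel] <- slopes[j] * xs + intercepts[j]
  }
  # per-boundary slope-change test: pooled-variance t on adjacent bins,
  # equivalent to the interaction contrast in the full HU x bin model
  df <- length(y) - 2L * k
  if (df < 1L) return(NULL)
  sigma2 <- sum(rss) / df
  boundary_p <- purrr::map_dbl(seq_len(k - 1L), function(j) {
    se <- sqrt(sigma2 * (1 / sxx[j] + 1 / sxx[j + 1L]))
    tstat <- (slopes[j + 1L] - slopes[j]) / se
    2 * stats::pt(-abs(tstat), df = df)
  })
  if (any(boundary_p >= alpha)) return(NULL)

  score_pred <- if (cv) bin_predictions(bin, hu, y, k, cv = TRUE) else pred
  list(
    edges = edges,
    per_bin = tibble::tibble(
      bin = seq_len(k),
      low = c(-Inf, edges), high = c(edges, Inf),
      n = counts, slope = slopes, intercept = intercepts,
      r_squared = r2, p_cor = p_cor
    ),
    boundary_p = boundary_p,
    metrics = prediction_metrics(cohort, score_pred)
  )
}

#' @export
print.bin_search_result <- function(x, ...) {
  cat(sprintf("<bin_search_result> %s: %d bins (edges %s), score %.3f\n",
              x$covariate, length(x$edges) + 1L,
              paste(signif(x$edges, 4), collapse = ", "), x$score))
  cat(sprintf("  %d/%d candidates retained at alpha = %g\n",
              x$n_retained, x$n_candidates, x$alpha))
  print(x$per_bin)
  invisible(x)
}

#' @method tidy bin_search_result
#' @export
tidy.bin_search_result <- function(x, ...) {
  dplyr::mutate(x$per_bin, covariate = x$covariate, .before = 1)
}

#' @method glance bin_search_result
#' @export
glance.bin_search_result <- function(x, ...) {
  tibble::tibble(covariate = x$covariate, n_bins = length(x$edges) + 1L,
                 score = x$score, mae_hct = x$metrics[["mae_hct"]],
                 r_hct = x$metrics[["r_hct"]],
                 mae_ecv = x$metrics[["mae_ecv"]],
                 r_ecv = x$metrics[["r_ecv"]],
                 n_retained = x$n_retained, alpha = x$alpha)
}

#' Turn a bin-search result into a stratified model
#'
#' @param result A `bin_search_result` over BMI.
#' @param sex The sex the search was run on (`"male"`, `"female"`, or
#'   `"any"`).
#' @param fallback Fallback policy for uncovered records.
#' @return A [stratified_hct_model()] with one route per bin.
#' @export
as_stratified_model <- function(result, sex = "any",
                                fallback = "flag_missing") {
  stopifnot(inherits(result, "bin_search_result"))
  if (result$covariate != "bmi") {
    stop("Only BMI bin results convert to a routed model.", call. = FALSE)
  }
  routes <- purrr::pmap(result$per_bin, function(bin, low, high, n, slope,
                                                 intercept, r_squared, p_cor) {
    list(model_predicate(sex, low, high),
         linear_hct_model(slope, intercept,
                          label = sprintf("%s_bin%d", sex, bin),
                          n_fit = n, r_squared = r_squared))
  })
  stratified_hct_model(routes, fallback = fallback,
                       label = sprintf("%s_bmi_binned", sex))
}
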