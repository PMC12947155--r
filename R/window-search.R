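#' Sliding-window search for a covariate subgroup with a significant model
#'
#' When no bin configuration survives the significance gates, a sliding
#' window of variable widths is moved across the covariate's range to find
#' the subset of records within which the attenuation-haematocrit
#' correlation is significant and whose refitted model most improves
#' whole-cohort predictions. Windows are inclusive intervals
#' `[start, start + width]`; widths default to 25% to 90% of the observed
#' covariate range in 5 equal steps, with starting positions on the same
#' 5-percentile lattice as [bin_search()] plus the data minimum. Duplicate
#' record subsets are evaluated once.
#'
#' Candidate windows are scored on a common footing: records inside the
#' window are predicted by the window's refitted model, records outside it
#' by the unrestricted whole-cohort fit, and [combined_score()] is taken
#' over the resulting whole-cohort metrics (cross-validated by default).
#' This makes windows of different sizes comparable and rewards a window
#' that covers every record the restricted model genuinely helps, rather
#' than a small locally-clean subset. Ties go to the narrower window, then
#' to the smaller lower edge.
#'
#' @inheritParams bin_search
#' @param width_fracs Window widths as fractions of the covariate range.
#' @param min_n Minimum records per window (default 10).
#' @param bonferroni If `TRUE` (the default), `alpha` is divided by the
#'   number of distinct candidate windows before gating, as in
#'   [bin_search()].
#' @param cv If `TRUE` (the default), scoring uses analytic leave-one-out
#'   predictions, as in [bin_search()]; `FALSE` scores in sample.
#' @return A `window_search_result` (list with `covariate`, `low`, `high`
#'   clipped to the data range, `model`, `correlation_p`, `score`,
#'   `metrics`, `n`, `alpha`, `grid_settings`), or `NULL` when no window
#'   passes the gate.
#' @export
window_search <- function(cohort, covariate = "bmi",
                          width_fracs = seq(0.25, 0.90, length.out = 5),
                          alpha = 0.05, min_n = 10L, bonferroni = TRUE,
                          cv = TRUE) {
  covariate <- match.arg(covariate, c("bmi", "age", "egfr", "creatinine"))
  if (length(width_fracs) == 0L) {
    stop("`width_fracs` must be non-empty.", call. = FALSE)
  }
  if (nrow(cohort) < min_n) stop("Cohort too small.", call. = FALSE)
  x <- cohort[[covariate]]
  rng <- range(x)
  starts <- unique(c(rng[1],
                     unname(stats::quantile(x, seq(0.10, 0.90, by = 0.05)))))
  grid <- tidyr::expand_grid(start = starts,
                             width = width_fracs * diff(rng))

  hu <- cohort$hu_blood
  y <- cohort$hct * 100
  pred_global <- bin_predictions(rep(1L, length(y)), hu, y, 1L, cv)

  # enumerate the distinct record subsets first so the gate can be
  # corrected for their multiplicity
  seen <- character(0)
  windows <- purrr::pmap(grid, function(start, width) {
    sel <- x >= start & x <= start + width
    n <- sum(sel)
    if (n < min_n) return(NULL)
    key <- paste(n, round(min(x[sel]), 10), round(max(x[sel]), 10))
    if (key %in% seen) return(NULL)
    seen <<- c(seen, key)
    if (stats::sd(hu[sel]) == 0) return(NULL)
    list(start = start, width = width, sel = sel, n = n)
  })
  windows <- purrr::compact(windows)
  if (length(windows) == 0L) return(NULL)
  gate_alpha <- if (bonferroni) alpha / length(windows) else alpha

  evaluated <- purrr::map(windows, function(w) {
    sel <- w$sel
    p <- pearson_p(hu[sel], y[sel])
    if (is.na(p) || p >= gate_alpha) return(NULL)
    model <- fit_linear(hu[sel], y[sel],
                        label = sprintf("%s_window", covariate))
    pred <- pred_global
    pred[sel] <- bin_predictions(rep(1L, w$n), hu[sel], y[sel], 1L, cv)
    list(low = max(w$start, rng[1]), high = min(w$start + w$width, rng[2]),
         width = w$width, model = model, correlation_p = p, n = w$n,
         metrics = prediction_metrics(cohort, pred))
  })
  retained <- purrr::compact(evaluated)
  if (length(retained) == 0L) return(NULL)

  metrics <- purrr::map_dfr(retained, ~ tibble::as_tibble_row(.x$metrics))
  scores <- combined_score(metrics$mae_hct, metrics$r_hct,
                           metrics$mae_ecv, metrics$r_ecv)
  ord <- order(-scores,
               purrr::map_dbl(retained, "width"),
               purrr::map_dbl(retained, "low"))
  best <- retained[[ord[1]]]
  structure(
    list(covariate = covariate, low = best$low, high = best$high,
         model = best$model, correlation_p = best$correlation_p,
         score = scores[ord[1]], metrics = best$metrics, n = best$n,
         alpha = gate_alpha, n_retained = length(retained),
         grid_settings = list(width_fracs = width_fracs, min_n = min_n,
                              cv = cv)),
    class = "window_search_result"
  )
}

#' @export
print.window_search_result <- function(x, ...) {
  cat(sprintf("<window_search_result> %s in [%.4g, %.4g] (n = %d)\n",
              x$covariate, x$low, x$high, x$n))
  cat(sprintf("  correlation P = %.3g, score %.3f\n", x$correlation_p, x$score))
  print(x$model)
  invisible(x)
}

#' @method tidy window_search_result
#' @export
tidy.window_search_result <- function(x, ...) {
  tibble::tibble(covariate = x$covariate, low = x$low, high = x$high,
                 slope = x$model$slope, intercept = x$model$intercept,
                 r_squared = x$model$r_squared, correlation_p = x$correlation_p,
                 n = x$n, score = x$score)
}

#' Serialize a search result to JSON (with a readable text report)
#'
#' @param result A `bin_search_result` or `window_search_result` (or `NULL`,
#'   serialized as an explicit no-result record).
#' @param path Output JSON path.
#' @param report Optional path for a plain-text summary of the selected
#'   stratification.
#' @return `path`, invisibly.
#' @export
write_search_result <- function(result, path, report = NULL) {
  payload <- if (is.null(result)) {
    list(selected = FALSE)
  } else if (inherits(result, "bin_search_result")) {
    list(selected = TRUE, type = "bins", covariate = result$covariate,
         edges = result$edges,
         per_bin = purrr::pmap(result$per_bin, function(...) {
           r <- list(...)
           r$low <- num_out(r$low); r$high <- num_out(r$high)
           r
         }),
         boundary_p = result$boundary_p, score = result$score,
         alpha = result$alpha, grid_settings = result$grid_settings)
  } else {
    list(selected = TRUE, type = "window", covariate = result$covariate,
         window = list(low = result$low, high = result$high),
         model = list(slope = result$model$slope,
                      intercept = result$model$intercept,
                      r_squared = result$model$r_squared, n = result$n),
         correlation_p = result$correlation_p, score = result$score,
         alpha = result$alpha, grid_settings = result$grid_settings)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(report)) {
    writeLines(utils::capture.output(print(result)), report)
  }
  invisible(path)
}
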