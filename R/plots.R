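#' Plot a cohort's attenuation-haematocrit calibration
#'
#' Scatter of haematocrit-percent against blood-pool attenuation, coloured
#' by sex, with any number of calibration lines overlaid.
#'
#' @param cohort Cohort tibble.
#' @param models Named list of [linear_hct_model()]s to overlay (stratified
#'   models are drawn per route).
#' @return A ggplot object.
#' @export
plot_calibration <- function(cohort, models = list()) {
  p <- ggplot2::ggplot(cohort,
                       ggplot2::aes(x = .data$hu_blood, y = .data$hct * 100)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sex), alpha = 0.5) +
    ggplot2::labs(x = "Blood-pool attenuation (HU)",
                  y = "Haematocrit (%)", colour = "Sex") +
    ggplot2::theme_minimal()
  lines <- purrr::imap_dfr(models, function(m, nm) {
    if (inherits(m, "stratified_hct_model")) {
      purrr::map_dfr(m$routes, function(r) {
        tibble::tibble(model = sprintf("%s [%s]", nm, r[[2]]$label),
                       slope = r[[2]]$slope, intercept = r[[2]]$intercept)
      })
    } else {
      tibble::tibble(model = nm, slope = m$slope, intercept = m$intercept)
    }
  })
  if (nrow(lines)) {
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   linetype = .data$model)
    )
  }
  p
}

#' @method autoplot hct_model_comparison
#' @export
autoplot.hct_model_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "label", "mae_hct", "r_hct", "mae_ecv", "r_ecv"),
    -"label", names_to = "metric", values_to = "value"
  )
  long$label <- factor(long$label, levels = unique(object$label))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Model comparison: Hct and ECV metrics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot bin_search_result
#' @export
autoplot.bin_search_result <- function(object, cohort = NULL, ...) {
  per_bin <- object$per_bin
  per_bin$bin <- factor(per_bin$bin)
  p <- ggplot2::ggplot()
  if (!is.null(cohort)) {
    x <- cohort[[object$covariate]]
    bin <- findInterval(x, c(-Inf, object$edges, Inf))
    pts <- tibble::tibble(hu = cohort$hu_blood, hct = cohort$hct * 100,
                          bin = factor(bin))
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$hu, y = .data$hct,
                               colour = .data$bin), alpha = 0.4)
  }
  p + ggplot2::geom_abline(
    data = per_bin,
    ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                 colour = .data$bin)
  ) +
    ggplot2::labs(x = "Blood-pool attenuation (HU)", y = "Haematocrit (%)",
                  colour = sprintf("%s bin", object$covariate)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ecv_map
#' @export
autoplot.ecv_map <- function(object, slice = NULL, ...) {
  d <- dim(object$ecv)
  slice <- slice %||% ceiling(d[3] / 2)
  sl <- object$ecv[, , slice]
  df <- tibble::tibble(x = rep(seq_len(d[1]), times = d[2]),
                       y = rep(seq_len(d[2]), each = d[1]),
                       ecv = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$ecv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s ECV map, slice %d (mean LV ECV %.3f)",
                                  object$source, slice, object$mean_lv_ecv),
                  fill = "ECV") +
    ggplot2::theme_void()
}
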