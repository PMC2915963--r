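#' Error-vs-distance profile plot
#'
#' Scatter of the per-site median percentage error against each site's
#' distance to the internal boundary, one panel per measure — the standard
#' way to read how quickly edge bias decays away from the guard boundary.
#' A pure function of the saved per-site medians, so profiles can be redrawn
#' from the CSV artifacts without re-simulation.
#'
#' @param per_location Per-site medians (the `per_location` element of
#'   [run_experiment()], or the corresponding CSV read back in).
#' @param measures Character vector of measures to plot (default: all
#'   present).
#' @param statistic Column to plot: `"med_pct_error"` (default) or
#'   `"med_abs_bias"`.
#' @param path Optional output file; written with [ggplot2::ggsave()].
#' @return The ggplot object, invisibly if `path` is given.
#' @export
plot_error_profile <- function(per_location, measures = NULL,
                               statistic = c("med_pct_error",
                                             "med_abs_bias"),
                               path = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(measures)) measures <- unique(per_location$measure)
  missing_m <- setdiff(measures, unique(per_location$measure))
  if (length(missing_m)) {
    stop("measure(s) not present in summary: ",
         paste(missing_m, collapse = ", "))
  }
  dat <- per_location[per_location$measure %in% measures, ]
  ylab <- if (statistic == "med_pct_error") {
    "median percentage error (%)"
  } else {
    "median absolute bias"
  }
  p <- ggplot2::ggplot(
    dat, ggplot2::aes(x = .data$dist_to_boundary,
                      y = .data[[statistic]])) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "distance to internal boundary", y = ylab) +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 6, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Contour map of median percentage error over the internal area
#'
#' Renders the per-site median percentage error for one measure as a filled
#' raster with contour lines over the internal square, optionally overlaying
#' the cluster centers (error hot-spots concentrate near the boundary and
#' around centers). Sites must form the regular evaluation mesh; the field
#' is drawn cell-wise on that mesh (values interpolated linearly between
#' mesh points by the contouring).
#'
#' @param per_location Per-site medians (see [plot_error_profile()]).
#' @param measure Single measure name.
#' @param centers Optional cluster-center data frame to overlay.
#' @param statistic Column to map (default `"med_pct_error"`).
#' @param bins Number of contour bins (default 10, quantile-spaced when the
#'   field varies).
#' @param path Optional output file.
#' @return The ggplot object, invisibly if `path` is given.
#' @export
plot_contour <- function(per_location, measure, centers = NULL,
                         statistic = "med_pct_error", bins = 10,
                         path = NULL) {
  if (!measure %in% unique(per_location$measure)) {
    stop("measure not present in summary: ", measure)
  }
  dat <- per_location[per_location$measure == measure, ]
  z <- dat[[statistic]]
  p <- ggplot2::ggplot(
    dat, ggplot2::aes(x = .data$x, y = .data$y,
                      z = .data[[statistic]])) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[statistic]])) +
    ggplot2::scale_fill_viridis_c(name = statistic) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = measure, x = "x", y = "y") +
    ggplot2::theme_bw()
  # contour lines only when the field actually varies
  if (length(unique(stats::na.omit(z))) > 1L) {
    lv <- unique(stats::quantile(z, probs = seq(0, 1, length.out = bins + 1),
                                 na.rm = TRUE, names = FALSE))
    lv <- lv[lv > min(z, na.rm = TRUE) & lv < max(z, na.rm = TRUE)]
    if (length(lv)) {
      p <- p + ggplot2::geom_contour(breaks = lv, colour = "white",
                                     linewidth = 0.3)
    }
  }
  if (!is.null(centers)) {
    p <- p + ggplot2::geom_point(
      data = centers,
      mapping = ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, shape = 16, size = 2, colour = "red")
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}
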