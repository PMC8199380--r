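#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an FWC map
#'
#' @param map An `fwc_map`; invalid pixels are shown blank.
#' @param roi Optional [roi_mask()] whose outline is overdrawn.
#' @return A ggplot.
#' @export
plot_fwc_map <- function(map, roi = NULL) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(map$fwc)), ncol(map$fwc)),
    col = rep(seq_len(ncol(map$fwc)), each = nrow(map$fwc)),
    fwc = as.vector(map$fwc)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$fwc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "FWC", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(roi)) {
    m <- if (inherits(roi, "roi_mask")) roi$mask else roi
    dd <- df[as.vector(m), ]
    p <- p + ggplot2::geom_tile(data = dd, fill = NA, colour = "red",
                                linewidth = 0.1)
  }
  p
}

#' ICC QC report plot
#'
#' Per-feature ICC with the retention (0.75) and excellence (0.9)
#' boundaries.
#'
#' @param object An `fwc_icc_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fwc_icc_report <- function(object, ...) {
  df <- dplyr::arrange(object$features, .data$icc)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc, y = .data$feature,
                                   colour = .data$grade)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(object$threshold, 0.9),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "ICC(2,1)", y = NULL, colour = "agreement") +
    ggplot2::theme_minimal()
}

#' Correlation screening heat map
#'
#' Spearman r_s per feature-by-metric cell; BH-significant cells are
#' outlined.
#'
#' @param object An `fwc_correlation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fwc_correlation_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$feature,
                                   fill = .data$r_s)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$bh_significant),
                       fill = NA, colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = expression(r[s])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Kaplan-Meier plot for a dichotomised marker
#'
#' @param curves Output of [km_curves()].
#' @param marker Optional marker name for the title.
#' @return A ggplot step plot of the two survival curves.
#' @export
plot_km <- function(curves, marker = NULL) {
  start <- curves |>
    dplyr::group_by(.data$group) |>
    dplyr::slice(1) |>
    dplyr::mutate(time = 0, survival = 1) |>
    dplyr::ungroup()
  ggplot2::ggplot(dplyr::bind_rows(start, curves),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival",
                  colour = "prognostic group", title = marker) +
    ggplot2::theme_minimal()
}
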