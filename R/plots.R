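# ggplot2 views of the pipeline's result types.

#' Plot a K-function curve against its CSR baseline
#'
#' @param object A `k_curve` tibble from [ripley_k()].
#' @param baseline Optional [csr_baseline()] tibble on the same radii; drawn
#'   as a ribbon of mean +/- 2 SD.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k_curve <- function(object, baseline = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$k)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = expression(r ~ (mu * m)),
                  y = expression(hat(K)(r) ~ (mu * m^2)),
                  title = sprintf("Ripley's K (N = %d)", attr(object, "n_points")))
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_ribbon(
      data = baseline,
      ggplot2::aes(x = .data$r, ymin = .data$mean_k - 2 * .data$sd_k,
                   ymax = .data$mean_k + 2 * .data$sd_k),
      inherit.aes = FALSE, alpha = 0.25
    ) +
      ggplot2::geom_line(data = baseline,
                         ggplot2::aes(x = .data$r, y = .data$mean_k),
                         inherit.aes = FALSE, linetype = "dashed")
  }
  p
}

#' Volcano-style view of gene calls
#'
#' Mean clustering Z against mean spot-count Z with hit thresholds and hit
#' highlighting, mirroring the standard two-readout screen summary plot.
#'
#' @param object A `gene_calls` tibble from [call_hits()].
#' @param z_hit Threshold lines to draw (default 2.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_calls <- function(object, z_hit = 2.5, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_z_mean_clustering_score,
                                   y = .data$mean_z_mean_spot_count,
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = c(-z_hit, z_hit), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-z_hit, z_hit), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean Z (clustering score)", y = "mean Z (spot count)",
                  colour = "hit")
}

#' Plot a fitted cell-cycle gate
#'
#' Log2 DAPI histogram with the fitted G1/G2 modes and exclusion cuts.
#'
#' @param object A `phase_gate` from [fit_phase_gate()].
#' @param cells Optional tibble with `dapi_total` used for the histogram; if
#'   omitted only the cut positions are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_gate <- function(object, cells = NULL, ...) {
  cuts <- tibble::tibble(
    cut = c(object$subg1_cut, object$g1_g2_cut, object$over4n_cut),
    kind = c("subG1", "G1/G2", ">4N")
  )
  p <- ggplot2::ggplot()
  if (!is.null(cells)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(x = log2(cells$dapi_total)),
      ggplot2::aes(x = .data$x), bins = 120, fill = "grey70"
    )
  }
  p +
    ggplot2::geom_vline(data = cuts,
                        ggplot2::aes(xintercept = .data$cut,
                                     colour = .data$kind),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 integrated DAPI", y = "cells", colour = "cut")
}

#' Plate heat map of a well-level feature
#'
#' @param wells Well summaries from [aggregate_wells()] (or with Z columns).
#' @param feature Column to map to fill.
#' @param replicate Replicate to show.
#' @return A ggplot object, faceted by plate.
#' @export
plot_plate_heatmap <- function(wells, feature = "mean_clustering_score",
                               replicate = 1L) {
  df <- dplyr::filter(wells, .data$replicate == !!replicate) |>
    dplyr::mutate(
      well_row = substr(.data$well, 1, 1),
      well_col = as.integer(substr(.data$well, 2, 3))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$well_col,
                                   y = .data$well_row,
                                   fill = .data[[feature]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~plate) +
    ggplot2::scale_y_discrete(limits = rev(sort(unique(df$well_row)))) +
    ggplot2::labs(x = "column", y = "row", fill = feature)
}
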