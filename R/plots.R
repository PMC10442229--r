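#' Plot an RT profile
#'
#' Early-positive/late-negative RT scores along one or more chromosomes,
#' optionally colored by a class track.
#'
#' @param data Tibble with `chrom`, `start`, `end`, `rt`, optionally `label`.
#' @return A ggplot.
#' @export
plot_rt_profile <- function(data) {
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$rt))
  if ("label" %in% names(data)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$label), width = NA)
  } else {
    p <- p + ggplot2::geom_area(fill = "grey70") + ggplot2::geom_line()
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "RT score (early > 0 > late)") +
    ggplot2::theme_minimal()
}

#' Plot a virtual 4C viewpoint profile
#'
#' @param profile A [virtual_4c()] profile.
#' @param calls Optional [far_cis_calls()]/[trans_calls()] result whose
#'   merged intervals are highlighted.
#' @return A ggplot.
#' @export
plot_viewpoint <- function(profile, calls = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$signal)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1,
                        scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "contacts per 10,000") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls$intervals) > 0) {
    p <- p + ggplot2::geom_rect(
      data = calls$intervals,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot an aggregate contact submatrix
#'
#' @param m A matrix from [aggregate_pairs()].
#' @return A ggplot heatmap centered on the anchor pair.
#' @export
plot_aggregate <- function(m) {
  flank <- (nrow(m) - 1) / 2
  d <- tidyr::expand_grid(i = -flank:flank, j = -flank:flank)
  d$value <- as.vector(m)
  ggplot2::ggplot(d, ggplot2::aes(.data$j, .data$i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "offset (bins)", y = "offset (bins)",
                  fill = "mean contacts") +
    ggplot2::theme_minimal()
}
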