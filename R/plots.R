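#' Plot a windowed genome-scan track
#'
#' Faceted per-statistic tracks along the genome; optional valley/peak
#' intervals are shaded.
#'
#' @param scan Tibble from [scan_windows()] (or any window table).
#' @param stats Character vector of statistic columns to plot.
#' @param valleys Optional `valley_set` tibble to shade.
#' @return A ggplot object.
#' @export
plot_scan <- function(scan, stats = c("fst", "dxy", "gmin"),
                      valleys = NULL) {
  stats <- intersect(stats, names(scan))
  long <- tidyr::pivot_longer(
    scan[, c("chrom", "start", "end", stats)],
    cols = dplyr::all_of(stats), names_to = "statistic",
    values_to = "value")
  long$mid <- (long$start + long$end) / 2
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(statistic ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(valleys) && nrow(valleys) > 0)
    p <- p + ggplot2::geom_rect(
      data = valleys,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "steelblue",
      inherit.aes = FALSE)
  p
}

#' @describeIn fit_hmm_classify Plot the fitted track with decoded states.
#' @export
autoplot.hmm_fit <- function(object, ...) {
  df <- tibble::tibble(index = seq_along(object$values),
                       value = object$values,
                       state = object$state)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c("grey50", "firebrick")) +
    ggplot2::labs(x = "window", y = "statistic") +
    ggplot2::theme_minimal()
}

#' @describeIn select_model Plot model posterior probabilities.
#' @param object An `abc_selection`.
#' @export
autoplot.abc_selection <- function(object, ...) {
  ggplot2::ggplot(object$posterior,
                  ggplot2::aes(x = .data$model, y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' Triangle plot of hybrid index versus interspecific heterozygosity
#'
#' Individuals fall inside the triangle bounded by
#' `h_int <= 2 * min(h, 1 - h)` at diagnostic markers; F1s sit at the apex
#' (0.5, 1), parents at the base corners.
#'
#' @param ancestry Tibble from [ancestry_indices()], optionally with a
#'   `class` column used for colour.
#' @return A ggplot object.
#' @export
plot_ancestry_triangle <- function(ancestry) {
  tri <- tibble::tibble(h = c(0, 0.5, 1), h_int = c(0, 1, 0))
  aes_pt <- if ("class" %in% names(ancestry))
    ggplot2::aes(x = .data$h, y = .data$h_int, colour = .data$class)
  else ggplot2::aes(x = .data$h, y = .data$h_int)
  ggplot2::ggplot(ancestry, aes_pt) +
    ggplot2::geom_path(data = tri,
                       ggplot2::aes(x = .data$h, y = .data$h_int),
                       inherit.aes = FALSE, linetype = 2,
                       colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "hybrid index (h)",
                  y = "interspecific heterozygosity") +
    ggplot2::theme_minimal()
}
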