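#' Bar chart of adenoma detection rates by GRS category
#'
#' @param trend A `polygrs_trend` object from [trend_across_categories()],
#'   or a `grs_study` (its trend component is used).
#' @return A ggplot object.
#' @export
plot_detection_rates <- function(trend) {
  if (inherits(trend, "grs_study")) trend <- trend$trend
  stopifnot(inherits(trend, "polygrs_trend"))
  tab <- trend$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$category, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$rate)),
      vjust = -0.4, size = 3.4
    ) +
    ggplot2::scale_y_continuous(
      labels = function(x) sprintf("%.0f%%", 100 * x),
      expand = ggplot2::expansion(mult = c(0, 0.12))
    ) +
    ggplot2::labs(
      x = "GRS risk category", y = "Adenoma detection rate",
      subtitle = sprintf("Cochran–Armitage p-trend = %.3g",
                         trend$p.value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier diagnosis-free curves
#'
#' Step curves of adenoma-diagnosis-free probability against age, one per
#' GRS risk group.
#'
#' @param object A `polygrs_km` object from [km_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polygrs_km <- function(object, ...) {
  tab <- generics::tidy(object)
  start <- tab |>
    dplyr::summarise(time = 0, survival = 1, .by = "group")
  tab <- dplyr::bind_rows(start,
                          tab[, c("group", "time", "survival")]) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Age (years)",
                  y = "Adenoma diagnosis-free probability",
                  colour = "GRS group") +
    ggplot2::theme_minimal()
}

#' Histogram of GRS with category cutpoints
#'
#' @param scores Score tibble from [compute_grs()].
#' @param low_cut,high_cut Category boundaries to mark (defaults 0.5, 1.5).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_grs_distribution <- function(scores, low_cut = 0.5, high_cut = 1.5,
                                  bins = 40) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$grs)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(low_cut, high_cut),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "GRS (relative risk vs population)", y = "Subjects") +
    ggplot2::theme_minimal()
}
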