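#' Distributions of island properties
#'
#' Plots the distributions of island length, GC content, observed/expected
#' CpG ratio and CpG density, optionally across several prediction sets.
#' Sliding-window islands are expected to pile up against their length and
#' composition thresholds, while cluster islands spread freely below them.
#'
#' @param ... Named island tibbles (e.g. `cpgcluster = isl1, tj = isl2`);
#'   unnamed sets fall back on their `source` column.
#' @return A ggplot object.
#' @export
plot_island_properties <- function(...) {
  sets <- list(...)
  nms <- names(sets) %||% rep("", length(sets))
  combined <- dplyr::bind_rows(purrr::map2(sets, nms, function(x, nm) {
    x <- as_tibble(x)
    if (nzchar(nm)) x$source <- nm
    if (!"source" %in% names(x)) x$source <- "islands"
    x
  }))
  long <- tidyr::pivot_longer(
    dplyr::select(combined, "source", "length", "gc_percent",
                  "oe_ratio", "cpg_density"),
    cols = c("length", "gc_percent", "oe_ratio", "cpg_density"),
    names_to = "property", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$source)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::labs(x = NULL, y = "islands", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_island_properties
#' @param object A `cgi_islands` tibble.
#' @method autoplot cgi_islands
#' @export
autoplot.cgi_islands <- function(object, ...) {
  plot_island_properties(object)
}

#' Plot within-island methylation heterogeneity
#'
#' Histogram of the maximal methylation difference between inner islands
#' hosted by each outer island, with the heterogeneity cutoff marked.
#'
#' @param het A `cgi_heterogeneity` result from [swa_heterogeneity()].
#' @return A ggplot object.
#' @export
plot_heterogeneity <- function(het) {
  cutoff <- attr(het, "diff_cutoff") %||% 30
  ggplot2::ggplot(as_tibble(het), ggplot2::aes(x = .data$max_diff)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "max methylation difference between hosted islands (%)",
                  y = "outer islands") +
    ggplot2::theme_minimal()
}

#' @rdname plot_heterogeneity
#' @param object A `cgi_heterogeneity` tibble.
#' @param ... Unused.
#' @method autoplot cgi_heterogeneity
#' @export
autoplot.cgi_heterogeneity <- function(object, ...) {
  plot_heterogeneity(object)
}

#' Plot an overlap sweep over calibrated island sets
#'
#' @param sweep Result of [sweep_overlap()].
#' @param stat Which statistic to draw, `"overlap_fraction"` or
#'   `"mean_coverage"`.
#' @return A ggplot object.
#' @export
plot_overlap_sweep <- function(sweep, stat = c("overlap_fraction",
                                               "mean_coverage")) {
  stat <- match.arg(stat)
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$threshold_log10,
                                      y = .data[[stat]],
                                      colour = .data$element)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10(p-value) threshold", y = stat, colour = NULL) +
    ggplot2::theme_minimal()
}
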