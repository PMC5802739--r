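#' Ordination scatter plot
#'
#' First two principal coordinates, optionally coloured by a metadata
#' column (e.g. `pma_week`) or by the dominant taxon.
#'
#' @param object a `pcoa_ordination`.
#' @param colour_by optional tibble with `sample_id` and one colour column.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pcoa_ordination <- function(object, colour_by = NULL, ...) {
  df <- object$coordinates
  pe <- object$proportion_explained
  if (!is.null(colour_by)) {
    df <- dplyr::left_join(df, colour_by, by = "sample_id")
    cvar <- setdiff(names(colour_by), "sample_id")[1]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::labs(
      x = sprintf("PCoA 1 (%.1f%%)", 100 * pe[1]),
      y = sprintf("PCoA 2 (%.1f%%)", 100 * pe[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[cvar]]))
  }
}

#' Trend-curve ribbon plot
#'
#' @param trend tibble from [poly_trend()].
#' @param points optional raw observations (columns x, y, group).
#' @return a ggplot.
#' @export
plot_trend <- function(trend, points = NULL) {
  p <- ggplot2::ggplot(trend, ggplot2::aes(.data$x, .data$fit,
                                           colour = .data$group,
                                           fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points, ggplot2::aes(.data$x, .data$y, colour = .data$group),
      inherit.aes = FALSE, alpha = 0.5)
  }
  p
}

#' Stacked composition-by-age plot
#'
#' @param binned tibble from [pma_binned_means()].
#' @return a ggplot.
#' @export
plot_binned_composition <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(.data$pma_bin, .data$mean_abundance,
                                       fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Postmenstrual age (weeks)",
                  y = "Mean relative abundance") +
    ggplot2::theme_minimal()
}

#' Antibiotic deviation trajectories
#'
#' Deviation from expected relative abundance against day relative to the
#' course start, one line per infant, coloured by responder call.
#'
#' @param series tibble from [deviation_series()].
#' @param calls tibble from [classify_responder()].
#' @return a ggplot.
#' @export
plot_deviation_series <- function(series, calls) {
  df <- dplyr::left_join(series, calls,
                         by = c("infant_id", "drug_class", "taxon"))
  ggplot2::ggplot(df, ggplot2::aes(.data$rel_day, .data$deviation,
                                   group = interaction(.data$infant_id,
                                                       .data$course_id),
                                   colour = .data$call)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_grid(taxon ~ drug_class) +
    ggplot2::scale_colour_manual(values = c(responder = "#3366cc",
                                            non_responder = "#cc3333",
                                            undetermined = "grey60")) +
    ggplot2::labs(x = "Days since course start",
                  y = "Deviation from expected relative abundance") +
    ggplot2::theme_minimal()
}
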