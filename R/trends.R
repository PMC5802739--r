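#' Quadratic trend curves with confidence bands
#'
#' Ordinary least squares of `y` on `{1, x, x^2}` per group, with the
#' pointwise 95% confidence interval of the fitted mean — the descriptive
#' trend used when plotting development measures against age.
#'
#' @param data data frame of observations.
#' @param x,y,group column names (group optional; `NULL` fits one curve).
#' @param grid_n evaluation points across the observed x range per group.
#' @param level confidence level for the band.
#' @return tibble: group, x, fit, lo, hi.
#' @export
poly_trend <- function(data, x, y, group = NULL, grid_n = 100, level = 0.95) {
  split_by <- if (is.null(group)) rep("all", nrow(data)) else data[[group]]
  purrr::map_dfr(split(data, split_by), function(d) {
    if (nrow(d) < 4) rlang::abort("need at least 4 points per group")
    xv <- d[[x]]
    if (length(unique(xv)) < 3) rlang::abort("collinear x: fewer than 3 distinct values")
    fit <- stats::lm(d[[y]] ~ xv + I(xv^2))
    gx <- seq(min(xv), max(xv), length.out = grid_n)
    pr <- stats::predict(fit, newdata = data.frame(xv = gx),
                         interval = "confidence", level = level)
    tibble::tibble(group = if (is.null(group)) "all" else d[[group]][1],
                   x = gx, fit = unname(pr[, "fit"]),
                   lo = unname(pr[, "lwr"]), hi = unname(pr[, "upr"]))
  })
}

#' Mean composition in postmenstrual-age bins
#'
#' Arithmetic mean relative abundance per taxon within each
#' (prematurity group, PMA bin), with bin occupancy — the numbers behind
#' stacked composition-by-age panels.
#'
#' @param proportions proportion tibble (see [relative_abundance()]).
#' @param records metadata tibble with `pma_week` and `group`.
#' @param bin_width bin width in weeks.
#' @return tibble: group, pma_bin (left edge), taxon, mean_abundance,
#'   n_samples.
#' @export
pma_binned_means <- function(proportions, records, bin_width = 2) {
  m <- counts_matrix(proportions)
  if (!ncol(m)) rlang::abort("empty input")
  rec <- records[match(colnames(m), records$sample_id), ]
  bin <- floor(rec$pma_week / bin_width) * bin_width
  long <- tibble::tibble(
    sample_id = rep(colnames(m), each = nrow(m)),
    taxon = rep(rownames(m), ncol(m)),
    abundance = as.vector(m),
    group = rep(rec$group, each = nrow(m)),
    pma_bin = rep(bin, each = nrow(m)))
  dplyr::group_by(long, .data$group, .data$pma_bin, .data$taxon) |>
    dplyr::summarise(mean_abundance = mean(.data$abundance),
                     n_samples = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop")
}
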