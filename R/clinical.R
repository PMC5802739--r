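#' Label samples relative to sepsis episodes
#'
#' A sample is `during` when its postnatal day lies within `window_days`
#' of a diagnosis day, `pre`/`post` when it falls in the adjacent band
#' `(window_days, 2*window_days]` before/after, and `none` otherwise
#' (including all samples of infants without sepsis). With multiple
#' episodes per infant the nearer diagnosis wins; on a distance tie,
#' `during` beats the other labels.
#'
#' @param records metadata tibble (sample_id, infant_id, postnatal_day).
#' @param sepsis sepsis tibble (see [read_sepsis()]).
#' @param window_days half-width of the during window, days.
#' @return tibble: sample_id, label (pre/during/post/none).
#' @export
sepsis_windows <- function(records, sepsis, window_days = 5) {
  label_one <- function(day, dx_days) {
    if (!length(dx_days)) return("none")
    delta <- day - dx_days
    lab <- ifelse(abs(delta) <= window_days, "during",
                  ifelse(delta < -window_days & delta >= -2 * window_days, "pre",
                         ifelse(delta > window_days & delta <= 2 * window_days,
                                "post", "none")))
    pri <- match(lab, c("during", "pre", "post", "none"))
    lab[order(abs(delta), pri)][1]
  }
  by_inf <- split(sepsis$diagnosis_day, sepsis$infant_id)
  tibble::tibble(
    sample_id = records$sample_id,
    label = vapply(seq_len(nrow(records)), function(i) {
      label_one(records$postnatal_day[i],
                by_inf[[records$infant_id[i]]] %||% numeric(0))
    }, character(1)))
}

#' Abundance summaries by sepsis window
#'
#' Per-taxon median and IQR of relative abundance within each window class
#' (pre/during/post) and the no-sepsis reference, rank-sum p-values of each
#' class against `none`, and the tabulation of the dominant organism in
#' during-sepsis samples.
#'
#' @param proportions proportion tibble (count-table layout).
#' @param labels tibble from [sepsis_windows()].
#' @param dominance tibble from [dominant_taxon()].
#' @return list with tibbles `summary` (taxon, label, n, median, q25, q75,
#'   p_vs_none) and `dominant_during` (dominant_taxon, n_cases).
#' @export
sepsis_abundance_summary <- function(proportions, labels, dominance) {
  m <- counts_matrix(proportions)
  lab <- labels$label[match(colnames(m), labels$sample_id)]
  long <- tibble::tibble(
    taxon = rep(rownames(m), ncol(m)),
    abundance = as.vector(m),
    label = rep(lab, each = nrow(m)))
  summ <- long |>
    dplyr::group_by(.data$taxon, .data$label) |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data$abundance),
                     q25 = stats::quantile(.data$abundance, 0.25),
                     q75 = stats::quantile(.data$abundance, 0.75),
                     .groups = "drop")
  classes <- setdiff(unique(lab), "none")
  if (length(classes)) {
    pv <- purrr::map_dfr(unique(long$taxon), function(tx) {
      ref <- long$abundance[long$taxon == tx & long$label == "none"]
      purrr::map_dfr(classes, function(cl) {
        x <- long$abundance[long$taxon == tx & long$label == cl]
        p <- if (length(x) && length(ref)) rank_sum_test(x, ref)$p else NA_real_
        tibble::tibble(taxon = tx, label = cl, p_vs_none = p)
      })
    })
    summ <- dplyr::left_join(summ, pv, by = c("taxon", "label"))
  } else {
    summ$p_vs_none <- NA_real_
  }
  dur <- labels$sample_id[labels$label == "during"]
  dom <- dominance[dominance$sample_id %in% dur, ]
  dom_tab <- dom |>
    dplyr::count(.data$dominant_taxon, name = "n_cases") |>
    dplyr::arrange(dplyr::desc(.data$n_cases))
  list(summary = summ, dominant_during = dom_tab)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric p-value by the probability method: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (relative tolerance 1e-7).
#'
#' @param tab 2x2 matrix or a length-4 vector (a, b, c, d, row-wise).
#' @return p-value.
#' @examples
#' fisher_exact_two_sided(matrix(c(16, 5, 6, 18), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, byrow = TRUE)
  if (!all(dim(tab) == 2)) rlang::abort("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    rlang::abort("cell counts must be non-negative integers")
  }
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n2 == 0 || k == 0 || sum(tab[, 2]) == 0) {
    rlang::abort("zero margin")
  }
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-sided rank-sum (Mann-Whitney) test
#'
#' Exact when the smaller group has at most `exact_max` observations and
#' the enumeration is tractable (at most 1e5 group assignments): all
#' assignments of the pooled values to groups are enumerated and the
#' p-value is the fraction whose rank-sum deviates from its null mean at
#' least as much as observed (ties handled by enumerating the observed
#' values themselves). Otherwise the normal approximation with
#' tie-corrected variance is used (no continuity correction).
#'
#' @param x,y numeric vectors.
#' @param exact_max exact-enumeration threshold on `min(length(x), length(y))`.
#' @return list with `p`, `statistic` (rank sum of `x`), `method`, and
#'   `all_tied` flag (p = 1 returned when every value is identical).
#' @export
rank_sum_test <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) rlang::abort("both groups must be non-empty")
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (length(unique(pooled)) == 1) {
    return(list(p = 1, statistic = W, method = "degenerate", all_tied = TRUE))
  }
  if (min(n1, n2) <= exact_max && choose(N, n1) <= 1e5) {
    idx <- utils::combn(N, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(p = min(1, p), statistic = W, method = method, all_tied = FALSE)
}

#' Cohort characteristic 2x2 tests
#'
#' Applies [fisher_exact_two_sided()] to a set of labeled 2x2 count rows
#' (group-by-outcome), the layout of a clinical characteristics table.
#'
#' @param tables tibble with columns label, a, b, c, d where the table is
#'   rows (a, b) / (c, d): outcome yes/no by cohort group.
#' @return input tibble with a `p` column appended.
#' @export
cohort_stats <- function(tables) {
  need <- c("label", "a", "b", "c", "d")
  if (!all(need %in% names(tables))) {
    rlang::abort("need columns label, a, b, c, d")
  }
  tables$p <- vapply(seq_len(nrow(tables)), function(i) {
    fisher_exact_two_sided(matrix(unlist(tables[i, c("a", "b", "c", "d")]),
                                  2, byrow = TRUE))
  }, numeric(1))
  tables
}
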