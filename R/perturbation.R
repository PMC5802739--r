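#' Model-expected relative abundance per sample
#'
#' Wrapper around [predict.taxon_model_fit()] returning a tidy per-sample
#' expectation on the relative scale. The fit must not contain antibiotic
#' covariates, so deviations from it isolate the course effect.
#'
#' @param fit a `taxon_model_fit` trained on age and birth-mode terms.
#' @param records metadata tibble for the samples to predict.
#' @return tibble: sample_id, taxon, expected.
#' @export
expected_abundance <- function(fit, records) {
  pred <- predict(fit, newdata = records, type = "relative")
  tibble::tibble(sample_id = records$sample_id,
                 taxon = fit$taxon,
                 expected = pmin(pmax(pred, 1e-12), 1 - 1e-12))
}

#' Deviation trajectories around antibiotic courses
#'
#' For every (infant, course) pair, the per-sample deviation
#' `observed - expected` relative abundance on a day axis re-zeroed at the
#' course start day; samples from `window[1]` to `window[2]` relative days
#' are retained. A sample inside two overlapping courses appears in both
#' series. Infants with a course but no retained samples yield an empty
#' series (no rows).
#'
#' @param observed proportion tibble (count-table layout) or a tidy tibble
#'   with columns sample_id, taxon, observed.
#' @param expected tidy tibble from [expected_abundance()].
#' @param records metadata tibble (sample_id, infant_id, postnatal_day).
#' @param courses course tibble (see [read_courses()]).
#' @param window relative-day range retained around course start.
#' @return tibble: infant_id, drug_class, course_id, taxon, sample_id,
#'   rel_day, deviation.
#' @export
deviation_series <- function(observed, expected, records, courses,
                             window = c(-10, 30)) {
  if (is.data.frame(observed) && identical(names(observed)[1], "taxon") &&
      !"observed" %in% names(observed)) {
    m <- counts_matrix(observed)
    observed <- tibble::tibble(
      sample_id = rep(colnames(m), each = nrow(m)),
      taxon = rep(rownames(m), ncol(m)),
      observed = as.vector(m))
  }
  obs <- dplyr::inner_join(observed, expected, by = c("sample_id", "taxon")) |>
    dplyr::mutate(deviation = .data$observed - .data$expected) |>
    dplyr::inner_join(dplyr::select(records, "sample_id", "infant_id",
                                    "postnatal_day"), by = "sample_id")
  courses <- dplyr::mutate(courses, course_id = dplyr::row_number())
  dplyr::inner_join(obs, courses, by = "infant_id",
                    relationship = "many-to-many") |>
    dplyr::mutate(rel_day = .data$postnatal_day - .data$start_day) |>
    dplyr::filter(.data$rel_day >= window[1], .data$rel_day <= window[2]) |>
    dplyr::arrange(.data$infant_id, .data$course_id, .data$taxon,
                   .data$rel_day) |>
    dplyr::select("infant_id", "drug_class", "course_id", "taxon",
                  "sample_id", "rel_day", "deviation")
}

#' Classify antibiotic response per course and per infant
#'
#' A course is a *response* when every deviation in the post-start window
#' (days 1-10 by default) is strictly negative and at least one in-window
#' sample exists; it is a non-response when any in-window deviation is
#' >= 0; it is undetermined when no in-window samples exist. Courses are
#' then summarised per (infant, drug class, taxon): an infant is a
#' responder if any of its courses responds, a non-responder if it has a
#' determined course and none responds, undetermined otherwise.
#'
#' @param series deviation tibble from [deviation_series()].
#' @param window in-window relative days (inclusive).
#' @return tibble: infant_id, drug_class, taxon, call
#'   (responder/non_responder/undetermined), n_window_samples.
#' @export
classify_responder <- function(series, window = c(1, 10)) {
  if (window[1] > window[2]) rlang::abort("window must be ordered")
  per_course <- series |>
    dplyr::mutate(in_win = .data$rel_day >= window[1] &
                    .data$rel_day <= window[2]) |>
    dplyr::group_by(.data$infant_id, .data$drug_class, .data$course_id,
                    .data$taxon) |>
    dplyr::summarise(
      n_window_samples = sum(.data$in_win),
      all_negative = sum(.data$in_win) > 0 &&
        all(.data$deviation[.data$in_win] < 0),
      .groups = "drop") |>
    dplyr::mutate(call = dplyr::case_when(
      n_window_samples == 0 ~ "undetermined",
      all_negative ~ "responder",
      TRUE ~ "non_responder"))
  per_course |>
    dplyr::group_by(.data$infant_id, .data$drug_class, .data$taxon) |>
    dplyr::summarise(
      n_window_samples = sum(.data$n_window_samples),
      call = dplyr::case_when(
        any(.data$call == "responder") ~ "responder",
        any(.data$call == "non_responder") ~ "non_responder",
        TRUE ~ "undetermined"),
      .groups = "drop")
}

#' Responder fraction among determined infants
#'
#' responders / (responders + non_responders); undetermined infants are
#' excluded from the denominator but counted in the output.
#'
#' @param calls tibble from [classify_responder()].
#' @param drug_class,taxon optional filters.
#' @return tibble: drug_class, taxon, fraction, n_responder,
#'   n_non_responder, n_undetermined.
#' @export
responder_fraction <- function(calls, drug_class = NULL, taxon = NULL) {
  if (!is.null(drug_class)) calls <- calls[calls$drug_class %in% drug_class, ]
  if (!is.null(taxon)) calls <- calls[calls$taxon %in% taxon, ]
  out <- calls |>
    dplyr::group_by(.data$drug_class, .data$taxon) |>
    dplyr::summarise(
      n_responder = sum(.data$call == "responder"),
      n_non_responder = sum(.data$call == "non_responder"),
      n_undetermined = sum(.data$call == "undetermined"),
      .groups = "drop") |>
    dplyr::mutate(fraction = .data$n_responder /
                    (.data$n_responder + .data$n_non_responder)) |>
    dplyr::select("drug_class", "taxon", "fraction", dplyr::everything())
  if (nrow(out) && all(out$n_responder + out$n_non_responder == 0)) {
    rlang::abort("no determined responder calls")
  }
  out
}

#' Partition total DNA into per-taxon absolute abundances
#'
#' Subdivides each sample's total DNA concentration across taxa in
#' proportion to their relative abundances; per-sample sums equal the DNA
#' concentration exactly. Samples with missing DNA are skipped with a
#' warning.
#'
#' @param records metadata tibble with `dna_ng_per_ul`.
#' @param proportions proportion tibble (count-table layout).
#' @return tibble: sample_id, taxon, absolute_ng_per_ul.
#' @export
partition_dna <- function(records, proportions) {
  m <- counts_matrix(proportions)
  dna <- records$dna_ng_per_ul[match(colnames(m), records$sample_id)]
  drop_s <- colnames(m)[is.na(dna)]
  if (length(drop_s)) {
    rlang::warn(paste0(length(drop_s),
                       " sample(s) lack DNA concentration; skipped"))
    keep <- !is.na(dna)
    m <- m[, keep, drop = FALSE]; dna <- dna[keep]
  }
  if (any(dna < 0)) rlang::abort("negative DNA concentration")
  abs_m <- sweep(m, 2, dna, "*")
  tibble::tibble(sample_id = rep(colnames(m), each = nrow(m)),
                 taxon = rep(rownames(m), ncol(m)),
                 absolute_ng_per_ul = as.vector(abs_m))
}
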