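#' Count tables
#'
#' Throughout the package a *count table* is a tibble whose first column,
#' `taxon`, holds taxonomic labels (typically genera) and whose remaining
#' columns are samples, each cell a non-negative integer read count. This
#' mirrors the on-disk TSV layout, so tables round-trip through
#' [read_count_table()] / [write_count_table()] unchanged.
#'
#' @param counts a count tibble (first column `taxon`).
#' @name count-table
NULL

#' @describeIn count-table validate a count tibble and return it invisibly.
#'   Errors name the offending row/column.
#' @export
validate_count_table <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 1L || names(counts)[1] != "taxon") {
    rlang::abort("a count table must have `taxon` as its first column")
  }
  if (anyDuplicated(counts$taxon)) {
    rlang::abort(paste0("duplicated taxon label: ",
                        counts$taxon[duplicated(counts$taxon)][1]))
  }
  if (anyDuplicated(names(counts))) {
    rlang::abort(paste0("duplicated sample id: ",
                        names(counts)[duplicated(names(counts))][1]))
  }
  for (j in seq_along(counts)[-1]) {
    x <- counts[[j]]
    if (!is.numeric(x)) {
      rlang::abort(paste0("non-numeric counts in sample ", names(counts)[j]))
    }
    bad <- which(x < 0 | !is.finite(x))
    if (length(bad)) {
      rlang::abort(paste0("negative or non-finite count at taxon ",
                          counts$taxon[bad[1]], ", sample ", names(counts)[j]))
    }
  }
  invisible(counts)
}

#' @describeIn count-table matrix view (taxa as rownames, samples as columns).
#' @export
counts_matrix <- function(counts) {
  validate_count_table(counts)
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts$taxon
  m
}

#' @describeIn count-table rebuild a count tibble from a matrix view.
#' @param m numeric matrix with taxa as rownames.
#' @export
counts_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(taxon = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

#' Per-sample read totals
#'
#' @param counts a count tibble.
#' @return tibble with `sample_id` and `reads` (column sums).
#' @export
sample_totals <- function(counts) {
  m <- counts_matrix(counts)
  tibble::tibble(sample_id = colnames(m), reads = unname(colSums(m)))
}

#' Aggregate taxa to a coarser level
#'
#' Sums count rows that share a label under `mapping`; column totals are
#' preserved exactly. Taxa absent from `mapping` keep their own label.
#'
#' @param counts a count tibble.
#' @param mapping named character vector, `taxon -> group label`.
#' @return aggregated count tibble.
#' @export
aggregate_taxa <- function(counts, mapping) {
  m <- counts_matrix(counts)
  lab <- mapping[rownames(m)]
  lab[is.na(lab)] <- rownames(m)[is.na(lab)]
  agg <- rowsum(m, group = unname(lab), reorder = FALSE)
  counts_tibble(agg)
}
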