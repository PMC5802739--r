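#' Read a taxon-by-sample count table
#'
#' Expects a TSV with taxa as rows and samples as columns; the first column
#' must be named `taxon` and all cells must be non-negative integers.
#'
#' @param path TSV file path.
#' @return validated count tibble.
#' @export
read_count_table <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(counts) >= 1L) names(counts)[1] <- "taxon"
  validate_count_table(counts)
  counts
}

#' Write a count table to TSV
#'
#' @param counts a count tibble.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  validate_count_table(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

metadata_cols <- c("sample_id", "infant_id", "postnatal_day", "pma_week",
                   "birth_mode", "group", "reads", "dna_ng_per_ul")

#' Read per-sample metadata
#'
#' TSV columns: `sample_id`, `infant_id`, `postnatal_day` (integer, birth
#' day = 0), `pma_week` (decimal weeks), `birth_mode` (vaginal/cesarean),
#' `group` (EP/MVP/TERM), `reads`, `dna_ng_per_ul`. When `counts` is
#' supplied the `reads` column is cross-checked against the table's column
#' sums, with a warning on mismatch.
#'
#' @param path TSV file path.
#' @param counts optional count tibble for cross-validation.
#' @return tibble of sample records, with logical flag columns
#'   `is_meconium` and `contamination_flag` initialised to `FALSE`.
#' @export
read_metadata <- function(path, counts = NULL) {
  rec <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(metadata_cols, names(rec))
  if (length(missing)) {
    rlang::abort(paste0("metadata is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(rec$sample_id)) {
    rlang::abort(paste0("duplicated sample_id: ",
                        rec$sample_id[duplicated(rec$sample_id)][1]))
  }
  if (any(rec$reads < 0)) rlang::abort("negative read totals in metadata")
  if (!"is_meconium" %in% names(rec)) rec$is_meconium <- FALSE
  if (!"contamination_flag" %in% names(rec)) rec$contamination_flag <- FALSE
  if (!is.null(counts)) {
    tot <- sample_totals(counts)
    chk <- dplyr::inner_join(rec, tot, by = "sample_id",
                             suffix = c("", "_table"))
    off <- chk$sample_id[chk$reads != chk$reads_table]
    if (length(off)) {
      rlang::warn(paste0("metadata reads disagree with count-table totals for ",
                         length(off), " sample(s), e.g. ", off[1]))
    }
  }
  rec
}

#' Read antibiotic-course records
#'
#' TSV columns: `infant_id`, `drug_class` (aminoglycoside/vancomycin),
#' `start_day`, `end_day` (postnatal days, end >= start).
#'
#' @param path TSV file path.
#' @return tibble of course records.
#' @export
read_courses <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("infant_id", "drug_class", "start_day", "end_day")
  if (!all(need %in% names(x))) {
    rlang::abort("courses file needs infant_id, drug_class, start_day, end_day")
  }
  if (nrow(x) && any(x$end_day < x$start_day)) {
    rlang::abort("course with end_day < start_day")
  }
  bad <- setdiff(unique(x$drug_class), c("aminoglycoside", "vancomycin"))
  if (length(bad)) rlang::abort(paste0("unknown drug_class: ", bad[1]))
  x
}

#' Read sepsis-event records
#'
#' TSV columns: `infant_id`, `diagnosis_day` (postnatal day, >= 0).
#'
#' @param path TSV file path.
#' @return tibble of sepsis records.
#' @export
read_sepsis <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("infant_id", "diagnosis_day") %in% names(x))) {
    rlang::abort("sepsis file needs infant_id, diagnosis_day")
  }
  if (nrow(x) && any(x$diagnosis_day < 0)) rlang::abort("negative diagnosis_day")
  x
}

#' Write a simulated cohort as a fixture directory
#'
#' Emits `counts.tsv`, `metadata.tsv`, `courses.tsv`, `sepsis.tsv` and
#' `truth.tsv` in the dialects the readers expect; the files round-trip
#' losslessly through [read_count_table()] and friends.
#'
#' @param cohort a `simulated_cohort` from [simulate_cohort()].
#' @param dir writable output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) rlang::abort(paste0("cannot create directory ", dir))
  paths <- file.path(dir, c("counts.tsv", "metadata.tsv", "courses.tsv",
                            "sepsis.tsv", "truth.tsv"))
  write_count_table(cohort$counts, paths[1])
  readr::write_tsv(cohort$samples, paths[2], progress = FALSE)
  readr::write_tsv(cohort$courses, paths[3], progress = FALSE)
  readr::write_tsv(cohort$sepsis, paths[4], progress = FALSE)
  readr::write_tsv(cohort$truth, paths[5], progress = FALSE)
  invisible(paths)
}
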