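#' Remove rare taxa
#'
#' Drops every taxon whose grand-total read count is strictly less than
#' `threshold` (default 0.001%) of the table's grand total — rare reads are
#' likely sequencing errors or chimaeras. The sample set is unchanged and
#' the operation is idempotent. The threshold is applied to taxon totals
#' across the whole table, the stricter reading of a global filter.
#'
#' @param counts a count tibble.
#' @param threshold fraction of total reads below which a taxon is dropped.
#' @return filtered count tibble.
#' @export
filter_rare <- function(counts, threshold = 1e-5) {
  m <- counts_matrix(counts)
  grand <- sum(m)
  if (grand == 0) return(counts)
  # strict less-than cutoff; the tolerance keeps integer boundary cases
  # (a taxon holding exactly threshold * grand reads) on the retained side
  cutoff <- threshold * grand
  keep <- rowSums(m) >= cutoff * (1 - 1e-12)
  if (!any(keep)) keep[which.max(rowSums(m))] <- TRUE
  counts_tibble(m[keep, , drop = FALSE])
}

#' Relative abundances
#'
#' Divides each sample column by its read total so columns sum to 1.
#' Zero-total samples yield all-zero columns and are reported in the
#' `zero_total_samples` attribute (with a warning).
#'
#' @param counts a count tibble.
#' @return proportion tibble in count-table layout.
#' @export
relative_abundance <- function(counts) {
  m <- counts_matrix(counts)
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero)) {
    rlang::warn(paste0(length(zero), " sample(s) have zero reads; ",
                       "returning all-zero columns"))
  }
  p <- sweep(m, 2, ifelse(tot == 0, 1, tot), "/")
  out <- counts_tibble(p)
  attr(out, "zero_total_samples") <- zero
  out
}

#' Dominant taxon per sample
#'
#' A taxon dominates a sample when it holds strictly more than half of the
#' reads; otherwise the sample has no dominant (`NA`). Optionally
#' aggregates counts to a coarser level first via `mapping`
#' (see [aggregate_taxa()]).
#'
#' @param counts a count or proportion tibble.
#' @param mapping optional named vector `taxon -> level label`.
#' @return tibble with `sample_id`, `dominant_taxon` (`NA` when no taxon
#'   exceeds 0.5) and `dominant_fraction` (the maximum proportion).
#' @export
dominant_taxon <- function(counts, mapping = NULL) {
  if (!is.null(mapping)) counts <- aggregate_taxa(counts, mapping)
  m <- counts_matrix(counts)
  if (!nrow(m) || !ncol(m)) rlang::abort("empty table")
  tot <- colSums(m)
  p <- sweep(m, 2, ifelse(tot == 0, 1, tot), "/")
  imax <- apply(p, 2, which.max)
  fmax <- p[cbind(imax, seq_len(ncol(p)))]
  tibble::tibble(
    sample_id = colnames(m),
    dominant_taxon = ifelse(fmax > 0.5, rownames(m)[imax], NA_character_),
    dominant_fraction = unname(fmax))
}

#' Per-sample richness
#'
#' Number of taxa (OTUs) observed with at least one read, per sample.
#' Apply [filter_rare()] first so error reads do not inflate richness.
#'
#' @param counts a count tibble.
#' @return tibble with `sample_id` and integer `richness`.
#' @export
richness <- function(counts) {
  m <- counts_matrix(counts)
  tibble::tibble(sample_id = colnames(m),
                 richness = unname(as.integer(colSums(m > 0))))
}

#' Flag low-read meconium samples and likely contamination
#'
#' Samples with fewer than `meconium_reads` reads are flagged as meconium
#' (very low bacterial load is biologically expected there). Samples with
#' fewer than `low_reads` reads whose composition is close to the mean
#' negative-control profile (Bray-Curtis dissimilarity below `threshold`)
#' are flagged as possibly contaminated. Flagged samples are retained, not
#' removed.
#'
#' @param counts a count tibble.
#' @param records metadata tibble (see [read_metadata()]).
#' @param controls count tibble of negative-control samples; its taxon
#'   space is union-padded with zeros against `counts`.
#' @param meconium_reads,low_reads depth gates for the two flags.
#' @param threshold Bray-Curtis dissimilarity below which a low-read
#'   sample counts as control-like.
#' @return `records` with `is_meconium` and `contamination_flag` updated.
#' @export
flag_low_read_and_contamination <- function(counts, records, controls = NULL,
                                            meconium_reads = 100,
                                            low_reads = 1000,
                                            threshold = 0.3) {
  records$is_meconium <- unname(records$reads < meconium_reads)
  records$contamination_flag <- FALSE
  low <- records$sample_id[records$reads < low_reads]
  if (length(low)) {
    if (is.null(controls) || ncol(controls) < 2) {
      rlang::abort("negative controls required to flag low-read samples")
    }
    m <- counts_matrix(counts)
    cm <- counts_matrix(controls)
    taxa <- union(rownames(m), rownames(cm))
    pad <- function(x) {
      out <- matrix(0, length(taxa), ncol(x), dimnames = list(taxa, colnames(x)))
      out[rownames(x), ] <- x
      out
    }
    m <- pad(m); cm <- pad(cm)
    ctl_tot <- colSums(cm)
    ctl_prop <- sweep(cm, 2, ifelse(ctl_tot == 0, 1, ctl_tot), "/")
    ctl_mean <- rowMeans(ctl_prop)
    for (s in intersect(low, colnames(m))) {
      tot <- sum(m[, s])
      prop <- if (tot == 0) m[, s] else m[, s] / tot
      d <- sum(abs(prop - ctl_mean)) / max(sum(prop + ctl_mean), .Machine$double.eps)
      records$contamination_flag[records$sample_id == s] <- d < threshold
    }
  }
  records
}
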