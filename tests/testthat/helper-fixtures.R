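# Shared fixtures, built in code at test time.

# small default-parameter cohort (cached per session)
small_cohort <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) {
      cache <<- simulate_cohort(cohort_params(n_ep = 8, n_mvp = 8, seed = seed))
    }
    cache
  }
})

# hand-built count tibble from a taxon-by-sample matrix
count_tbl <- function(m, taxa = NULL, samples = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  counts_tibble(m)
}

# random count table for property loops
random_count_tbl <- function(n_taxa, n_samples, max_count = 500) {
  m <- matrix(rpois(n_taxa * n_samples, lambda = runif(n_taxa, 1, max_count)),
              n_taxa, n_samples)
  count_tbl(m)
}

# flat curve parameters with no subject variation, for truth-recovery tests
flat_phase_params <- function() {
  tibble::tribble(
    ~taxon, ~base_logit, ~peak_pma_week, ~width_weeks, ~max_logit_level, ~subject_sd, ~ep_only,
    "Staphylococcus",   0.0,   30,  3, 2.5, 0, FALSE,
    "Enterobacter",     0.5,   NA, NA, 0.0, 0, FALSE,
    "Bifidobacterium", -0.5,   NA, NA, 0.0, 0, FALSE)
}
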