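#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> ordinate -> model -> antibiotics
#' -> sepsis -> cohort-stats with plain-TSV handoff between stages, so each
#' stage is independently inspectable and re-runnable. Stage outputs land
#' in `config$out_dir`; a `manifest.json` records the resolved config, the
#' package version, and an md5 checksum per output file. Re-running with
#' the same config and seed reproduces identical outputs.
#'
#' Config entries (a list, or a YAML file path): `out_dir`; `seed`;
#' `stages` (character subset of simulate, preprocess, ordinate, model,
#' antibiotics, sepsis, cohort_stats); `input_dir` (pre-existing fixture
#' directory, required when `simulate` is disabled); `simulate` (arguments
#' for [cohort_params()]); `rare_threshold`; `permutations`; `terms`
#' (PERMANOVA covariates); `model_taxa`; `basis_size`; `window`
#' (responder window); `sepsis_window_days`; `tables_2x2` (path to a TSV
#' with columns label, a, b, c, d).
#'
#' @param config list or YAML path.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    stages = c("simulate", "preprocess", "ordinate", "model", "antibiotics",
               "sepsis", "cohort_stats"),
    seed = NULL, rare_threshold = 1e-5, permutations = 999,
    terms = c("pma_week", "postnatal_day", "birth_mode"),
    model_taxa = c("Staphylococcus", "Enterococcus", "Enterobacter",
                   "Bifidobacterium"),
    basis_size = 6, window = c(1, 10), sepsis_window_days = 5,
    tables_2x2 = NULL, input_dir = NULL, simulate = list())
  config <- utils::modifyList(defaults, config)
  stages <- config$stages
  stochastic <- any(c("simulate", "ordinate") %in% stages)
  if (stochastic && is.null(config$seed)) {
    rlang::abort("seed is required when stochastic stages are enabled")
  }
  out <- config$out_dir
  if (is.null(out)) rlang::abort("config$out_dir is required")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_msg <- function(...) message("[pipeline] ", ...)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out, name)
    readr::write_tsv(df, path, progress = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    if (!name %in% stages) return(invisible(NULL))
    log_msg("stage ", name)
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("stage ", name, " failed: ", conditionMessage(e)))
    })
  }

  data_dir <- config$input_dir
  stage("simulate", {
    prm <- do.call(cohort_params,
                   utils::modifyList(config$simulate,
                                     list(seed = config$seed)))
    coh <- simulate_cohort(prm)
    write_cohort(coh, out)
    outputs <- c(outputs, file.path(out, c("counts.tsv", "metadata.tsv",
                                           "courses.tsv", "sepsis.tsv",
                                           "truth.tsv")))
    data_dir <- out
  })
  if (is.null(data_dir)) {
    rlang::abort("no input data: enable the simulate stage or set input_dir")
  }
  counts <- read_count_table(file.path(data_dir, "counts.tsv"))
  records <- read_metadata(file.path(data_dir, "metadata.tsv"), counts)

  filtered <- counts; prop <- NULL
  stage("preprocess", {
    filtered <- filter_rare(counts, config$rare_threshold)
    prop <- relative_abundance(filtered)
    emit(prop, "proportions.tsv")
    emit(dominant_taxon(prop), "dominance.tsv")
    emit(richness(filtered), "richness.tsv")
  })
  if (is.null(prop)) prop <- relative_abundance(filtered)

  ordr <- NULL
  stage("ordinate", {
    d <- bray_curtis(prop)
    ordr <- pcoa(d, records)
    emit(ordr$coordinates, "coordinates.tsv")
    pm <- permanova(d, records, config$terms,
                    permutations = config$permutations, seed = config$seed)
    emit(pm$table, "permanova.tsv")
  })

  fits <- list()
  stage("model", {
    for (tx in intersect(config$model_taxa, filtered$taxon)) {
      fits[[tx]] <- fit_taxon_model(
        filtered, records, tx, smooth_terms = "pma_week",
        linear_terms = intersect("birth_mode", names(records)),
        basis_size = config$basis_size)
    }
    emit(purrr::map_dfr(fits, function(f) {
      tibble::tibble(taxon = f$taxon, sample_id = f$sample_id,
                     fitted_relative = f$fitted_relative)
    }), "fits.tsv")
  })

  stage("antibiotics", {
    if (!length(fits)) {
      rlang::abort("requires the model stage: no fitted taxon models found")
    }
    courses <- read_courses(file.path(data_dir, "courses.tsv"))
    expected <- purrr::map_dfr(fits, expected_abundance, records = records)
    ser <- deviation_series(prop, expected, records, courses)
    calls <- classify_responder(ser, window = config$window)
    emit(calls, "responder_calls.tsv")
    emit(responder_fraction(calls), "responder_fractions.tsv")
  })

  stage("sepsis", {
    sep <- read_sepsis(file.path(data_dir, "sepsis.tsv"))
    labels <- sepsis_windows(records, sep, config$sepsis_window_days)
    emit(labels, "sepsis_labels.tsv")
    summ <- sepsis_abundance_summary(prop, labels, dominant_taxon(prop))
    emit(summ$summary, "sepsis_summary.tsv")
    emit(summ$dominant_during, "sepsis_dominant.tsv")
  })

  stage("cohort_stats", {
    if (!is.null(config$tables_2x2)) {
      tabs <- readr::read_tsv(config$tables_2x2, show_col_types = FALSE,
                              progress = FALSE)
      emit(cohort_stats(tabs), "cohort_stats.tsv")
    }
  })

  manifest <- list(
    package = "preemiegut",
    version = as.character(utils::packageVersion("preemiegut")),
    created = format(Sys.time(), tz = "UTC"),
    config = config[setdiff(names(config), "out_dir")],
    out_dir = out,
    outputs = lapply(unique(outputs), function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
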