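#' Parameters for a synthetic preterm-infant cohort
#'
#' Defaults encode the study conditions the analyses assume: 45 preterm
#' infants (21 extremely premature born before week 28, 24 moderately/very
#' premature), 2-11 stool samples per infant over postnatal days 0-60,
#' sequencing depth averaging ~68,000 reads with a low-read meconium first
#' sample, four-phase succession over postmenstrual age
#' (Staphylococcus -> Enterococcus -> Enterobacter -> Bifidobacterium),
#' Enterococcus blooms restricted to the extremely premature group,
#' antibiotic courses with a responder/non-responder mixture, and sepsis
#' events whose hazard tracks Staphylococcus abundance.
#'
#' @param n_ep,n_mvp,n_term cohort sizes by prematurity group. `n_term`
#'   defaults to 0; term infants are an opt-in comparison group sampled
#'   over their first 15 postnatal weeks.
#' @param ga_range_ep,ga_range_mvp,ga_range_term gestational age at birth,
#'   weeks (min, max).
#' @param samples_per_infant_range integer (min, max) samples per infant.
#' @param followup_days last possible preterm sampling day (birth = day 0).
#' @param depth_log_mean,depth_log_sd log-normal read-depth parameters;
#'   defaults give a mean depth of 68,000 reads.
#' @param depth_max reads are capped at this depth.
#' @param meconium_depth_max each infant's first sample draws its depth
#'   uniformly from [23, `meconium_depth_max`).
#' @param phase_params tibble of per-taxon curve parameters with columns
#'   `taxon`, `base_logit`, `peak_pma_week`, `width_weeks`,
#'   `max_logit_level` (Gaussian-bump amplitude on the logit scale),
#'   `subject_sd`, `ep_only` (bump amplitude zeroed outside the EP group).
#' @param dm_conc Dirichlet-multinomial concentration (overdispersion;
#'   smaller = noisier compositions).
#' @param course_prob named per-drug probability that an infant receives a
#'   course (drugs: aminoglycoside, vancomycin).
#' @param responder_frac named per-drug fraction of coursed infants whose
#'   microbiota responds to the drug.
#' @param antibiotic_effect multiplicative suppression in (0, 1] applied to
#'   susceptible taxa of responders during days 1-10 after course start.
#' @param susceptible named list of character vectors: taxa suppressed by
#'   each drug class. Enterococcus is deliberately absent from the
#'   vancomycin set, so suppressing its competitors makes its relative
#'   abundance rise during vancomycin.
#' @param sepsis_rate per-day hazard scale; the daily sepsis probability is
#'   `sepsis_rate` times the infant's expected Staphylococcus share.
#' @param seed integer seed; all randomness is split into per-infant
#'   streams derived from it, so removing infants does not perturb the
#'   draws of the remaining ones.
#' @return a `cohort_params` list, validated.
#' @export
cohort_params <- function(n_ep = 21, n_mvp = 24, n_term = 0,
                          ga_range_ep = c(24, 27.9),
                          ga_range_mvp = c(28, 32),
                          ga_range_term = c(39, 41),
                          samples_per_infant_range = c(2, 11),
                          followup_days = 60,
                          depth_log_mean = log(68000) - 0.8^2 / 2,
                          depth_log_sd = 0.8,
                          depth_max = 282000,
                          meconium_depth_max = 52000,
                          phase_params = default_phase_params(),
                          dm_conc = 30,
                          course_prob = c(aminoglycoside = 0.7, vancomycin = 0.3),
                          responder_frac = c(aminoglycoside = 0.5, vancomycin = 0.5),
                          antibiotic_effect = 0.15,
                          susceptible = list(
                            aminoglycoside = c("Staphylococcus", "Enterococcus",
                                               "Enterobacter", "Escherichia",
                                               "Bifidobacterium"),
                            vancomycin = c("Staphylococcus", "Bifidobacterium",
                                           "Streptococcus")),
                          sepsis_rate = 0.02,
                          seed = 1L) {
  p <- list(n_ep = n_ep, n_mvp = n_mvp, n_term = n_term,
            ga_range_ep = ga_range_ep, ga_range_mvp = ga_range_mvp,
            ga_range_term = ga_range_term,
            samples_per_infant_range = samples_per_infant_range,
            followup_days = followup_days,
            depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
            depth_max = depth_max, meconium_depth_max = meconium_depth_max,
            phase_params = phase_params, dm_conc = dm_conc,
            course_prob = course_prob, responder_frac = responder_frac,
            antibiotic_effect = antibiotic_effect, susceptible = susceptible,
            sepsis_rate = sepsis_rate, seed = as.integer(seed))
  class(p) <- "cohort_params"
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p) {
  if (p$n_ep < 0 || p$n_mvp < 0 || p$n_term < 0) {
    rlang::abort("cohort sizes must be non-negative")
  }
  if (p$n_ep + p$n_mvp + p$n_term <= 0) {
    rlang::abort("cohort must contain at least one infant")
  }
  if (!nrow(p$phase_params)) rlang::abort("phase_params must be non-empty")
  ok_range <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!ok_range(p$ga_range_ep) || !ok_range(p$ga_range_mvp) ||
      !ok_range(p$ga_range_term) || !ok_range(p$samples_per_infant_range)) {
    rlang::abort("range parameters must be ordered (min, max)")
  }
  if (any(p$responder_frac < 0 | p$responder_frac > 1) ||
      any(p$course_prob < 0 | p$course_prob > 1)) {
    rlang::abort("fractions must lie in [0, 1]")
  }
  if (p$antibiotic_effect <= 0 || p$antibiotic_effect > 1) {
    rlang::abort("antibiotic_effect must lie in (0, 1]")
  }
  if (any(p$phase_params$subject_sd < 0) || p$depth_log_sd < 0) {
    rlang::abort("standard deviations must be non-negative")
  }
  invisible(p)
}

#' Default per-taxon succession-curve parameters
#'
#' Gaussian bumps on the logit scale over postmenstrual age (weeks):
#' Staphylococcus peaks near 27.5 weeks and wanes by 35; Enterococcus peaks
#' at 30 weeks with its bump restricted to extremely premature infants;
#' Enterobacter peaks at 35 weeks with wide between-infant timing spread;
#' Bifidobacterium rises gradually after 30 weeks towards term age. Minor
#' genera provide richness background; the rarest are fodder for the
#' rare-read filter.
#'
#' @return tibble of curve parameters, one row per taxon.
#' @export
default_phase_params <- function() {
  tibble::tribble(
    ~taxon,            ~base_logit, ~peak_pma_week, ~width_weeks, ~max_logit_level, ~subject_sd, ~ep_only,
    "Staphylococcus",          1.0,           27.5,          3.0,              3.0,        0.6,   FALSE,
    "Enterococcus",           -3.0,           30.0,          2.5,              6.0,        1.8,    TRUE,
    "Enterobacter",            0.0,           35.0,          3.5,              3.5,        1.4,   FALSE,
    "Bifidobacterium",        -2.5,           46.0,          6.0,              6.5,        1.5,   FALSE,
    "Escherichia",            -1.5,           38.0,          5.0,              2.0,        0.8,   FALSE,
    "Streptococcus",          -1.2,             NA,           NA,              0.0,        0.6,   FALSE,
    "Lactobacillus",          -2.5,             NA,           NA,              0.0,        0.6,   FALSE,
    "Veillonella",            -3.0,           44.0,          5.0,              2.0,        0.8,   FALSE,
    "Bacteroides",            -3.0,             NA,           NA,              0.0,        0.8,   FALSE,
    "Clostridium",            -3.5,             NA,           NA,              0.0,        0.6,   FALSE,
    "Haemophilus",            -5.0,             NA,           NA,              0.0,        0.5,   FALSE,
    "Corynebacterium",        -5.5,             NA,           NA,              0.0,        0.5,   FALSE)
}

# Expected composition (softmax over taxa) for one infant at given PMA,
# with optional per-taxon logit adjustments (antibiotic suppression).
expected_composition <- function(phase, pma_week, is_ep, subject_eff,
                                 logit_adjust = NULL) {
  bump <- ifelse(is.na(phase$peak_pma_week) | (phase$ep_only & !is_ep), 0,
                 phase$max_logit_level *
                   exp(-(pma_week - phase$peak_pma_week)^2 /
                         (2 * phase$width_weeks^2)))
  logit <- phase$base_logit + bump + subject_eff
  if (!is.null(logit_adjust)) logit <- logit + logit_adjust
  e <- exp(logit - max(logit))
  e / sum(e)
}

# Deterministic per-infant substream seed (stays below 2^31).
infant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a longitudinal preterm-infant cohort
#'
#' Generates, per infant: gestational age at birth, birth mode, a sampling
#' schedule whose first sample is meconium, antibiotic courses with latent
#' responder labels, per-taxon subject random intercepts, expected
#' compositions from Gaussian-bump succession curves on the logit scale
#' (softmax-normalised), Dirichlet-multinomial read counts at a simulated
#' depth, DNA concentrations increasing with postmenstrual age, and sepsis
#' events with hazard proportional to the expected Staphylococcus share.
#' Responder infants have susceptible taxa suppressed by
#' `antibiotic_effect` during days 1-10 after each course start.
#'
#' @param params a [cohort_params()] object.
#' @return a `simulated_cohort`: list with tibbles `samples`, `counts`,
#'   `courses`, `sepsis`, `truth`, plus the `params` used. `truth` records
#'   every latent assignment (gestational age, per-taxon subject effects,
#'   responder labels).
#' @examples
#' coh <- simulate_cohort(cohort_params(n_ep = 3, n_mvp = 3, seed = 7))
#' dplyr::count(coh$samples, group)
#' @export
simulate_cohort <- function(params) {
  validate_cohort_params(params)
  phase <- params$phase_params
  taxa <- phase$taxon
  groups <- rep(c("EP", "MVP", "TERM"),
                c(params$n_ep, params$n_mvp, params$n_term))
  n_inf <- length(groups)
  within_idx <- stats::ave(seq_len(n_inf), groups, FUN = seq_along)
  ids <- sprintf("%s%02d", groups, within_idx)
  # stream index is (group block + within-group index): dropping one group's
  # infants leaves the other groups' random streams untouched
  stream_idx <- c(EP = 0L, MVP = 100000L, TERM = 200000L)[groups] + within_idx

  samples <- list(); counts <- list(); courses <- list()
  sepsis <- list(); truth <- list()

  for (i in seq_len(n_inf)) {
    set.seed(infant_seed(params$seed, stream_idx[i]))
    grp <- groups[i]
    ga_rng <- switch(grp, EP = params$ga_range_ep, MVP = params$ga_range_mvp,
                     TERM = params$ga_range_term)
    ga <- stats::runif(1, ga_rng[1], ga_rng[2])
    # C-section frequency differs by prematurity group (common in MVP)
    p_cs <- switch(grp, EP = 0.57, MVP = 0.88, TERM = 0.15)
    birth_mode <- if (stats::runif(1) < p_cs) "cesarean" else "vaginal"
    followup <- if (grp == "TERM") 105L else as.integer(params$followup_days)

    spr <- params$samples_per_infant_range
    n_s <- spr[1] + sample.int(spr[2] - spr[1] + 1, 1) - 1L
    day1 <- sample(0:2, 1)
    later <- sort(sample(setdiff(3:followup, day1), n_s - 1))
    days <- c(day1, later)
    pma <- ga + days / 7

    # depths: first sample is meconium, uniform on [23, meconium_depth_max)
    depth <- round(pmin(params$depth_max,
                        stats::rlnorm(n_s, params$depth_log_mean,
                                      params$depth_log_sd)))
    depth[1] <- round(stats::runif(1, 23, params$meconium_depth_max))

    # antibiotic courses + latent responder labels
    drugs <- names(params$course_prob)
    has_course <- grp != "TERM" & stats::runif(length(drugs)) < params$course_prob
    responder <- stats::setNames(rep(NA, length(drugs)), drugs)
    crs <- NULL
    for (d in seq_along(drugs)) {
      if (!has_course[d]) next
      start <- if (drugs[d] == "aminoglycoside") sample(0:3, 1) else sample(7:30, 1)
      dur <- sample(3:7, 1)
      responder[d] <- stats::runif(1) < params$responder_frac[drugs[d]]
      crs <- dplyr::bind_rows(crs, tibble::tibble(
        infant_id = ids[i], drug_class = drugs[d],
        start_day = start, end_day = start + dur))
    }
    if (!is.null(crs)) courses[[i]] <- crs

    eff <- stats::rnorm(nrow(phase), 0, phase$subject_sd)

    # expected composition per sample (with antibiotic suppression windows)
    probs <- matrix(0, nrow(phase), n_s)
    for (s in seq_len(n_s)) {
      adj <- rep(0, nrow(phase))
      if (!is.null(crs)) {
        for (k in seq_len(nrow(crs))) {
          rel <- days[s] - crs$start_day[k]
          if (rel >= 1 && rel <= 10 && isTRUE(responder[crs$drug_class[k]])) {
            sus <- taxa %in% params$susceptible[[crs$drug_class[k]]]
            adj[sus] <- adj[sus] + log(params$antibiotic_effect)
          }
        }
      }
      probs[, s] <- expected_composition(phase, pma[s], grp == "EP", eff, adj)
    }

    cnt <- matrix(0L, nrow(phase), n_s)
    for (s in seq_len(n_s)) {
      pdm <- rdirichlet1(probs[, s] * params$dm_conc)
      cnt[, s] <- as.integer(stats::rmultinom(1, depth[s], pdm))
    }

    dna <- exp(0.3 + 0.07 * (pma - 30) + stats::rnorm(n_s, 0, 0.7))
    dna[1] <- exp(-2 + stats::rnorm(1, 0, 0.7))  # meconium: low biomass

    sid <- sprintf("%s_d%02d", ids[i], days)
    colnames(cnt) <- sid
    rownames(cnt) <- taxa
    counts[[i]] <- cnt
    samples[[i]] <- tibble::tibble(
      sample_id = sid, infant_id = ids[i], postnatal_day = as.integer(days),
      pma_week = pma, birth_mode = birth_mode, group = grp,
      reads = unname(colSums(cnt)), dna_ng_per_ul = round(dna, 4))

    # sepsis: daily Bernoulli, hazard scaled by expected Staph share
    if (grp != "TERM" && params$sepsis_rate > 0) {
      staph <- match("Staphylococcus", taxa)
      last_dx <- -Inf
      for (day in 3:followup) {
        share <- expected_composition(phase, ga + day / 7, grp == "EP", eff)[staph]
        if (stats::runif(1) < min(1, params$sepsis_rate * share) &&
            day - last_dx >= 7) {
          sepsis[[length(sepsis) + 1]] <- tibble::tibble(
            infant_id = ids[i], diagnosis_day = as.integer(day))
          last_dx <- day
        }
      }
    }

    tr <- tibble::tibble(infant_id = ids[i], group = grp, ga_birth_week = ga,
                         responder_aminoglycoside = responder["aminoglycoside"],
                         responder_vancomycin = responder["vancomycin"])
    tr[paste0("eff_", taxa)] <- as.list(eff)
    truth[[i]] <- tr
  }

  cnt_all <- do.call(cbind, counts)
  out <- list(
    samples = dplyr::bind_rows(samples),
    counts = counts_tibble(cnt_all),
    courses = if (length(courses)) dplyr::bind_rows(courses) else
      tibble::tibble(infant_id = character(), drug_class = character(),
                     start_day = integer(), end_day = integer()),
    sepsis = if (length(sepsis)) dplyr::bind_rows(sepsis) else
      tibble::tibble(infant_id = character(), diagnosis_day = integer()),
    truth = dplyr::bind_rows(truth),
    params = params)
  class(out) <- "simulated_cohort"
  out
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort>", nrow(x$truth), "infants,",
      nrow(x$samples), "samples,", nrow(x$counts), "taxa;",
      nrow(x$courses), "antibiotic courses,",
      nrow(x$sepsis), "sepsis cases\n")
  invisible(x)
}
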