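fit_staph <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- small_cohort()
      cache <<- fit_taxon_model(coh$counts, coh$samples, "Staphylococcus",
                                smooth_terms = "pma_week",
                                linear_terms = "birth_mode", basis_size = 6)
    }
    cache
  }
})

test_that("expected abundance reproduces fitted values and the offset contract", {
  coh <- small_cohort()
  fit <- fit_staph()
  ea <- expected_abundance(fit, coh$samples)
  expect_equal(ea$expected, unname(fit$fitted_relative), tolerance = 1e-8)
  expect_true(all(ea$expected > 0 & ea$expected < 1))

  # two hypothetical samples differing only in reads predict identically
  nd <- coh$samples[c(1, 1), ]
  nd$sample_id <- c("a", "b")
  nd$reads <- c(1000, 64000)
  pr <- expected_abundance(fit, nd)
  expect_equal(pr$expected[1], pr$expected[2], tolerance = 1e-12)
})

test_that("deviations are near zero for infants without antibiotics", {
  prm <- cohort_params(n_ep = 10, n_mvp = 10,
                       course_prob = c(aminoglycoside = 0, vancomycin = 0),
                       samples_per_infant_range = c(6, 11), seed = 55)
  coh <- simulate_cohort(prm)
  fit <- fit_taxon_model(coh$counts, coh$samples, "Staphylococcus",
                         basis_size = 6)
  prop <- counts_matrix(relative_abundance(coh$counts))
  dev <- prop["Staphylococcus", ] - expected_abundance(fit, coh$samples)$expected
  expect_gte(length(dev), 20)
  expect_lt(abs(mean(dev)), 0.05)
})

test_that("deviation series re-zero the day axis at course start", {
  obs <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                        taxon = "Staphylococcus",
                        observed = c(0.5, 0.3, 0.2))
  exp_ab <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                           taxon = "Staphylococcus",
                           expected = c(0.5, 0.3, 0.2))
  rec <- tibble::tibble(sample_id = c("s1", "s2", "s3"), infant_id = "i1",
                        postnatal_day = c(4, 10, 50))
  crs <- tibble::tibble(infant_id = "i1", drug_class = "aminoglycoside",
                        start_day = 4, end_day = 8)
  ser <- deviation_series(obs, exp_ab, rec, crs)
  expect_equal(ser$deviation, c(0, 0))  # day 50 is outside (-10, 30]
  expect_equal(ser$rel_day, c(0, 6))

  # translation equivariance
  rec2 <- dplyr::mutate(rec, postnatal_day = postnatal_day + 11)
  crs2 <- dplyr::mutate(crs, start_day = start_day + 11,
                        end_day = end_day + 11)
  ser2 <- deviation_series(obs, exp_ab, rec2, crs2)
  expect_equal(ser2$rel_day, ser$rel_day)

  # two courses produce two series; a sample may sit in both
  crs3 <- dplyr::bind_rows(crs, dplyr::mutate(crs, start_day = 8, end_day = 12))
  ser3 <- deviation_series(obs, exp_ab, rec, crs3)
  expect_setequal(unique(ser3$course_id), c(1, 2))
  expect_identical(sum(ser3$sample_id == "s2"), 2L)

  # infant with a course but no retained samples: empty series, no error
  far <- dplyr::mutate(rec, postnatal_day = postnatal_day + 200)
  expect_identical(nrow(deviation_series(obs, exp_ab, far, crs)), 0L)
})

test_that("responder calls implement the consistently-negative rule", {
  mk <- function(days, devs) {
    tibble::tibble(infant_id = "i1", drug_class = "aminoglycoside",
                   course_id = 1L, taxon = "Enterococcus",
                   sample_id = paste0("s", seq_along(days)),
                   rel_day = days, deviation = devs)
  }
  expect_identical(classify_responder(mk(c(2, 6), c(-0.1, -0.3)))$call,
                   "responder")
  expect_identical(classify_responder(mk(c(2, 6), c(-0.1, 0.02)))$call,
                   "non_responder")
  expect_identical(classify_responder(mk(c(2, 6), c(-0.1, 0)))$call,
                   "non_responder")  # zero is not a response
  expect_identical(classify_responder(mk(c(-3, 15), c(-0.4, -0.4)))$call,
                   "undetermined")

  # monotone: making any in-window deviation more negative never turns a
  # responder into a non-responder
  set.seed(31)
  for (i in 1:20) {
    days <- sample(1:10, 4)
    devs <- runif(4, -0.5, 0.5)
    base <- classify_responder(mk(days, devs))$call
    pushed <- classify_responder(mk(days, devs - runif(4, 0, 0.5)))$call
    if (base == "responder") expect_identical(pushed, "responder")
  }
})

test_that("per-infant summaries and fractions count calls correctly", {
  calls <- tibble::tibble(
    infant_id = sprintf("i%02d", 1:12),
    drug_class = "aminoglycoside",
    taxon = "Enterococcus",
    call = rep(c("responder", "non_responder", "undetermined"), c(5, 5, 2)),
    n_window_samples = rep(c(2L, 2L, 0L), c(5, 5, 2)))
  fr <- responder_fraction(calls)
  expect_equal(fr$fraction, 0.5)
  expect_identical(fr$n_undetermined, 2L)

  und <- dplyr::mutate(calls, call = "undetermined")
  expect_error(responder_fraction(und), "no determined")

  # an infant with one responding course among several is a responder
  ser <- tibble::tibble(infant_id = "i1", drug_class = "aminoglycoside",
                        course_id = c(1L, 1L, 2L), taxon = "Enterococcus",
                        sample_id = c("a", "b", "c"),
                        rel_day = c(2, 5, 3), deviation = c(-0.2, -0.1, 0.3))
  merged <- classify_responder(ser)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$call, "responder")
})

test_that("DNA partitioning conserves totals exactly", {
  prop <- count_tbl(cbind(s1 = c(0.4, 0.6), s2 = c(1, 0)))
  rec <- tibble::tibble(sample_id = c("s1", "s2"), dna_ng_per_ul = c(10, 3))
  ab <- partition_dna(rec, prop)
  expect_equal(ab$absolute_ng_per_ul[ab$sample_id == "s1"], c(4, 6))
  expect_equal(ab$absolute_ng_per_ul[ab$sample_id == "s2"], c(3, 0))
  sums <- tapply(ab$absolute_ng_per_ul, ab$sample_id, sum)
  expect_equal(as.vector(sums[c("s1", "s2")]), c(10, 3), tolerance = 1e-9)

  rec$dna_ng_per_ul[2] <- NA
  expect_warning(ab2 <- partition_dna(rec, prop), "skipped")
  expect_setequal(unique(ab2$sample_id), "s1")
})
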