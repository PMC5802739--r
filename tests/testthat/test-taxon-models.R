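test_that("NB log-likelihood matches direct mass-function evaluation", {
  set.seed(1)
  for (theta in c(0.3, 2, 50)) {
    mu <- runif(40, 0.5, 200)
    y <- rnbinom(40, size = theta, mu = mu)
    expect_equal(preemiegut:::nb_loglik(y, mu, theta),
                 sum(dnbinom(y, size = theta, mu = mu, log = TRUE)),
                 tolerance = 1e-8)
  }
})

test_that("the Poisson limit reproduces a glm fit on the same design", {
  coh <- small_cohort()
  fit <- fit_taxon_model(coh$counts, coh$samples, "Enterobacter",
                         smooth_terms = character(0),
                         linear_terms = "birth_mode", subject = NULL,
                         dispersion = Inf, lambda_grid = 0)
  df <- data.frame(y = counts_matrix(coh$counts)["Enterobacter", ],
                   x = factor(coh$samples$birth_mode),
                   off = log(coh$samples$reads))
  g <- glm(y ~ x, offset = off, family = poisson, data = df)
  expect_equal(unname(fit$coefficients[1:2]), unname(coef(g)),
               tolerance = 1e-4)
  expect_equal(fit$deviance, deviance(g), tolerance = 1e-3)
})

test_that("the read-total offset puts the fit on the relative scale", {
  coh <- small_cohort()
  fit1 <- fit_taxon_model(coh$counts, coh$samples, "Staphylococcus",
                          basis_size = 6)
  doubled <- counts_tibble(2 * counts_matrix(coh$counts))
  rec2 <- coh$samples
  rec2$reads <- 2 * rec2$reads
  fit2 <- fit_taxon_model(doubled, rec2, "Staphylococcus", basis_size = 6)
  grid <- tibble::tibble(
    pma_week = seq(min(coh$samples$pma_week), max(coh$samples$pma_week),
                   length.out = 30),
    infant_id = "NEW", reads = 1)
  p1 <- suppressWarnings(predict(fit1, grid))
  p2 <- suppressWarnings(predict(fit2, grid))
  expect_equal(log(p1), log(p2), tolerance = 0.05)
})

test_that("a randomly permuted covariate explains almost nothing", {
  coh <- small_cohort()
  rec <- coh$samples
  set.seed(99)
  rec$noise <- sample(rec$pma_week)
  led <- variance_ledger(coh$counts, rec, "Staphylococcus",
                         terms = c("pma_week", "noise"),
                         smooth = c("pma_week", "noise"), basis_size = 6)
  expect_lt(led$deviance_fraction[led$term == "noise"], 0.05)
  expect_gt(led$deviance_fraction[led$term == "pma_week"],
            led$deviance_fraction[led$term == "noise"])
})

test_that("variance explained telescopes over nested fits", {
  coh <- small_cohort()
  full <- fit_taxon_model(coh$counts, coh$samples, "Staphylococcus",
                          basis_size = 6)
  expect_equal(variance_explained(full, full), 0)

  null_fit <- fit_taxon_model(coh$counts, coh$samples, "Staphylococcus",
                              smooth_terms = character(0),
                              linear_terms = character(0), subject = NULL,
                              dispersion = full$theta)
  ve <- variance_explained(full, null_fit)
  expect_equal(ve,
               (null_fit$deviance - full$deviance) / full$null_deviance,
               tolerance = 1e-12)
  expect_gt(ve, 0)
  expect_error(variance_explained(
    fit_taxon_model(coh$counts, coh$samples, "Enterococcus", basis_size = 6),
    full), "different data")
})

test_that("the fit is invariant to taxon and sample order", {
  coh <- small_cohort()
  base <- fit_taxon_model(coh$counts, coh$samples, "Staphylococcus",
                          basis_size = 6)
  set.seed(2)
  rows <- sample(nrow(coh$counts))
  cols <- c(1, 1 + sample(ncol(coh$counts) - 1))
  shuf <- coh$counts[rows, cols]
  fit2 <- fit_taxon_model(shuf, coh$samples, "Staphylococcus", basis_size = 6)
  expect_equal(fit2$deviance, base$deviance, tolerance = 1e-6)
  ord <- match(base$sample_id, fit2$sample_id)
  expect_equal(fit2$fitted_relative[ord], base$fitted_relative,
               tolerance = 1e-6)
})

test_that("quadratic trends recover known curves", {
  # exactly quadratic data: zero residuals
  x <- seq(25, 40, length.out = 30)
  y <- 1 + 0.5 * x - 0.02 * x^2
  tr <- poly_trend(data.frame(x = x, y = y), "x", "y", grid_n = 30)
  expect_equal(tr$fit, 1 + 0.5 * tr$x - 0.02 * tr$x^2, tolerance = 1e-9)
  expect_lt(max(tr$hi - tr$lo), 1e-6)

  # constant response: flat curve
  yc <- rep(2, 30)
  trc <- poly_trend(data.frame(x = x, y = yc), "x", "y")
  expect_equal(trc$fit, rep(2, nrow(trc)), tolerance = 1e-9)

  # noisy quadratic, n = 200: coefficients recovered within 3 SE
  set.seed(10)
  xn <- runif(200, 25, 45)
  yn <- 2 - 0.3 * xn + 0.01 * xn^2 + rnorm(200, 0, 0.3)
  fit <- lm(yn ~ xn + I(xn^2))
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(est - c(2, -0.3, 0.01)) < 3 * se))
  trn <- poly_trend(data.frame(x = xn, y = yn), "x", "y", grid_n = 5)
  expect_true(all(trn$lo <= trn$fit & trn$fit <= trn$hi))

  expect_error(poly_trend(data.frame(x = 1:3, y = 1:3), "x", "y"), "4 points")
  expect_error(poly_trend(data.frame(x = rep(1:2, 3), y = rnorm(6)), "x", "y"),
               "collinear")
})

test_that("PMA-binned means respect occupancy and simplex structure", {
  coh <- small_cohort()
  prop <- relative_abundance(coh$counts)
  binned <- pma_binned_means(prop, coh$samples, bin_width = 2)
  sums <- dplyr::summarise(dplyr::group_by(binned, group, pma_bin),
                           s = sum(mean_abundance), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))

  # a bin holding a single sample reproduces that sample exactly
  one <- coh$samples$sample_id[1]
  sub <- prop[, c("taxon", one)]
  b1 <- pma_binned_means(sub, coh$samples[coh$samples$sample_id == one, ],
                         bin_width = 2)
  expect_equal(sort(b1$mean_abundance),
               sort(unname(counts_matrix(sub)[, 1])), tolerance = 1e-12)

  # Bifidobacterium rises towards term-equivalent age
  late <- binned$mean_abundance[binned$taxon == "Bifidobacterium" &
                                  binned$pma_bin >= 38]
  early <- binned$mean_abundance[binned$taxon == "Bifidobacterium" &
                                   binned$pma_bin <= 28]
  expect_gt(mean(late), mean(early))
})
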