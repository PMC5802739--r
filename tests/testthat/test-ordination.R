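test_that("Bray-Curtis matches hand evaluation and its bounds", {
  a <- c(2, 1, 0); b <- c(0, 1, 3)
  d <- bray_curtis(count_tbl(cbind(a, b)))
  expect_equal(d[1, 2], 5 / 7, tolerance = 1e-12)

  ident <- bray_curtis(count_tbl(cbind(a, a)))
  expect_equal(ident[1, 2], 0)

  disjoint <- bray_curtis(count_tbl(cbind(c(4, 0), c(0, 9))))
  expect_equal(disjoint[1, 2], 1)

  set.seed(8)
  for (i in 1:10) {
    tbl <- random_count_tbl(6, 5)
    d <- bray_curtis(tbl)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    # common rescaling of a proportion table leaves dissimilarities unchanged
    p <- counts_matrix(relative_abundance(tbl))
    expect_equal(bray_curtis(counts_tibble(7.3 * p)),
                 bray_curtis(counts_tibble(p)), tolerance = 1e-12)
  }
  expect_error(bray_curtis(count_tbl(matrix(1:3, ncol = 1))), "two samples")
})

test_that("Bray-Curtis agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(2)
  tbl <- random_count_tbl(8, 10)
  d <- bray_curtis(tbl)
  v <- as.matrix(vegan::vegdist(t(counts_matrix(tbl)), method = "bray"))
  expect_equal(unname(d), unname(v), tolerance = 1e-12)
})

test_that("PCoA recovers closed-form and exact-embedding cases", {
  # two samples at dissimilarity 0.5: one axis, coordinates +/- 0.25
  d2 <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  o2 <- pcoa(d2)
  expect_equal(sort(o2$coordinates$axis1), c(-0.25, 0.25), tolerance = 1e-12)
  expect_error(development_index(o2), "two positive axes")

  # points on a line embed exactly on axis 1
  x <- c(0, 1, 3, 6, 10)
  dl <- as.matrix(dist(x))
  ol <- pcoa(dl)
  expect_equal(ol$proportion_explained[1], 1, tolerance = 1e-9)

  # Gower reconstruction: Euclidean point configurations are reproduced
  set.seed(4)
  pts <- matrix(rnorm(7 * 3), 7, 3)
  de <- as.matrix(dist(pts))
  oe <- pcoa(de)
  coords <- as.matrix(oe$coordinates[, grep("^axis", names(oe$coordinates))])
  expect_equal(unname(as.matrix(dist(coords))), unname(de), tolerance = 1e-9)

  # degenerate all-equal matrix warns and returns zeros
  deq <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(oz <- pcoa(deq), "equal")
  expect_true(all(oz$coordinates$axis1 == 0))
})

test_that("PCoA axes agree with classical scaling and orient along PMA", {
  coh <- small_cohort()
  prop <- relative_abundance(coh$counts)
  d <- bray_curtis(prop)
  o <- pcoa(d, coh$samples)
  cm <- cmdscale(d, k = 3, eig = TRUE)
  expect_equal(o$eigenvalues[1:3], cm$eig[1:3], tolerance = 1e-8)
  expect_equal(abs(o$coordinates$axis1), abs(unname(cm$points[, 1])),
               tolerance = 1e-8)
  for (ax in c("axis1", "axis2")) {
    rho <- cor(o$coordinates[[ax]], coh$samples$pma_week, method = "spearman")
    expect_gte(rho, 0)
  }
  di <- development_index(o)
  expect_equal(di$development_index,
               o$coordinates$axis1 + o$coordinates$axis2)
})

test_that("development index tracks postmenstrual age on the default simulation", {
  coh <- small_cohort()
  o <- pcoa(bray_curtis(relative_abundance(filter_rare(coh$counts))),
            coh$samples)
  rho <- cor(o$coordinates$development_index, coh$samples$pma_week,
             method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("PERMANOVA partitions variance like vegan and respects invariants", {
  skip_if_not_installed("vegan")
  coh <- small_cohort()
  prop <- relative_abundance(coh$counts)
  d <- bray_curtis(prop)
  rec <- coh$samples
  terms <- c("pma_week", "postnatal_day", "birth_mode")
  pm <- permanova(d, rec, terms, permutations = 99, seed = 4)
  va <- vegan::adonis2(as.dist(d) ~ pma_week + postnatal_day + birth_mode,
                       data = rec, permutations = 99, by = "terms")
  expect_equal(pm$table$SS[1:3], va$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(pm$table$R2[1:3], va$R2[1:3], tolerance = 1e-8)
  expect_equal(pm$table$pseudo_F[1:3], va$F[1:3], tolerance = 1e-8)

  # R2 of terms plus residual sums to one
  expect_equal(sum(pm$table$R2), 1, tolerance = 1e-9)

  # consistent relabeling leaves R2 unchanged
  set.seed(1)
  perm <- sample(nrow(d))
  pm2 <- permanova(d[perm, perm], rec[perm, ], terms,
                   permutations = 99, seed = 4)
  expect_equal(pm2$table$R2, pm$table$R2, tolerance = 1e-9)

  # a term collinear with an earlier one is reported and skipped
  rec$pma_copy <- rec$pma_week
  expect_warning(pm3 <- permanova(d, rec, c("pma_week", "pma_copy"),
                                  permutations = 49, seed = 1),
                 "rank-deficient")
  expect_true(is.na(pm3$table$p[2]))
  expect_equal(pm3$table$SS[1], pm$table$SS[1], tolerance = 1e-9)
})

test_that("PERMANOVA separates clusters maximally and rejects constants", {
  set.seed(6)
  m <- cbind(matrix(rpois(5 * 6, c(100, 1, 1, 1, 1)), 5, 6),
             matrix(rpois(5 * 6, c(1, 1, 1, 1, 100)), 5, 6))
  tbl <- count_tbl(m)
  rec <- tibble::tibble(sample_id = colnames(counts_matrix(tbl)),
                        cluster = rep(c("a", "b"), each = 6))
  d <- bray_curtis(tbl)
  pm <- permanova(d, rec, "cluster", permutations = 199, seed = 2)
  expect_equal(pm$table$p[1], 1 / 200)

  rec$const <- 1
  expect_error(permanova(d, rec, "const", permutations = 99),
               "constant covariate")
})

test_that("exact PERMANOVA p equals exhaustive enumeration by an independent route", {
  set.seed(13)
  m <- matrix(rpois(4 * 6, 40), 4, 6)
  tbl <- count_tbl(m)
  g <- rep(c("a", "b"), each = 3)
  rec <- tibble::tibble(sample_id = colnames(counts_matrix(tbl)), grp = g)
  d <- bray_curtis(tbl)

  # independent one-way pseudo-F from pairwise distances (no projection):
  # SS_total = sum d^2 / n, SS_within = sum over groups of within-group
  # squared distances / group size
  oracle_F <- function(d, g) {
    n <- length(g)
    ss_tot <- sum(d[upper.tri(d)]^2) / n
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      dd <- d[idx, idx]
      ss_w <- ss_w + sum(dd[upper.tri(dd)]^2) / length(idx)
    }
    ((ss_tot - ss_w) / (length(unique(g)) - 1)) /
      (ss_w / (n - length(unique(g))))
  }
  perms <- preemiegut:::all_permutations(6)
  f_obs <- oracle_F(d, g)
  f_all <- apply(perms, 1, function(p) oracle_F(d[p, p], g))
  p_oracle <- mean(f_all >= f_obs - 1e-12)

  pm <- permanova(d, rec, "grp", permutations = "exact")
  expect_equal(pm$table$pseudo_F[1], f_obs, tolerance = 1e-10)
  expect_equal(pm$table$p[1], p_oracle, tolerance = 1e-12)
})

test_that("strata permutations shuffle only within groups", {
  coh <- small_cohort()
  prop <- relative_abundance(coh$counts)
  d <- bray_curtis(prop)
  pm <- permanova(d, coh$samples, "pma_week", permutations = 99, seed = 3,
                  strata = "infant_id")
  expect_true(pm$table$p[1] >= 1 / 100 && pm$table$p[1] <= 1)
})
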