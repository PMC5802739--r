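#' Bray-Curtis dissimilarity matrix
#'
#' d(a, b) = sum|a_i - b_i| / sum(a_i + b_i) between sample columns; bounded
#' in [0, 1] and scale-invariant on proportions. A pair of all-zero samples
#' gets d = 0 with a warning.
#'
#' @param counts a count or proportion tibble, or a numeric matrix with
#'   taxa as rows and samples as columns.
#' @return symmetric dissimilarity matrix with sample ids as dimnames.
#' @export
bray_curtis <- function(counts) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  if (ncol(m) < 2) rlang::abort("need at least two samples")
  if (any(m < 0)) rlang::abort("negative abundances")
  num <- as.matrix(stats::dist(t(m), method = "manhattan"))
  cs <- colSums(m)
  den <- outer(cs, cs, "+")
  if (any(den == 0 & upper.tri(den))) {
    rlang::warn("pair(s) of all-zero samples; their dissimilarity is set to 0")
  }
  d <- ifelse(den == 0, 0, num / ifelse(den == 0, 1, den))
  dimnames(d) <- list(colnames(m), colnames(m))
  diag(d) <- 0
  d
}

# Gower-centered matrix G = (I - 11'/n) (-d^2/2) (I - 11'/n)
gower_center <- function(d) {
  a <- -0.5 * d^2
  rc <- rowMeans(a)
  sweep(sweep(a, 1, rc), 2, rc) + mean(a)
}

#' Principal coordinates analysis
#'
#' Classical scaling: the squared dissimilarities are double-centered,
#' eigendecomposed, and coordinates formed as eigenvector times square
#' root of eigenvalue for the positive eigenvalues. Negative eigenvalues
#' are reported untouched (no Cailliez/Lingoes correction). The first two
#' axis signs are oriented so the axis increases with `pma_week` when
#' metadata is given (Spearman correlation >= 0); otherwise so the
#' largest-magnitude coordinate is positive. The per-sample development
#' index is the sum of the first two axis coordinates.
#'
#' @param d symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param records optional metadata tibble with `sample_id` and `pma_week`,
#'   used for axis orientation.
#' @return object of class `pcoa_ordination`: list with `coordinates`
#'   (tibble `sample_id`, `axis1`, `axis2`, ..., `development_index`),
#'   `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(d, records = NULL) {
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
  if (max(abs(d - t(d))) > 1e-12) rlang::abort("dissimilarity matrix not symmetric")
  g <- gower_center(d)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * sqrt(.Machine$double.eps)
  pos <- which(e$values > tol)
  if (!length(pos)) {
    rlang::warn("all dissimilarities equal; returning zero coordinates")
    coords <- matrix(0, n, 2)
    pos <- integer(0)
  } else {
    coords <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), length(pos))
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  # axis sign orientation for the first two axes
  for (j in seq_len(min(2L, ncol(coords)))) {
    flip <- FALSE
    if (!is.null(records) && "pma_week" %in% names(records)) {
      pma <- records$pma_week[match(rownames(coords), records$sample_id)]
      rho <- suppressWarnings(stats::cor(coords[, j], pma, method = "spearman",
                                         use = "complete.obs"))
      flip <- is.finite(rho) && rho < 0
    } else {
      flip <- coords[which.max(abs(coords[, j])), j] < 0
    }
    if (flip) coords[, j] <- -coords[, j]
  }
  dev_idx <- if (ncol(coords) >= 2) coords[, 1] + coords[, 2] else rep(NA_real_, n)
  out <- list(
    coordinates = dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(coords)),
      tibble::as_tibble(coords, .name_repair = "minimal"),
      tibble::tibble(development_index = unname(dev_idx))),
    eigenvalues = e$values,
    proportion_explained = if (length(pos)) {
      c(e$values[pos] / sum(e$values[pos]),
        rep(0, n - length(pos)))[seq_len(n)]
    } else rep(0, n))
  class(out) <- "pcoa_ordination"
  out
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("<pcoa_ordination>", nrow(x$coordinates), "samples;",
      sum(x$eigenvalues > 0), "positive axes; axis 1-2 explain",
      sprintf("%.1f%%", 100 * sum(x$proportion_explained[1:2])), "\n")
  invisible(x)
}

#' Development index
#'
#' The sum of a sample's scores on the first two principal coordinates —
#' a scalar measure of microbiota maturation that increases with
#' postmenstrual age under the axis orientation applied by [pcoa()].
#'
#' @param ord a `pcoa_ordination`.
#' @return tibble with `sample_id` and `development_index`.
#' @export
development_index <- function(ord) {
  stopifnot(inherits(ord, "pcoa_ordination"))
  if (sum(ord$eigenvalues > 0) < 2) {
    rlang::abort("development index needs at least two positive axes")
  }
  dplyr::select(ord$coordinates, "sample_id", "development_index")
}

#' Permutational multivariate ANOVA on a dissimilarity matrix
#'
#' Sequential (Type-I) partitioning of the Gower-centered distance matrix
#' over an ordered list of covariates. Per-term pseudo-F uses the residual
#' from the full model; p-values come from permuting sample labels
#' (`p = (1 + #[F* >= F]) / (1 + permutations)`). Permutation is free by
#' default; `strata` restricts permutations within groups (e.g. infant) for
#' repeated-measures designs. `permutations = "exact"` enumerates all `n!`
#' orderings (small n only) and returns `p = #[F* >= F] / n!` including the
#' identity.
#'
#' @param d symmetric dissimilarity matrix.
#' @param data data frame of covariates, rows aligned to (or carrying a
#'   `sample_id` column matched against) the rows of `d`.
#' @param terms character vector of column names, in testing order.
#' @param permutations integer number of permutations, or `"exact"`.
#' @param seed integer seed for the permutation stream.
#' @param strata optional column name in `data`; permutations then shuffle
#'   only within its levels.
#' @return object of class `permanova_result` with a tidy `table`
#'   (term, df, SS, R2, pseudo_F, p) including the residual row.
#' @export
permanova <- function(d, data, terms, permutations = 999, seed = 1,
                      strata = NULL) {
  n <- nrow(d)
  if ("sample_id" %in% names(data) && !is.null(rownames(d))) {
    data <- data[match(rownames(d), data$sample_id), , drop = FALSE]
  }
  if (nrow(data) != n) rlang::abort("covariates not aligned to samples")
  for (tm in terms) {
    if (length(unique(data[[tm]])) < 2) {
      rlang::abort(paste0("constant covariate: ", tm))
    }
  }
  g <- gower_center(d)
  ss_total <- sum(diag(g))

  # incremental hat matrices for the sequential model sequence
  hats <- vector("list", length(terms) + 1)
  X <- matrix(1, n, 1)
  hats[[1]] <- X %*% solve(crossprod(X)) %*% t(X)
  dfs <- numeric(length(terms))
  rank_prev <- 1
  skipped <- character(0)
  for (j in seq_along(terms)) {
    Xj <- stats::model.matrix(stats::reformulate(terms[seq_len(j)]), data = data)
    q <- qr(Xj)
    if (q$rank <= rank_prev) {
      skipped <- c(skipped, terms[j])
      hats[[j + 1]] <- hats[[j]]
      dfs[j] <- 0
      next
    }
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[j + 1]] <- tcrossprod(Q)
    dfs[j] <- q$rank - rank_prev
    rank_prev <- q$rank
  }
  if (length(skipped)) {
    rlang::warn(paste0("rank-deficient term(s) skipped: ",
                       paste(skipped, collapse = ", ")))
  }
  df_res <- n - rank_prev

  stat_fun <- function(gp) {
    tr <- vapply(hats, function(h) sum(h * gp), numeric(1))
    ss <- diff(tr)                       # sequential SS per term
    ss_res <- sum(diag(gp)) - tr[length(tr)]
    f <- (ss / pmax(dfs, 1)) / (ss_res / df_res)
    f[dfs == 0] <- NA_real_
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat_fun(g)

  strata_id <- if (!is.null(strata)) data[[strata]] else NULL
  perm_one <- function() {
    if (is.null(strata_id)) return(sample.int(n))
    idx <- seq_len(n)
    for (lev in unique(strata_id)) {
      w <- which(strata_id == lev)
      idx[w] <- w[sample.int(length(w))]
    }
    idx
  }

  if (identical(permutations, "exact")) {
    perms <- all_permutations(n)
    count <- rep(0L, length(terms))
    for (k in seq_len(nrow(perms))) {
      fp <- stat_fun(g[perms[k, ], perms[k, ]])$f
      count <- count + as.integer(!is.na(fp) & fp >= obs$f - 1e-12)
    }
    pvals <- count / nrow(perms)
    n_perm <- nrow(perms)
  } else {
    set.seed(as.integer(seed))
    count <- rep(0L, length(terms))
    for (k in seq_len(permutations)) {
      p <- perm_one()
      fp <- stat_fun(g[p, p])$f
      count <- count + as.integer(!is.na(fp) & fp >= obs$f - 1e-12)
    }
    pvals <- (1 + count) / (1 + permutations)
    n_perm <- permutations
  }
  pvals[dfs == 0] <- NA_real_

  tab <- tibble::tibble(
    term = c(terms, "Residual"),
    df = c(dfs, df_res),
    SS = c(obs$ss, obs$ss_res),
    R2 = c(obs$ss, obs$ss_res) / ss_total,
    pseudo_F = c(obs$f, NA_real_),
    p = c(pvals, NA_real_))
  out <- list(table = tab, permutations = n_perm, seed = seed,
              ss_total = ss_total)
  class(out) <- "permanova_result"
  out
}

# all n! permutations of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n > 8) rlang::abort("exact enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("Permutational multivariate ANOVA (", x$permutations,
      " permutations)\n", sep = "")
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}
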