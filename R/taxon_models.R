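#' Negative-binomial log-likelihood
#'
#' Direct evaluation of the NB2 mass function (size `theta`, mean `mu`)
#' summed over the data, via log-gamma terms.
#'
#' @param y counts; @param mu means; @param theta dispersion (size).
#' @return total log-likelihood.
#' @keywords internal
nb_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu)))
}

nb_deviance <- function(y, mu, theta) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + theta) * log((y + theta) / (mu + theta))
  2 * sum(t1 - t2)
}

# cubic B-spline basis with knots spread over the covariate range
bspline_basis <- function(x, df, xr = range(x)) {
  degree <- 3
  nk <- df - degree + 1          # interior + boundary knot count
  inner <- seq(xr[1], xr[2], length.out = nk)
  knots <- c(rep(xr[1], degree), inner, rep(xr[2], degree))
  splines::splineDesign(knots, pmin(pmax(x, xr[1]), xr[2]), ord = degree + 1,
                        outer.ok = TRUE)
}

# second-difference penalty matrix D'D for k basis coefficients
diff_penalty <- function(k) {
  D <- diff(diag(k), differences = 2)
  crossprod(D)
}

# one penalized IRLS fit at fixed penalties and dispersion
pirls_nb <- function(y, X, offset, P, theta, maxit = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 0.5) - mean(offset)
  eta <- offset + drop(X %*% beta)
  mu <- exp(eta)
  dev <- nb_deviance(y, mu, theta)
  for (it in seq_len(maxit)) {
    w <- pmax(mu / (1 + mu / theta), 1e-8)   # floor: flat-region samples
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X + P
    ridge <- 1e-7 * max(diag(A), 1)
    beta_new <- tryCatch(
      solve(A, XtW %*% z),
      error = function(e) solve(A + diag(ridge, ncol(X)), XtW %*% z))
    beta_new <- drop(beta_new)
    eta <- offset + drop(X %*% beta_new)
    eta <- pmin(pmax(eta, -25), 25)
    mu <- exp(eta)
    dev_new <- nb_deviance(y, mu, theta)
    converged <- abs(dev - dev_new) < tol * (abs(dev_new) + 0.1)
    beta <- beta_new
    dev <- dev_new
    if (converged) break
  }
  XtWX <- XtW %*% X
  edf <- tryCatch(sum(diag(solve(XtWX + P, XtWX))),
                  error = function(e) {
                    sum(diag(solve(XtWX + P + diag(1e-7 * max(diag(XtWX), 1),
                                                   ncol(X)), XtWX)))
                  })
  list(beta = beta, mu = mu, eta = eta, deviance = dev, edf = edf,
       iterations = it, converged = it < maxit || converged)
}

#' Fit an age-adjusted taxon abundance model
#'
#' Penalized negative-binomial regression with log link for a single
#' taxon's read counts: cubic B-spline smooths (second-difference penalty)
#' for the smooth covariates, unpenalized linear/factor terms, a log
#' read-total offset so the mean structure is on the relative-abundance
#' scale, and ridge-penalized per-infant intercepts as the subject term.
#' The dispersion is estimated by method of moments from the Pearson
#' residuals of an initial Poisson fit, then held fixed; the smoothing and
#' ridge penalties are chosen by minimizing AIC (deviance + 2 edf) over a
#' fixed log-spaced grid.
#'
#' @param counts a count tibble.
#' @param records metadata tibble aligned by `sample_id`.
#' @param taxon response taxon label (a row of `counts`).
#' @param smooth_terms covariates modeled as penalized splines.
#' @param linear_terms covariates entering linearly (factors allowed).
#' @param subject grouping column for ridge intercepts (`NULL` to omit).
#' @param basis_size B-spline basis dimension per smooth (>= 4).
#' @param dispersion `"estimate"`, or a positive number, or `Inf` for the
#'   Poisson limit.
#' @param lambda_grid candidate smoothing penalties; a single value skips
#'   selection. `lambda_subject_grid` likewise for the subject ridge.
#' @return object of class `taxon_model_fit`.
#' @export
fit_taxon_model <- function(counts, records, taxon,
                            smooth_terms = "pma_week",
                            linear_terms = character(0),
                            subject = "infant_id",
                            basis_size = 8,
                            dispersion = "estimate",
                            lambda_grid = 10^seq(-1, 4, length.out = 6),
                            lambda_subject_grid = c(1, 10)) {
  if (basis_size < 4) rlang::abort("basis_size must be at least 4")
  m <- counts_matrix(counts)
  if (!taxon %in% rownames(m)) rlang::abort(paste0("taxon not in table: ", taxon))
  records <- records[match(colnames(m), records$sample_id), , drop = FALSE]
  if (anyNA(records$sample_id)) rlang::abort("metadata missing for some samples")
  y <- as.numeric(m[taxon, ])
  totals <- colSums(m)
  if (any(totals <= 0)) rlang::abort("zero-read sample; remove before fitting")
  offset <- log(totals)

  # design: intercept | splines per smooth | linear terms | subject dummies
  blocks <- list(intercept = matrix(1, length(y), 1))
  pen_idx <- list()
  ranges <- list()
  for (tm in smooth_terms) {
    x <- records[[tm]]
    if (length(unique(x)) < 2) rlang::abort(paste0("zero-variance covariate: ", tm))
    ranges[[tm]] <- range(x)
    B <- bspline_basis(x, basis_size)
    blocks[[paste0("s_", tm)]] <- B
  }
  for (tm in linear_terms) {
    x <- records[[tm]]
    if (length(unique(x)) < 2) rlang::abort(paste0("zero-variance covariate: ", tm))
    mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
    colnames(mm) <- paste0(tm, seq_len(ncol(mm)))
    blocks[[tm]] <- mm
  }
  subj_levels <- NULL
  if (!is.null(subject)) {
    f <- factor(records[[subject]])
    subj_levels <- levels(f)
    Z <- stats::model.matrix(~ f - 1)
    colnames(Z) <- subj_levels
    blocks[["subject"]] <- Z
  }
  X <- do.call(cbind, blocks)
  sizes <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1

  penalty_at <- function(lam_s, lam_u) {
    P <- matrix(0, ncol(X), ncol(X))
    for (tm in smooth_terms) {
      i <- which(names(blocks) == paste0("s_", tm))
      idx <- starts[i]:ends[i]
      P[idx, idx] <- lam_s * diff_penalty(length(idx))
    }
    if (!is.null(subject)) {
      i <- which(names(blocks) == "subject")
      idx <- starts[i]:ends[i]
      P[idx, idx] <- diag(lam_u, length(idx))
    }
    P
  }

  n10 <- length(y)
  if (n10 < 5 * basis_size) {
    rlang::warn("few samples relative to basis size; fit may be unstable")
  }

  fit_at <- function(theta, lam_s, lam_u) {
    pirls_nb(y, X, offset, penalty_at(lam_s, lam_u), theta)
  }

  # dispersion: method of moments from an initial Poisson fit
  if (identical(dispersion, "estimate")) {
    f0 <- fit_at(1e8, stats::median(lambda_grid), lambda_subject_grid[1])
    mu0 <- f0$mu
    inv_theta <- sum((y - mu0)^2 - mu0) / sum(mu0^2)
    theta <- 1 / max(inv_theta, 1e-4)
    theta <- min(theta, 1e8)
  } else {
    theta <- if (is.infinite(dispersion)) 1e8 else dispersion
  }

  if (!is.null(subject)) {
    grid <- expand.grid(lam_s = lambda_grid, lam_u = lambda_subject_grid)
  } else {
    grid <- expand.grid(lam_s = lambda_grid, lam_u = 0)
  }
  best <- NULL; best_aic <- Inf
  for (k in seq_len(nrow(grid))) {
    fk <- fit_at(theta, grid$lam_s[k], grid$lam_u[k])
    aic <- fk$deviance + 2 * fk$edf
    if (aic < best_aic) {
      best_aic <- aic; best <- fk
      best$lambda <- grid$lam_s[k]; best$lambda_subject <- grid$lam_u[k]
    }
  }
  if (!best$converged) {
    rlang::warn(paste0("IRLS did not converge in ", best$iterations,
                       " iterations for ", taxon))
  }

  # null model: intercept + offset only, same theta
  null_fit <- pirls_nb(y, blocks$intercept, offset, matrix(0, 1, 1), theta)

  out <- list(
    taxon = taxon,
    coefficients = stats::setNames(best$beta, colnames(X)),
    blocks = names(blocks), block_start = starts, block_end = ends,
    smooth_terms = smooth_terms, linear_terms = linear_terms,
    subject = subject, subj_levels = subj_levels,
    basis_size = basis_size, ranges = ranges,
    lambda = best$lambda, lambda_subject = best$lambda_subject,
    theta = theta, edf = best$edf,
    fitted_counts = best$mu,
    # relative scale is clamped to (0, 1): a proportion cannot exceed one
    fitted_relative = pmin(pmax(best$mu / totals, 1e-12), 1 - 1e-12),
    offset = offset, y = y,
    sample_id = colnames(m),
    deviance = best$deviance,
    null_deviance = null_fit$deviance,
    loglik = nb_loglik(y, best$mu, theta),
    aic = best_aic,
    converged = best$converged,
    records = records)
  class(out) <- "taxon_model_fit"
  out
}

#' @export
print.taxon_model_fit <- function(x, ...) {
  cat("<taxon_model_fit> ", x$taxon, ": NB(theta=", signif(x$theta, 3),
      "), edf=", signif(x$edf, 3),
      ", deviance explained=",
      sprintf("%.1f%%", 100 * (1 - x$deviance / x$null_deviance)), "\n", sep = "")
  invisible(x)
}

#' Predict expected counts or relative abundances from a fitted model
#'
#' Predictions for new samples use the population level of the subject term
#' (subject effect 0) unless the infant was in the training data.
#' Postmenstrual ages outside the fitted range are clamped with a warning.
#'
#' @param object a `taxon_model_fit`.
#' @param newdata metadata tibble; needs the model covariates plus `reads`.
#' @param type `"relative"` (expected count / reads) or `"counts"`.
#' @param ... unused.
#' @export
predict.taxon_model_fit <- function(object, newdata = NULL,
                                    type = c("relative", "counts"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "relative") object$fitted_relative else
             object$fitted_counts)
  }
  eta <- rep(object$coefficients[1], nrow(newdata))
  ci <- 1
  for (tm in object$smooth_terms) {
    x <- newdata[[tm]]
    xr <- object$ranges[[tm]]
    if (any(x < xr[1] | x > xr[2])) {
      rlang::warn(paste0("predictions outside fitted ", tm,
                         " range are clamped"))
    }
    B <- bspline_basis(x, object$basis_size, xr)
    idx <- ci + seq_len(ncol(B))
    eta <- eta + drop(B %*% object$coefficients[idx])
    ci <- ci + ncol(B)
  }
  for (tm in object$linear_terms) {
    train_x <- object$records[[tm]]
    if (is.numeric(train_x)) {
      k <- 1
      eta <- eta + newdata[[tm]] * object$coefficients[ci + 1]
    } else {
      lev <- levels(factor(train_x))
      mm <- stats::model.matrix(~x, list(x = factor(newdata[[tm]], levels = lev)))
      mm <- mm[, -1, drop = FALSE]
      k <- ncol(mm)
      eta <- eta + drop(mm %*% object$coefficients[ci + seq_len(k)])
    }
    ci <- ci + k
  }
  if (!is.null(object$subject)) {
    u <- object$coefficients[object$block_start[object$blocks == "subject"] - 1 +
                               match(newdata[[object$subject]],
                                     object$subj_levels)]
    u[is.na(u)] <- 0
    eta <- eta + u
  }
  rel <- exp(pmin(pmax(eta, -30), 30))
  if (type == "relative") unname(rel) else unname(rel * newdata$reads)
}

#' Deviance fraction explained by the terms dropped from a nested model
#'
#' `(deviance_reduced - deviance_full) / null_deviance`: the share of the
#' null deviance attributable to the terms present in `fit` but not in
#' `reduced`. Both fits must be on the same data (checked via response).
#'
#' Both fits must share the dispersion (fit the reduced model with
#' `dispersion = fit$theta`), otherwise deviances are not comparable.
#'
#' @param fit full-model `taxon_model_fit`.
#' @param reduced nested `taxon_model_fit`.
#' @return fraction in [0, 1] (small negative values are clipped to 0).
#' @export
variance_explained <- function(fit, reduced) {
  if (!identical(fit$y, reduced$y)) rlang::abort("models fit to different data")
  if (abs(log(fit$theta / reduced$theta)) > 1e-6) {
    rlang::warn("dispersion differs between fits; deviances are not comparable")
  }
  full_terms <- c(fit$smooth_terms, fit$linear_terms)
  red_terms <- c(reduced$smooth_terms, reduced$linear_terms)
  if (!all(red_terms %in% full_terms)) rlang::abort("models are not nested")
  max(0, (reduced$deviance - fit$deviance) / fit$null_deviance)
}

#' Sequential variance-explained ledger over an ordered term list
#'
#' Fits the model sequence `~1`, `~t1`, `~t1+t2`, ... (all with the same
#' subject term and dispersion handling) and attributes deviance fractions
#' to each term in order, with an approximate likelihood-ratio p-value
#' (chi-squared on the change in effective degrees of freedom; flagged
#' approximate because penalties shrink the reference distribution).
#'
#' @inheritParams fit_taxon_model
#' @param terms ordered covariates; names listed in `smooth` are splined.
#' @param smooth subset of `terms` to model as smooths.
#' @param ... passed on to [fit_taxon_model()].
#' @return tibble: term, deviance_fraction, edf, p_approx.
#' @export
variance_ledger <- function(counts, records, taxon, terms,
                            smooth = intersect(terms, c("pma_week", "postnatal_day")),
                            subject = "infant_id", ...) {
  # one dispersion, estimated under the full model, shared by the whole
  # sequence so sequential deviances are on a common scale
  full <- fit_taxon_model(counts, records, taxon,
                          smooth_terms = intersect(terms, smooth),
                          linear_terms = setdiff(terms, smooth),
                          subject = subject, ...)
  fits <- vector("list", length(terms) + 1)
  fits[[1]] <- fit_taxon_model(counts, records, taxon,
                               smooth_terms = character(0),
                               linear_terms = character(0),
                               subject = subject, dispersion = full$theta, ...)
  for (j in seq_along(terms)) {
    use <- terms[seq_len(j)]
    fits[[j + 1]] <- if (j == length(terms)) full else
      fit_taxon_model(counts, records, taxon,
                      smooth_terms = intersect(use, smooth),
                      linear_terms = setdiff(use, smooth),
                      subject = subject, dispersion = full$theta, ...)
  }
  null_dev <- fits[[1]]$null_deviance
  purrr::map_dfr(seq_along(terms), function(j) {
    ddev <- fits[[j]]$deviance - fits[[j + 1]]$deviance
    dedf <- max(fits[[j + 1]]$edf - fits[[j]]$edf, 0.5)
    tibble::tibble(
      term = terms[j],
      deviance_fraction = max(0, ddev / null_dev),
      edf = dedf,
      p_approx = stats::pchisq(max(ddev, 0), df = dedf, lower.tail = FALSE))
  })
}
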