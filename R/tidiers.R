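#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PERMANOVA result
#'
#' @param x a `permanova_result`.
#' @param ... unused.
#' @return tibble with one row per term plus the residual row.
#' @export
tidy.permanova_result <- function(x, ...) x$table

#' @export
glance.permanova_result <- function(x, ...) {
  tibble::tibble(n_terms = sum(x$table$term != "Residual"),
                 permutations = x$permutations,
                 ss_total = x$ss_total,
                 r2_model = sum(x$table$R2[x$table$term != "Residual"]))
}

#' Tidy a fitted taxon model
#'
#' @param x a `taxon_model_fit`.
#' @param ... unused.
#' @return tibble of coefficients with their design block.
#' @export
tidy.taxon_model_fit <- function(x, ...) {
  block <- character(length(x$coefficients))
  for (i in seq_along(x$blocks)) {
    block[x$block_start[i]:x$block_end[i]] <- x$blocks[i]
  }
  tibble::tibble(term = names(x$coefficients), block = block,
                 estimate = unname(x$coefficients))
}

#' @export
glance.taxon_model_fit <- function(x, ...) {
  tibble::tibble(taxon = x$taxon, n = length(x$y), theta = x$theta,
                 edf = x$edf, deviance = x$deviance,
                 null_deviance = x$null_deviance,
                 deviance_explained = 1 - x$deviance / x$null_deviance,
                 logLik = x$loglik, AIC = x$aic, converged = x$converged)
}

#' Tidy an ordination
#'
#' @param x a `pcoa_ordination`.
#' @param ... unused.
#' @return the per-sample coordinate tibble with the development index.
#' @export
tidy.pcoa_ordination <- function(x, ...) x$coordinates

#' @export
glance.pcoa_ordination <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$coordinates),
                 n_positive_axes = sum(x$eigenvalues > 0),
                 prop_axis1 = x$proportion_explained[1],
                 prop_axis2 = x$proportion_explained[2])
}
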