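#' Genetic and environmental correlation matrices from a multivariate fit
#'
#' `rA_ij = A_ij / sqrt(A_ii * A_jj)` and analogously for C and E. Cells
#' whose diagonal entries are nonpositive (possible under the direct
#' parameterization) are returned as `NA` rather than fabricated.
#'
#' @param fit a multivariate `biometric_fit`.
#' @param ci compute 95% profile-likelihood intervals for each off-diagonal
#'   correlation (slow; default `FALSE`).
#' @returns A list with matrices `rA` and `rE` (and `rC` when C is in the
#'   model), plus a tibble `ci` when requested.
#' @export
genetic_env_correlations <- function(fit, ci = FALSE) {
  if (length(fit$params$means) < 2L) abort("requires a multivariate fit")
  corr_of <- function(m) {
    d <- diag(m)
    bad <- d <= 0
    if (any(bad)) warn("nonpositive component variance; correlation cells set to NA")
    s <- sqrt(ifelse(bad, NA_real_, d))
    out <- m / outer(s, s)
    diag(out) <- ifelse(bad, NA_real_, 1)
    out
  }
  out <- list()
  for (k in intersect(c("A", "C", "E"), fit$components)) {
    out[[paste0("r", k)]] <- corr_of(fit$params[[k]])
  }
  if (ci) {
    tr <- fit$params$trait_names
    cells <- which(upper.tri(diag(length(tr))), arr.ind = TRUE)
    rows <- list()
    for (k in intersect(c("A", "E"), fit$components)) {
      for (r in seq_len(nrow(cells))) {
        i <- cells[r, 1]; j <- cells[r, 2]
        pci <- profile_ci(fit, sprintf("r%s:%s:%s", k, tr[i], tr[j]))
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          pci, component = k, trait1 = tr[i], trait2 = tr[j], .before = 1)
      }
    }
    out$ci <- dplyr::bind_rows(rows)
  }
  out
}

#' Order predictors by regression-coefficient magnitude
#'
#' Sorts facet labels by absolute standardized beta, descending, and appends
#' the target trait last -- the entry order used for the ordered Cholesky
#' model. Ties are broken by the facets' input (inventory) order, and any
#' tie is reported.
#'
#' @param betas named numeric vector of standardized betas (or a data frame
#'   with columns `term` and `estimate`).
#' @param target label of the trait entered last.
#' @returns Character vector: facets in decreasing `|beta|`, then `target`.
#' @export
#' @examples
#' order_by_beta(c(O2 = 0.42, FA = 0.09, E3 = 0.08), target = "MM-I")
order_by_beta <- function(betas, target) {
  if (is.data.frame(betas)) {
    betas <- setNames(betas$estimate, betas$term)
  }
  if (anyDuplicated(names(betas))) abort("duplicate facet labels")
  if (target %in% names(betas)) {
    abort("target must not appear among the facet betas")
  }
  ab <- abs(betas)
  if (anyDuplicated(ab)) {
    tied <- names(betas)[ab %in% ab[duplicated(ab)]]
    inform(sprintf("tied |beta| broken by inventory order: %s",
                   paste(tied, collapse = ", ")))
  }
  ord <- order(-ab, seq_along(ab))  # stable: input order breaks ties
  c(names(betas)[ord], target)
}

#' Ordered Cholesky decomposition: personality-shared vs unique variance
#'
#' Fits an AE (or ACE) Cholesky model with the traits in the supplied order,
#' target last, and decomposes the target's genetic and environmental
#' variance into the part transmitted through the preceding (personality)
#' variables versus the part unique to the target. With Cholesky paths
#' `l_tj` into the target row `t`, the shared fraction is
#' `sum(l_tj^2, j < t) / sum(l_tj^2, j <= t)`, computed separately for A and
#' E. In the bivariate case the shared genetic fraction equals `rA^2`.
#'
#' @param cohort twin-cohort tibble.
#' @param ordering trait labels, target last (length >= 2), e.g. from
#'   [order_by_beta()].
#' @param components model components (default AE).
#' @param n_starts,seed passed to [fit_biometric()].
#' @param ci compute profile-likelihood CIs for the shared fractions
#'   (default `FALSE`).
#' @returns An object of class `cholesky_decomposition`: `ordering`, `rA`,
#'   `rE`, `target`, `target_a2`/`target_c2`/`target_e2` (standardized
#'   shares), `shared_a_fraction`, `shared_e_fraction`, optional `ci`, and
#'   the underlying `fit`.
#' @export
cholesky_shared_unique <- function(cohort, ordering,
                                   components = c("A", "E"),
                                   n_starts = 3, seed = NULL, ci = FALSE) {
  if (length(ordering) < 2L) abort("ordering must contain at least 2 traits")
  fit <- fit_biometric(cohort, traits = ordering, components = components,
                       parameterization = "cholesky",
                       n_starts = n_starts, seed = seed)
  t <- length(ordering)
  shared_frac <- function(pr, comp) {
    L <- t(chol(pr[[comp]] + diag(1e-12, t)))
    tot <- sum(L[t, 1:t]^2)
    if (tot <= 0) return(NA_real_)
    sum(L[t, seq_len(t - 1)]^2) / tot
  }
  corr <- genetic_env_correlations(fit)
  std <- fit$standardized[t, ]
  out <- list(
    ordering = ordering, target = ordering[t],
    rA = corr$rA, rE = corr$rE,
    shared_a_fraction = shared_frac(fit$params, "A"),
    shared_e_fraction = shared_frac(fit$params, "E"),
    fit = fit
  )
  for (k in fit$components) {
    out[[paste0("target_", tolower(k), "2")]] <- std[[paste0(tolower(k), "2")]]
  }
  if (ci) {
    out$ci <- dplyr::bind_rows(
      dplyr::mutate(profile_ci(fit, function(pr) shared_frac(pr, "A")),
                    quantity = "shared_a_fraction", .before = 1),
      dplyr::mutate(profile_ci(fit, function(pr) shared_frac(pr, "E")),
                    quantity = "shared_e_fraction", .before = 1))
  }
  class(out) <- "cholesky_decomposition"
  out
}

#' @export
print.cholesky_decomposition <- function(x, ...) {
  cat(sprintf("<cholesky_decomposition> target `%s` after %d predecessor(s)\n",
              x$target, length(x$ordering) - 1L))
  cat(sprintf("  target a2 = %.3f (shared with predecessors: %.1f%%)\n",
              x$target_a2, 100 * x$shared_a_fraction))
  cat(sprintf("  target e2 = %.3f (shared with predecessors: %.1f%%)\n",
              x$target_e2, 100 * x$shared_e_fraction))
  invisible(x)
}
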