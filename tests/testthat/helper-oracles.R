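# Independent oracles and fixture builders used across the suite.

# Naive per-record FIML -2LL: dense determinant/solve per family, no
# grouping, no Cholesky factorization. Independent of the package's grouped
# sufficient-statistics evaluation path.
naive_fiml <- function(params, cohort, traits) {
  p <- length(traits)
  fams <- split(seq_len(nrow(cohort)), cohort$family_id)
  total <- 0
  for (ix in fams) {
    y <- rep(NA_real_, 2 * p)
    for (r in ix) {
      off <- if (cohort$twin_order[r] == 1L) 0L else p
      y[off + seq_len(p)] <- unlist(cohort[r, traits])
    }
    obs <- !is.na(y)
    if (!any(obs)) next
    Sig <- expected_pair_covariance(params, cohort$zygosity[ix[1]])
    S <- Sig[obs, obs, drop = FALSE]
    d <- y[obs] - rep(params$means, 2)[obs]
    total <- total + sum(obs) * log(2 * pi) + log(det(S)) +
      drop(t(d) %*% solve(S) %*% d)
  }
  total
}

# Brute-force Benjamini-Hochberg step-up adjusted p-values.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Build a cohort whose per-group ML sample moments (mean, scatter/n) equal
# the given pair covariances EXACTLY: draw, center, whiten, recolor. The ML
# optimum of any model then sits at parameters implying those moments.
moment_matched_group <- function(n, Sigma, zygosity, id0, trait_names) {
  k <- nrow(Sigma)
  p <- k / 2
  X <- matrix(rnorm(n * k), n, k)
  X <- sweep(X, 2, colMeans(X))
  S <- crossprod(X) / n
  X <- X %*% solve(chol(S)) %*% chol(Sigma)
  rows <- lapply(1:2, function(tw) {
    y <- X[, (tw - 1) * p + seq_len(p), drop = FALSE]
    colnames(y) <- paste0("pheno_", trait_names)
    dplyr::bind_cols(
      tibble::tibble(family_id = sprintf("%s%05d", tolower(zygosity), id0 + seq_len(n)),
                     zygosity = zygosity, twin_order = tw,
                     sex = 0L, age = 40),
      tibble::as_tibble(y))
  })
  dplyr::bind_rows(rows)
}

moment_matched_cohort <- function(params, n_mz, n_dz, seed = 1) {
  trait_names <- params$trait_names
  withr::with_seed(seed, dplyr::bind_rows(
    moment_matched_group(n_mz, expected_pair_covariance(params, "MZ"),
                         "MZ", 0L, trait_names),
    moment_matched_group(n_dz, expected_pair_covariance(params, "DZ"),
                         "DZ", n_mz, trait_names)))
}

# Standardized univariate AE parameter set.
ae_params <- function(a2 = 0.5) {
  biometric_params(A = a2, E = 1 - a2, means = 0)
}

# Closed-form standard error of an empirical covariance between components
# i, j of a multivariate normal (for Monte-Carlo tolerance bands).
cov_mc_se <- function(Sigma, i, j, n) {
  sqrt((Sigma[i, i] * Sigma[j, j] + Sigma[i, j]^2) / n)
}

# Cross-twin covariance matrix between twin-1 and twin-2 phenotype blocks.
empirical_cross_cov <- function(cohort, zygosity, traits) {
  cols <- paste0("pheno_", traits)
  sub <- cohort[cohort$zygosity == zygosity, c("family_id", "twin_order", cols)]
  w <- tidyr::pivot_wider(sub, names_from = "twin_order",
                          values_from = dplyr::all_of(cols),
                          names_glue = "{.value}@{twin_order}")
  w <- w[stats::complete.cases(w), ]
  t1 <- as.matrix(w[, paste0(cols, "@1")])
  t2 <- as.matrix(w[, paste0(cols, "@2")])
  stats::cov(t1, t2)
}
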