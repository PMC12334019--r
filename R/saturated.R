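# Saturated and constrained mean/covariance models for the classical twin
# design assumption tests. Per zygosity the saturated model has a free
# 2p-mean and a free 2p x 2p covariance (no within-pair symmetry imposed);
# the constraint chain equates means within pairs, then across zygosity,
# then variances within pairs and across zygosity.

# correlation matrix from unconstrained lower-tri z via row-normalized
# Cholesky; z_ij = l_ij / l_ii
corr_from_z <- function(z, k) {
  L <- diag(k)
  L[lower.tri(L)] <- z
  L <- L / sqrt(rowSums(L^2))
  tcrossprod(L)
}

z_from_corr <- function(R) {
  L <- t(chol(R + diag(1e-10, nrow(R))))
  L <- L / sqrt(rowSums(L^2))
  (L / diag(L))[lower.tri(L)]
}

# model levels: "saturated", "means_pair", "means_zyg", "var_zyg"
saturated_family_fit <- function(stats, model) {
  p <- stats$p; k <- 2 * p
  nz <- k * (k - 1) / 2

  # moment starts from per-zygosity pair groups (fall back to pooled)
  start_mom <- function(zyg) {
    g <- Filter(function(g) g$zygosity == zyg && length(g$idx) == k, stats$groups)
    if (length(g)) {
      g <- g[[which.max(vapply(g, `[[`, numeric(1), "n"))]]
      list(mean = g$mean, cov = g$scatter + diag(1e-8, k))
    } else list(mean = rep(0, k), cov = diag(k))
  }
  mom <- list(MZ = start_mom("MZ"), DZ = start_mom("DZ"))

  layout <- switch(
    model,
    saturated  = list(n_mean = 2L * k, n_sd = 2L * k),
    means_pair = list(n_mean = 2L * p, n_sd = 2L * k),
    means_zyg  = list(n_mean = p,      n_sd = 2L * k),
    var_zyg    = list(n_mean = p,      n_sd = p)
  )
  n_par <- layout$n_mean + layout$n_sd + 2L * nz

  unpack <- function(theta) {
    mth <- theta[seq_len(layout$n_mean)]
    sth <- theta[layout$n_mean + seq_len(layout$n_sd)]
    zth <- theta[layout$n_mean + layout$n_sd + seq_len(2L * nz)]
    mu <- switch(model,
      saturated  = list(MZ = mth[1:k], DZ = mth[k + 1:k]),
      means_pair = list(MZ = rep(mth[1:p], 2), DZ = rep(mth[p + 1:p], 2)),
      list(MZ = rep(mth[1:p], 2), DZ = rep(mth[1:p], 2)))
    sds <- switch(model,
      var_zyg = {
        s <- exp(sth[1:p]); list(MZ = rep(s, 2), DZ = rep(s, 2))
      },
      list(MZ = exp(sth[1:k]), DZ = exp(sth[k + 1:k])))
    sig <- list(
      MZ = diag(sds$MZ) %*% corr_from_z(zth[seq_len(nz)], k) %*% diag(sds$MZ),
      DZ = diag(sds$DZ) %*% corr_from_z(zth[nz + seq_len(nz)], k) %*% diag(sds$DZ))
    list(mu = mu, sig = sig)
  }

  obj <- function(theta) {
    st <- unpack(theta)
    val <- m2ll_from_stats(stats, st$sig, st$mu)
    if (!is.finite(val)) 1e12 else val
  }

  mean_start <- switch(model,
    saturated  = c(mom$MZ$mean, mom$DZ$mean),
    means_pair = c((mom$MZ$mean[1:p] + mom$MZ$mean[p + 1:p]) / 2,
                   (mom$DZ$mean[1:p] + mom$DZ$mean[p + 1:p]) / 2),
    (mom$MZ$mean[1:p] + mom$MZ$mean[p + 1:p] +
       mom$DZ$mean[1:p] + mom$DZ$mean[p + 1:p]) / 4)
  sd_start <- switch(model,
    var_zyg = log(sqrt((diag(mom$MZ$cov)[1:p] + diag(mom$MZ$cov)[p + 1:p] +
                          diag(mom$DZ$cov)[1:p] + diag(mom$DZ$cov)[p + 1:p]) / 4)),
    c(log(sqrt(diag(mom$MZ$cov))), log(sqrt(diag(mom$DZ$cov)))))
  z_start <- c(z_from_corr(stats::cov2cor(mom$MZ$cov)),
               z_from_corr(stats::cov2cor(mom$DZ$cov)))
  start <- c(mean_start, sd_start, z_start)

  ans <- nlminb(start, obj, control = list(iter.max = 2000, eval.max = 8000))
  list(minus2LL = ans$objective, n_params = n_par, model = model,
       converged = ans$convergence == 0)
}

#' Assumption tests of the classical twin design
#'
#' Fits a fully saturated model (free means and free covariance per
#' zygosity, twin order unconstrained) and the standard constraint chain --
#' means equal within pairs, means equal across zygosity, variances equal
#' within pairs and across zygosity -- comparing each constrained model to
#' the saturated model by likelihood ratio. Non-significant tests support
#' the equal-means/equal-variances assumptions required before biometric
#' modeling.
#'
#' @param cohort twin-cohort tibble.
#' @param traits trait/column names; default all `pheno_`/`score_` columns.
#' @returns A tibble with one row per constrained model: `model`,
#'   `delta_minus2LL`, `delta_df`, `p_value`, `delta_aic`, `preferred`.
#' @export
assumption_tests <- function(cohort, traits = NULL) {
  stats <- cohort_stats(cohort, traits)
  sat <- saturated_family_fit(stats, "saturated")
  rows <- lapply(c("means_pair", "means_zyg", "var_zyg"), function(m) {
    fit <- saturated_family_fit(stats, m)
    d <- max(0, fit$minus2LL - sat$minus2LL)
    ddf <- sat$n_params - fit$n_params
    pv <- pchisq(d, df = ddf, lower.tail = FALSE)
    tibble(model = m, delta_minus2LL = d, delta_df = ddf, p_value = pv,
           delta_aic = (fit$minus2LL + 2 * fit$n_params) -
             (sat$minus2LL + 2 * sat$n_params),
           preferred = if (pv >= 0.05) m else "saturated")
  })
  dplyr::bind_rows(rows)
}

#' Intraclass twin correlation
#'
#' Pearson correlation of twin-1 versus twin-2 values over complete pairs
#' of one zygosity group, with the analytic standard error
#' `(1 - r^2) / sqrt(n_pairs - 1)`.
#'
#' @param cohort twin-cohort tibble.
#' @param trait a single trait/column name.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @returns A one-row tibble: `zygosity`, `r`, `se`, `n_pairs`.
#' @export
intraclass_corr <- function(cohort, trait, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  col <- resolve_traits(cohort, trait)
  sub <- cohort[cohort$zygosity == zygosity, c("family_id", "twin_order", col)]
  wide <- tidyr::pivot_wider(sub, names_from = "twin_order",
                             values_from = dplyr::all_of(col), names_prefix = "t")
  if (!all(c("t1", "t2") %in% names(wide))) {
    abort("fewer than 3 complete pairs in the zygosity group")
  }
  wide <- wide[complete.cases(wide[c("t1", "t2")]), ]
  n <- nrow(wide)
  if (n < 3L) abort("fewer than 3 complete pairs in the zygosity group")
  r <- cor(wide$t1, wide$t2)
  tibble(zygosity = zygosity, r = r, se = (1 - r^2) / sqrt(n - 1), n_pairs = n)
}

#' Twin correlations for several traits
#'
#' MZ and DZ intraclass correlations with standard errors for each trait,
#' joined with the variance-component heuristic flags.
#'
#' @param cohort twin-cohort tibble.
#' @param traits trait/column names; default all `pheno_`/`score_` columns.
#' @returns A tibble with one row per trait: `trait`, `r_mz`, `se_mz`,
#'   `n_mz`, `r_dz`, `se_dz`, `n_dz`, plus the heuristic flags of
#'   [heuristic_components()].
#' @export
twin_correlations <- function(cohort, traits = NULL) {
  cols <- resolve_traits(cohort, traits)
  rows <- lapply(cols, function(col) {
    mz <- intraclass_corr(cohort, col, "MZ")
    dz <- intraclass_corr(cohort, col, "DZ")
    tibble(trait = sub("^(pheno|score)_", "", col),
           r_mz = mz$r, se_mz = mz$se, n_mz = mz$n_pairs,
           r_dz = dz$r, se_dz = dz$se, n_dz = dz$n_pairs)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(out, heuristic_components(out$r_mz, out$r_dz))
}

#' Variance-component heuristic from twin correlations
#'
#' Classical screening rules: additive genetic (A) effects are suggested
#' when `r_mz > r_dz`; shared-environment (C) effects when
#' `r_mz < 2 * r_dz`; dominance (D) effects when `r_mz > 2 * r_dz` (both
#' comparisons strict, so an exact 2:1 ratio flags neither C nor D). E is
#' always present since it absorbs measurement error.
#'
#' @param r_mz,r_dz numeric vectors of MZ and DZ intraclass correlations.
#' @returns A tibble with logical columns `A_suggested`, `C_suggested`,
#'   `D_suggested`.
#' @export
#' @examples
#' heuristic_components(r_mz = c(0.36, 0.50, 0.53), r_dz = c(0.31, 0.25, 0.15))
heuristic_components <- function(r_mz, r_dz) {
  tibble(A_suggested = r_mz > r_dz,
         C_suggested = r_mz < 2 * r_dz,
         D_suggested = r_mz > 2 * r_dz)
}
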