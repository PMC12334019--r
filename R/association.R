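#' Fisher-z confidence interval for a Pearson correlation
#'
#' `z = atanh(r)` with standard error `1 / sqrt(n - 3)`; the interval is
#' back-transformed by `tanh`.
#'
#' @param r correlation, `|r| < 1`.
#' @param n sample size, `n > 3`.
#' @param level confidence level (default 0.95).
#' @returns A one-row tibble: `r`, `n`, `lower`, `upper`.
#' @export
#' @examples
#' pearson_ci(0.78, 1983)
pearson_ci <- function(r, n, level = 0.95) {
  if (n <= 3) abort("n must exceed 3")
  if (abs(r) >= 1) abort("|r| must be < 1")
  z <- atanh(r)
  hw <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tibble(r = r, n = n, lower = tanh(z - hw), upper = tanh(z + hw))
}

#' Cluster-robust (GEE-style) regression for twin data
#'
#' Gaussian identity-link generalized estimating equations: coefficients by
#' iteratively reweighted generalized least squares under a working
#' correlation (independence, or exchangeable with a moment-estimated
#' within-cluster correlation), with a cluster-robust sandwich covariance on
#' the family identifier. With singleton clusters and independence working
#' correlation the coefficients reduce to ordinary least squares.
#'
#' Standardized betas are obtained by z-scoring the response and all
#' continuous predictors before fitting; binary 0/1 predictors (e.g. sex)
#' are left on their original scale. P-values are two-sided normal, and
#' Benjamini-Hochberg FDR adjustment is applied across the non-covariate
#' predictors only.
#'
#' @param data data frame; rows with missing model variables are dropped.
#' @param formula model formula, e.g. `y ~ x1 + x2 + age + sex`.
#' @param cluster name of the cluster (family) identifier column.
#' @param working working correlation structure.
#' @param covariates terms treated as covariates: excluded from the FDR
#'   family and from facet selection (default `c("age", "sex")`).
#' @param standardize z-score the response and continuous predictors
#'   (default `TRUE`).
#' @returns An object of class `twin_gee` with a coefficient table
#'   (`term`, `estimate`, `robust_se`, `statistic`, `p_raw`, `p_fdr`,
#'   `covariate`), `marginal_r2`, `n_clusters`, `n_obs`, `rho`. Supports
#'   [tidy()] and [glance()].
#' @export
clustered_regression <- function(data, formula, cluster = "family_id",
                                 working = c("exchangeable", "independence"),
                                 covariates = c("age", "sex"),
                                 standardize = TRUE) {
  working <- match.arg(working)
  vars <- all.vars(formula)
  keep <- complete.cases(data[, c(vars, cluster)])
  data <- data[keep, , drop = FALSE]
  if (standardize) {
    for (v in vars) {
      x <- data[[v]]
      if (is.numeric(x) && !all(x %in% c(0, 1)) && sd(x) > 0) {
        data[[v]] <- (x - mean(x)) / sd(x)
      }
    }
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    warn(sprintf("dropping collinear column(s): %s", paste(dropped, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  cl <- as.character(data[[cluster]])
  if (length(unique(cl)) < 2L) abort("at least 2 clusters are required")
  idx <- split(seq_along(cl), cl)
  if (max(lengths(idx)) > 2L) abort("clusters must have size 1 or 2")

  n <- length(y); k <- ncol(X)
  beta <- qr.coef(qr(X), y)
  rho <- 0
  for (iter in 1:50) {
    r <- y - drop(X %*% beta)
    sigma2 <- sum(r^2) / (n - k)
    if (working == "exchangeable") {
      num <- 0; n_pairs <- 0
      for (ix in idx) {
        if (length(ix) == 2L) {
          num <- num + r[ix[1]] * r[ix[2]]
          n_pairs <- n_pairs + 1L
        }
      }
      rho <- if (n_pairs > 0) max(-0.49, min(0.99, num / (n_pairs * sigma2))) else 0
    }
    XtWX <- matrix(0, k, k); XtWy <- rep(0, k)
    for (ix in idx) {
      Xi <- X[ix, , drop = FALSE]
      if (length(ix) == 2L && rho != 0) {
        Vi_inv <- solve(matrix(c(1, rho, rho, 1), 2))
        XtWX <- XtWX + t(Xi) %*% Vi_inv %*% Xi
        XtWy <- XtWy + t(Xi) %*% Vi_inv %*% y[ix]
      } else {
        XtWX <- XtWX + crossprod(Xi)
        XtWy <- XtWy + crossprod(Xi, y[ix])
      }
    }
    beta_new <- solve(XtWX, XtWy)
    done <- max(abs(beta_new - beta)) < 1e-10
    beta <- drop(beta_new)
    if (done || working == "independence") break
  }

  # sandwich: A^{-1} M A^{-1} with bread A = sum Xc' Vc^-1 Xc
  r <- y - drop(X %*% beta)
  A <- matrix(0, k, k); M <- matrix(0, k, k)
  for (ix in idx) {
    Xi <- X[ix, , drop = FALSE]
    Vi_inv <- if (length(ix) == 2L && rho != 0) {
      solve(matrix(c(1, rho, rho, 1), 2))
    } else diag(length(ix))
    XtV <- t(Xi) %*% Vi_inv
    A <- A + XtV %*% Xi
    u <- XtV %*% r[ix]
    M <- M + tcrossprod(u)
  }
  Ainv <- solve(A)
  V <- Ainv %*% M %*% Ainv
  se <- sqrt(diag(V))
  zstat <- beta / se
  p_raw <- 2 * pnorm(-abs(zstat))

  terms <- colnames(X)
  is_cov <- terms %in% c("(Intercept)", covariates)
  p_fdr <- rep(NA_real_, k)
  p_fdr[!is_cov] <- bh_fdr(p_raw[!is_cov])
  fitted <- drop(X %*% beta)

  structure(
    list(coefficients = tibble(term = terms, estimate = unname(beta),
                               robust_se = unname(se), statistic = unname(zstat),
                               p_raw = unname(p_raw), p_fdr = p_fdr,
                               covariate = is_cov),
         marginal_r2 = marginal_r2_values(fitted, y),
         n_clusters = length(idx), n_obs = n, rho = rho,
         working = working, fitted = fitted, y = y, formula = formula),
    class = "twin_gee"
  )
}

marginal_r2_values <- function(fitted, y) {
  if (sd(fitted) < 1e-12) {
    warn("constant fitted values; marginal R2 set to 0")
    return(0)
  }
  cor(fitted, y)^2
}

#' Marginal R-squared of a fitted association model
#'
#' Squared Pearson correlation between fitted and observed values.
#'
#' @param result a `twin_gee` fit.
#' @param y observed response; defaults to the response used in the fit.
#' @returns A number in `[0, 1]`.
#' @export
marginal_r2 <- function(result, y = NULL) {
  stopifnot(inherits(result, "twin_gee"))
  marginal_r2_values(result$fitted, y %||% result$y)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values with monotonicity
#' enforcement (wraps `stats::p.adjust(method = "BH")`).
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @returns Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Select facets for twin modeling from an association fit
#'
#' Returns the non-covariate predictors whose raw p-value falls below the
#' screening threshold, in decreasing order of `|beta|` -- the set (and
#' order) carried into the ordered Cholesky models.
#'
#' @param result a `twin_gee` fit (or its [tidy()] table).
#' @param threshold raw p-value cutoff (default 0.01).
#' @returns Character vector of facet labels (possibly empty, with a
#'   warning since downstream twin models are then skipped).
#' @export
select_facets <- function(result, threshold = 0.01) {
  tab <- if (inherits(result, "twin_gee")) result$coefficients else result
  cand <- tab[!tab$covariate & tab$term != "(Intercept)", ]
  sel <- cand[cand$p_raw < threshold, ]
  sel <- sel[order(-abs(sel$estimate)), ]
  inform(sprintf("%d of %d facets pass p < %g: %s",
                 nrow(sel), nrow(cand), threshold,
                 if (nrow(sel)) paste(sel$term, collapse = ", ") else "(none)"))
  if (nrow(sel) == 0L) warn("no facets selected; downstream twin model will be skipped")
  sel$term
}
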