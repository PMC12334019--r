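#' Fit an ACE-family biometric model by full-information maximum likelihood
#'
#' Minimizes the FIML \eqn{-2\log L} of the cohort over trait means and the
#' requested variance components, by quasi-Newton iteration from `n_starts`
#' jittered starting points. The default start splits the pooled
#' within-person sample covariance evenly among the included components.
#'
#' @param cohort twin-cohort tibble (phenotypes typically residualized and
#'   standardized beforehand; see [preprocess_cohort()]).
#' @param traits trait/column names; default all `pheno_`/`score_` columns.
#' @param components subset of `c("A", "C", "E")`; must contain `"E"`.
#'   Models including A or C require both zygosity groups among the pairs.
#' @param parameterization `"cholesky"` (components positive-semidefinite by
#'   construction) or `"direct"` (unconstrained symmetric matrices; estimates
#'   may be indefinite).
#' @param n_starts number of optimizer starts (first from the
#'   moment-based start, the rest jittered).
#' @param seed optional integer seed controlling the jitter.
#' @param include_singles include unpaired responders through their marginal
#'   likelihood (default `TRUE`).
#' @returns An object of class `biometric_fit`: a list with `params`
#'   (a [biometric_params()]), `minus2LL`, `n_params`, `aic`, `standardized`
#'   (per-trait variance shares, see [standardize_components()]),
#'   `converged`, `n_pairs_used`, `n_singles_used`, plus optimizer
#'   diagnostics. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' spec <- std_biometric_spec(a2 = 0.5)
#' sim <- simulate_twin_cohort(spec, n_mz = 300, n_dz = 150, seed = 1)
#' fit <- fit_biometric(sim, components = c("A", "E"), n_starts = 2, seed = 1)
#' glance(fit)
fit_biometric <- function(cohort, traits = NULL,
                          components = c("A", "C", "E"),
                          parameterization = c("cholesky", "direct"),
                          n_starts = 5, seed = NULL,
                          include_singles = TRUE) {
  parameterization <- match.arg(parameterization)
  components <- match.arg(components, c("A", "C", "E"), several.ok = TRUE)
  if (!"E" %in% components) abort("components must contain E")
  components <- intersect(c("A", "C", "E"), components)  # canonical order
  stats <- cohort_stats(cohort, traits, include_singles = include_singles)
  p <- stats$p
  trait_names <- sub("^(pheno|score)_", "", stats$cols)

  zyg_pairs <- unique(vapply(
    Filter(function(g) any(g$idx <= p) && any(g$idx > p), stats$groups),
    function(g) g$zygosity, character(1)))
  if (any(c("A", "C") %in% components) && length(zyg_pairs) < 2L) {
    abort("models including A or C need complete pairs of both zygosities",
          class = "twinace_error_unidentified")
  }

  fit <- fit_from_stats(stats, components, parameterization, n_starts, seed,
                        trait_names)
  fit$n_pairs_used <- stats$n_pairs_used
  fit$n_singles_used <- stats$n_singles_used
  fit$stats <- stats
  fit$traits <- trait_names
  fit$standardized <- standardize_components(fit)
  fit
}

# optimizer core, shared with profile CIs (which refit under a penalty)
fit_from_stats <- function(stats, components, parameterization, n_starts, seed,
                           trait_names, extra_obj = NULL, theta_start = NULL) {
  p <- stats$p
  q <- n_ltri(p)
  obj <- function(theta) {
    pr <- theta_to_params(theta, p, components, parameterization, trait_names)
    val <- m2ll_from_stats(stats,
                           list(MZ = expected_pair_covariance(pr, "MZ"),
                                DZ = expected_pair_covariance(pr, "DZ")),
                           rep(pr$means, 2))
    if (!is.null(extra_obj)) val <- val + extra_obj(pr)
    if (!is.finite(val)) 1e12 else val
  }

  start0 <- theta_start %||% moment_start(stats, components, parameterization)
  run_starts <- function() {
    lapply(seq_len(n_starts), function(i) {
      st <- if (i == 1L) start0 else {
        start0 * (1 + 0.1 * rnorm(length(start0))) + 0.02 * rnorm(length(start0))
      }
      ans <- nlminb(st, obj, control = list(iter.max = 1000, eval.max = 4000))
      list(par = ans$par, value = ans$objective, code = ans$convergence)
    })
  }
  runs <- if (is.null(seed)) run_starts() else withr::with_seed(seed, run_starts())
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  spread <- if (length(vals) >= 2L) diff(sort(vals))[1] else 0
  g <- pracma::grad(obj, best$par, heps = 1e-6)
  rel_grad <- max(abs(g)) / max(1, abs(best$value))

  params <- theta_to_params(best$par, p, components, parameterization, trait_names)
  n_params <- p + length(components) * q
  structure(
    list(params = params, theta = best$par,
         minus2LL = best$value, n_params = n_params,
         aic = best$value + 2 * n_params,
         components = components, parameterization = parameterization,
         converged = best$code == 0 && spread < 0.01 && rel_grad < 1e-4,
         start_values = vals, rel_grad = rel_grad,
         objective = obj),
    class = "biometric_fit"
  )
}

# start: E gets half the pooled within-person covariance, the other included
# components split the rest evenly; means start at the observed means
moment_start <- function(stats, components, parameterization) {
  p <- stats$p
  # pooled within-person mean and covariance from group stats
  num <- matrix(0, p, p); mu <- rep(0, p); n_tot <- rep(0, p)
  for (g in stats$groups) {
    for (half in list(which(g$idx <= p), which(g$idx > p))) {
      if (length(half) == 0) next
      tr <- ifelse(g$idx[half] > p, g$idx[half] - p, g$idx[half])
      mu[tr] <- mu[tr] + g$n * g$mean[half]
      n_tot[tr] <- n_tot[tr] + g$n
      num[tr, tr] <- num[tr, tr] + g$n *
        (g$scatter[half, half, drop = FALSE] + tcrossprod(g$mean[half]))
    }
  }
  mu <- mu / pmax(n_tot, 1)
  S <- num / pmax(outer(n_tot, n_tot, pmin), 1) - tcrossprod(mu)
  S <- (S + t(S)) / 2 + diag(1e-6, p)
  n_comp <- length(components)
  w <- if (n_comp == 1L) 1 else {
    setNames(rep((1 - 0.5) / (n_comp - 1), n_comp), components)
  }
  if (n_comp > 1L) w["E"] <- 0.5
  ix <- lower.tri(diag(p), diag = TRUE)
  blocks <- lapply(components, function(k) {
    Sk <- S * if (n_comp == 1L) 1 else w[[k]]
    if (parameterization == "cholesky") t(chol(Sk))[ix] else Sk[ix]
  })
  c(mu, unlist(blocks))
}

#' Standardized variance components of a fitted model
#'
#' Per-trait shares `X_tt / (A_tt + C_tt + E_tt)` for each included
#' component. For a direct-parameterization fit the possibly indefinite
#' estimates are used as-is (with a warning when a diagonal is negative).
#'
#' @param fit a `biometric_fit`.
#' @returns A tibble with columns `trait`, and `a2`/`c2`/`e2` for the
#'   included components.
#' @export
standardize_components <- function(fit) {
  pr <- fit$params
  tot <- diag(pr$A) + diag(pr$C) + diag(pr$E)
  if (any(tot <= 0)) abort("nonpositive total variance; cannot standardize")
  if (any(c(diag(pr$A), diag(pr$C), diag(pr$E)) < -1e-8)) {
    warn("negative component variance estimate; standardized shares computed as-is")
  }
  out <- tibble(trait = pr$trait_names)
  for (k in fit$components) {
    out[[paste0(tolower(k), "2")]] <- diag(pr[[k]]) / tot
  }
  out
}

#' Likelihood-ratio comparison of nested biometric models
#'
#' `delta_minus2LL = nested$minus2LL - full$minus2LL` is referred to a
#' chi-square distribution with `delta_df` degrees of freedom; small
#' negative differences (optimizer noise) are clipped to zero with a
#' warning. The nested model is preferred when the test is non-significant.
#'
#' @param full,nested `biometric_fit` objects fitted to the same cohort,
#'   with `nested$n_params < full$n_params`.
#' @param alpha significance level for the preference rule (default 0.05).
#' @returns A one-row tibble: `delta_minus2LL`, `delta_df`, `p_value`,
#'   `delta_aic` (nested minus full), `preferred`.
#' @export
compare_models <- function(full, nested, alpha = 0.05) {
  if (!identical(full$stats$fingerprint, nested$stats$fingerprint)) {
    abort("models were fitted to different cohorts")
  }
  if (nested$n_params >= full$n_params) {
    abort("`nested` must have fewer parameters than `full`")
  }
  d <- nested$minus2LL - full$minus2LL
  if (d < 0) {
    if (d < -0.01) warn(sprintf("nested model fit better by %.4f in -2LL; clipping to 0", -d))
    d <- 0
  }
  ddf <- full$n_params - nested$n_params
  pv <- pchisq(d, df = ddf, lower.tail = FALSE)
  lab <- function(f) paste(f$components, collapse = "")
  d_aic <- nested$aic - full$aic
  lab_full <- lab(full); lab_nested <- lab(nested)
  tibble(full = lab_full, nested = lab_nested,
         delta_minus2LL = d, delta_df = ddf, p_value = pv,
         delta_aic = d_aic,
         preferred = if (pv >= alpha) lab_nested else lab_full)
}

# ---- profile-likelihood confidence intervals ---------------------------

# Build the scalar function of a parameter set referenced by `quantity`.
# Accepted forms: a function(params) -> scalar, or strings
#   "a2:<trait>", "c2:<trait>", "e2:<trait>"  standardized shares
#   "rA:<t1>:<t2>", "rC:...", "rE:..."        component correlations
quantity_fun <- function(fit, quantity) {
  if (is.function(quantity)) return(quantity)
  parts <- strsplit(quantity, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  tr_id <- function(x) {
    i <- match(x, fit$params$trait_names)
    if (is.na(i)) abort(sprintf("unknown trait `%s`", x))
    i
  }
  if (kind %in% c("a2", "c2", "e2")) {
    i <- if (length(parts) > 1) tr_id(parts[2]) else 1L
    comp <- toupper(substr(kind, 1, 1))
    function(pr) pr[[comp]][i, i] / (pr$A[i, i] + pr$C[i, i] + pr$E[i, i])
  } else if (kind %in% c("rA", "rC", "rE")) {
    i <- tr_id(parts[2]); j <- tr_id(parts[3])
    comp <- substr(kind, 2, 2)
    function(pr) {
      m <- pr[[comp]]
      denom <- m[i, i] * m[j, j]
      if (denom <= 0) return(NA_real_)
      m[i, j] / sqrt(denom)
    }
  } else {
    abort(sprintf("unknown quantity `%s`", quantity))
  }
}

#' Profile-likelihood confidence interval for a model quantity
#'
#' Likelihood-based bounds: the values of the target quantity at which the
#' re-optimized \eqn{-2\log L} (all other parameters free) rises by the
#' chi-square(1) critical value above its minimum, located by root-finding
#' to a tolerance of 1e-4 on the quantity scale. The constrained
#' re-optimization uses an escalated quadratic penalty on the quantity.
#' Falls back to a Wald interval (numeric Hessian + delta method) when
#' profiling fails, and flags bounds that run out of the feasible window.
#'
#' @param fit a converged `biometric_fit`.
#' @param quantity a string such as `"a2:trait1"` or `"rA:t1:t2"` (see
#'   Details) or a function of the parameter set.
#' @param level confidence level (default 0.95).
#' @param bound_window half-width of the search window around the estimate,
#'   in Wald-SE units (default 8).
#' @returns A one-row tibble: `estimate`, `lower`, `upper`, `method`
#'   (`"profile"` or `"wald"`), `lower_open`, `upper_open`.
#' @export
profile_ci <- function(fit, quantity, level = 0.95, bound_window = 8) {
  if (!isTRUE(fit$converged)) {
    warn("profiling a fit that did not meet the convergence criteria")
  }
  qf <- quantity_fun(fit, quantity)
  qhat <- qf(fit$params)
  crit <- qchisq(level, df = 1)
  f_min <- fit$minus2LL
  p <- length(fit$params$means)

  # Wald scale for stepping (and as fallback)
  wald <- tryCatch(wald_ci(fit, qf, level), error = function(e) NULL)
  se <- if (!is.null(wald) && is.finite(wald$se) && wald$se > 0) wald$se else
    max(0.1, abs(qhat) * 0.25)

  prof <- function(v, theta_init) {
    # escalate the penalty weight; keep the tightest solution
    th <- theta_init
    ans <- NULL
    for (w in c(1e5, 1e7)) {
      pen <- function(pr) {
        qv <- qf(pr)
        if (!is.finite(qv)) return(1e8)
        w * (qv - v)^2
      }
      sub <- fit_from_stats(fit$stats, fit$components, fit$parameterization,
                            n_starts = 1, seed = NULL,
                            trait_names = fit$params$trait_names,
                            extra_obj = pen, theta_start = th)
      th <- sub$theta
      ans <- sub
    }
    pr <- ans$params
    list(theta = th,
         m2ll = m2ll_from_stats(fit$stats,
                                list(MZ = expected_pair_covariance(pr, "MZ"),
                                     DZ = expected_pair_covariance(pr, "DZ")),
                                rep(pr$means, 2)))
  }

  one_side <- function(dir) {
    th <- fit$theta
    step <- 0.5 * se * dir
    v_in <- qhat; f_in <- f_min
    v_out <- NULL
    for (i in 1:24) {
      v_try <- qhat + i * step
      if (abs(v_try - qhat) > bound_window * se) break
      pr <- prof(v_try, th)
      th <- pr$theta
      if (pr$m2ll - f_min >= crit) { v_out <- v_try; break }
      v_in <- v_try; f_in <- pr$m2ll
    }
    if (is.null(v_out)) return(list(bound = qhat + dir * bound_window * se, open = TRUE))
    root <- tryCatch(
      uniroot(function(v) prof(v, th)$m2ll - f_min - crit,
              interval = sort(c(v_in, v_out)), tol = 1e-4)$root,
      error = function(e) NULL)
    if (is.null(root)) list(bound = v_out, open = FALSE)
    else list(bound = root, open = FALSE)
  }

  res <- tryCatch({
    lo <- one_side(-1); hi <- one_side(1)
    tibble(estimate = qhat, lower = lo$bound, upper = hi$bound,
           method = "profile", lower_open = lo$open, upper_open = hi$open)
  }, error = function(e) NULL)
  if (is.null(res)) {
    if (is.null(wald)) abort("both profile and Wald intervals failed")
    res <- tibble(estimate = qhat, lower = wald$lower, upper = wald$upper,
                  method = "wald", lower_open = FALSE, upper_open = FALSE)
  }
  res
}

# Wald interval via numeric Hessian of -2LL and the delta method
wald_ci <- function(fit, qf, level = 0.95) {
  obj <- fit$objective
  H <- pracma::hessian(obj, fit$theta)
  # Var(theta) = 2 * H^{-1} for H the Hessian of -2LL
  V <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) NULL)
  if (is.null(V)) abort("singular Hessian")
  p <- length(fit$params$means)
  qtheta <- function(th) {
    qf(theta_to_params(th, p, fit$components, fit$parameterization,
                       fit$params$trait_names))
  }
  g <- pracma::grad(qtheta, fit$theta)
  se <- sqrt(max(0, drop(t(g) %*% V %*% g)))
  z <- qnorm(1 - (1 - level) / 2)
  qhat <- qtheta(fit$theta)
  list(lower = qhat - z * se, upper = qhat + z * se, se = se)
}
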