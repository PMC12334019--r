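#' Biometric parameter set
#'
#' Holds the component covariance contributions of an ACE-family model plus
#' trait means. Under `parameterization = "cholesky"` each component is
#' `L %*% t(L)` of a lower-triangular path matrix and is positive
#' semidefinite by construction; under `"direct"` the symmetric matrices are
#' taken as-is and may be indefinite (the direct variance approach leaves
#' estimates unconstrained).
#'
#' @param A,C,E symmetric `p x p` component matrices (omit a component by
#'   leaving it `NULL`; E is required).
#' @param means numeric vector of trait means.
#' @param parameterization `"direct"` or `"cholesky"`.
#' @param trait_names optional labels.
#' @returns A `biometric_params` list with elements `A`, `C`, `E` (missing
#'   components are zero matrices), `include`, `means`, `parameterization`.
#' @export
biometric_params <- function(A = NULL, C = NULL, E, means,
                             parameterization = c("direct", "cholesky"),
                             trait_names = NULL) {
  parameterization <- match.arg(parameterization)
  p <- length(means)
  as_comp <- function(m) {
    if (is.null(m)) return(matrix(0, p, p))
    if (is.null(dim(m)) && length(m) == 1L) m <- diag(m, p, p)
    m <- as.matrix(m)
    stopifnot(all(dim(m) == c(p, p)))
    (m + t(m)) / 2
  }
  include <- c("A", "C", "E")[!c(is.null(A), is.null(C), FALSE)]
  trait_names <- trait_names %||% paste0("trait", seq_len(p))
  structure(
    list(A = as_comp(A), C = as_comp(C), E = as_comp(E),
         include = include, means = setNames(as.numeric(means), trait_names),
         parameterization = parameterization, trait_names = trait_names),
    class = "biometric_params"
  )
}

#' Expected twin-pair covariance structure
#'
#' The stacked (twin 1, twin 2) covariance implied by an ACE-family model:
#' within-twin block `A + C + E`, cross-twin block `A + C` for MZ pairs and
#' `0.5 * A + C` for DZ pairs.
#'
#' @param params a `biometric_params` object (or a fitted model's `$params`).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @returns A symmetric `2p x 2p` matrix.
#' @export
#' @examples
#' pr <- biometric_params(A = 0.5, E = 0.5, means = 0)
#' expected_pair_covariance(pr, "MZ")
expected_pair_covariance <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  within <- params$A + params$C + params$E
  cross <- if (zygosity == "MZ") params$A + params$C else 0.5 * params$A + params$C
  rbind(cbind(within, cross), cbind(t(cross), within))
}

# ---- sufficient statistics ---------------------------------------------

# Resolve trait specifiers to phenotype column names in the cohort.
resolve_traits <- function(cohort, traits = NULL) {
  if (is.null(traits)) {
    traits <- grep("^(pheno|score)_", names(cohort), value = TRUE)
    if (length(traits) == 0L) abort("no pheno_/score_ columns found in cohort")
    return(traits)
  }
  vapply(traits, function(tr) {
    for (cand in c(tr, paste0("score_", tr), paste0("pheno_", tr))) {
      if (cand %in% names(cohort)) return(cand)
    }
    abort(sprintf("trait `%s` not found in cohort", tr))
  }, character(1), USE.NAMES = FALSE)
}

# Group the cohort by (zygosity, missingness pattern) and compute the
# sufficient statistics used by the grouped FIML evaluation: per group the
# count, the mean of the observed 2p-subvector, and the ML scatter matrix
# about that mean. Results are identical to record-wise evaluation.
cohort_stats <- function(cohort, traits = NULL, include_singles = TRUE) {
  cols <- resolve_traits(cohort, traits)
  p <- length(cols)
  wide <- cohort |>
    dplyr::select(dplyr::all_of(c("family_id", "zygosity", "twin_order", cols))) |>
    tidyr::pivot_wider(names_from = "twin_order", values_from = dplyr::all_of(cols),
                       names_glue = "{.value}@{twin_order}")
  # stack columns in (twin1 traits, twin2 traits) order
  y <- matrix(NA_real_, nrow(wide), 2 * p)
  for (j in seq_len(p)) {
    c1 <- paste0(cols[j], "@1"); c2 <- paste0(cols[j], "@2")
    if (c1 %in% names(wide)) y[, j] <- wide[[c1]]
    if (c2 %in% names(wide)) y[, p + j] <- wide[[c2]]
  }
  obs <- !is.na(y)
  is_pair <- rowSums(obs[, seq_len(p), drop = FALSE]) > 0 &
    rowSums(obs[, p + seq_len(p), drop = FALSE]) > 0
  if (!include_singles) {
    keep <- is_pair
    y <- y[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
    wide <- wide[keep, ]; is_pair <- is_pair[keep]
  }
  keep <- rowSums(obs) > 0
  y <- y[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
  zyg <- wide$zygosity[keep]; is_pair <- is_pair[keep]

  key <- paste(zyg, apply(obs, 1, function(o) paste(which(o), collapse = ",")))
  groups <- lapply(split(seq_along(key), key), function(ix) {
    idx <- which(obs[ix[1], ])
    yy <- y[ix, idx, drop = FALSE]
    m <- colMeans(yy)
    ctr <- sweep(yy, 2, m)
    list(n = length(ix), idx = idx, zygosity = zyg[ix[1]],
         mean = m, scatter = crossprod(ctr) / length(ix))
  })
  list(groups = groups, p = p, cols = cols,
       n_pairs_used = sum(is_pair), n_singles_used = sum(!is_pair),
       fingerprint = paste(length(key), p,
                           format(sum(y[obs]), digits = 12),
                           format(sum(y[obs]^2), digits = 12)))
}

# -2 log likelihood from grouped sufficient statistics; `sig` is a list with
# MZ and DZ 2p x 2p implied covariances, `mu` the stacked 2p mean vector
# (or a list with per-zygosity mean vectors, for saturated-family models).
m2ll_from_stats <- function(stats, sig, mu, penalty = 1e12) {
  total <- 0
  per_zyg_mu <- is.list(mu)
  for (g in stats$groups) {
    mu_g <- if (per_zyg_mu) mu[[g$zygosity]] else mu
    S <- sig[[g$zygosity]][g$idx, g$idx, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(penalty)
    k <- length(g$idx)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv_scatter <- chol2inv(ch) %*% g$scatter
    d <- g$mean - mu_g[g$idx]
    qf <- sum(backsolve(ch, d, transpose = TRUE)^2)
    total <- total + g$n * (k * log(2 * pi) + logdet + sum(diag(Sinv_scatter)) + qf)
  }
  total
}

#' Full-information -2 log-likelihood of a twin cohort
#'
#' Evaluates minus twice the multivariate-normal log-likelihood of the
#' cohort under the pair covariance structure implied by `params`. Complete
#' pairs use the `2p x 2p` structure for their zygosity, unpaired responders
#' the `p x p` marginal; record-level missing entries drop the corresponding
#' rows and columns of the mean and covariance. Internally, records sharing
#' a missingness pattern are pooled through sufficient statistics, with
#' results identical to record-wise evaluation.
#'
#' @param params a [biometric_params()] object.
#' @param cohort twin-cohort tibble.
#' @param traits trait/column names; default all `pheno_`/`score_` columns
#'   (must match `length(params$means)`).
#' @returns A single number; if the implied covariance is singular a large
#'   penalized value is returned (no error).
#' @export
fiml_minus2ll <- function(params, cohort, traits = NULL) {
  stats <- cohort_stats(cohort, traits)
  if (stats$p != length(params$means)) {
    abort("number of traits in cohort does not match params")
  }
  sig <- list(MZ = expected_pair_covariance(params, "MZ"),
              DZ = expected_pair_covariance(params, "DZ"))
  m2ll_from_stats(stats, sig, rep(params$means, 2))
}

# ---- parameter vector packing ------------------------------------------

n_ltri <- function(p) p * (p + 1) / 2

ltri_fill <- function(v, p) {
  m <- matrix(0, p, p)
  m[lower.tri(m, diag = TRUE)] <- v
  m
}

sym_fill <- function(v, p) {
  m <- ltri_fill(v, p)
  m + t(m) - diag(diag(m), p, p)
}

# theta layout: [means (p)] [component blocks, in `include` order]
theta_to_params <- function(theta, p, include, parameterization, trait_names) {
  q <- n_ltri(p)
  means <- theta[seq_len(p)]
  off <- p
  comps <- list(A = NULL, C = NULL, E = NULL)
  for (k in include) {
    v <- theta[off + seq_len(q)]
    off <- off + q
    comps[[k]] <- if (parameterization == "cholesky") {
      L <- ltri_fill(v, p)
      tcrossprod(L)
    } else sym_fill(v, p)
  }
  pr <- biometric_params(A = comps$A, C = comps$C, E = comps$E, means = means,
                         parameterization = parameterization,
                         trait_names = trait_names)
  pr$include <- include
  pr
}

params_to_theta <- function(params) {
  p <- length(params$means)
  ix <- lower.tri(diag(p), diag = TRUE)
  blocks <- lapply(params$include, function(k) {
    m <- params[[k]]
    if (params$parameterization == "cholesky") {
      L <- t(chol(m + diag(1e-10, p)))
      L[ix]
    } else m[ix]
  })
  c(as.numeric(params$means), unlist(blocks))
}
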