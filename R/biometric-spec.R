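#' Biometric generating specification for twin simulation
#'
#' A `biometric_spec` bundles everything needed to generate multivariate twin
#' phenotypes under the classical twin design: per-trait means and age/sex
#' effects, and the additive-genetic (A), shared-environment (C) and
#' unique-environment (E) covariance contributions. Co-twins correlate 1.0
#' (MZ) or 0.5 (DZ) on the genetic latents, share the C latents, and have
#' independent E latents.
#'
#' @param A,C,E symmetric positive-semidefinite `p x p` covariance
#'   contributions. Scalars are promoted to `diag(x, p)`.
#' @param means numeric vector of trait means (length `p`).
#' @param beta_age,beta_sex numeric vectors of per-trait fixed effects of age
#'   (per year) and sex (coded 0/1); default 0.
#' @param trait_names optional character vector of trait labels.
#' @returns An object of class `biometric_spec` with elements `A`, `C`, `E`,
#'   `means`, `beta_age`, `beta_sex`, `trait_names`, `n_traits` and a
#'   `standardized` flag (`TRUE` when `diag(A + C + E) == 1`).
#' @seealso [std_biometric_spec()] for building a spec from standardized
#'   variance shares and component correlations, [simulate_twin_cohort()].
#' @export
#' @examples
#' spec <- biometric_spec(A = 0.5, C = 0, E = 0.5, means = 0)
#' spec$standardized
biometric_spec <- function(A, C, E, means,
                           beta_age = NULL, beta_sex = NULL,
                           trait_names = NULL) {
  p <- length(means)
  expand <- function(m, label) {
    if (is.null(dim(m)) && length(m) == 1L) m <- diag(m, p, p)
    m <- as.matrix(m)
    if (!all(dim(m) == c(p, p))) {
      abort(sprintf("component %s must be %d x %d", label, p, p))
    }
    if (max(abs(m - t(m))) > 1e-8) {
      abort(sprintf("component %s is not symmetric", label))
    }
    ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      abort(sprintf("component %s is not positive-semidefinite (min eigenvalue %.3g)",
                    label, min(ev)),
            class = "twinace_error_nonpsd")
    }
    (m + t(m)) / 2
  }
  A <- expand(A, "A"); C <- expand(C, "C"); E <- expand(E, "E")
  total <- A + C + E
  ev <- eigen(total, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort("total covariance A + C + E must be positive-definite")
  }
  beta_age <- beta_age %||% rep(0, p)
  beta_sex <- beta_sex %||% rep(0, p)
  stopifnot(length(beta_age) == p, length(beta_sex) == p)
  trait_names <- trait_names %||% paste0("trait", seq_len(p))
  stopifnot(length(trait_names) == p)
  dimnames(A) <- dimnames(C) <- dimnames(E) <- list(trait_names, trait_names)
  structure(
    list(A = A, C = C, E = E,
         means = setNames(as.numeric(means), trait_names),
         beta_age = setNames(as.numeric(beta_age), trait_names),
         beta_sex = setNames(as.numeric(beta_sex), trait_names),
         trait_names = trait_names, n_traits = p,
         standardized = max(abs(diag(total) - 1)) <= 1e-10),
    class = "biometric_spec"
  )
}

#' Build a standardized biometric spec from variance shares and correlations
#'
#' Convenience constructor for simulation studies specified on the
#' standardized scale: per-trait variance shares `a2`, `c2`, `e2`
#' (`e2 = 1 - a2 - c2`) and component correlation matrices. Component
#' covariances are `sqrt(share_i) * r_ij * sqrt(share_j)`, so the total
#' phenotypic variance of every trait is 1.
#'
#' @param a2,c2 numeric vectors of standardized additive-genetic and
#'   shared-environment variance shares per trait (`c2` defaults to 0).
#' @param rA,rC,rE component correlation matrices (default identity).
#' @inheritParams biometric_spec
#' @returns A [biometric_spec()].
#' @export
#' @examples
#' # bivariate: heritabilities 0.5 / 0.4, genetic correlation 0.85
#' std_biometric_spec(a2 = c(0.5, 0.4), rA = matrix(c(1, .85, .85, 1), 2))
std_biometric_spec <- function(a2, c2 = NULL, rA = NULL, rC = NULL, rE = NULL,
                               means = NULL, beta_age = NULL, beta_sex = NULL,
                               trait_names = NULL) {
  p <- length(a2)
  c2 <- c2 %||% rep(0, p)
  e2 <- 1 - a2 - c2
  if (any(a2 < 0) || any(c2 < 0) || any(e2 <= 0)) {
    abort("variance shares must satisfy a2 >= 0, c2 >= 0, a2 + c2 < 1")
  }
  comp <- function(share, r) {
    r <- r %||% diag(p)
    s <- sqrt(share)
    outer(s, s) * as.matrix(r)
  }
  biometric_spec(A = comp(a2, rA), C = comp(c2, rC), E = comp(e2, rE),
                 means = means %||% rep(0, p),
                 beta_age = beta_age, beta_sex = beta_sex,
                 trait_names = trait_names)
}

#' Default generating values for the four music-use-motivation dimensions
#'
#' Returns the standardized four-variate AE generating structure used
#' throughout the package's simulation studies of music-use motivation
#' (transcendence, emotion regulation, social bonding, identity/expression):
#' heritabilities 0.50, 0.40, 0.38, 0.52 with unique-environment complements,
#' and the genetic and unique-environment correlation matrices estimated for
#' these dimensions in adult twin data.
#'
#' @param traits character subset of `c("MM-T", "MM-E", "MM-S", "MM-I")`.
#' @returns A [biometric_spec()] restricted to `traits`.
#' @export
#' @examples
#' mm_motivation_spec(c("MM-T", "MM-E"))
mm_motivation_spec <- function(traits = c("MM-T", "MM-E", "MM-S", "MM-I")) {
  all_tr <- c("MM-T", "MM-E", "MM-S", "MM-I")
  traits <- match.arg(traits, all_tr, several.ok = TRUE)
  a2 <- c(`MM-T` = 0.50, `MM-E` = 0.40, `MM-S` = 0.38, `MM-I` = 0.52)
  rA <- matrix(c(1.00, 0.85, 0.80, 0.90,
                 0.85, 1.00, 0.75, 0.80,
                 0.80, 0.75, 1.00, 0.71,
                 0.90, 0.80, 0.71, 1.00), 4, 4, dimnames = list(all_tr, all_tr))
  rE <- matrix(c(1.00, 0.75, 0.59, 0.69,
                 0.75, 1.00, 0.48, 0.54,
                 0.59, 0.48, 1.00, 0.55,
                 0.69, 0.54, 0.55, 1.00), 4, 4, dimnames = list(all_tr, all_tr))
  idx <- match(traits, all_tr)
  std_biometric_spec(a2 = a2[idx],
                     rA = rA[idx, idx, drop = FALSE],
                     rE = rE[idx, idx, drop = FALSE],
                     trait_names = traits)
}

#' @export
print.biometric_spec <- function(x, ...) {
  cat(sprintf("<biometric_spec> %d trait(s)%s\n", x$n_traits,
              if (x$standardized) ", standardized" else ""))
  shares <- vapply(c("A", "C", "E"), function(k) diag(x[[k]]), numeric(x$n_traits))
  shares <- as.matrix(shares)
  if (x$n_traits == 1L) shares <- t(shares)
  tot <- rowSums(shares)
  cat("variance shares:\n")
  print(round(shares / tot, 3))
  invisible(x)
}
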