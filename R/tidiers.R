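#' Tidy a biometric model fit
#'
#' One row per trait x component with the standardized variance share; with
#' `conf.int = TRUE`, 95% profile-likelihood bounds are added (slow).
#'
#' @param x a `biometric_fit`.
#' @param conf.int add profile-likelihood confidence bounds.
#' @param conf.level confidence level.
#' @param ... unused.
#' @returns A tibble with columns `trait`, `component`, `estimate` (and
#'   `conf.low`, `conf.high` when requested).
#' @method tidy biometric_fit
#' @export
tidy.biometric_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  rows <- tidyr::pivot_longer(x$standardized, -"trait",
                              names_to = "component", values_to = "estimate")
  if (conf.int) {
    ci <- purrr::pmap(rows, function(trait, component, estimate) {
      profile_ci(x, paste0(component, ":", trait), level = conf.level)
    })
    rows$conf.low <- vapply(ci, function(z) z$lower, numeric(1))
    rows$conf.high <- vapply(ci, function(z) z$upper, numeric(1))
  }
  rows
}

#' Glance at a biometric model fit
#'
#' @param x a `biometric_fit`.
#' @param ... unused.
#' @returns A one-row tibble: `model`, `minus2LL`, `n_params`, `AIC`,
#'   `converged`, `n_pairs_used`, `n_singles_used`.
#' @method glance biometric_fit
#' @export
glance.biometric_fit <- function(x, ...) {
  tibble(model = paste(x$components, collapse = ""),
         minus2LL = x$minus2LL, n_params = x$n_params, AIC = x$aic,
         converged = x$converged,
         n_pairs_used = x$n_pairs_used %||% NA_integer_,
         n_singles_used = x$n_singles_used %||% NA_integer_)
}

#' @export
print.biometric_fit <- function(x, ...) {
  cat(sprintf("<biometric_fit> %s model (%s), %d trait(s)\n",
              paste(x$components, collapse = ""), x$parameterization,
              length(x$params$trait_names)))
  cat(sprintf("  -2LL = %.3f  AIC = %.3f  converged: %s\n",
              x$minus2LL, x$aic, x$converged))
  print(x$standardized)
  invisible(x)
}

#' Stacked variance-share plot of a biometric fit
#'
#' @param object a `biometric_fit`.
#' @param ... unused.
#' @returns A ggplot: standardized a2/c2/e2 shares stacked per trait.
#' @method autoplot biometric_fit
#' @export
autoplot.biometric_fit <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(toupper(substr(d$component, 1, 1)), c("E", "C", "A"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$estimate,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(A = "#2166ac", C = "#92c5de",
                                          E = "#d6604d")) +
    ggplot2::labs(x = NULL, y = "standardized variance share",
                  fill = "component") +
    ggplot2::theme_minimal()
}

#' @method tidy twin_gee
#' @export
tidy.twin_gee <- function(x, ...) x$coefficients

#' @method glance twin_gee
#' @export
glance.twin_gee <- function(x, ...) {
  tibble(marginal_r2 = x$marginal_r2, n_obs = x$n_obs,
         n_clusters = x$n_clusters, working = x$working, rho = x$rho)
}

#' @export
print.twin_gee <- function(x, ...) {
  cat(sprintf("<twin_gee> %s working correlation (rho = %.3f), %d obs in %d clusters\n",
              x$working, x$rho, x$n_obs, x$n_clusters))
  cat(sprintf("  marginal R2 = %.3f\n", x$marginal_r2))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Coefficient plot for a cluster-robust association fit
#'
#' @param object a `twin_gee`.
#' @param ... unused.
#' @returns A ggplot of standardized betas with 95% robust intervals.
#' @method autoplot twin_gee
#' @export
autoplot.twin_gee <- function(object, ...) {
  d <- object$coefficients
  d <- d[d$term != "(Intercept)", ]
  d$term <- stats::reorder(d$term, abs(d$estimate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$robust_se,
      xmax = .data$estimate + 1.96 * .data$robust_se)) +
    ggplot2::labs(x = "standardized beta (95% robust CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method tidy cholesky_decomposition
#' @export
tidy.cholesky_decomposition <- function(x, ...) {
  comps <- intersect(c("a", "e"), substr(tolower(x$fit$components), 1, 1))
  dplyr::bind_rows(lapply(comps, function(k) {
    tot <- x[[paste0("target_", k, "2")]]
    sh <- x[[paste0("shared_", k, "_fraction")]]
    tibble(component = toupper(k), target_share = tot,
           shared_fraction = sh, unique_fraction = 1 - sh)
  }))
}

#' Shared-versus-unique variance plot for an ordered Cholesky decomposition
#'
#' @param object a `cholesky_decomposition`.
#' @param ... unused.
#' @returns A ggplot: the target's genetic and environmental variance split
#'   into predecessor-shared and unique parts.
#' @method autoplot cholesky_decomposition
#' @export
autoplot.cholesky_decomposition <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(d, c("shared_fraction", "unique_fraction"),
                           names_to = "part", values_to = "fraction")
  d$part <- ifelse(d$part == "shared_fraction", "shared with predecessors",
                   "unique")
  d$variance <- d$fraction * d$target_share
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$variance,
                                  fill = .data$part)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of total phenotypic variance",
                  fill = NULL,
                  title = paste0("variance decomposition: ", object$target)) +
    ggplot2::theme_minimal()
}
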