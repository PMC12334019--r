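#' Simulate a twin cohort with known biometric structure
#'
#' Generates same-sex MZ/DZ twin pairs plus unpaired responders under the
#' classical twin design. Additive-genetic latents of co-twins correlate 1.0
#' (MZ) or 0.5 (DZ), shared-environment latents are identical within a pair,
#' and unique-environment latents are independent; each latent block is
#' coloured by the matrix square root of the corresponding component of
#' `spec`. Phenotype = mean + beta_age * age + beta_sex * sex + a + c + e.
#' Co-twins share age and sex (same-sex pairs only).
#'
#' The genetic latents use the pair-factor construction
#' `g_i = sqrt(rho) * g_pair + sqrt(1 - rho) * g_own` with `rho = 1` (MZ) or
#' `0.5` (DZ), which reproduces the required cross-twin correlation for any
#' positive-semidefinite A.
#'
#' @param spec a [biometric_spec()].
#' @param n_mz,n_dz numbers of complete MZ and DZ pairs.
#' @param n_singles number of unpaired responders, drawn from the marginal
#'   (within-person) distribution; zygosity labels assigned in proportion to
#'   `n_mz : n_dz`.
#' @param age_range numeric length-2; ages drawn uniformly per family.
#' @param sex_ratio probability that a family is female (`sex = 1`).
#' @param seed optional integer; when supplied the cohort is a deterministic
#'   function of it and the global RNG state is left untouched.
#' @returns A tibble with columns `family_id`, `zygosity` (`"MZ"`/`"DZ"`),
#'   `twin_order` (1/2), `sex` (0/1), `age`, and one `pheno_<trait>` column
#'   per trait. The generating `spec` and `seed` are attached as attributes
#'   `"spec"` and `"seed"`.
#' @export
#' @examples
#' spec <- std_biometric_spec(a2 = 0.5)
#' sim <- simulate_twin_cohort(spec, n_mz = 100, n_dz = 50, seed = 1)
#' dplyr::count(sim, zygosity, twin_order)
simulate_twin_cohort <- function(spec, n_mz, n_dz, n_singles = 0,
                                 age_range = c(31, 55), sex_ratio = 0.66,
                                 seed = NULL) {
  stopifnot(inherits(spec, "biometric_spec"))
  if (any(c(n_mz, n_dz, n_singles) < 0) ||
      any(c(n_mz, n_dz, n_singles) != round(c(n_mz, n_dz, n_singles)))) {
    abort("n_mz, n_dz and n_singles must be nonnegative integers")
  }
  run <- function() {
    p <- spec$n_traits
    rA <- mat_sqrt(spec$A); rC <- mat_sqrt(spec$C); rE <- mat_sqrt(spec$E)

    gen_pairs <- function(n, rho, zyg, id0) {
      if (n == 0L) return(NULL)
      g_pair <- matrix(rnorm(n * p), n, p)
      g1 <- sqrt(rho) * g_pair + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
      g2 <- sqrt(rho) * g_pair + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
      cc <- matrix(rnorm(n * p), n, p) %*% rC
      a1 <- g1 %*% rA; a2 <- g2 %*% rA
      e1 <- matrix(rnorm(n * p), n, p) %*% rE
      e2 <- matrix(rnorm(n * p), n, p) %*% rE
      age <- runif(n, age_range[1], age_range[2])
      sex <- rbinom(n, 1, sex_ratio)
      fixed <- tcrossprod(rep(1, n), spec$means) +
        outer(age, spec$beta_age) + outer(sex, spec$beta_sex)
      mk <- function(ord, y) {
        out <- tibble(
          family_id = sprintf("%s%05d", tolower(zyg), id0 + seq_len(n)),
          zygosity = zyg, twin_order = ord, sex = sex, age = age
        )
        colnames(y) <- paste0("pheno_", spec$trait_names)
        dplyr::bind_cols(out, as_tibble(y))
      }
      dplyr::bind_rows(mk(1L, fixed + a1 + cc + e1),
                       mk(2L, fixed + a2 + cc + e2))
    }

    gen_singles <- function(n) {
      if (n == 0L) return(NULL)
      zyg <- if (n_mz + n_dz > 0) {
        ifelse(runif(n) < n_mz / (n_mz + n_dz), "MZ", "DZ")
      } else rep("MZ", n)
      age <- runif(n, age_range[1], age_range[2])
      sex <- rbinom(n, 1, sex_ratio)
      y <- tcrossprod(rep(1, n), spec$means) +
        outer(age, spec$beta_age) + outer(sex, spec$beta_sex) +
        matrix(rnorm(n * p), n, p) %*% rA +
        matrix(rnorm(n * p), n, p) %*% rC +
        matrix(rnorm(n * p), n, p) %*% rE
      colnames(y) <- paste0("pheno_", spec$trait_names)
      dplyr::bind_cols(
        tibble(family_id = sprintf("sgl%05d", seq_len(n)), zygosity = zyg,
               twin_order = 1L, sex = sex, age = age),
        as_tibble(y)
      )
    }

    out <- dplyr::bind_rows(gen_pairs(n_mz, 1.0, "MZ", 0L),
                            gen_pairs(n_dz, 0.5, "DZ", n_mz),
                            gen_singles(n_singles))
    dplyr::arrange(out, .data$family_id, .data$twin_order)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}

# symmetric PSD square root (tolerates zero eigenvalues, unlike chol)
mat_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Specification of a Likert item set
#'
#' Describes how a latent trait maps onto 5-point (or other) ordinal item
#' responses: per-item loadings and reverse keying, the common thresholds
#' cutting the latent continuum into categories, a person-level acquiescence
#' intercept, and item uniqueness noise.
#'
#' @param n_items number of items.
#' @param loading latent-to-item weight(s), recycled to `n_items`.
#' @param reverse_keyed logical vector (recycled) marking reverse-keyed
#'   items; a *balanced* scale has equal counts keyed each way, an
#'   *unbalanced* scale has none.
#' @param thresholds strictly increasing cutpoints; `k` thresholds give
#'   categories `1 .. k + 1`.
#' @param acquiescence_sd SD of the person-level additive response-style
#'   intercept (applied to every item regardless of keying).
#' @param uniqueness_sd per-item noise SD, recycled.
#' @returns A `likert_item_spec` list.
#' @export
likert_item_spec <- function(n_items, loading = 1, reverse_keyed = FALSE,
                             thresholds = c(-1.5, -0.5, 0.5, 1.5),
                             acquiescence_sd = 0, uniqueness_sd = 1) {
  if (any(diff(thresholds) <= 0)) {
    abort("thresholds must be strictly increasing")
  }
  if (acquiescence_sd < 0 || any(uniqueness_sd < 0)) {
    abort("acquiescence_sd and uniqueness_sd must be nonnegative")
  }
  structure(
    list(n_items = as.integer(n_items),
         loading = rep_len(loading, n_items),
         reverse_keyed = rep_len(as.logical(reverse_keyed), n_items),
         thresholds = as.numeric(thresholds),
         acquiescence_sd = acquiescence_sd,
         uniqueness_sd = rep_len(uniqueness_sd, n_items)),
    class = "likert_item_spec"
  )
}

#' Simulate ordinal item responses from a latent trait
#'
#' Each item's latent value is `s * loading * trait + acquiescence + noise`
#' where `s = -1` for reverse-keyed items, the acquiescence intercept is
#' drawn once per respondent, and the response category is one plus the
#' number of thresholds below the item latent.
#'
#' @param latent_trait numeric vector of respondent trait values.
#' @param item_spec a [likert_item_spec()].
#' @param seed optional integer seed.
#' @returns Integer matrix (respondents x items) of categories in
#'   `1 .. length(thresholds) + 1`, with the injected acquiescence latents
#'   attached as attribute `"acquiescence"`.
#' @export
#' @examples
#' spec <- likert_item_spec(4)
#' simulate_likert_items(c(-2, 0, 2), spec, seed = 1)
simulate_likert_items <- function(latent_trait, item_spec, seed = NULL) {
  stopifnot(inherits(item_spec, "likert_item_spec"))
  if (any(!is.finite(latent_trait))) abort("latent trait must be finite")
  run <- function() {
    n <- length(latent_trait); k <- item_spec$n_items
    acq <- rnorm(n, 0, item_spec$acquiescence_sd)
    sign <- ifelse(item_spec$reverse_keyed, -1, 1)
    lat <- outer(latent_trait, sign * item_spec$loading) + acq +
      matrix(rnorm(n * k), n, k) * rep(item_spec$uniqueness_sd, each = n)
    resp <- matrix(1L, n, k)
    for (th in item_spec$thresholds) resp <- resp + (lat > th)
    storage.mode(resp) <- "integer"
    attr(resp, "acquiescence") <- acq
    resp
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Add simulated item responses for a trait to a cohort
#'
#' Appends `item_<prefix>_<k>` columns generated from one of the cohort's
#' phenotype columns via [simulate_likert_items()].
#'
#' @param cohort a twin-cohort tibble.
#' @param trait trait name (the `pheno_<trait>` column is the latent).
#' @param item_spec a [likert_item_spec()].
#' @param prefix column prefix; defaults to `trait`.
#' @param seed optional integer seed.
#' @returns `cohort` with item columns appended; the acquiescence latents are
#'   stored in attribute `"acquiescence"`.
#' @export
add_likert_items <- function(cohort, trait, item_spec, prefix = trait,
                             seed = NULL) {
  col <- paste0("pheno_", trait)
  if (!col %in% names(cohort)) abort(sprintf("no column `%s` in cohort", col))
  resp <- simulate_likert_items(cohort[[col]], item_spec, seed = seed)
  colnames(resp) <- paste0("item_", prefix, "_", seq_len(ncol(resp)))
  out <- dplyr::bind_cols(cohort, as_tibble(resp))
  attr(out, "acquiescence") <- attr(resp, "acquiescence")
  attr(out, "spec") <- attr(cohort, "spec")
  out
}

#' Randomly reduce complete pairs to unpaired responders
#'
#' Each complete pair independently loses its second-born record with
#' probability `p_drop`; families already unpaired are untouched. Record
#' order, family identifiers and zygosity are preserved.
#'
#' @param cohort a twin-cohort tibble.
#' @param p_drop probability in `[0, 1]` of dropping twin 2 from a pair.
#' @param seed optional integer seed.
#' @returns The reduced cohort tibble.
#' @export
drop_to_singles <- function(cohort, p_drop, seed = NULL) {
  if (p_drop < 0 || p_drop > 1) abort("p_drop must be in [0, 1]")
  run <- function() {
    pairs <- unique(cohort$family_id[cohort$twin_order == 2L])
    dropped <- pairs[runif(length(pairs)) < p_drop]
    cohort[!(cohort$family_id %in% dropped & cohort$twin_order == 2L), ]
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "spec") <- attr(cohort, "spec")
  out
}

#' Read and write the twin-cohort delimited format
#'
#' The on-disk schema is a UTF-8 comma-separated file with a header row and
#' columns `family_id`, `zygosity`, `twin_order`, `sex`, `age`, followed by
#' `pheno_<name>` and `item_<scale>_<k>` columns; missing values are empty
#' fields. `write_twin_cohort()` also writes a `<path>.yml` sidecar recording
#' the generating seed and spec when available.
#'
#' @param cohort a twin-cohort tibble.
#' @param path file path.
#' @returns `write_twin_cohort()` returns `path` invisibly;
#'   `read_twin_cohort()` returns the cohort tibble.
#' @export
write_twin_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  spec <- attr(cohort, "spec")
  meta <- list(seed = attr(cohort, "seed"),
               n_records = nrow(cohort),
               traits = grep("^pheno_", names(cohort), value = TRUE))
  if (!is.null(spec)) {
    meta$spec <- list(trait_names = spec$trait_names,
                      means = as.numeric(spec$means),
                      beta_age = as.numeric(spec$beta_age),
                      beta_sex = as.numeric(spec$beta_sex),
                      A = as.numeric(spec$A), C = as.numeric(spec$C),
                      E = as.numeric(spec$E))
  }
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_twin_cohort
#' @export
read_twin_cohort <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  progress = FALSE) |>
    dplyr::mutate(twin_order = as.integer(.data$twin_order),
                  sex = as.integer(.data$sex))
}
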