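#' Run the full twin-analysis workflow from a single configuration
#'
#' Executes the study stages in order -- cohort acquisition (simulation or
#' file), preprocessing, twin correlations and assumption tests, univariate
#' ACE/AE/CE/E model fitting with nested comparisons, a multivariate AE
#' Cholesky fit with genetic/environmental correlations, cluster-robust
#' association models with FDR control, facet selection, and ordered
#' Cholesky decompositions -- writing each stage's tables to `output_dir`
#' together with deterministic provenance (seed, content hashes) and a
#' timing log.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{seed}{master seed; every stochastic stage derives its own
#'       stream from it.}
#'     \item{cohort}{either `list(file = "path.csv")` or
#'       `list(simulate = list(n_mz, n_dz, n_singles, spec))` where `spec`
#'       is `"mm_motivation"` or a list with `a2`, optional `c2`, `rA`,
#'       `rE`, `trait_names`.}
#'     \item{traits}{trait names to analyse (default: all).}
#'     \item{residualize}{adjust scores for age and sex (default `TRUE`).}
#'     \item{stages}{subset of `c("correlations", "assumptions",
#'       "univariate", "multivariate", "association", "decompose")`
#'       (default: the first four).}
#'     \item{models}{character vector of univariate model menus
#'       (default `c("ACE", "AE", "CE", "E")`).}
#'     \item{association}{`list(response, predictors, threshold = 0.01)`;
#'       required for the association/decompose stages.}
#'     \item{output_dir}{where tables are written.}
#'   }
#' @returns (Invisibly) a named list with the per-stage results:
#'   `cohort`, `twin_correlations`, `assumptions`, `univariate`
#'   (fits + comparisons), `multivariate`, `association`, `decomposition`,
#'   and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("correlations", "assumptions",
                                 "univariate", "multivariate")
  results <- list()
  timings <- list()
  clock <- function(label, expr) {
    t0 <- Sys.time()
    on.exit(timings[[label]] <<- as.numeric(Sys.time() - t0, units = "secs"))
    expr
  }

  # ---- cohort -----------------------------------------------------------
  cohort <- clock("cohort", {
    cc <- config$cohort %||% abort("config$cohort is required")
    if (!is.null(cc$file)) {
      read_twin_cohort(cc$file)
    } else if (!is.null(cc$simulate)) {
      sim <- cc$simulate
      spec <- pipeline_spec(sim$spec %||% "mm_motivation")
      simulate_twin_cohort(spec,
                           n_mz = sim$n_mz %||% 418L,
                           n_dz = sim$n_dz %||% 188L,
                           n_singles = sim$n_singles %||% 0L,
                           seed = seed)
    } else abort("config$cohort needs `file` or `simulate`")
  })
  traits <- config$traits %||% sub("^(pheno|score)_", "",
                                   grep("^(pheno|score)_", names(cohort),
                                        value = TRUE))

  # ---- preprocessing: age/sex residualization of every analysis score ---
  if (isTRUE(config$residualize %||% TRUE)) {
    cohort <- clock("residualize", {
      for (tr in traits) {
        col <- resolve_traits(cohort, tr)
        cohort[[paste0("score_", tr)]] <-
          residualize_age_sex(cohort[[col]], cohort$age, cohort$sex)
      }
      cohort
    })
  }
  results$cohort <- cohort
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_twin_cohort(cohort, cohort_path)

  # ---- twin correlations + heuristics -----------------------------------
  if ("correlations" %in% stages) {
    results$twin_correlations <- clock("correlations",
                                       twin_correlations(cohort, traits))
  }

  # ---- assumption tests --------------------------------------------------
  if ("assumptions" %in% stages) {
    results$assumptions <- clock("assumptions", {
      dplyr::bind_rows(lapply(traits, function(tr) {
        dplyr::mutate(assumption_tests(cohort, tr), trait = tr, .before = 1)
      }))
    })
  }

  # ---- univariate model menu --------------------------------------------
  if ("univariate" %in% stages) {
    results$univariate <- clock("univariate", {
      menu <- config$models %||% c("ACE", "AE", "CE", "E")
      per_trait <- lapply(traits, function(tr) {
        fits <- lapply(menu, function(m) {
          fit_biometric(cohort, traits = tr,
                        components = strsplit(m, "")[[1]],
                        n_starts = config$n_starts %||% 3L,
                        seed = seed + 101L)
        })
        names(fits) <- menu
        cmp <- if ("ACE" %in% menu && length(menu) > 1L) {
          dplyr::bind_rows(lapply(setdiff(menu, "ACE"), function(m) {
            dplyr::mutate(compare_models(fits$ACE, fits[[m]]),
                          trait = tr, .before = 1)
          }))
        }
        list(fits = fits, comparisons = cmp,
             shares = dplyr::bind_rows(lapply(names(fits), function(m) {
               dplyr::mutate(tidy(fits[[m]]), model = m, .before = 1)
             })))
      })
      names(per_trait) <- traits
      per_trait
    })
  }

  # ---- multivariate AE fit ----------------------------------------------
  if ("multivariate" %in% stages && length(traits) > 1L) {
    results$multivariate <- clock("multivariate", {
      fit <- fit_biometric(cohort, traits = traits, components = c("A", "E"),
                           n_starts = config$n_starts %||% 3L,
                           seed = seed + 202L)
      list(fit = fit, correlations = genetic_env_correlations(fit))
    })
  }

  # ---- association + facet selection + decomposition --------------------
  if (any(c("association", "decompose") %in% stages)) {
    ac <- config$association %||%
      abort("config$association is required for the association stage")
    results$association <- clock("association", {
      lapply(ac$response, function(resp) {
        fml <- stats::reformulate(c(ac$predictors, "age", "sex"),
                                  response = resolve_traits(cohort, resp))
        clustered_regression(cohort, fml)
      }) |> setNames(ac$response)
    })
    if ("decompose" %in% stages) {
      results$decomposition <- clock("decompose", {
        lapply(ac$response, function(resp) {
          gee <- results$association[[resp]]
          facets <- select_facets(gee, threshold = ac$threshold %||% 0.01)
          facets <- sub("^(pheno|score)_", "", facets)
          if (length(facets) == 0L) return(NULL)
          betas <- setNames(
            gee$coefficients$estimate[match(paste0("score_", facets),
                                            gee$coefficients$term)],
            facets)
          betas[is.na(betas)] <- gee$coefficients$estimate[
            match(facets, gee$coefficients$term)][is.na(betas)]
          ordering <- order_by_beta(betas, target = resp)
          cholesky_shared_unique(cohort, ordering,
                                 n_starts = config$n_starts %||% 2L,
                                 seed = seed + 303L)
        }) |> setNames(ac$response)
      })
    }
  }

  # ---- reports + provenance ---------------------------------------------
  files <- report_tables(results, out_dir)
  files <- c(cohort = cohort_path, files)
  prov <- list(seed = seed,
               package_version = as.character(utils::packageVersion("twinace")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               stages = stages,
               files = as.list(unname(tools::md5sum(files))) |>
                 setNames(basename(files)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(c(sprintf("twinace pipeline log (seed %d)", seed),
               sprintf("%s: %.2fs", names(timings), unlist(timings))),
             file.path(out_dir, "log.txt"))
  results$files <- files
  invisible(results)
}

pipeline_spec <- function(spec) {
  if (is.character(spec)) {
    if (spec == "mm_motivation") return(mm_motivation_spec())
    abort(sprintf("unknown named spec `%s`", spec))
  }
  as_mat <- function(m, p) if (is.null(m)) NULL else matrix(unlist(m), p, p)
  p <- length(spec$a2)
  std_biometric_spec(a2 = as.numeric(spec$a2),
                     c2 = if (!is.null(spec$c2)) as.numeric(spec$c2),
                     rA = as_mat(spec$rA, p), rC = as_mat(spec$rC, p),
                     rE = as_mat(spec$rE, p),
                     trait_names = spec$trait_names %||% NULL)
}

#' Write the pipeline's delimited report tables
#'
#' Renders each available result as a comma-separated table with a fixed
#' column order, numbers rounded to 2 decimals as printed in study reports;
#' the full-precision values are written alongside as `*_raw.csv`.
#'
#' @param results the list returned by [run_pipeline()] (any subset of its
#'   elements may be present).
#' @param out_dir output directory.
#' @returns Named character vector of files written.
#' @export
report_tables <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(tab, name) {
    if (is.null(tab) || nrow(tab) == 0L) return()
    raw <- file.path(out_dir, paste0(name, "_raw.csv"))
    fmt <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tab, raw, na = "")
    rounded <- dplyr::mutate(tab, dplyr::across(
      dplyr::where(is.numeric), ~ round(.x, 2)))
    readr::write_csv(rounded, fmt, na = "")
    files[[paste0(name, "_raw")]] <<- raw
    files[[name]] <<- fmt
  }

  emit(results$twin_correlations, "twin_correlations")
  emit(results$assumptions, "assumption_tests")
  if (!is.null(results$univariate)) {
    emit(dplyr::bind_rows(lapply(names(results$univariate), function(tr) {
      dplyr::mutate(results$univariate[[tr]]$shares, trait = tr)
    })), "univariate_components")
    cmps <- dplyr::bind_rows(lapply(results$univariate, `[[`, "comparisons"))
    emit(cmps, "model_comparisons")
  }
  if (!is.null(results$multivariate)) {
    fit <- results$multivariate$fit
    emit(tidy(fit), "multivariate_components")
    corr <- results$multivariate$correlations
    long <- function(m, comp) {
      d <- as.data.frame(as.table(m))
      names(d) <- c("trait1", "trait2", "value")
      d <- d[as.integer(d$trait1) < as.integer(d$trait2), ]
      dplyr::mutate(tibble::as_tibble(d), component = comp, .before = 1)
    }
    emit(dplyr::bind_rows(long(corr$rA, "rA"), long(corr$rE, "rE")),
         "genetic_environmental_correlations")
  }
  if (!is.null(results$association)) {
    emit(dplyr::bind_rows(lapply(names(results$association), function(resp) {
      gee <- results$association[[resp]]
      dplyr::mutate(tidy(gee), response = resp,
                    marginal_r2 = gee$marginal_r2, .before = 1)
    })), "association")
  }
  if (!is.null(results$decomposition)) {
    emit(dplyr::bind_rows(lapply(names(results$decomposition), function(resp) {
      dc <- results$decomposition[[resp]]
      if (is.null(dc)) return(NULL)
      dplyr::mutate(tidy(dc), target = resp,
                    ordering = paste(dc$ordering, collapse = " > "),
                    .before = 1)
    })), "variance_decomposition")
  }
  files
}
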