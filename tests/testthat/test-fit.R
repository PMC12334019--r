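test_that("ML on moment-matched data recovers the generating values exactly", {
  cohort <- moment_matched_cohort(ae_params(0.5), n_mz = 300, n_dz = 150, seed = 51)
  fit <- fit_biometric(cohort, components = c("A", "E"), n_starts = 2, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$standardized$a2, 0.5, tolerance = 1e-4)
  expect_equal(fit$standardized$e2, 0.5, tolerance = 1e-4)
  expect_equal(unname(fit$params$means), 0, tolerance = 1e-4)
  # method-of-moments oracle agrees on noiseless data
  r_mz <- intraclass_corr(cohort, "trait1", "MZ")$r
  r_dz <- intraclass_corr(cohort, "trait1", "DZ")$r
  expect_equal(fit$standardized$a2, 2 * (r_mz - r_dz), tolerance = 1e-3)
  expect_equal(fit$standardized$e2, 1 - r_mz, tolerance = 1e-3)
})

test_that("ACE fit on moment-matched ACE data matches the moment oracle", {
  pr <- biometric_params(A = 0.4, C = 0.2, E = 0.4, means = 0)
  cohort <- moment_matched_cohort(pr, 400, 200, seed = 52)
  fit <- fit_biometric(cohort, components = c("A", "C", "E"),
                       n_starts = 2, seed = 2)
  r_mz <- intraclass_corr(cohort, "trait1", "MZ")$r
  r_dz <- intraclass_corr(cohort, "trait1", "DZ")$r
  expect_equal(fit$standardized$a2, 2 * (r_mz - r_dz), tolerance = 1e-3)
  expect_equal(fit$standardized$c2, 2 * r_dz - r_mz, tolerance = 1e-3)
  expect_equal(fit$standardized$e2, 1 - r_mz, tolerance = 1e-3)
  expect_equal(sum(unlist(fit$standardized[1, -1])), 1, tolerance = 1e-8)
  expect_equal(fit$aic, fit$minus2LL + 2 * fit$n_params, tolerance = 1e-9)
})

test_that("nesting holds and parameterizations agree at the optimum", {
  spec <- mm_motivation_spec(c("MM-T", "MM-E"))
  sim <- simulate_twin_cohort(spec, 200, 100, seed = 53)
  ace <- fit_biometric(sim, components = c("A", "C", "E"), n_starts = 2, seed = 3)
  ae_chol <- fit_biometric(sim, components = c("A", "E"), n_starts = 2, seed = 3)
  ae_dir <- fit_biometric(sim, components = c("A", "E"),
                          parameterization = "direct", n_starts = 2, seed = 3)
  e_only <- fit_biometric(sim, components = "E", n_starts = 2, seed = 3)
  expect_lte(ace$minus2LL, ae_chol$minus2LL + 0.01)
  expect_lte(ae_chol$minus2LL, e_only$minus2LL + 0.01)
  expect_equal(ae_chol$minus2LL, ae_dir$minus2LL, tolerance = 0.01)
  expect_equal(ae_chol$standardized$a2, ae_dir$standardized$a2, tolerance = 0.01)
})

test_that("unpaired responders contribute through the marginal likelihood", {
  spec <- std_biometric_spec(a2 = 0.5)
  sim <- simulate_twin_cohort(spec, 150, 80, n_singles = 400, seed = 54)
  with_s <- fit_biometric(sim, components = c("A", "E"), n_starts = 2, seed = 4)
  without_s <- fit_biometric(sim, components = c("A", "E"), n_starts = 2,
                             seed = 4, include_singles = FALSE)
  expect_identical(with_s$n_singles_used, 400L)
  expect_identical(without_s$n_singles_used, 0L)
  expect_gt(with_s$minus2LL, without_s$minus2LL)  # more records, more -2LL
})

test_that("unidentified or malformed model requests error early", {
  spec <- std_biometric_spec(a2 = 0.5)
  mz_only <- simulate_twin_cohort(spec, 100, 0, seed = 55)
  expect_error(fit_biometric(mz_only, components = c("A", "E")),
               class = "twinace_error_unidentified")
  expect_error(fit_biometric(mz_only, components = c("A", "C")), "contain E")
})

test_that("model comparison reports delta -2LL, chi-square p, and AIC preference", {
  pr <- biometric_params(A = 0.5, E = 0.5, means = 0)
  cohort <- moment_matched_cohort(pr, 300, 150, seed = 56)
  ace <- fit_biometric(cohort, components = c("A", "C", "E"), n_starts = 2, seed = 5)
  ae <- fit_biometric(cohort, components = c("A", "E"), n_starts = 2, seed = 5)
  e <- fit_biometric(cohort, components = "E", n_starts = 2, seed = 5)
  cmp <- compare_models(ace, ae)
  expect_equal(cmp$delta_minus2LL, 0, tolerance = 0.01)
  expect_gt(cmp$p_value, 0.9)
  expect_equal(cmp$delta_aic, -2, tolerance = 0.01)  # same fit, 1 fewer param
  expect_identical(cmp$preferred, "AE")
  cmp2 <- compare_models(ace, e)
  expect_lt(cmp2$p_value, 1e-6)
  expect_identical(cmp2$preferred, "ACE")
  other <- moment_matched_cohort(pr, 100, 50, seed = 57)
  e2 <- fit_biometric(other, components = "E", n_starts = 1)
  expect_error(compare_models(ace, e2), "different cohorts")
  expect_error(compare_models(ae, ace), "fewer parameters")
})

test_that("profile CI tracks the Wald interval in the near-quadratic regime", {
  spec <- std_biometric_spec(a2 = 0.5)
  sim <- simulate_twin_cohort(spec, 2000, 1000, seed = 58)
  fit <- fit_biometric(sim, components = c("A", "E"), n_starts = 2, seed = 6)
  prof <- profile_ci(fit, "a2:trait1")
  wald <- twinace:::wald_ci(fit, twinace:::quantity_fun(fit, "a2:trait1"))
  expect_equal(prof$lower, wald$lower, tolerance = 0.01)
  expect_equal(prof$upper, wald$upper, tolerance = 0.01)
  expect_identical(prof$method, "profile")
  expect_lt(prof$lower, fit$standardized$a2)
  expect_gt(prof$upper, fit$standardized$a2)
})

test_that("profile CI width at study pair counts is near the reported scale", {
  spec <- std_biometric_spec(a2 = 0.5)
  sim <- simulate_twin_cohort(spec, 418, 188, seed = 59)
  fit <- fit_biometric(sim, components = c("A", "E"), n_starts = 2, seed = 7)
  ci <- profile_ci(fit, "a2:trait1")
  width <- ci$upper - ci$lower
  expect_gt(width, 0.08)   # reported interval 0.43-0.56 spans ~0.13
  expect_lt(width, 0.20)
})

test_that("tidy/glance expose shares and fit statistics", {
  pr <- biometric_params(A = diag(2) * 0.5, E = diag(2) * 0.5, means = c(0, 0),
                         trait_names = c("x", "y"))
  cohort <- moment_matched_cohort(pr, 200, 100, seed = 60)
  fit <- fit_biometric(cohort, components = c("A", "E"), n_starts = 1)
  td <- tidy(fit)
  expect_named(td, c("trait", "component", "estimate"))
  expect_equal(nrow(td), 4L)
  gl <- glance(fit)
  expect_identical(gl$model, "AE")
  expect_identical(gl$n_pairs_used, 300L)
  # diagonal A on moment-matched data: standardized shares at 0.5
  expect_equal(td$estimate, rep(0.5, 4), tolerance = 1e-3)
})
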