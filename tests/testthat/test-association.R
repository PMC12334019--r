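test_that("Fisher-z interval reproduces printed bounds and the null symmetry", {
  ci <- pearson_ci(0.78, 1983)
  expect_equal(round(ci$lower, 2), 0.76)
  expect_equal(round(ci$upper, 2), 0.80)
  # rounding-invariant over the full reported n range
  for (n in c(1961, 1975, 1987)) {
    ci_n <- pearson_ci(0.78, n)
    expect_equal(round(c(ci_n$lower, ci_n$upper), 2), c(0.76, 0.80))
  }
  ci0 <- pearson_ci(0, 100)
  expect_equal(ci0$lower, -ci0$upper)
  expect_error(pearson_ci(0.5, 3), "exceed 3")
  expect_error(pearson_ci(1, 100), "< 1")
})

test_that("Fisher-z intervals achieve close to nominal coverage", {
  rho <- 0.5; n <- 200; reps <- 2000
  covered <- withr::with_seed(81, vapply(seq_len(reps), function(i) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- pearson_ci(cor(x, y), n)
    ci$lower <= rho && rho <= ci$upper
  }, logical(1)))
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})

test_that("GEE with singleton clusters degenerates to OLS", {
  withr::with_seed(82, {
    n <- 300
    d <- tibble::tibble(family_id = as.character(1:n),
                        x1 = rnorm(n), x2 = rnorm(n),
                        age = runif(n, 31, 55), sex = rbinom(n, 1, 0.5))
    d$y <- 0.5 * d$x1 + rnorm(n)
  })
  gee <- clustered_regression(d, y ~ x1 + x2 + age + sex,
                              working = "independence", standardize = FALSE)
  ols <- lm(y ~ x1 + x2 + age + sex, data = d)
  expect_equal(gee$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  # robust SEs match the sandwich package's clustered HC0 covariance
  skip_if_not_installed("sandwich")
  vc <- sandwich::vcovCL(ols, cluster = d$family_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(gee$coefficients$robust_se, unname(sqrt(diag(vc))),
               tolerance = 1e-6)
})

test_that("duplicating every record inflates naive SEs by sqrt(2) but not robust SEs", {
  withr::with_seed(83, {
    n <- 400
    d <- tibble::tibble(family_id = as.character(1:n), x = rnorm(n))
    d$y <- 0.4 * d$x + rnorm(n)
  })
  dup <- dplyr::bind_rows(d, d)  # twin 2 is a copy of twin 1
  gee <- clustered_regression(dup, y ~ x, working = "independence",
                              standardize = FALSE)
  ols_dup <- lm(y ~ x, data = dup)
  naive_se <- sqrt(diag(vcov(ols_dup)))
  ratio <- gee$coefficients$robust_se / unname(naive_se)
  expect_equal(ratio, rep(sqrt(2), 2), tolerance = 0.15)
})

test_that("clustered regression recovers generating betas with near-nominal type I error", {
  spec <- std_biometric_spec(a2 = c(0.5, 0.5), rA = diag(2), rE = diag(2),
                             trait_names = c("f1", "f2"))
  gen <- function(seed) {
    sim <- simulate_twin_cohort(spec, 500, 250, n_singles = 500, seed = seed)
    sim$pheno_y <- withr::with_seed(seed + 1,
      0.4 * sim$pheno_f1 + 0 * sim$pheno_f2 + rnorm(nrow(sim), 0, sqrt(1 - 0.16)))
    sim
  }
  sim <- gen(840)
  gee <- clustered_regression(sim, pheno_y ~ pheno_f1 + pheno_f2 + age + sex)
  b <- gee$coefficients
  expect_equal(b$estimate[b$term == "pheno_f1"], 0.4, tolerance = 0.05)
  expect_lt(abs(b$estimate[b$term == "pheno_f2"]), 0.05)
  # null rejection rate near 5% over replicates
  rej <- vapply(1:120, function(i) {
    s <- gen(9000 + 7 * i)
    g <- clustered_regression(s, pheno_y ~ pheno_f1 + pheno_f2 + age + sex)
    g$coefficients$p_raw[g$coefficients$term == "pheno_f2"] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)
})

test_that("exchangeable and independence working correlations agree under zero clustering", {
  withr::with_seed(85, {
    n_fam <- 400
    d <- tibble::tibble(family_id = rep(as.character(1:n_fam), each = 2),
                        x = rnorm(2 * n_fam))
    d$y <- 0.3 * d$x + rnorm(2 * n_fam)   # no shared family component
  })
  g_ex <- clustered_regression(d, y ~ x, working = "exchangeable",
                               standardize = FALSE)
  g_in <- clustered_regression(d, y ~ x, working = "independence",
                               standardize = FALSE)
  expect_lt(abs(g_ex$rho), 0.1)
  expect_equal(g_ex$coefficients$estimate, g_in$coefficients$estimate,
               tolerance = 0.01)
})

test_that("marginal R2 behaves at the extremes and at a tuned population value", {
  withr::with_seed(86, {
    x <- rnorm(2000)
    y <- sqrt(0.3) * x + sqrt(0.7) * rnorm(2000)  # population R2 = 0.30
    d <- tibble::tibble(family_id = as.character(1:2000), x = x, y = y,
                        yy = x)
  })
  g <- clustered_regression(d, y ~ x, standardize = FALSE)
  expect_lt(abs(marginal_r2(g) - 0.30), 0.03)
  perfect <- clustered_regression(d, yy ~ x, standardize = FALSE)
  expect_equal(marginal_r2(perfect), 1, tolerance = 1e-9)
  expect_warning(null_fit <- clustered_regression(d, y ~ 1, standardize = FALSE),
                 "constant fitted")
  expect_equal(null_fit$marginal_r2, 0)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  withr::with_seed(87, {
    for (k in c(1, 5, 19, 40)) {
      p <- runif(k)^2
      expect_equal(bh_fdr(p), bh_stepup(p), tolerance = 1e-12)
    }
  })
  expect_equal(bh_fdr(0.03), 0.03)           # single p unchanged
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  p <- withr::with_seed(88, runif(30))
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in p rank
  # BH never discovers fewer than Bonferroni
  bonf <- p.adjust(p, method = "bonferroni")
  expect_gte(sum(adj < 0.05), sum(bonf < 0.05))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("facet selection applies the screening threshold to non-covariates only", {
  tab <- tibble::tibble(
    term = c("(Intercept)", "O2", "FA", "E3", "N2", "age", "sex"),
    estimate = c(0, 0.42, 0.09, 0.08, 0.03, -0.1, 0.09),
    p_raw = c(0.5, 1e-6, 0.004, 0.001, 0.4, 1e-5, 1e-4),
    covariate = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_message(sel <- select_facets(tab), "3 of 4")
  expect_identical(sel, c("O2", "FA", "E3"))  # decreasing |beta|
  expect_message(all_sel <- select_facets(tab, threshold = 1))
  expect_identical(sort(all_sel), sort(c("O2", "FA", "E3", "N2")))
  tab0 <- dplyr::mutate(tab, p_raw = pmax(p_raw, 0.5))
  expect_warning(expect_message(none <- select_facets(tab0)), "no facets")
  expect_length(none, 0)
})
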