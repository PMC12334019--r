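balanced_scale <- function(k = 8, prefix = "b") {
  ids <- paste0(prefix, seq_len(k))
  scale_definition("balanced", ids, reverse_keyed = ids[seq(2, k, by = 2)])
}

test_that("acquiescence score is the un-recoded mean minus the midpoint", {
  sc <- balanced_scale(4)
  d <- data.frame(b1 = c(3, 5, 4), b2 = c(3, 5, 2), b3 = c(3, 5, 4),
                  b4 = c(3, 5, NA))
  s <- acquiescence_score(d, sc)
  expect_equal(s[1], 0)          # all at midpoint
  expect_equal(s[2], 2)          # all strongly agree on a balanced scale
  expect_equal(s[3], mean(c(4, 2, 4)) - 3)  # mean over answered items
  unb <- scale_definition("mm", c("m1", "m2"))
  expect_error(acquiescence_score(d, unb), class = "twinace_error_unbalanced")
})

test_that("acquiescence score tracks the injected latent better than any item", {
  spec <- likert_item_spec(16, loading = 0.8,
                           reverse_keyed = rep(c(FALSE, TRUE), 8),
                           acquiescence_sd = 0.5)
  trait <- withr::with_seed(21, rnorm(8000))
  resp <- simulate_likert_items(trait, spec, seed = 22)
  acq <- attr(resp, "acquiescence")
  d <- as.data.frame(resp)
  names(d) <- paste0("b", 1:16)
  score <- acquiescence_score(d, balanced_scale(16))
  r_score <- cor(score, acq)
  r_items <- apply(resp, 2, cor, y = acq)
  expect_gt(r_score, max(abs(r_items)))
  # invariant to the trait level on a noiseless symmetric balanced scale
  quiet <- likert_item_spec(8, loading = 1, reverse_keyed = rep(c(FALSE, TRUE), 4),
                            acquiescence_sd = 0, uniqueness_sd = 0)
  resp0 <- simulate_likert_items(seq(-2, 2, length.out = 50), quiet, seed = 23)
  d0 <- as.data.frame(resp0); names(d0) <- paste0("b", 1:8)
  expect_equal(sd(acquiescence_score(d0, balanced_scale(8))), 0)
})

test_that("acquiescence adjustment matches an independent normal-equations solve", {
  withr::with_seed(24, {
    n <- 5000
    acq <- rnorm(n, 0, 0.5)
    # tuned so the population adjusted R2 sits near 0.045
    comp <- rnorm(n, 0, 0.4) + 0.2 * acq + rnorm(n, 0, 0.23)
  })
  out <- adjust_for_acquiescence(comp, acq)
  # oracle: explicit normal equations + adjusted R2 formula
  X <- cbind(1, acq)
  beta <- solve(t(X) %*% X, t(X) %*% comp)
  res <- comp - X %*% beta
  r2 <- 1 - sum(res^2) / sum((comp - mean(comp))^2)
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  expect_gt(r2_adj, 0.03); expect_lt(r2_adj, 0.06)
  expect_equal(out$r2_adj, r2_adj, tolerance = 1e-10)
  expect_equal(out$residuals, as.numeric(scale(res)), tolerance = 1e-10)
  # residuals exactly orthogonal to the acquiescence score
  expect_lt(abs(sum(out$residuals * acq)), 1e-8 * n)
})

test_that("acquiescence adjustment handles degenerate regressors", {
  y <- c(1, 2, 3, 4)
  expect_warning(out <- adjust_for_acquiescence(y, rep(0.5, 4)), "constant")
  expect_equal(out$residuals, as.numeric(scale(y)))
  expect_equal(out$r2_adj, 0)
  expect_error(adjust_for_acquiescence(y, y), class = "twinace_error_constant")
})

test_that("composite scores equal brute-force recoded row means", {
  sc <- scale_definition("s", paste0("i", 1:6), reverse_keyed = c("i2", "i5"),
                         excluded_items = "i6")
  expect_equal(composite_score(data.frame(i1 = 2, i2 = 2, i3 = 2, i4 = 2,
                                          i5 = 2, i6 = 5),
                               scale_definition("s4", paste0("i", 1:6))),
               2.5)  # plain mean, no recoding
  expect_equal(composite_score(
    data.frame(i1 = 5, i2 = 1, i3 = NA, i4 = NA, i5 = NA, i6 = NA),
    scale_definition("two", c("i1", "i2"), reverse_keyed = "i2")), 5)
  m <- withr::with_seed(25, matrix(sample(c(1:5, NA), 300 * 6, TRUE,
                                          prob = c(rep(0.18, 5), 0.1)),
                                   300, 6, dimnames = list(NULL, paste0("i", 1:6))))
  got <- composite_score(as.data.frame(m), sc)
  # elementwise oracle
  mm <- m[, 1:5]
  mm[, c(2, 5)] <- 6 - mm[, c(2, 5)]
  expect_equal(got, ifelse(rowSums(!is.na(mm)) >= 2.5, rowMeans(mm, na.rm = TRUE),
                           NA_real_))
  # invariance under item-order relabeling
  sc_perm <- scale_definition("s", rev(sc$item_ids), reverse_keyed = c("i2", "i5"),
                              excluded_items = "i6")
  expect_equal(composite_score(as.data.frame(m), sc_perm), got)
  expect_error(composite_score(as.data.frame(m),
                               scale_definition("x", "i1", excluded_items = "i1")),
               "excluded")
})

test_that("cronbach alpha matches its closed form", {
  two <- scale_definition("t", c("i1", "i2"))
  d <- data.frame(i1 = c(1, 2, 3, 4, 5), i2 = c(1, 2, 3, 4, 5))
  expect_equal(cronbach_alpha(d, two)$alpha, 1)
  ind <- withr::with_seed(26, data.frame(i1 = sample(1:5, 50000, TRUE),
                                         i2 = sample(1:5, 50000, TRUE)))
  expect_lt(abs(cronbach_alpha(ind, two)$alpha), 0.05)
  # 9-item scale: alpha from the generating covariance as oracle
  k <- 9; lambda <- 0.7; psi <- 0.8
  Sigma <- matrix(lambda^2, k, k); diag(Sigma) <- lambda^2 + psi^2
  alpha_pop <- k / (k - 1) * (1 - sum(diag(Sigma)) / sum(Sigma))
  trait <- withr::with_seed(27, rnorm(20000))
  items <- outer(trait, rep(lambda, k)) +
    withr::with_seed(28, matrix(rnorm(20000 * k, 0, psi), 20000, k))
  # continuous items: alpha formula applies on any metric
  dd <- as.data.frame(items); names(dd) <- paste0("i", 1:k)
  sc <- scale_definition("nine", names(dd), response_min = -100, response_max = 100)
  got <- cronbach_alpha(dd, sc)
  expect_equal(got$alpha, alpha_pop, tolerance = 0.02)
  expect_identical(got$n_respondents, 20000L)
})

test_that("age/sex residualization is orthogonal to the covariates", {
  spec <- biometric_spec(A = 0.5, C = 0, E = 0.5, means = 0, beta_age = 0.3)
  sim <- simulate_twin_cohort(spec, 5000, 0, seed = 29)
  res <- residualize_age_sex(sim$pheno_trait1, sim$age, sim$sex)
  expect_lt(abs(cor(res, sim$age)), 0.02)
  expect_equal(sd(res), 1, tolerance = 1e-12)
  # with no generating effects the residuals are the z-scores
  spec0 <- biometric_spec(A = 0.5, C = 0, E = 0.5, means = 0)
  sim0 <- simulate_twin_cohort(spec0, 5000, 0, seed = 30)
  res0 <- residualize_age_sex(sim0$pheno_trait1, sim0$age, sim0$sex)
  expect_gt(cor(res0, scale(sim0$pheno_trait1)[, 1]), 0.999)
  expect_error(residualize_age_sex(2 * sim0$age, sim0$age, sim0$sex),
               class = "twinace_error_constant")
  expect_warning(residualize_age_sex(sim0$pheno_trait1, sim0$age,
                                     rep(1, nrow(sim0))), "constant")
})

test_that("preprocess_cohort wires composites, acquiescence and residualization", {
  spec <- std_biometric_spec(a2 = 0.5, trait_names = "mm")
  sim <- simulate_twin_cohort(spec, 400, 200, seed = 31)
  sim <- add_likert_items(sim, "mm",
                          likert_item_spec(6, loading = 0.9, acquiescence_sd = 0.4),
                          seed = 32)
  bal <- likert_item_spec(16, loading = 0.8, reverse_keyed = rep(c(FALSE, TRUE), 8),
                          acquiescence_sd = 0.4)
  sim <- add_likert_items(sim, "mm", bal, prefix = "bfi", seed = 33)
  scales <- list(scale_definition("mm", paste0("item_mm_", 1:6)))
  bal_sc <- scale_definition("bfi", paste0("item_bfi_", 1:16),
                             reverse_keyed = paste0("item_bfi_", seq(2, 16, 2)))
  out <- preprocess_cohort(sim, scales, balanced_scale = bal_sc)
  expect_true("score_mm" %in% names(out))
  expect_equal(mean(out$score_mm), 0, tolerance = 1e-10)
  expect_equal(sd(out$score_mm), 1, tolerance = 1e-10)
  info <- attr(out, "preprocess")$acquiescence_r2_adj
  expect_true(is.numeric(info$mm))  # mm was acquiescence-adjusted
  # residuals orthogonal to the acquiescence estimate used for adjustment
  acq <- acquiescence_score(sim, bal_sc)
  resid_mm <- adjust_for_acquiescence(
    composite_score(sim, scales[[1]]), acq)$residuals
  expect_lt(abs(sum(resid_mm * acq)), 1e-8 * nrow(sim))
})
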