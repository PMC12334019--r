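#' Define a questionnaire scale
#'
#' @param name scale label.
#' @param item_ids character vector of item column names (unique, nonempty).
#' @param reverse_keyed subset of `item_ids` scored in the opposite
#'   direction.
#' @param response_min,response_max integer response bounds (e.g. 1 and 5 for
#'   a 5-point Likert scale).
#' @param excluded_items subset of `item_ids` dropped from scoring
#'   (sensitivity analyses, e.g. removing a single item from a facet).
#' @returns A `scale_definition` list with a `balanced` flag (equal counts of
#'   reverse- and positively keyed items).
#' @export
scale_definition <- function(name, item_ids, reverse_keyed = character(),
                             response_min = 1L, response_max = 5L,
                             excluded_items = character()) {
  if (length(item_ids) == 0L || anyDuplicated(item_ids)) {
    abort("item_ids must be nonempty and unique")
  }
  if (!all(reverse_keyed %in% item_ids)) abort("reverse_keyed must be a subset of item_ids")
  if (!all(excluded_items %in% item_ids)) abort("excluded_items must be a subset of item_ids")
  structure(
    list(name = name, item_ids = item_ids, reverse_keyed = reverse_keyed,
         response_min = as.integer(response_min),
         response_max = as.integer(response_max),
         excluded_items = excluded_items,
         balanced = length(reverse_keyed) * 2L == length(item_ids)),
    class = "scale_definition"
  )
}

item_matrix <- function(data, scale, recode = TRUE, exclude = TRUE) {
  ids <- scale$item_ids
  if (exclude) ids <- setdiff(ids, scale$excluded_items)
  if (length(ids) == 0L) abort("all items of the scale are excluded")
  missing_cols <- setdiff(ids, colnames(data))
  if (length(missing_cols)) {
    abort(sprintf("items not found in data: %s", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(data)[, ids, drop = FALSE])
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < scale$response_min || rng[2] > scale$response_max) {
    abort("responses outside the declared response range")
  }
  if (recode) {
    rev <- intersect(scale$reverse_keyed, ids)
    m[, rev] <- scale$response_min + scale$response_max - m[, rev]
  }
  m
}

#' Acquiescence score from a balanced inventory
#'
#' On a perfectly balanced inventory (equal numbers of positively and
#' reverse-keyed items) trait content cancels in the plain item mean, so the
#' mean of the *un-recoded* responses minus the scale midpoint isolates the
#' yea-saying response style. Respondents with missing items are scored over
#' the items they answered.
#'
#' @param data data frame or matrix containing the item columns.
#' @param scale a balanced [scale_definition()].
#' @returns Numeric vector of acquiescence scores (0 = no directional bias).
#' @export
#' @examples
#' sc <- scale_definition("bal", c("i1", "i2"), reverse_keyed = "i2")
#' acquiescence_score(data.frame(i1 = c(3, 5), i2 = c(3, 5)), sc)
acquiescence_score <- function(data, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  if (!scale$balanced) {
    abort("acquiescence is only identified on a balanced inventory",
          class = "twinace_error_unbalanced")
  }
  m <- item_matrix(data, scale, recode = FALSE, exclude = FALSE)
  rowMeans(m, na.rm = TRUE) - (scale$response_min + scale$response_max) / 2
}

#' Regression adjustment of a composite for acquiescence
#'
#' Ordinary least squares of the composite on the acquiescence score (with
#' intercept); the z-standardized residuals carry forward into all analyses.
#'
#' @param composite numeric vector of raw composite scores.
#' @param acq numeric vector of acquiescence scores, same length.
#' @returns A list with `residuals` (mean 0, SD 1) and `r2_adj` (adjusted
#'   R-squared of the acquiescence regression).
#' @export
adjust_for_acquiescence <- function(composite, acq) {
  stopifnot(length(composite) == length(acq))
  if (sd(composite, na.rm = TRUE) == 0) abort("composite is constant")
  if (sd(acq, na.rm = TRUE) == 0 || all(is.na(acq))) {
    warn("acquiescence score is constant; returning z-scored composite")
    return(list(residuals = z_standardize(composite), r2_adj = 0))
  }
  fit <- lm(composite ~ acq, na.action = stats::na.exclude)
  res <- residuals(fit)
  if (sd(res, na.rm = TRUE) < 1e-12) {
    abort("residuals are constant after acquiescence adjustment (perfect collinearity)",
          class = "twinace_error_constant")
  }
  list(residuals = z_standardize(res),
       r2_adj = summary(fit)$adj.r.squared)
}

#' Composite (subscale) score
#'
#' Reverse-keyed items are recoded as `min + max - x`, then the mean is taken
#' over non-excluded, non-missing items. The result is missing when fewer
#' than half of the scale's (non-excluded) items were answered.
#'
#' @inheritParams acquiescence_score
#' @returns Numeric vector of composite scores on the item metric.
#' @export
composite_score <- function(data, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  m <- item_matrix(data, scale)
  answered <- rowSums(!is.na(m))
  out <- rowMeans(m, na.rm = TRUE)
  out[answered < ncol(m) / 2] <- NA_real_
  out
}

#' Cronbach's alpha for a scale
#'
#' `alpha = k / (k - 1) * (1 - sum(item variances) / var(item sum))` over
#' complete-case respondents, after reverse-keyed recoding.
#'
#' @inheritParams acquiescence_score
#' @returns A one-row tibble with `alpha`, `n_items`, `n_respondents`.
#' @export
cronbach_alpha <- function(data, scale) {
  m <- item_matrix(data, scale)
  if (ncol(m) < 2L) abort("Cronbach's alpha requires at least 2 items")
  m <- m[complete.cases(m), , drop = FALSE]
  total_var <- var(rowSums(m))
  if (total_var <= 0) abort("zero variance in the item sum")
  k <- ncol(m)
  tibble(alpha = k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var),
         n_items = k, n_respondents = nrow(m))
}

#' Residualize a variable for age and sex
#'
#' OLS of `y` on an intercept, age, and sex; returns z-standardized
#' residuals. Applied to every analysis variable before twin modeling to
#' avoid mean-structure biases in the covariance estimates.
#'
#' @param y numeric response vector (may contain `NA`).
#' @param age,sex numeric covariate vectors of the same length.
#' @returns Numeric vector of standardized residuals (`NA` where `y` is).
#' @export
residualize_age_sex <- function(y, age, sex) {
  stopifnot(length(y) == length(age), length(y) == length(sex))
  if (sd(y, na.rm = TRUE) == 0) abort("y is constant")
  X <- cbind(age = age, sex = sex)
  keep <- apply(X, 2, function(v) sd(v, na.rm = TRUE) > 0)
  if (!all(keep)) {
    warn(sprintf("dropping constant covariate(s): %s",
                 paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  df <- data.frame(y = y, X)
  fit <- lm(y ~ ., data = df, na.action = stats::na.exclude)
  res <- residuals(fit)
  if (sd(res, na.rm = TRUE) < 1e-12) {
    abort("residuals are constant after age/sex adjustment",
          class = "twinace_error_constant")
  }
  z_standardize(res)
}

z_standardize <- function(x) {
  unname((x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE))
}

#' Preprocess a cohort's item responses into analysis-ready scores
#'
#' For each scale: composite scoring, optional acquiescence adjustment (for
#' unbalanced scales, using the acquiescence score computed from
#' `balanced_scale`), then age/sex residualization. Adds one
#' `score_<scale>` column per scale.
#'
#' @param cohort twin-cohort tibble containing the item columns.
#' @param scales list of [scale_definition()]s to score.
#' @param balanced_scale optional balanced [scale_definition()] used to
#'   estimate acquiescence; when supplied, every *unbalanced* scale in
#'   `scales` is acquiescence-adjusted before residualization.
#' @param residualize adjust all scores for age and sex (default `TRUE`).
#' @returns `cohort` with standardized `score_<name>` columns appended and a
#'   `"preprocess"` attribute recording per-scale `r2_adj` values.
#' @export
preprocess_cohort <- function(cohort, scales, balanced_scale = NULL,
                              residualize = TRUE) {
  acq <- if (!is.null(balanced_scale)) acquiescence_score(cohort, balanced_scale)
  info <- list()
  for (sc in scales) {
    comp <- composite_score(cohort, sc)
    if (!is.null(acq) && !sc$balanced) {
      adj <- adjust_for_acquiescence(comp, acq)
      comp <- adj$residuals
      info[[sc$name]] <- adj$r2_adj
    } else {
      comp <- z_standardize(comp)
    }
    if (residualize) comp <- residualize_age_sex(comp, cohort$age, cohort$sex)
    cohort[[paste0("score_", sc$name)]] <- comp
  }
  attr(cohort, "preprocess") <- list(acquiescence_r2_adj = info)
  cohort
}
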