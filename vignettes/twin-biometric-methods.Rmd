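---
title: "Biometric modeling of twin questionnaire data with twinace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biometric modeling of twin questionnaire data with twinace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
library(dplyr)
```

## The model

twinace implements the classical twin design (CTD) for continuous
questionnaire composites. The phenotypic covariance of a set of traits is
decomposed into additive genetic (A), shared-environment (C) and
unique-environment (E) contributions, identified by the contrast between
monozygotic (MZ) co-twins, who share all segregating genes, and dizygotic
(DZ) co-twins, who share half on average. The implied covariance of a
stacked twin pair \((y_1, y_2)\) is

\[
\Sigma_{zyg} \;=\;
\begin{pmatrix}
A + C + E & \rho_{zyg}A + C \\
\rho_{zyg}A + C & A + C + E
\end{pmatrix},
\qquad \rho_{MZ} = 1,\; \rho_{DZ} = \tfrac12 .
\]

Estimation is full-information maximum likelihood (FIML): every record
contributes the multivariate-normal likelihood of its observed entries, so
unpaired responders enter through the \(p \times p\) marginal
\(A + C + E\) and partially missing records through the corresponding
submatrix. Internally, records sharing a missingness pattern are pooled
through sufficient statistics (count, pattern mean, ML scatter); this is an
algebraic regrouping of the record-wise log-likelihood and the test suite
verifies it against a naive per-record evaluation.

Two parameterizations are available. The **Cholesky** form writes each
component as \(LL^\top\) of a lower-triangular path matrix, keeping the
estimate positive semidefinite by construction; it also defines the ordered
decomposition used for shared-versus-unique variance (below). The
**direct** form estimates the symmetric component matrices without
constraint, so variance estimates can go negative — informative near the
boundary, and the convention under which direct-variance estimates are
usually reported. Standardization divides each diagonal element by the
trait's total, as-is, with a warning if a component variance is negative.

## What the generator emulates

`simulate_twin_cohort()` produces the study conditions the rest of the
package is validated against: same-sex MZ/DZ pairs plus unpaired
responders, ages uniform on 31–55 years, a configurable female fraction
(default 0.66), and per-trait age/sex mean effects. Genetic latents use the
pair-factor construction
\(g_i = \sqrt{\rho}\, g_{pair} + \sqrt{1-\rho}\, g_{own,i}\), coloured by
the symmetric square root of A — this reproduces the required cross-twin
correlation for any positive-semidefinite A, including rank-deficient
matrices where a Cholesky factor would fail. C latents are drawn once per
family, E latents per person.

`mm_motivation_spec()` carries the default generating values for the four
music-use-motivation dimensions (transcendence, emotion regulation, social
bonding, identity/expression): standardized AE structure with
heritabilities 0.50 / 0.40 / 0.38 / 0.52 and the genetic and
unique-environment correlation matrices reported for these dimensions in
adult twin data. Simulation studies in the tests and the acceptance script
use 418 MZ and 188 DZ complete pairs, the complete-pair counts available
for these composites.

Likert items are generated by thresholding
\(\pm\lambda \cdot \text{trait} + \text{acq} + \varepsilon\) at fixed
cutpoints, with a single person-level acquiescence intercept applied to
every item regardless of keying. That operationalization matches the
downstream correction: on a perfectly balanced inventory the trait content
cancels in the plain item mean, so the un-recoded mean minus the scale
midpoint isolates the response style.

What the generator does **not** emulate: non-normal trait distributions,
assortative mating, gene–environment interaction or correlation,
opposite-sex DZ pairs, and any informative missingness (unpaired
responders are missing completely at random, since the response mechanism
of real registries is unknown). Passing tests therefore demonstrate
correctness of the estimators under the stated generating model, not
robustness to these violations.

## Preprocessing order

Raw items flow through a fixed sequence, mirroring standard practice for
agreement-keyed questionnaires: (1) composite scoring with reverse-keyed
recoding, a mean over answered items, and a missing result when fewer than
half the items were answered; (2) acquiescence adjustment of unbalanced
composites — OLS on the balanced-inventory acquiescence score,
z-standardized residuals carried forward; (3) age/sex residualization of
every analysis variable (linear age; polynomial terms were considered and
omitted as the generator's mean structure is linear). The half-answered
missing-item rule is a convention choice; it keeps per-trait Ns stable
without imputation.

## Fitting, convergence, and intervals

`fit_biometric()` minimizes the FIML \(-2\log L\) by quasi-Newton
iteration (`nlminb`) from `n_starts` starting points. The first start
splits the pooled within-person covariance evenly among the included
components (E receiving half), the rest are jittered from it; this start is
close enough that a single start almost always reaches the optimum, and
multi-starts serve as a reproducibility check. A fit is flagged
`converged` when the optimizer reports success, the best two starts agree
within 0.01 in \(-2\log L\), and the relative finite-difference gradient
at the optimum is below \(10^{-4}\) — an absolute gradient criterion is not
meaningful against finite-difference noise on a likelihood of magnitude
\(10^3\)–\(10^4\).

Confidence intervals are profile-likelihood by default: the bound is the
value of the target quantity (a standardized share, a genetic or
environmental correlation, or any user function of the parameters) at
which the re-optimized \(-2\log L\) rises by \(\chi^2_1(0.95) = 3.841\).
The constrained re-optimization uses a quadratic penalty on the quantity
with escalated weight (\(10^5\), then \(10^7\)), warm-started while
stepping outward, and the crossing is located by root-finding to \(10^{-4}\)
on the quantity scale. When profiling fails, a Wald interval (numeric
Hessian plus delta method) is the fallback, and bounds that run out of the
search window are flagged open rather than silently truncated. The test
suite checks ~95% empirical coverage for heritability at the study's pair
counts over 200 replicates, and agreement with the Wald interval in the
near-quadratic large-sample regime.

Model comparison follows the likelihood-ratio convention:
\(\Delta(-2\log L)\) against \(\chi^2_{\Delta df}\), with small negative
differences (optimizer noise) clipped to zero, AIC reported alongside, and
the nested model preferred when the test is non-significant. Boundary
effects (a variance constrained at zero under the null) make these tests
conservative; the type-I simulations in the suite accept rejection at or
below the nominal rate for this reason.

## Assumption tests and the correlation heuristic

`assumption_tests()` fits a fully saturated model — free 2p-mean and free
\(2p \times 2p\) covariance per zygosity, within-pair symmetry *not*
imposed — and the usual constraint chain: means equal within pairs, means
equal across zygosity, then variances equal within pairs and across
zygosity, each compared to the saturated model. Covariances are
parameterized as log-SDs plus a row-normalized Cholesky of the correlation
matrix so that equality constraints on variances are direct parameter
sharing.

`intraclass_corr()` is the Pearson correlation of twin 1 versus twin 2
over complete pairs with the analytic standard error
\((1 - r^2)/\sqrt{n_{pairs} - 1}\) — the convention that reproduces
printed twin-correlation SEs exactly after rounding.
`heuristic_components()` applies the classical screening rules
(\(r_{MZ} > r_{DZ}\) suggests A, \(r_{MZ} < 2 r_{DZ}\) suggests C,
\(r_{MZ} > 2 r_{DZ}\) suggests D, both strict so the exact 2:1 ratio flags
neither); D is only ever flagged, never fitted, as dominance is not
identified alongside C in the CTD.

## Multivariate structure

Genetic and environmental correlations are
\(r^A_{ij} = A_{ij} / \sqrt{A_{ii} A_{jj}}\) (analogously for E); under
the direct parameterization a nonpositive diagonal renders the cell
undefined and it is returned as `NA` rather than fabricated.

The ordered Cholesky decomposition, `cholesky_shared_unique()`, enters
predictor variables first — sorted by decreasing \(|\beta|\) from the
association model via `order_by_beta()`, ties broken by the inventory
(input) order and reported — and the target last. With paths \(l_{tj}\)
into the target row, the fraction of the target's genetic variance shared
with its predecessors is \(\sum_{j<t} l_{tj}^2 / \sum_{j\le t} l_{tj}^2\);
in the bivariate case this reduces algebraically to \((r^A)^2\), an
identity the tests verify. Fractions are invariant to rescaling any
predecessor. Joint fits are practical up to roughly a dozen variables;
beyond that the \(2p \times 2p\) likelihood and the parameter count grow
quickly.

## Phenotypic association layer

`clustered_regression()` is a Gaussian identity-link GEE: iteratively
reweighted GLS under an exchangeable working correlation (the natural
choice for twins; independence is also available), with a cluster-robust
sandwich covariance on the family identifier. The exchangeable parameter
is moment-estimated from within-cluster residual products. Standardized
betas z-score the response and continuous predictors while 0/1 covariates
stay on their own scale. Benjamini–Hochberg FDR adjustment is applied per
model across the non-covariate predictors only, and `select_facets()`
applies the p < 0.01 screen that decides which predictors carry into the
twin models. Phenotypic correlations use Fisher-z intervals
(`pearson_ci()`); when correlations are computed on unrelated individuals,
the deterministic rule is to keep first-born twins plus all unpaired
responders.

## Numerical choices and degenerate inputs

* Singular implied covariances during optimization return a large penalty
  (\(10^{12}\)) instead of crashing, so the optimizer backtracks.
* A constant acquiescence score degrades the adjustment to plain
  z-scoring with a warning; perfect collinearity (residual variance below
  \(10^{-12}\)) is an error, as is a constant response after age/sex
  adjustment.
* Collinear design columns in the association model are dropped with a
  warning (QR pivoting); a single cluster is an error.
* Model comparison requires matching cohort fingerprints (record counts
  plus data checksums) to prevent cross-cohort likelihood differences.
* All simulation is seeded per call through an isolated RNG scope, so a
  cohort is a deterministic function of its seed and the global RNG state
  is never disturbed.

## Problem sizes used in validation

The test suite and the acceptance script validate estimator behavior at
418 MZ / 188 DZ pairs (univariate, bivariate and four-variate recovery,
50 replicates per configuration; profile-CI coverage over 200
replicates), with larger cohorts (up to \(10^5\) pairs) only for moment
convergence checks of the generator, and 2,000-replicate closed-form
coverage checks for the Fisher-z interval. These sizes were chosen so each
recovery study pins the estimate mean well inside the acceptance bands
while a full run stays comfortable on a single CPU.

## A worked example

```{r example, eval = FALSE}
spec <- mm_motivation_spec(c("MM-T", "MM-E"))
cohort <- simulate_twin_cohort(spec, n_mz = 418, n_dz = 188,
                               n_singles = 600, seed = 1)

twin_correlations(cohort)

fit <- fit_biometric(cohort, components = c("A", "E"), seed = 1)
tidy(fit)
genetic_env_correlations(fit)$rA

dc <- cholesky_shared_unique(cohort, c("MM-T", "MM-E"), seed = 1)
tidy(dc)
autoplot(dc)
```

## Known limitations

Ordinal (liability-threshold) likelihoods are not implemented — composites
are treated as continuous, as is conventional for multi-item scales. ADE
and ACDE models, sex-limitation and heterogeneity models, and
common/independent-pathway multivariate models are out of scope, as are
causal-direction analyses: genetic correlations quantify shared etiology,
not causation. The saturated-model machinery optimizes
\(O(p^2)\)-parameter covariances per zygosity and is intended for small
trait sets.
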