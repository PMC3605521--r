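---
title: "Nutrient balances: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient balances: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutribalance)
```

## The model and its assumptions

A tissue sample's ionome is treated as a composition: a vector of strictly
positive parts carrying only relative information, closed to a constant κ.
The package's working assumption — the one under which all of its statistics
are calibrated — is that ionomes are *logistic-normal*: Gaussian in isometric
log-ratio (ilr) coordinates, not in raw or log concentrations. Under this
assumption ilr coordinates support ordinary multivariate machinery
(covariances, Mahalanobis distances, discriminant axes), while raw-scale
statistics are artefacts of the closure.

An SBP (sequential binary partition) encodes the analyst's hierarchy of
nutrient contrasts. The built-in `default_ionome_sbp()` splits mobile
macronutrients from the Ca–Mg pair first, then N,P from K, then N from P
(the protein-vs-rRNA tradeoff), then Ca from Mg — each row an orthonormal
log contrast with coefficient √(rs/(r+s)). Any valid SBP spans the same
space: distances, CDA eigenvalues and outlier flags are SBP-invariant, and
the tests assert this rather than privileging one basis.

Sign convention: the +1 group is the numerator, so a positive balance means
the +1 group's geometric mean exceeds the −1 group's. Row order is preserved
as given; validation checks the sequential-binary structure by set
containment and reports the first violating row.

## Units, closure, and the filling value

κ and the unit annotation travel with every composition; conversions
(% ↔ g/kg) are explicit operations. This is deliberate: raw-scale
covariance structure depends on the closure, so silent rescaling would be
dangerous, while all log-ratio quantities are provably unaffected (asserted
at 1e-12 in the tests).

The filling value Fv = κ − Σ(measured parts) makes a measured subcomposition
an exact composition on the dry-matter scale. Once appended it is an
ordinary part and may enter an SBP (the optional [N,P,K,Ca,Mg | Fv] row),
but it is excluded by default from raw/log/alr analysis variables
(`representation_matrix()`): it is the unanalysed remainder, not a nutrient,
and for an exactly closed table keeping it would make the raw variables
collinear — within-group scatter of rank D−1 and no canonical solution. That
collinearity is not a bug but the geometry of closed data; the package
surfaces it as an explicit error naming the cause.

One subtlety worth recording: the log-Euclidean distance ε between two
compositions closed to a *common* κ does not depend on the magnitude of κ —
a shared rescaling cancels in log differences. What ε does depend on is the
*choice of representation* of the same relative data: per-unit-dry-matter
concentrations (varying totals, Fv embedding) versus re-closure to the
nutrient sum give different ε, while the Aitchison distance over the same
five parts is identical. The bias decomposition ε² = 𝒜² + D·(ln g(x)/g(y))²
holds exactly in either representation; only the geometric-mean ratio term
moves.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| κ | 100 | % (or 1000 g/kg) | matches how leaf analyses are reported |
| outlier α | 0.01 | — | conventional screening level for robust Mahalanobis cutoffs |
| normality α | 0.01 | — | per-variable Anderson–Darling decision level |
| ellipse level | 0.95 | — | data and mean-confidence ellipse coverage |
| MCD | `MASS::cov.rob(method = "mcd")` defaults | — | robust scatter; seed settable for determinism |
| alr denominator | last retained part | — | conventional; any part may be chosen |

Outlier screening runs on ilr coordinates by default (raw-space Mahalanobis
inherits closure biases) and per group, since discriminant analysis assumes
within-group ellipsoids; both are flags, and the mask is returned, never
applied silently. The Anderson–Darling test uses the estimated-parameters
case with the (1 + 0.75/n + 2.25/n²) correction and the standard
piecewise-exponential p-value approximation, so cross-implementation checks
are meaningful to 1e-6; no multiple-testing correction is applied across the
normality battery (aggregate fractions are reported as raw per-variable
outcomes).

## Canonical discriminant analysis

Classical CDA: with W the pooled within-group covariance (unbiased, divisor
n−g) and B the between-group covariance (divisor g−1), the axes solve
W⁻¹Ba = λa, computed through a Cholesky-symmetrized eigenproblem and
normalized to a′Wa = 1, so canonical scores have unit within-group variance.
Each axis is oriented so its largest-magnitude loading is positive;
eigenvalues are clipped at zero and at most min(g−1, p) axes are retained.
Classification is nearest group mean in canonical space, which equals
within-group Mahalanobis distance restricted to the discriminant subspace —
hence invariant under any invertible linear map of the inputs. This is the
precise sense in which alr-based and ilr-based discriminant analyses are the
same analysis: identical eigenvalues and identical cross-validated
misclassification, asserted exactly in the tests. Axis coordinates
themselves are only defined up to the usual sign/scale conventions, so
comparisons against other software should use invariants (eigenvalue ratios,
error rates), not raw loadings.

Data ellipses scale the per-group score covariance by χ²(0.95, 2); mean
ellipses divide the covariance by n. Mean-ellipse overlap is decided by a
conservative directional test (distance between centers against the sum of
the two radii along the center-to-center direction), not an exact likelihood
test — adequate for the qualitative disjoint/overlapping call it supports.

## The synthetic-ionome generator

`simulate_ionomes()` draws each group from its Gaussian in balance space and
back-transforms through the inverse ilr map, so simulated concentrations are
strictly positive and exactly closed by construction. A master seed derives
one stream per group, so adding or dropping groups never perturbs the others.
When dry-matter embedding is requested, the [nutrients | Fv] balance is drawn
as a Gaussian around the value implied by the requested mean Fv mass
fraction; the nutrient balances are provably untouched by the embedding.

`preset_species_panel()` fixes eight groups — six domesticated fruit crops
and two wild species — whose mean concentration profiles were chosen once
from typical published foliar survey ranges (e.g. kiwifruit
N 2.5, P 0.20, K 2.5, Ca 3.0, Mg 0.35 % dry mass), with within-group balance
standard deviation 0.15 (a typical field-survey spread on the log-ratio
scale), n = 150 per group, and per-species Fv fractions of 1 − total
nutrient content. The wild pair carries a low-Ca, ericaceous-type signature;
the panel records its own effect size (the smallest wild-to-domesticated
Mahalanobis distance between group means, ≈ 4.9) so that separation tests
derive their thresholds from declared parameters rather than from observed
output.

What the generator does *not* emulate: measurement censoring and
below-detection zeros (a multiplicative-replacement hook exists but no
zero-inflation model), between-year or developmental-stage drift, laboratory
batch effects, and any calibration to real per-species means. A green test
on the panel therefore establishes that the machinery recovers a stated
logistic-normal world, not that real orchard surveys behave this way.

## Numerical choices

- Identities are asserted at 1e-10 relative (1e-12 absolute at zero);
  orthonormality at 1e-12; these constants live in one internal config.
- Zeros and negative parts are rejected at the type boundary with the
  offending part named; replacement below a detection limit is an explicit
  preprocessing call (`replace_below_detection()`, multiplicative, default
  0.65 × limit).
- AD p-values are clamped to [0, 1]; normal CDF tail values are guarded
  against log-underflow.
- Ties in CDA eigenvalues make individual axes non-unique; every invariant
  the package asserts (distances in the retained subspace, eigenvalues,
  error rates) is stable under such rotations.
- The worked-example checks compare at two printed decimals, the precision
  at which the reference values are stated.

## Known limitations

- No amalgamation arithmetic (the framework argues against amalgamated
  ratios) and no DRIS indices; ratio counting is provided for context only.
- No data-driven SBP discovery (principal balances): SBPs here are
  knowledge-driven inputs.
- No quadratic or regularized discriminant variants.
- Mean-ellipse overlap is a conservative geometric test, not an inferential
  comparison of group means.
- Pipeline configuration is JSON-only (no YAML dependency).
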