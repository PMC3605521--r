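# nutribalance

Compositional data analysis of plant ionomes: nutrient balances, Aitchison
geometry, and the diagnostics that go with them.

## The problem

Leaf tissue nutrient data (N, P, K, Ca, Mg concentrations, the *ionome*) are
compositional: each sample is a vector of strictly positive parts that carries
only relative information and is closed to a constant sum κ (1, 100 %, or
1000 g kg⁻¹ dry matter, with a *filling value* Fv absorbing the unanalysed
remainder). Statistics computed on such data in the usual Euclidean way are
artefacts of the chosen scale: correlations between raw concentrations change
in magnitude, significance and even sign when the closure is changed (the
classical spurious-correlation problem), a D-part ionome generates
D(D−1)/2 dual and D(D−1)²/2 amalgamated ratios while carrying only D−1
degrees of freedom, and Euclidean distances between ordinary log-transformed
samples are systematically inflated.

`nutribalance` implements the log-ratio framework that resolves this for
tissue nutrient diagnosis, plus the downstream classification pipeline
(robust outlier screening → normality diagnostics → canonical discriminant
analysis) and a logistic-normal synthetic-ionome generator with known ground
truth.

## The model

For a composition **c** = (c₁, …, c_D) closed to κ:

- **alr**: ln(c_j / c_A) against a chosen denominator part A;
- **clr**: ln(c_i / g(**c**)) with g the geometric mean; components sum to 0;
- **ilr / balances**: a *sequential binary partition* (SBP) is a (D−1)×D
  matrix of {+1, −1, 0} contrasts splitting the part set hierarchically.
  Row j with r parts in the +1 group and s parts in the −1 group gives

  ilr_j = √(rs/(r+s)) · ln( g(c⁺) / g(c⁻) ),

  an orthonormal coordinate system of the simplex. The built-in ionome SBP
  (`default_ionome_sbp()`) is [N,P,K | Ca,Mg], [N,P | K], [N | P], [Ca | Mg],
  optionally preceded by [N,P,K,Ca,Mg | Fv].
- **Aitchison distance** 𝒜: the Euclidean distance between ilr vectors
  (identical for every valid SBP). For ordinary log-transformed data the
  squared Euclidean distance obeys

  ε² = 𝒜² + D · ( ln g(**x**)/g(**y**) )² ≥ 𝒜²,

  so ε carries a nonnegative bias that vanishes only when the two samples
  share a geometric mean; `log_euclidean_bias()` reports the decomposition.

## Worked example

```r
library(nutribalance)

# the classic worked tissue: 2.50% N, 0.15% P
tissue <- composition(c(N = 2.50, P = 0.15), kappa = 2.65, unit = "%",
                      close = FALSE)
alr(tissue, denominator = "N")   # P/N: -2.81  (ln 0.15/2.50)
sbp2 <- sbp_validate(rbind(c(1, -1)), part_labels = c("N", "P"))
ilr(tissue, sbp2)                # [N | P]: 1.99  (sqrt(1/2) ln 16.7)

count_ratios(10)
#> D = 10 parts: 45 dual ratios, 405 amalgamated ratios, 9 dof

# synthetic eight-species leaf panel (6 domesticated + 2 wild), dry-matter
# embedded, Gaussian in ilr coordinates
sbp <- default_ionome_sbp()
sim <- simulate_ionomes(preset_species_panel(seed = 42, n_per_group = 50))
sim$table
#> <composition_table> 400 samples x 6 parts [N,P,K,Ca,Mg,Fv], kappa = 100 (%)
#>    sample_id     group        N         P        K       Ca        Mg       Fv
#> s1        s1 kiwifruit 2.585900 0.2014195 2.253338 3.862784 0.4308656 90.66569
#> ...

co  <- ilr(sim$table, sbp)                      # 4 balance coordinates
fit <- fit_cda(co, table_groups(sim$table))     # canonical discriminant analysis
fit
#> <cda_model> 8 groups, 4 variables, 4 canonical axes
#> eigenvalues: 1819 286.6 60.55 15.62
cv_misclassification(co, table_groups(sim$table), folds = 10, seed = 1)
#> 0.05   # 10-fold species-level misclassification
```

The first canonical eigenvalues dominate: most between-species separation
lives in two balance contrasts. The 5% species-level error is the
cross-validated counterpart of the per-species confidence ellipses
(`confidence_ellipses(fit)`), whose 95% mean-confidence regions are disjoint
between the wild and domesticated super-clusters.

Every pairwise log-Euclidean distance is at least the Aitchison distance
(`pairwise_distances(tab, sbp)`), with equality only at matched geometric
means — the numerical bias that motivates working in balances.

## Command line

```sh
nutribalance simulate --seed 42 -o synth/
nutribalance transform --representation ilr --kappa 100 -o ilr.csv synth/ionomes.csv
nutribalance distance  --metric both -o dist.csv synth/ionomes.csv
nutribalance diagnose  --alpha 0.01 -o report/ synth/ionomes.csv
nutribalance da        --representation all -o da/ synth/ionomes.csv
nutribalance run       -o out/ synth/ionomes.csv     # full pipeline + manifest
```

(The `nutribalance` script is installed under the package `exec/` directory;
equivalently `Rscript -e 'nutribalance::nutribalance_main()' <args>`.)

## Layout

- `R/composition.R`, `R/composition_table.R` — simplex types, closure,
  filling value, alr/clr, ratio combinatorics, CSV/JSON I/O
- `R/sbp.R` — SBP validation, orthonormal bases, ilr forward/inverse,
  balance dendrograms (JSON/Newick)
- `R/geometry.R` — Aitchison distance/norm, log-Euclidean bias decomposition,
  pairwise distance matrices
- `R/diagnostics.R` — Anderson–Darling normality across representations,
  scale-dependency correlation reports, robust MCD outlier screening
- `R/discriminant.R` — canonical discriminant analysis, confidence ellipses,
  cross-validated misclassification
- `R/simulate.R` — logistic-normal ionome generator and the preset panel
- `R/pipeline.R` — run configuration, full pipeline, CLI
- `vignettes/nutrient-balances.Rmd` — methods and design notes
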