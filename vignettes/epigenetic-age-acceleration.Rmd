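---
title: "Epigenetic age acceleration: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenetic age acceleration: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiaccel)
```

## The clock model

A linear epigenetic clock scores a methylation profile as
$s = b_0 + \sum_p w_p \beta_p$, with $\beta_p \in [0,1]$ the beta value of
clock CpG $p$. The score is interpreted on a calibrated age scale: ageing
is fast during development and roughly linear afterwards, so the transform

$$
T(a) = \begin{cases}
\log(a+1) - \log(a_\mathrm{adult}+1), & a \le a_\mathrm{adult}\\[2pt]
(a - a_\mathrm{adult})/(a_\mathrm{adult}+1), & a > a_\mathrm{adult}
\end{cases}
$$

is log-linear below the knot $a_\mathrm{adult}$ (default 20 years) and
linear above it; it is continuous, strictly increasing and zero at the
knot. `transform_age()` / `inverse_transform_age()` implement the pair, and
DNAm age is $T^{-1}(s)$. Because clock files do not always restate their
calibration, the transform is pinned in the package and `adult_age` travels
with the clock file (`#adult_age=` header, default 20), so files are
self-describing.

**Missing clock probes.** Clocks are routinely applied across array
generations (27K/450K) whose probe sets differ. Missing cells are filled in
a fixed tier order: the clock's *gold-standard mean* for that CpG when the
file ships one, else the cohort-wide mean of the probe, else 0.5. The gold
tier comes first so that a clock distributed with reference means behaves
identically in every cohort; the 0.5 fallback is a last resort that the
imputation report makes visible. A clock with more than half its probes
entirely absent is refused as inapplicable to the platform.

**No normalization.** The package performs no array normalization. Instead,
the per-sample mean beta is exported by `predict_dnam_age()` so it can be
carried as a covariate in the association models — a check on global
methylation shifts masquerading as ageing effects.

## The two acceleration measures

`compute_age_acceleration()` regresses DNAm age on chronological age *in
controls only* (ordinary least squares) and defines every sample's
acceleration as its residual from that line. Two exact consequences — used
as test invariants — are that control accelerations have mean zero and zero
correlation with age. Which samples count as controls is configurable:
strictly `control`, or `non_case` (controls plus an other-disease group).
The default excludes other-disease samples, so a second disease group
cannot drag the anchor line; the alternative is one switch away.

`fit_multivariate()` fits `DNAmAge ~ age + status (+ covariates)` and
`years_of_acceleration()` reports $\hat\beta_\mathrm{status} /
\hat\beta_\mathrm{age}$ — the case effect re-expressed in chronological
years, which is robust to a clock whose slope against age differs from 1
(common in brain tissue). The ratio is kept at full precision internally
and rounded to one decimal only for reporting. Wald tests use the normal
reference throughout (large-sample convention); standard errors are
classical.

Group comparisons use the Kruskal–Wallis test (base R's midrank,
tie-corrected statistic with a $\chi^2$ upper-tail P). All-identical values
return $H = 0$, $P = 1$ rather than an error. The $\chi^2$ reference is an
approximation: exhaustive enumeration of all two-group rank configurations
at $n \le 8$ shows it tracks the exact permutation mid-P (the standard
convention for discrete nulls) to better than 0.01 wherever the test can
reject ($P \lesssim 0.1$), while in the middle of the distribution the
discreteness of the permutation null makes differences of up to ~0.07
unavoidable for any $\chi^2$-based P. The test suite asserts the
tail-region agreement exhaustively; groups smaller than 5 trigger a
warning.

`run_stratified()` re-runs the acceleration analysis independently within
each stratum (e.g. brain region), *refitting the control line per stratum*,
because tissues can differ in both clock slope and offset; strata below a
minimum size (default 6) are skipped with a logged reason.

## The sibship model

Family designs (affected subject, unaffected sibling, mother) confound
genetics and shared environment with status unless the family structure is
modelled. `fit_random_intercept()` fits

$$\mathrm{DNAmAge}_{ij} = \beta_0 + \beta_a\,\mathrm{age}_{ij} +
\beta_s\,\mathrm{status}_{ij} + u_j + e_{ij},\qquad
u_j \sim N(0, \sigma^2_b),\; e_{ij} \sim N(0, \sigma^2_w)$$

by REML. REML rather than ML is the standard convention for variance
components (ML's variance estimates are biased low at few groups). The
implementation profiles the fixed effects and residual variance in closed
form for a given variance ratio $\lambda = \sigma^2_b/\sigma^2_w$ —
per-group compound-symmetry algebra, no large matrix inversions — and
maximises the restricted likelihood by a one-dimensional search over
$\log\lambda$, with the $\lambda = 0$ boundary checked explicitly. At the
boundary the fit equals OLS exactly; a boundary solution is a valid result,
not an error. The test suite cross-checks estimates, standard errors,
variance components and the restricted likelihood against `lme4` on the
same data, and verifies 95% Wald coverage by simulation.

## Cell composition

Methylation is cell-type specific, so blood cell-mixture differences can
confound case/control comparisons. Three complementary tools:

* `estimate_cell_composition()` projects each sample onto the convex hull
  of a signature matrix: minimise $\|y - Sw\|^2$ subject to $w \ge 0$,
  $\sum w = 1$. The equality constraint (rather than $\le 1$) keeps
  proportions interpretable and testable; unexplained signal goes to
  `residual_norm` instead. The solver enumerates the faces of the simplex
  and solves the equality-constrained least-squares problem on each via its
  KKT system — exact for the ≤ 15 cell types that occur in practice, and
  verified in tests against random-simplex search.
* `reference_free_adjust()` handles the no-signature case. Probe loadings
  come from the top-$k$ singular vectors of the beta matrix residualised on
  the full design (intercept, age, status); per-sample surrogate scores are
  then the projection of the *age-only*-residualised beta matrix onto those
  loadings. The second step matters: scores computed from the fully
  residualised matrix are orthogonal to status by construction and could
  never absorb a confounded status effect, whereas re-projecting the
  age-residualised data restores the status-aligned mixture variation, so a
  latent factor that fakes a status effect is absorbed (tests verify > 80%
  shrinkage in that construction, and stability within 1 SE when no latent
  structure exists). With $k = 0$ the result is exactly the unadjusted fit.
* `mediation_test()` asks whether a cell proportion *transmits* the status
  effect on acceleration: path $a$ (mediator on status), path $b$
  (acceleration on mediator + status), indirect effect $ab$ with a Sobel z
  and a seeded percentile bootstrap. This is deliberately the linear
  product-of-coefficients decomposition — a transparent, testable
  simplification of a full structural-equation mediation analysis, and
  labelled as such in its output. For nested linear fits
  total = direct + indirect holds exactly.

## Marginal CpG statistics and meta-analysis

`marginal_cpg_stats()` computes per probe: the Pearson correlation with
age; the signed $-\log_{10} P$ of the correlation test against acceleration
(sign = sign of the correlation); and the signed $-\log_{10} P$ of a
Wilcoxon rank-sum case/control comparison (positive = hypermethylated in
cases). The rank-sum test was chosen for the status axis to match the
nonparametric group-test convention used elsewhere in the pipeline.
P-values are floored at $10^{-300}$ and signed values capped at $\pm 300$,
so every statistic is finite and serialisable; zero-variance probes get
zeros and a flag. Clock CpGs are coloured by the sign of their training-set
age correlation when the clock file carries that annotation.

`classify_quadrants()` labels probes significant on both axes at an
uncorrected threshold (default 0.05) by their sign pair; concordant
case-hypermethylated, acceleration-positive CpGs land "upper-right".
`preservation_correlation()` measures cross-dataset replication as the
Pearson correlation of a chosen signed statistic over shared probes.

Dataset-level meta-analysis offers both `stouffer_meta()` (weighted z) and
`fixed_effects_meta()` (inverse-variance pooling). Because the combination
rule behind a published pooled result is often unstated, the
inverse-variance function also reports the unweighted mean of the
per-dataset years-of-acceleration as a secondary summary; both are emitted,
neither is privileged.

## The synthetic generator

`generate_cohort()` builds cohorts in which every quantity the pipeline
estimates is known exactly:

* Clock CpGs are affine in transformed age, $\beta_j = a_j + b_j T(a)$,
  slopes of mixed signs kept inside $[0.02, 0.98]$ over the configured age
  range (infeasible slopes are an error). Weights $w_j = b_j / \sum b^2$
  and intercept $-\sum w_j a_j$ make the noiseless predictor return the
  true age *exactly* — the generator inverts the predictor's construction,
  which is what makes 1e-8-level recovery tests possible.
* Case acceleration is injected on the chronological-year scale (effective
  age = age + delta), matching how effects are reported in years; noise is
  added on the transformed scale, so year-scale error grows below the
  calibration knot exactly as the clock's calibration implies.
* Optional cell-type mixtures: Dirichlet mixing weights over a random
  signature, with a case composition shift (defaults: fewer CD4T and B,
  more NK — the blood phenotype the pipeline is built to probe).
* Planted case-associated background CpGs are both shifted in cases and
  correlated with the realised acceleration, so quadrant recovery can be
  tested against ground truth.
* The sibship design draws a shared per-family year-scale offset plus
  individual noise; `simulate_sibship_data()` is a lightweight year-scale
  shortcut for exercising the mixed model alone.

Defaults mirror the cohort structure the pipeline targets: 30 cases / 60
controls, ages 20–80, delta 6.6 years, transformed-scale noise 0.095
(≈ 2 years above the knot), a 353-CpG clock, 6 cell types, 29 sibships,
10 planted CpGs among 1000 background probes. Everything is reproducible
from a single integer seed; no global random state is consumed outside the
generator functions.

What the generator does *not* emulate: probe-type chemistry, batch and
position effects, beta-value heteroskedasticity near the boundaries, and
realistic linkage between acceleration and cell composition. Passing
recovery tests on these cohorts therefore demonstrates correctness of the
estimators under their stated model, not robustness to the artefacts of
real arrays — that is what the mean-beta covariate, the reference-free
adjustment and the stratified analyses are for on real data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: fewer than 3 controls or zero
control age variance, rank-deficient designs (reported with the collinear
column names), zero-variance mediators and probes, all-identical group
values, and clocks missing more than half their probes are all either hard
errors or defined results, never silent NaNs. The REML search runs on
$\log\lambda \in [-14, 14]$ with an explicit boundary comparison;
deconvolution accepts solutions to $10^{-6}$ in objective (the
face-enumeration solver is exact to rounding).

Simulation-based tests use sizes chosen to make Monte-Carlo error small
relative to the tolerance being asserted while keeping the default test run
in tens of seconds: 100 replicates for the 6.6-year recovery check, 2000
null replicates for Kruskal–Wallis calibration, 1000 replicates at 50
sibships for Wald coverage, 600 probes × 6 cell types for deconvolution
accuracy. `scripts/acceptance.R` re-runs the headline computations at the
same sizes from a single command-line seed.

## Known limitations

Clock files are taken at face value (probe identifiers matched
case-sensitively, never remapped across array generations); no IDAT
parsing, no BMIQ/quantile normalization, no training of new clocks. The
mixed model is a single random intercept — no crossed or nested effects, no
random slopes. Robust/heteroskedastic standard errors are not offered. The
mediation test is the linear simplification described above, not a full
SEM. Multiple-testing correction is deliberately absent from the marginal
analysis, which follows an uncorrected-threshold, effect-pattern reading of
per-CpG results.
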