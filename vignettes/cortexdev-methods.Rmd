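---
title: "Models and methods behind cortexdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cortexdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexdev)
```

`cortexdev` connects two views of adolescent cortical development: in vivo
diffusion-MRI microstructure summarised per functional network, and
post-mortem cell-type gene expression trajectories. This vignette documents
the statistical models, the synthetic-data generators that stand in for the
two real imaging cohorts and two expression datasets, the tunable parameters
and their defaults, and the numerical and design choices a maintainer should
know about. Every empirical statement here is computed by the package's test
suite or acceptance script; nothing is asserted from outside.

## The imaging cohort generator

`generate_cohort()` emulates a cross-sectional developmental MRI study: 88
subjects by default, ages uniform on 8–19 y (the age histogram of the
emulated cohort is not available, so uniform is the least-informative
choice), sex assigned with male fraction 42/88.

**Effect calibration.** Each network × metric pair carries a standardized
age slope `beta_age`, a standardized sex contrast `beta_sex` (sex coded
±0.5 so the coefficient is a mean contrast; the coding convention in the
emulated analyses is unstated, so ours is documented rather than asserted),
and a target adjusted R² `r2_target`. On the standardized scale the
generated signal is

```
y* = b * z(age) + beta_sex * sex + e,    e ~ N(0, 1 - r2_target)
```

and the metric is `baseline_mean + baseline_sd * y*`. Two calibration
details matter:

* The sample-standardized slope estimator is the Pearson correlation, whose
  expectation at n = 88 is shrunk by roughly `(1 - beta^2) / (2n)`. The
  generating slope `b` is inflated by the first-order inverse of that factor
  so that the *mean recovered* slope equals `beta_age`, which is the
  generator's contract (the recovery tests and acceptance script measure the
  fitted slope, not the latent one).
* Rows of the packaged effect table (`default_effect_table()`) that come
  with a reported coefficient use `r2_target = beta_age^2`; rows known only
  through a mean R² use `beta_age = sign * sqrt(R²)`. Baseline means/SDs are
  plausible cortical magnitudes (e.g. cortical thickness 2.8 ± 0.15 mm,
  apparent soma radius 11.0 ± 0.6 µm); they are placeholders exposed in the
  table because the emulated study does not publish per-network raw
  means/SDs, and all downstream statistics are computed on the standardized
  scale.

**Signal fractions on the simplex.** `f_neurite`, `f_soma` and
`f_extracellular` must sum to 1 exactly on every row. They are generated by
a multiplicative (stick-breaking) logistic-normal: the neurite effect drives
`logit(f_neurite)` directly, and a second coordinate splits the remainder
between soma and extracellular. This parameterisation was chosen over an
additive log-ratio with a common denominator because it keeps the
`f_neurite` channel free of the second coordinate's noise: the neurite
fraction's adjusted R² then recovers its target (0.53) to well within the
0.02 tolerance, which an ALR construction misses by ~0.1 through noise
leakage. An `f_extracellular` effect enters the second coordinate with a
negative sign; when both soma and extracellular effects are specified in one
network, the coordinate carries their difference (an approximation,
documented here, that never affects the neurite channel). At the default
between-subject SDs (~0.03–0.04 on the fraction scale) the logistic link is
effectively linear, so the standardized-slope calibration carries through
the transform with negligible attenuation (< 0.005 in R²).

**Puberty.** `pds = clip(round(1 + (age - 8) * 4/11 + eps), 1, 5)` with
`eps ~ N(0, 0.68)`. The noise SD was calibrated once, by simulation at the
default design (n = 88, ages 8–19), so that the expected R² of a linear
regression of pds on age is 0.72, the association strength the cohort is
meant to reproduce; the generator exposes no other pubertal parameter.

## Network statistics

`fit_age_model()` is ordinary least squares on the z-scored outcome with
z-scored age (and optionally sex, pds and interactions), so coefficients are
standardized effect sizes and a single-predictor age slope equals the
Pearson correlation — this identity is tested numerically. Confidence
intervals use t quantiles (n = 88 is a small sample). AIC model selection
(`select_model_aic()`) requires identical row sets across candidates,
breaks ties toward fewer parameters and then listed order. Significance uses
the fixed strict rule `p < 0.005` with no multiple-testing correction across
networks, mirroring the analysis style the package reproduces.

`icc_absolute_agreement()` computes single-measure ICC(2,1) from the two-way
ANOVA mean squares,

```
ICC(2,1) = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE)),
```

on a complete subject × session grid (incomplete grids are rejected;
negative estimates are returned unclipped and flagged). Single-measure
rather than average-measure because a single session's map is the unit of
reuse. A property worth knowing: at the repeatability design size (n = 6,
k = 5) this estimator is not mean-unbiased — for a true variance ratio of
0.97 its expectation is ≈ 0.954 (the estimate is a concave function of the
subject mean square, and MSR has only 5 degrees of freedom). The package
reports the estimator faithfully rather than debiasing it; recovery tests
that expect the mean estimate to sit within 0.01 of the true ratio at this
design size will therefore fail, and the test suite documents exactly that.

## Expression trajectory models

`fit_age_spline()` models one gene's expression against age with a rank-5
thin-plate regression spline ("maximum 5 knots"): a second-derivative
penalty whose null space contains linear trends, so straight lines are
reproduced exactly (tested to 1e-6) and an unpenalized full-rank fit
interpolates (tested to 1e-8 on a 5-point fixture; the minimum-sample
precondition is n ≥ k so this limiting case is reachable). The smoothing
parameter is chosen by GCV by default, with REML available through
`method`; the fitting engine is `mgcv::gam`, the standard tool for this
model class. For the multi-region RNA-seq dialect, RIN and sex enter as
linear confounders, region as a factor, and donor as a ridge-penalized
random intercept (`s(donor, bs = "re")`); region-specific smooths sharing
one smoothing parameter are available via `by_region = TRUE`, our reading of
a shared-smooth specification whose exact semantics are ambiguous. The
fitted curve and its derivative are evaluated on a 0.1-y age grid; the
derivative comes from a central difference of the basis expansion at
h = 1e-3, which is the basis-exact derivative up to O(h²) ≈ 1e-6.

The smooth-term p-value is the approximate F-test of the age smooth against
the covariate-only null. It is approximate by construction: under the null
its distribution is close to, but not exactly, uniform (measured rejection
3.5–7% at nominal 5% across designs). The test suite asserts near-nominal
rejection rates at several thresholds rather than exact KS-uniformity, which
the approximation cannot promise; mild conservatism only makes the
downstream Benjamini–Hochberg selection (`select_age_genes()`, q < 0.05)
more conservative, and empirical FDR control under the global null is
verified directly over 100 replicate null datasets of 200 genes
(100 samples each — sizes chosen to make the check thorough but quick).

**Trajectory summaries.** `celltype_trajectory()` averages per-gene fitted
curves within a cell type, optionally z-scoring (default) or demeaning each
gene's curve across the grid first; z-before-averaging is the default
because the alternative order is ambiguous in the emulated analyses, and
both are exposed. A constant gene's normalized curve is defined as
identically zero (the 0/0 case). When a region is requested, only that
region's samples are fitted, so regional timing is preserved rather than
flattened into a shared smooth. `peak_growth_age()` returns the age of the
global maximum of the derivative (ties to the earliest age, boundary maxima
flagged censored, flat curves return none — note that for a monotone decay
the derivative's maximum legitimately sits at a grid boundary).
`expression_ratio_crossover()` finds the first negative-to-positive sign
change of (oligodendrocyte − astrocyte) with linear interpolation between
bracketing grid points and never extrapolates.

Both estimators are exact to within one grid step on generating curves
(`generating_trajectory()` provides the analytic oracle). Through the k = 5
smoother on noisy data they inherit a smoothing bias — the fitted crossover
runs ≈ 1 y late at the default noise level — but regional *ordering* is
robust: with the default catalog, crossover and peak-growth ages in primary
motor cortex precede medial frontal cortex in ≥ 95% of seeded replicates,
and that ordering (not absolute recovery through the smoother) is the
acceptance-level claim.

**Enrichment and stages.** `enrichment_test()` is a one-sided Fisher exact
test per gene set against the background universe with BH correction across
sets and a q < 0.001 flag; it is verified exhaustively against a hand-coded
hypergeometric tail on all 2×2 tables with total ≤ 30. `stage_gene_counts()`
assigns an age-gene to a developmental stage (defaults: infancy 0–1,
childhood 1–12, adolescence 12–20, young adulthood 20–40 y — the emulated
analysis does not publish its windows, so these are config-exposed) when its
fitted |derivative| exceeds an activity threshold (default 0.01 expression
units/y) anywhere in the window; the assignment rule is likewise unstated in
the source analyses, and this derivative-activity rule is our documented
stand-in.

## The gene catalog

`make_gene_catalog()` assigns each synthetic gene one of three trajectory
shapes: `logistic_rise` (`amplitude / (1 + exp(-rate (t - midpoint)))`),
`exponential_decay` (`amplitude * exp(-rate * t)`, held flat before the
regional onset), or `flat`, evaluated at `t = age - regional_offset`.
Cell-type archetypes encode the expected biology — oligodendrocyte and
excitatory genes rise (oligodendrocyte midpoint ~18 y, the adolescent
myelination wave), astrocyte/microglia/OPC/endothelial genes decay from
early life, inhibitory genes are flat — with mild per-gene jitter.
Regional offsets follow the sensorimotor-to-association axis (M1/V1 at 0 y
… MFC at +6 y), which places the generating astrocyte/oligodendrocyte
crossover at 19.7 y in M1 and ~6 y later in MFC. Amplitudes, baselines and
rates are in normalized/log2-RPKM units and are deliberate, fixed choices:
they produce trajectory magnitudes and crossover timing in the range the
emulated datasets report, and they are not adjusted per analysis.

What the generator does *not* emulate: microarray probe effects, batch
structure beyond RIN and donor intercepts, heteroscedastic or heavy-tailed
noise, gene–gene correlation, and postmortem-interval covariates. Passing
tests therefore demonstrate correctness of the estimators under a clean
version of the assumed data-generating process, not robustness to every
artefact of real post-mortem data.

## Soma composition simulation

A grey-matter voxel is modelled as five cell populations with literature
counts per mm³ (microglia 6,500; astrocytes 15,700; oligodendrocytes
12,500; neurons 92,000; endothelial cells 0.35 × neurons) and Gaussian
radius distributions (2.0 ± 0.5, 5.5 ± 1.5, 5.5 ± 1.5, 8.0 ± 2.0,
9.0 ± 0.5 µm). The MR apparent soma radius of a radius distribution is

```
R_soma = sqrt( E[R^5] / E[R^3] ),
```

the higher-order-moment weighting through which spherically restricted
diffusion sees cell bodies. `apparent_radius()` is the Monte-Carlo
estimator with a delta-method (or bootstrap) standard error;
`analytic_apparent_radius()` is the closed form from Gaussian raw moments
`E[R^3] = mu^3 + 3 mu sigma^2`, `E[R^5] = mu^5 + 10 mu^3 sigma^2 +
15 mu sigma^4`, count-weighted across populations. Negative Gaussian draws
are handled by rejection resampling, which at the coefficients of variation
above (≤ 0.27) preserves the nominal mean and SD far better than clipping;
the analytic form ignores the truncation and warns when sigma/mu > 0.4.
The two routes agree within 3 Monte-Carlo SEs across random population sets
(asserted with the multiplicity allowance a 99.7% band requires).

Age coupling assumes each cell type's expression slope is proportional to
its count: `N_i(age) = N_i(8) * (1 + s_i (age - 8))` (exponential coupling
available). `slopes_from_catalog()` derives the slope vector from the
catalog's generating curves over 8–19 y, standardizes it to unit maximum,
holds the neuron slope at zero (glial turnover, not neuron number, is the
modelled driver; config-overridable) and multiplies by a single calibration
constant, default 0.015/y for the strongest cell type — a plausible glial
turnover magnitude chosen once. The true expression-slope-to-count constant
behind the reported ~1% developmental decrease in the apparent radius is
not published, so the package reproduces the *direction* (an
oligodendrocyte-dominant increase with astrocyte/endothelial decline
strictly decreases the analytic radius across 8→19 y, tested monotonically)
and exposes the magnitude. Voxel totals drift with age rather than being
renormalized — the alternative (fixed total) is not distinguishable from
the published description, and drift is the simpler reading.

## Pipeline and reproducibility

`run_pipeline()` executes cohort/repeatability/expression simulation,
network statistics, ICC, age-gene selection with replication, trajectory
and crossover summaries, and the soma sweep, in dependency order with
per-stage sub-seeds derived from one global seed. All outputs are TSV with
a `# config_hash:` header (the hash covers the scientific config, not the
output path), plus a JSON manifest with per-file md5s; re-running the same
config and seed reproduces every output byte-identically, and `resume =
TRUE` skips stages whose outputs exist. Defaults mirror the emulated study
sizes; the test suite and acceptance checks scale some simulation sizes
(e.g. the FDR null uses 100-sample datasets; the Monte-Carlo oracle uses
1e5 radii) as the package's own balance of thoroughness against runtime.

## Known limitations

* The ICC(2,1) mean bias at small n documented above is a property of the
  prescribed estimator, not a bug; users needing unbiased variance-ratio
  estimates at n = 6 should fit variance components directly.
* Smooth-term p-values are approximate; exact frequentist calibration is
  not claimed anywhere the package reports them.
* Crossover/peak estimates on fitted trajectories inherit the k = 5
  smoother's bias (≈ +1 y at default noise); comparisons *between* regions
  are the supported inference.
* The soma simulation has no diffusion-signal forward model, no spatial
  packing constraints and no exchange; it quantifies composition effects on
  the moment ratio only.
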