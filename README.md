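# cortexdev

Tools for studying adolescent cortical development jointly from in vivo
microstructural MRI summaries and post-mortem brain gene expression.

During adolescence the cortex thins and loses grey-matter volume, but the
cellular processes behind those macroscopic changes are not directly
observable with structural MRI. Biophysical diffusion-MRI models (SANDI,
NODDI, DTI) summarise each cortical region by interpretable tissue
parameters — the neurite, soma and extracellular signal fractions
(`f_neurite + f_soma + f_extracellular = 1`), the MR apparent soma radius
`R_soma`, orientation dispersion, and tensor metrics — while developmental
transcriptome datasets measure how cell-type-specific gene expression changes
with age in the same tissue. `cortexdev` implements the statistical pipeline
that connects the two: it is written for imaging neuroscientists and
computational biologists who want a tested, reproducible implementation of
the analyses, exercised end-to-end on synthetic data with known ground truth.

The package provides four analysis layers plus an orchestrator:

* **Synthetic data generators** that emulate the study designs the analyses
  assume: an imaging cohort (n = 88, ages 8–19 y) with network-level metric
  tables driven by a packaged table of standardized effect sizes; a
  6-subject × 5-session repeatability study with known variance components; a
  single-region normalized expression dataset (n = 214, ages 0.5–72 y); and a
  multi-region log2-RPKM dataset (20 donors × 11 cortical regions, RIN/sex
  covariates, donor effects) whose genes follow cell-type-specific trajectory
  shapes with regional timing offsets along the sensorimotor-to-association
  axis.
* **Network statistics**: standardized linear age models (z-scored outcome
  and age, sex coded ±0.5) returning β with t-based 95% CIs, adjusted R²,
  AIC/BIC; AIC model selection; a strict `p < 0.005` significance rule; and
  the two-way random-effects absolute-agreement intraclass correlation
  ICC(2,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE)).
* **Expression trajectories**: per-gene penalized thin-plate spline age
  models (basis dimension k = 5, GCV or REML smoothing, RIN/sex/region
  confounders and a donor random intercept for the RNA-seq dialect),
  Benjamini–Hochberg selection of age-genes (q < 0.05), cross-dataset
  replication overlap, per-cell-type mean trajectories, peak-growth ages,
  astrocyte/oligodendrocyte expression-ratio crossover ages, Fisher-exact
  gene-set enrichment, and developmental-stage gene counts.
* **Soma composition simulation**: voxel-scale cell populations (microglia,
  astrocytes, oligodendrocytes, neurons, endothelial cells) with Gaussian
  radius distributions, expression-slope-coupled counts over age, and the
  moment-based MR apparent soma radius
  `R_soma = sqrt(E[R^5] / E[R^3])`, estimated by Monte Carlo and in closed
  form from Gaussian moments.
* **Pipeline**: `run_pipeline()` executes simulate → fit → summarize with a
  YAML config, seeded sub-streams, TSV outputs stamped with the config hash,
  and a JSON manifest; a thin CLI wrapper lives at `inst/cli/cortexdev.R`.

## Worked example

```r
library(cortexdev)

# one synthetic cohort at the packaged effect sizes, and its age model
tab <- generate_cohort(cohort_spec(seed = 1))
fit_age_model(tab, metric = "CTh", network = "default_mode")
#> <cortex_model_fit> default_mode / CTh (n = 88)
#>   terms: age
#>   term   beta  ci_lo  ci_hi        p
#> 1  age -0.589 -0.762 -0.416 1.56e-09
#>   adj R^2 = 0.339, AIC = 217.21, BIC = 224.65

# repeatability of a metric with true variance ratio 0.97
rep_tab <- generate_repeatability(
  repeatability_spec(6, 5, sqrt(0.97), sqrt(0.005), sqrt(0.025), seed = 1))
icc_absolute_agreement(rep_tab)
#> <icc_result> ICC(2,1) = 0.9776 (n = 6 subjects, k = 5 sessions)

# glial expression-ratio crossover in an early- vs late-maturing region
cat0 <- make_gene_catalog()
ds <- generate_expression(expression_spec("multi_region_rpkm",
                                          catalog = cat0, seed = 1))
tr_o <- celltype_trajectory(ds, cat0, "oligodendrocyte", region = "M1",
                            normalize = "none")
tr_a <- celltype_trajectory(ds, cat0, "astrocyte", region = "M1",
                            normalize = "none")
expression_ratio_crossover(tr_o, tr_a)
#> # A tibble: 1 × 2
#>   region crossover_age
#>   <chr>          <dbl>
#> 1 M1              19.3

# apparent soma radius of the baseline voxel composition
analytic_apparent_radius(default_cell_populations())
#> <apparent_radius_result> r_app = 9.2411 um (SE 0, n = 0, analytic)
```

The single-cohort age β (−0.589) scatters around its generating value of
−0.59; averaged over 500 cohorts it recovers it to three decimals. The
crossover near 19 y in primary motor cortex is the fitted estimate of the
generating curves' crossing at 19.7 y — oligodendrocyte-specific expression
overtakes astrocyte expression earliest in sensorimotor regions, and ~6 years
later in medial frontal cortex. The baseline apparent radius (9.24 µm) is
dominated by neurons and endothelial cells because the estimator weights
cells by high-order moments of their radii.

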