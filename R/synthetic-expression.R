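#' Cortical region and cell-type labels
#'
#' Eleven cortical regions sampled by the multi-region expression dialect and
#' the seven major cortical cell types used for gene annotation.
#'
#' @return Character vector of labels.
#' @export
cortical_regions <- function() {
  c("A1C", "DLPFC", "IPC", "ITC", "M1", "MFC", "OFC", "S1", "STC", "V1",
    "VLPFC")
}

#' @rdname cortical_regions
#' @export
cortical_cell_types <- function() {
  c("excitatory", "inhibitory", "oligodendrocyte", "OPC", "astrocyte",
    "microglia", "endothelial")
}

# Regional maturational timing offsets (years) along the
# sensorimotor-to-association axis: primary motor/visual earliest, medial
# frontal latest.
default_region_offsets <- function(regions = cortical_regions()) {
  known <- c(A1C = 1, DLPFC = 5, IPC = 2.5, ITC = 3, M1 = 0, MFC = 6,
             OFC = 4, S1 = 0.5, STC = 2.5, V1 = 0, VLPFC = 4.5)
  missing <- setdiff(regions, names(known))
  if (length(missing)) {
    abort(sprintf("no timing offset defined for region(s): %s",
                  paste(missing, collapse = ", ")))
  }
  known[regions]
}

#' Build a synthetic gene catalog
#'
#' Assigns each gene to one cortical cell type and gives it a generative age
#' trajectory: `logistic_rise` (`amplitude / (1 + exp(-rate * (t - midpoint)))`),
#' `exponential_decay` (`amplitude * exp(-rate * t)`) or `flat` (baseline
#' only), where `t = age - regional_offset`. Default shapes encode the
#' expected biology: oligodendrocyte and excitatory-neuron genes rise through
#' adolescence, astrocyte/microglia/OPC/endothelial genes decay from early
#' life, and inhibitory-neuron genes are flat. Regional offsets follow the
#' sensorimotor-to-association timing axis (see
#' [default_region_offsets()]). Per-gene jitter around the cell-type
#' archetype is drawn under `seed`.
#'
#' @param n_per_type Genes per cell type.
#' @param regions Region labels for which offsets are defined.
#' @param region_offsets Named numeric vector of timing offsets (years).
#' @param seed Integer seed for per-gene parameter jitter.
#' @return Tibble with columns `gene`, `cell_type`, `shape`, `midpoint_age`,
#'   `rate`, `amplitude`, `baseline` and one `offset_<region>` column per
#'   region.
#' @export
make_gene_catalog <- function(n_per_type = 20, regions = cortical_regions(),
                              region_offsets = default_region_offsets(regions),
                              seed = 1L) {
  archetypes <- tibble(
    cell_type = cortical_cell_types(),
    shape = c("logistic_rise", "flat", "logistic_rise", "exponential_decay",
              "exponential_decay", "exponential_decay", "exponential_decay"),
    midpoint_age = c(10, NA, 18, NA, NA, NA, NA),
    rate = c(0.30, 0, 0.35, 0.03, 0.04, 0.05, 0.04),
    amplitude = c(1.5, 0, 2.5, 1.2, 2.0, 1.0, 1.0),
    baseline = c(3.5, 2.9, 2.0, 2.4, 2.7, 1.5, 2.0)
  )
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(archetypes)), function(i) {
      a <- archetypes[i, ]
      n <- n_per_type
      tibble(
        gene = sprintf("%s_%03d", toupper(substr(a$cell_type, 1, 4)), seq_len(n)),
        cell_type = a$cell_type,
        shape = a$shape,
        midpoint_age = if (is.na(a$midpoint_age)) NA_real_ else
          a$midpoint_age + rnorm(n, 0, 1),
        rate = pmax(a$rate * exp(rnorm(n, 0, 0.15)), 1e-4),
        amplitude = if (a$shape == "flat") 0 else
          pmax(a$amplitude * exp(rnorm(n, 0, 0.2)), 0.05),
        baseline = a$baseline + rnorm(n, 0, 0.2)
      )
    })
    catalog <- dplyr::bind_rows(rows)
    for (r in regions) catalog[[paste0("offset_", r)]] <- unname(region_offsets[r])
    catalog
  })
}

# Evaluate a catalog row's generating trajectory at ages t (already shifted
# by the regional offset). Returns the trajectory *without* baseline.
trajectory_shape <- function(shape, t, midpoint, rate, amplitude) {
  switch(shape,
    logistic_rise = amplitude * plogis(rate * (t - midpoint)),
    exponential_decay = amplitude * exp(-rate * pmax(t, 0)),
    flat = rep(0, length(t)),
    abort(sprintf("unknown trajectory shape '%s'", shape))
  )
}

# Mean generating curve (baseline + shape) for one cell type in one region,
# averaged over catalog genes; used for oracle checks and slope derivation.
catalog_mean_curve <- function(catalog, cell_type, region, ages) {
  rows <- catalog[catalog$cell_type == cell_type, ]
  if (!nrow(rows)) abort(sprintf("no genes of cell type '%s' in catalog", cell_type))
  off_col <- paste0("offset_", region)
  if (!off_col %in% names(catalog)) {
    abort(sprintf("catalog has no offsets for region '%s'", region))
  }
  curves <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    r$baseline + trajectory_shape(r$shape, ages - r[[off_col]],
                                  r$midpoint_age, r$rate, r$amplitude)
  }, numeric(length(ages)))
  rowMeans(matrix(curves, nrow = length(ages)))
}

#' Noise-free mean trajectory implied by a gene catalog
#'
#' Evaluates the generating (noise-free) mean expression curve and its exact
#' derivative for one cell type in one region on an age grid, packaged as a
#' `celltype_trajectory`. This is the analytic oracle against which the
#' estimators operating on fitted data can be validated, and the reference
#' for generating crossover/peak ages.
#'
#' @param catalog Gene catalog ([make_gene_catalog()]).
#' @param cell_type Cell type label.
#' @param region Region label (must have offsets in the catalog).
#' @param ages Age grid (years).
#' @return A `celltype_trajectory` with zero-width band.
#' @export
generating_trajectory <- function(catalog, cell_type, region,
                                  ages = seq(0.5, 40, by = 0.1)) {
  m <- catalog_mean_curve(catalog, cell_type, region, ages)
  rows <- catalog[catalog$cell_type == cell_type, ]
  off <- rows[[paste0("offset_", region)]]
  d <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    t <- ages - off[i]
    switch(r$shape,
      logistic_rise = {
        p <- plogis(r$rate * (t - r$midpoint_age))
        r$amplitude * r$rate * p * (1 - p)
      },
      exponential_decay = ifelse(t > 0,
        -r$rate * r$amplitude * exp(-r$rate * t), 0),
      flat = rep(0, length(t)))
  }, numeric(length(ages)))
  structure(
    list(cell_type = cell_type, region = region, n_genes = nrow(rows),
         normalize = "none",
         grid = tibble(age = ages, mean = m, lo = m, hi = m,
                       deriv = rowMeans(matrix(d, nrow = length(ages))))),
    class = "celltype_trajectory")
}

#' Expression cohort specification
#'
#' Two dialects mirror the two post-mortem data sources the pipeline
#' emulates: `single_region_normalized` is a larger single-region microarray
#' style dataset (expression z-scored per gene after generation, no
#' covariates), and `multi_region_rpkm` is a small RNA-seq style dataset with
#' one sample per donor x region, log2-RPKM scale, RIN and sex covariates and
#' a per-donor random effect.
#'
#' @param dialect `"single_region_normalized"` or `"multi_region_rpkm"`.
#' @param n_samples Sample count (single-region dialect).
#' @param n_donors Donor count (multi-region dialect).
#' @param regions Regions to sample (multi-region dialect).
#' @param age_range Age range in years.
#' @param male_fraction Probability a donor is male.
#' @param rin_mean,rin_sd RNA-integrity-number distribution.
#' @param gamma_rin Linear RIN effect on expression (units per RIN unit).
#' @param donor_sd SD of the per-donor random intercept.
#' @param catalog Gene catalog ([make_gene_catalog()]).
#' @param noise_sd Residual Gaussian noise SD (expression units).
#' @param seed Integer seed.
#' @return An object of class `expression_spec`.
#' @export
expression_spec <- function(dialect = c("single_region_normalized",
                                        "multi_region_rpkm"),
                            n_samples = 214, n_donors = 20,
                            regions = cortical_regions(),
                            age_range = NULL, male_fraction = 0.5,
                            rin_mean = 8.3, rin_sd = 0.8, gamma_rin = 0.15,
                            donor_sd = 0.2,
                            catalog = make_gene_catalog(),
                            noise_sd = 0.4, seed = 1L) {
  dialect <- match.arg(dialect)
  age_range <- age_range %||%
    if (dialect == "single_region_normalized") c(0.5, 72) else c(0.5, 40)
  if (dialect == "multi_region_rpkm") {
    off_cols <- paste0("offset_", regions)
    missing <- regions[!off_cols %in% names(catalog)]
    if (length(missing)) {
      abort(sprintf("catalog lacks offsets for region(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  structure(
    list(dialect = dialect, n_samples = as.integer(n_samples),
         n_donors = as.integer(n_donors), regions = regions,
         age_range = as.numeric(age_range), male_fraction = male_fraction,
         rin_mean = rin_mean, rin_sd = rin_sd, gamma_rin = gamma_rin,
         donor_sd = donor_sd, catalog = catalog, noise_sd = noise_sd,
         seed = seed),
    class = "expression_spec")
}

#' Generate a synthetic expression dataset
#'
#' Per gene g and sample k the generated expression is
#' `baseline_g + shape_g(age_k - offset_region) + gamma_rin * (RIN_k - rin_mean)
#' + donor_k + noise` (RIN and donor terms only in the `multi_region_rpkm`
#' dialect). The `single_region_normalized` dialect z-scores each gene across
#' samples after generation, matching pre-normalized microarray data.
#'
#' @param spec An [expression_spec()].
#' @return An object of class `expression_dataset`: a list with `expr`
#'   (gene x sample numeric matrix), `samples` (tibble of per-sample
#'   metadata), `scale` (`"normalized"` or `"log2rpkm"`), `dialect`, and the
#'   generating `catalog`.
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  catalog <- spec$catalog
  with_seed(spec$seed, {
    if (spec$dialect == "single_region_normalized") {
      n <- spec$n_samples
      samples <- tibble(
        sample_id = sprintf("samp-%04d", seq_len(n)),
        donor = sprintf("donor-%04d", seq_len(n)),
        age = runif(n, spec$age_range[1], spec$age_range[2]),
        region = "DLPFC",
        sex = ifelse(runif(n) < spec$male_fraction, "M", "F"),
        rin = rnorm(n, spec$rin_mean, spec$rin_sd)
      )
      donor_eff <- rep(0, n)
      rin_eff <- rep(0, n)   # normalized dialect: technical variance removed
    } else {
      nd <- spec$n_donors
      donors <- tibble(
        donor = sprintf("donor-%02d", seq_len(nd)),
        age = runif(nd, spec$age_range[1], spec$age_range[2]),
        sex = ifelse(runif(nd) < spec$male_fraction, "M", "F"),
        donor_eff = rnorm(nd, 0, spec$donor_sd)
      )
      grid <- expand.grid(d = seq_len(nd), r = seq_along(spec$regions))
      samples <- tibble(
        sample_id = sprintf("samp-%04d", seq_len(nrow(grid))),
        donor = donors$donor[grid$d],
        age = donors$age[grid$d],
        region = spec$regions[grid$r],
        sex = donors$sex[grid$d],
        rin = rnorm(nrow(grid), spec$rin_mean, spec$rin_sd)
      )
      donor_eff <- donors$donor_eff[grid$d]
      rin_eff <- spec$gamma_rin * (samples$rin - spec$rin_mean)
    }

    off_cols <- paste0("offset_", samples$region)
    expr <- matrix(NA_real_, nrow = nrow(catalog), ncol = nrow(samples),
                   dimnames = list(catalog$gene, samples$sample_id))
    for (i in seq_len(nrow(catalog))) {
      g <- catalog[i, ]
      offsets <- vapply(off_cols, function(cn) {
        if (!cn %in% names(catalog)) {
          abort(sprintf("catalog has no offsets for region '%s'",
                        sub("^offset_", "", cn)))
        }
        g[[cn]]
      }, numeric(1))
      mu <- g$baseline + trajectory_shape(g$shape, samples$age - offsets,
                                          g$midpoint_age, g$rate, g$amplitude)
      expr[i, ] <- mu + rin_eff + donor_eff +
        rnorm(nrow(samples), 0, spec$noise_sd)
    }

    if (spec$dialect == "single_region_normalized") {
      expr <- t(scale(t(expr)))
      scale_tag <- "normalized"
    } else {
      scale_tag <- "log2rpkm"
    }

    structure(
      list(expr = expr, samples = samples, scale = scale_tag,
           dialect = spec$dialect, catalog = catalog),
      class = "expression_dataset")
  })
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (%s, %s)\n",
              nrow(x$expr), ncol(x$expr), x$dialect, x$scale))
  cat(sprintf("  regions: %s\n", paste(unique(x$samples$region), collapse = ", ")))
  cat(sprintf("  ages: %.1f-%.1f y\n", min(x$samples$age), max(x$samples$age)))
  invisible(x)
}
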