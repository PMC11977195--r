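# Voxel-scale cell composition simulation of the MR apparent soma radius:
# Gaussian radius distributions per cell type, expression-slope-coupled
# counts over age, and the moment-based estimator sqrt(E[R^5] / E[R^3]).

#' Construct a cell population
#'
#' @param name Cell type label.
#' @param count Cells per cubic millimetre (>= 0).
#' @param radius_mean Mean soma radius in micrometres (> 0).
#' @param radius_sd SD of soma radius in micrometres (>= 0).
#' @return One-row tibble with the population parameters.
#' @export
cell_population <- function(name, count, radius_mean, radius_sd) {
  if (count < 0) abort("count must be >= 0")
  if (radius_mean <= 0) abort("radius_mean must be > 0")
  if (radius_sd < 0) abort("radius_sd must be >= 0")
  tibble(name = name, count = count, radius_mean = radius_mean,
         radius_sd = radius_sd)
}

#' Baseline human grey-matter voxel composition
#'
#' Literature-based counts per cubic millimetre and Gaussian radius
#' parameters for the five simulated cell populations: microglia 6500 at
#' 2.0 +/- 0.5 um; astrocytes 15,700 and oligodendrocytes 12,500, both at
#' 5.5 +/- 1.5 um; neurons 92,000 at 8.0 +/- 2.0 um; endothelial cells at
#' 0.35 x the neuron count, 9.0 +/- 0.5 um.
#'
#' @return Tibble of five [cell_population()] rows.
#' @export
default_cell_populations <- function() {
  n_neuro <- 92000
  dplyr::bind_rows(
    cell_population("microglia", 6500, 2.0, 0.5),
    cell_population("astrocyte", 15700, 5.5, 1.5),
    cell_population("oligodendrocyte", 12500, 5.5, 1.5),
    cell_population("neuron", n_neuro, 8.0, 2.0),
    cell_population("endothelial", n_neuro * 0.35, 9.0, 0.5)
  )
}

#' Sample soma radii for one population
#'
#' Gaussian draws with non-positive values replaced by rejection resampling,
#' which preserves positivity without the mean/SD distortion of clipping at
#' the small coefficient-of-variation values typical of soma radii.
#'
#' @param pop One-row population tibble ([cell_population()]).
#' @param n Number of radii to draw (>= 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` positive radii (micrometres).
#' @export
sample_radii <- function(pop, n, seed = NULL) {
  if (n < 1) abort("n must be >= 1")
  if (pop$radius_sd < 0) abort("radius_sd must be >= 0")
  with_seed(seed, {
    r <- rnorm(n, pop$radius_mean, pop$radius_sd)
    bad <- which(r <= 0)
    while (length(bad)) {
      r[bad] <- rnorm(length(bad), pop$radius_mean, pop$radius_sd)
      bad <- bad[r[bad] <= 0]
    }
    r
  })
}

#' MR apparent soma radius of a radius sample
#'
#' The MR-weighted effective soma radius of a distribution of cell body
#' radii, `sqrt(mean(r^5) / mean(r^3))`: spherical restriction weights each
#' cell by higher-order moments of its radius, so large cells dominate. The
#' Monte-Carlo standard error is propagated by the delta method (or
#' bootstrap).
#'
#' @param radii Positive numeric vector (micrometres).
#' @param se_method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `se_method = "bootstrap"`.
#' @return An `apparent_radius_result`: list with `r_app`, `mc_se`,
#'   `n_samples`, `method`.
#' @export
apparent_radius <- function(radii, se_method = c("delta", "bootstrap"),
                            n_boot = 200) {
  se_method <- match.arg(se_method)
  if (!length(radii)) abort("empty radius sample")
  if (any(radii <= 0)) abort("all radii must be > 0")
  n <- length(radii)
  r3 <- radii^3
  r5 <- radii^5
  m3 <- mean(r3)
  m5 <- mean(r5)
  r_app <- sqrt(m5 / m3)
  if (n == 1) {
    se <- 0
  } else if (se_method == "delta") {
    # g(m5, m3) = sqrt(m5/m3); grad = (1/(2 r_app m3), -r_app/(2 m3))
    v5 <- var(r5) / n
    v3 <- var(r3) / n
    c53 <- stats::cov(r5, r3) / n
    g5 <- 1 / (2 * r_app * m3)
    g3 <- -r_app / (2 * m3)
    se <- sqrt(max(g5^2 * v5 + g3^2 * v3 + 2 * g5 * g3 * c53, 0))
  } else {
    bs <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      sqrt(mean(radii[idx]^5) / mean(radii[idx]^3))
    })
    se <- stats::sd(bs)
  }
  structure(
    list(r_app = r_app, mc_se = se, n_samples = n, method = "monte_carlo"),
    class = "apparent_radius_result")
}

#' @export
print.apparent_radius_result <- function(x, ...) {
  cat(sprintf("<apparent_radius_result> r_app = %.4f um (SE %.2g, n = %d, %s)\n",
              x$r_app, x$mc_se, x$n_samples, x$method))
  invisible(x)
}

#' Closed-form apparent soma radius from Gaussian moments
#'
#' Count-weighted analytic counterpart of [apparent_radius()] using Gaussian
#' raw moments `E[R^3] = mu^3 + 3 mu sigma^2` and
#' `E[R^5] = mu^5 + 10 mu^3 sigma^2 + 15 mu sigma^4`:
#' `sqrt(sum_i N_i E[R_i^5] / sum_i N_i E[R_i^3])`. The truncation applied to
#' keep sampled radii positive is ignored here; a warning is issued when any
#' population has `sigma / mu > 0.4`, where that approximation degrades.
#'
#' @param pops Tibble of [cell_population()] rows with total count > 0.
#' @return An `apparent_radius_result` with `mc_se = 0` and
#'   `method = "analytic"`.
#' @export
analytic_apparent_radius <- function(pops) {
  if (any(pops$radius_mean <= 0)) abort("radius means must be > 0")
  if (any(pops$radius_sd < 0)) abort("radius SDs must be >= 0")
  if (sum(pops$count) <= 0) abort("total cell count must be > 0")
  cv <- pops$radius_sd / pops$radius_mean
  if (any(cv > 0.4)) {
    warn("some populations have sigma/mu > 0.4; positive-truncation bias of the Gaussian-moment formula may be noticeable")
  }
  mu <- pops$radius_mean
  s2 <- pops$radius_sd^2
  m3 <- mu^3 + 3 * mu * s2
  m5 <- mu^5 + 10 * mu^3 * s2 + 15 * mu * s2^2
  w <- pops$count
  structure(
    list(r_app = sqrt(sum(w * m5) / sum(w * m3)), mc_se = 0,
         n_samples = 0L, method = "analytic"),
    class = "apparent_radius_result")
}

#' Cell-count composition slopes
#'
#' Fractional per-year count change per cell type, used to couple the voxel
#' composition to the developmental gene-expression findings under the
#' assumption that cell-type expression slope is proportional to cell count.
#'
#' @param oligodendrocyte,astrocyte,microglia,neuron,endothelial Fractional
#'   change per year (1/years).
#' @return Named numeric vector of slopes.
#' @export
composition_slopes <- function(oligodendrocyte = 0, astrocyte = 0,
                               microglia = 0, neuron = 0, endothelial = 0) {
  c(microglia = microglia, astrocyte = astrocyte,
    oligodendrocyte = oligodendrocyte, neuron = neuron,
    endothelial = endothelial)
}

#' Derive composition slopes from a gene catalog's generating trajectories
#'
#' Computes the mean expression derivative of each cell type's generating
#' curves (pooled over regions) across `age_range`, standardizes the vector
#' to unit maximum magnitude, and multiplies by a single `calibration`
#' constant converting standardized expression slope into fractional count
#' change per year. The neuron slope is held at zero by default
#' (`fix_neuron`), reflecting that glial turnover, not neuron number, drives
#' the modelled composition change.
#'
#' @param catalog Gene catalog ([make_gene_catalog()]).
#' @param age_range Length-2 ages (years) over which slopes are averaged.
#' @param calibration Fractional count change per year for the cell type with
#'   the strongest expression slope.
#' @param fix_neuron Hold the neuron slope at 0.
#' @return Named slope vector as from [composition_slopes()].
#' @export
slopes_from_catalog <- function(catalog, age_range = c(8, 19),
                                calibration = 0.015, fix_neuron = TRUE) {
  ages <- seq(age_range[1], age_range[2], by = 0.5)
  regions <- sub("^offset_", "", grep("^offset_", names(catalog), value = TRUE))
  if (!length(regions)) abort("catalog carries no regional offsets")
  mean_slope <- function(ct) {
    sl <- vapply(regions, function(r) {
      cur <- catalog_mean_curve(catalog, ct, r, ages)
      (cur[length(cur)] - cur[1]) / diff(range(ages))
    }, numeric(1))
    mean(sl)
  }
  raw <- c(
    microglia = mean_slope("microglia"),
    astrocyte = mean_slope("astrocyte"),
    oligodendrocyte = mean_slope("oligodendrocyte"),
    neuron = mean(c(mean_slope("excitatory"), mean_slope("inhibitory"))),
    endothelial = mean_slope("endothelial")
  )
  std <- raw / max(abs(raw))
  if (fix_neuron) std["neuron"] <- 0
  std * calibration
}

#' Cell counts at a given age under linear slope coupling
#'
#' `N_i(age) = N_i(ref) * (1 + s_i * (age - ref_age))` (or
#' `N_i(ref) * exp(s_i * (age - ref_age))` with `coupling = "exponential"`);
#' radius distributions are unchanged. A slope that would drive any count
#' negative at the requested age is an error naming the offending type.
#'
#' @param pops Baseline populations ([default_cell_populations()]).
#' @param slopes Named slope vector ([composition_slopes()]).
#' @param age Target age (years).
#' @param ref_age Reference age at which `pops` counts hold (default 8).
#' @param coupling `"linear"` (default) or `"exponential"`.
#' @return Population tibble with counts updated.
#' @export
counts_at_age <- function(pops, slopes, age, ref_age = 8,
                          coupling = c("linear", "exponential")) {
  coupling <- match.arg(coupling)
  s <- slopes[pops$name]
  if (anyNA(s)) {
    abort(sprintf("no slope given for population(s): %s",
                  paste(pops$name[is.na(s)], collapse = ", ")))
  }
  factor <- if (coupling == "linear") 1 + s * (age - ref_age)
            else exp(s * (age - ref_age))
  if (any(factor < 0)) {
    bad <- pops$name[factor < 0][1]
    abort(sprintf("negative cell count for '%s' at age %.1f y", bad, age))
  }
  out <- pops
  out$count <- unname(pops$count * factor)
  out
}

#' Apparent soma radius across an age sweep
#'
#' For each age, updates the composition with [counts_at_age()], draws
#' `n_samples` radii allocated to populations proportionally to their
#' counts, and estimates the Monte-Carlo apparent radius alongside the
#' closed-form value from [analytic_apparent_radius()]. The same seed is
#' reused at every age step (common random numbers), so the age trend is not
#' swamped by sampling noise.
#'
#' @param pops Baseline populations.
#' @param slopes Named slope vector.
#' @param ages Ascending ages (years), at least 2.
#' @param n_samples Radii per age step.
#' @param seed Integer seed reused at each age.
#' @param ref_age Reference age for the slope coupling.
#' @return List with `table` (tibble `age`, `r_app`, `mc_se`, `r_analytic`),
#'   `percent_change` (Monte-Carlo endpoint change, percent) and
#'   `percent_change_analytic`.
#' @export
age_sweep <- function(pops, slopes, ages, n_samples = 1e5, seed = 1L,
                      ref_age = 8) {
  if (length(ages) < 2) abort("need at least 2 ages")
  if (is.unsorted(ages, strictly = TRUE)) abort("ages must be sorted ascending")
  rows <- lapply(ages, function(a) {
    pa <- counts_at_age(pops, slopes, a, ref_age = ref_age)
    alloc <- round(n_samples * pa$count / sum(pa$count))
    alloc[alloc < 1] <- 1
    radii <- with_seed(seed, {
      unlist(lapply(seq_len(nrow(pa)), function(i) {
        sample_radii(pa[i, ], alloc[i])
      }), use.names = FALSE)
    })
    mc <- apparent_radius(radii)
    tibble(age = a, r_app = mc$r_app, mc_se = mc$mc_se,
           r_analytic = analytic_apparent_radius(pa)$r_app)
  })
  tab <- dplyr::bind_rows(rows)
  pc <- function(x) 100 * (x[length(x)] - x[1]) / x[1]
  list(table = tab, percent_change = pc(tab$r_app),
       percent_change_analytic = pc(tab$r_analytic))
}
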