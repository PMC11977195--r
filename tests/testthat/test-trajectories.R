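make_two_region_catalog <- function() {
  # one oligodendrocyte gene crossing a flat astrocyte gene exactly where the
  # logistic passes its midpoint: at age 20 in M1, age 26 in MFC
  cat_ <- tibble::tibble(
    gene = c("OL1", "AS1"),
    cell_type = c("oligodendrocyte", "astrocyte"),
    shape = c("logistic_rise", "flat"),
    midpoint_age = c(10, NA), rate = c(1, 0),
    amplitude = c(2, 0), baseline = c(2, 3),
    offset_M1 = c(10, 0), offset_MFC = c(16, 0))
  cat_
}

test_that("a single-gene trajectory equals that gene's spline fit", {
  set.seed(10)
  age <- runif(60, 0.5, 30)
  y <- 1 + 0.2 * age + rnorm(60, 0, 0.1)
  ds <- make_gene_dataset(age, y)
  cat_ <- tibble::tibble(gene = "G1", cell_type = "oligodendrocyte",
                         shape = "flat", midpoint_age = NA, rate = 0,
                         amplitude = 0, baseline = 0, offset_DLPFC = 0)
  tr <- celltype_trajectory(ds, cat_, "oligodendrocyte", normalize = "none")
  f <- fit_age_spline(ds, "G1")
  expect_equal(tr$grid$mean, f$grid$fit, tolerance = 1e-10)
  expect_equal(tr$grid$deriv, f$grid$deriv, tolerance = 1e-10)
  expect_equal(tr$n_genes, 1)
})

test_that("demeaning cancels mirror-image gene pairs", {
  set.seed(11)
  age <- runif(80, 0.5, 30)
  f_curve <- 2 * plogis(0.5 * (age - 15))
  expr <- rbind(G1 = 5 + f_curve, G2 = 1 - f_curve)
  ds <- make_gene_dataset(age, expr[1, ])
  ds$expr <- expr
  cat_ <- tibble::tibble(gene = c("G1", "G2"),
                         cell_type = "astrocyte", shape = "flat",
                         midpoint_age = NA, rate = 0, amplitude = 0,
                         baseline = 0, offset_DLPFC = 0)
  tr <- celltype_trajectory(ds, cat_, "astrocyte", normalize = "demean")
  expect_lt(max(abs(tr$grid$mean)), 1e-6)
})

test_that("z-normalizing a constant gene's curve yields the zero curve", {
  age <- seq(1, 30, length.out = 40)
  ds <- make_gene_dataset(age, rep(0, 40))
  ds$expr[1, ] <- 5   # constant expression
  cat_ <- tibble::tibble(gene = "G1", cell_type = "microglia", shape = "flat",
                         midpoint_age = NA, rate = 0, amplitude = 0,
                         baseline = 5, offset_DLPFC = 0)
  tr <- celltype_trajectory(ds, cat_, "microglia", normalize = "z")
  expect_true(all(tr$grid$mean == 0))
})

test_that("rising oligodendrocyte gene sets give increasing mean curves", {
  cat_ <- make_gene_catalog(n_per_type = 5, seed = 2)
  tr <- generating_trajectory(cat_, "oligodendrocyte", "M1", seq(0.5, 30, 0.1))
  expect_true(all(diff(tr$grid$mean) >= 0))
  # fitted on low-noise data: endpoint clearly above start
  ds <- generate_expression(expression_spec(
    "multi_region_rpkm", n_donors = 15, regions = c("M1", "MFC"),
    catalog = cat_, noise_sd = 0.05, donor_sd = 0, seed = 3))
  trf <- celltype_trajectory(ds, cat_, "oligodendrocyte", region = "M1",
                             normalize = "none")
  expect_gt(trf$grid$mean[nrow(trf$grid)], trf$grid$mean[1] + 1)
})

test_that("unknown cell types are rejected", {
  cat_ <- make_gene_catalog(n_per_type = 2)
  ds <- generate_expression(expression_spec("single_region_normalized",
                                            n_samples = 30, catalog = cat_,
                                            seed = 1))
  expect_error(celltype_trajectory(ds, cat_, "neuronoid"), "unknown cell type")
})

test_that("peak growth age finds logistic midpoints and flags edge cases", {
  cat_ <- make_two_region_catalog()
  ages <- seq(0.5, 40, 0.1)
  # logistic derivative peaks at midpoint + regional offset
  pk_m1 <- peak_growth_age(generating_trajectory(cat_, "oligodendrocyte", "M1", ages))
  expect_lt(abs(pk_m1$age - 20), 0.1 + 1e-9)
  expect_false(pk_m1$censored)
  pk_mfc <- peak_growth_age(generating_trajectory(cat_, "oligodendrocyte", "MFC", ages))
  expect_lt(pk_m1$age, pk_mfc$age)

  # monotone decay peaks (least-negative derivative aside) at a boundary
  decay <- tibble::tibble(gene = "D1", cell_type = "astrocyte",
                          shape = "exponential_decay", midpoint_age = NA,
                          rate = 0.1, amplitude = 2, baseline = 1,
                          offset_M1 = 0, offset_MFC = 0)
  pk_d <- peak_growth_age(generating_trajectory(decay, "astrocyte", "M1", ages))
  expect_true(pk_d$censored)

  # flat trajectory: no peak
  flat <- generating_trajectory(make_two_region_catalog(), "astrocyte", "M1", ages)
  pk_f <- peak_growth_age(flat)
  expect_true(pk_f$flat)
  expect_true(is.na(pk_f$age))
})

test_that("crossover detection interpolates exact analytic roots", {
  grid <- seq(0, 30, 0.1)
  mk_traj <- function(mean, region = "M1") {
    structure(list(cell_type = "x", region = region, n_genes = 1,
                   normalize = "none",
                   grid = tibble::tibble(age = grid, mean = mean,
                                         lo = mean, hi = mean, deriv = 0)),
              class = "celltype_trajectory")
  }
  cx <- expression_ratio_crossover(mk_traj(grid - 20), mk_traj(rep(0, length(grid))))
  expect_equal(cx$crossover_age, 20)

  # never crossing: none, not extrapolated
  cx2 <- expression_ratio_crossover(mk_traj(rep(-1, length(grid))),
                                    mk_traj(rep(0, length(grid))))
  expect_true(is.na(cx2$crossover_age))

  # mismatched grids and regions are errors
  short <- structure(list(cell_type = "x", region = "M1", n_genes = 1,
                          normalize = "none",
                          grid = tibble::tibble(age = grid[-1], mean = 0,
                                                lo = 0, hi = 0, deriv = 0)),
                     class = "celltype_trajectory")
  expect_error(expression_ratio_crossover(mk_traj(grid), short), "mismatched")
  expect_error(expression_ratio_crossover(mk_traj(grid), mk_traj(grid, "MFC")),
               "regions")
})

test_that("generating-curve crossovers respect the regional timing offsets", {
  cat_ <- make_two_region_catalog()
  ages <- seq(0.5, 40, 0.1)
  tr <- function(ct, r) generating_trajectory(cat_, ct, r, ages)
  cx_m1 <- expression_ratio_crossover(tr("oligodendrocyte", "M1"),
                                      tr("astrocyte", "M1"))
  cx_mfc <- expression_ratio_crossover(tr("oligodendrocyte", "MFC"),
                                       tr("astrocyte", "MFC"))
  expect_lt(abs(cx_m1$crossover_age - 20), 0.5)
  expect_lt(cx_m1$crossover_age, cx_mfc$crossover_age)
})

test_that("stage gene counts follow the derivative-activity rule", {
  cat_ <- make_gene_catalog(n_per_type = 2, seed = 5)
  ds <- generate_expression(expression_spec("single_region_normalized",
                                            n_samples = 60, catalog = cat_,
                                            seed = 5))
  fits <- fit_age_splines(ds)
  # flat fits -> zero counts everywhere
  flat_fits <- lapply(fits, function(f) {
    f$grid$deriv <- 0
    f
  })
  counts0 <- stage_gene_counts(names(fits), cat_, flat_fits)
  expect_true(all(counts0$n_genes == 0))

  # a rising oligodendrocyte gene with an adolescent midpoint lands there
  oligo <- cat_$gene[cat_$cell_type == "oligodendrocyte"][1]
  counts <- stage_gene_counts(oligo, cat_, fits)
  adol <- counts[counts$stage == "adolescence" &
                   counts$cell_type == "oligodendrocyte", ]
  expect_equal(adol$n_genes, 1)

  bad <- tibble::tibble(stage = c("a", "b"), age_min = c(0, 5),
                        age_max = c(10, 15))
  expect_error(stage_gene_counts(oligo, cat_, fits, stage_windows = bad),
               "overlap")
})
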