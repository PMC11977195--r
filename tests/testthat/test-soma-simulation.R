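test_that("apparent radius of a delta distribution is the radius itself", {
  expect_equal(apparent_radius(rep(5, 100))$r_app, 5)
  pop <- cell_population("x", 10, 5, 0)
  expect_identical(unique(sample_radii(pop, 50, seed = 1)), 5)
  expect_equal(analytic_apparent_radius(pop)$r_app, 5)
})

test_that("apparent radius matches direct arithmetic on {2, 8}", {
  r <- apparent_radius(c(2, 8))
  expect_equal(r$r_app, sqrt(16400 / 260), tolerance = 1e-12)
})

test_that("analytic radius of neurons-only matches the Gaussian moments", {
  pop <- cell_population("neuron", 92000, 8, 2)
  # E[R^3] = 608, E[R^5] = 55168 at mu = 8, sigma = 2
  expect_equal(analytic_apparent_radius(pop)$r_app, sqrt(55168 / 608),
               tolerance = 1e-12)
  # bit-exact reproducibility of the five-population baseline
  expect_identical(analytic_apparent_radius(default_cell_populations())$r_app,
                   analytic_apparent_radius(default_cell_populations())$r_app)
})

test_that("apparent radius is scale-equivariant and bounded", {
  set.seed(2)
  r <- rlnorm(500, log(5), 0.3)
  a1 <- apparent_radius(r)$r_app
  expect_equal(apparent_radius(3.7 * r)$r_app, 3.7 * a1, tolerance = 1e-12)
  expect_gte(a1, mean(r))      # moment-weighting favours large radii
  expect_lte(a1, max(r))
})

test_that("rejection resampling keeps radii positive and means unbiased", {
  r <- sample_radii(cell_population("x", 1, 1, 10), 2000, seed = 3)
  expect_true(all(r > 0))
  # microglia-like population: sample mean within 3 SE of 2.0
  r2 <- sample_radii(cell_population("microglia", 6500, 2, 0.5), 1e5, seed = 4)
  expect_lt(abs(mean(r2) - 2.0), 3 * 0.5 / sqrt(1e5))
  expect_error(sample_radii(cell_population("x", 1, 2, 0.5), 0), "n must be")
  expect_error(apparent_radius(numeric()), "empty")
  expect_error(apparent_radius(c(1, -2)), "> 0")
  expect_error(cell_population("x", 1, 2, -1), ">= 0")
})

test_that("Monte-Carlo and analytic estimators agree within 3 MC SEs", {
  # 3 SE is a 99.7% band; allow one exceedance over the 20 random draws
  set.seed(5)
  exceed <- 0L
  for (i in 1:20) {
    k <- sample(2:4, 1)
    pops <- dplyr::bind_rows(lapply(seq_len(k), function(j) {
      mu <- runif(1, 1.5, 12)
      cell_population(sprintf("p%d", j), runif(1, 1000, 90000), mu,
                      runif(1, 0, 0.28) * mu)
    }))
    alloc <- pmax(round(3e4 * pops$count / sum(pops$count)), 1)
    radii <- unlist(lapply(seq_len(k), function(j) {
      sample_radii(pops[j, ], alloc[j])
    }))
    mc <- apparent_radius(radii)
    an <- analytic_apparent_radius(pops)
    if (abs(mc$r_app - an$r_app) >= 3 * mc$mc_se + 1e-6) exceed <- exceed + 1L
  }
  expect_lte(exceed, 1L)
})

test_that("delta-method and bootstrap standard errors agree in magnitude", {
  set.seed(6)
  r <- rnorm(5000, 8, 2)
  r <- r[r > 0]
  se_d <- apparent_radius(r, "delta")$mc_se
  se_b <- apparent_radius(r, "bootstrap", n_boot = 400)$mc_se
  expect_lt(abs(se_d - se_b) / se_d, 0.35)
})

test_that("slope coupling updates counts linearly and guards negatives", {
  pops <- default_cell_populations()
  s <- composition_slopes(oligodendrocyte = 0.02)
  at18 <- counts_at_age(pops, s, 18)
  expect_equal(at18$count[at18$name == "oligodendrocyte"], 15000)
  expect_equal(at18$count[at18$name == "neuron"], 92000)

  expect_error(counts_at_age(pops, composition_slopes(astrocyte = -0.2), 19),
               "astrocyte")
  # exponential coupling never goes negative
  e <- counts_at_age(pops, composition_slopes(astrocyte = -0.2), 19,
                     coupling = "exponential")
  expect_gt(e$count[e$name == "astrocyte"], 0)
})

test_that("warning is raised when the Gaussian-moment approximation degrades", {
  expect_warning(analytic_apparent_radius(cell_population("x", 10, 2, 1)),
                 "sigma/mu")
})

test_that("increasing a small-radius population lowers the analytic radius", {
  pops <- default_cell_populations()
  base <- analytic_apparent_radius(pops)$r_app
  vals <- vapply(seq(1, 2, by = 0.25), function(f) {
    p <- pops
    p$count[p$name == "oligodendrocyte"] <- 12500 * f
    analytic_apparent_radius(p)$r_app
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], base)
})

test_that("age sweeps are flat under zero slopes and internally consistent", {
  pops <- default_cell_populations()
  sw <- age_sweep(pops, composition_slopes(), c(8, 13, 19), n_samples = 2e4,
                  seed = 7)
  expect_equal(sw$percent_change_analytic, 0)
  expect_lt(abs(sw$percent_change), 0.5)
  expect_equal(length(unique(round(sw$table$r_analytic, 10))), 1)
  for (i in seq_len(nrow(sw$table))) {
    expect_lt(abs(sw$table$r_app[i] - sw$table$r_analytic[i]),
              3 * sw$table$mc_se[i] + 1e-6)
  }
  expect_error(age_sweep(pops, composition_slopes(), 8), "at least 2")
  expect_error(age_sweep(pops, composition_slopes(), c(13, 8)), "ascending")
})

test_that("catalog-derived slopes are standardized with neurons held fixed", {
  sl <- slopes_from_catalog(make_gene_catalog(n_per_type = 4, seed = 1),
                            calibration = 0.015)
  expect_equal(unname(sl["neuron"]), 0)
  expect_equal(max(abs(sl)), 0.015)
  expect_gt(sl[["oligodendrocyte"]], 0)
  expect_lt(sl[["astrocyte"]], 0)
})
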