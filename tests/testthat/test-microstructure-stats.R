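test_that("a noiseless age outcome gives beta = 1, R^2 = 1, tiny p", {
  set.seed(1)
  age <- runif(40, 8, 19)
  tab <- make_cohort_table(age, value = age)
  # a perfect fit legitimately triggers lm's "unreliable summary" warning
  fit <- suppressWarnings(fit_age_model(tab, "CTh", "default_mode"))
  expect_equal(fit$terms$beta[1], 1, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  expect_lt(fit$terms$p[1], 1e-12)
  expect_true(fit$terms$ci_lo[1] <= fit$terms$beta[1])
  expect_true(fit$terms$ci_hi[1] >= fit$terms$beta[1])
})

test_that("the standardized single-predictor slope equals the Pearson r", {
  set.seed(42)
  for (i in 1:5) {
    age <- runif(30, 8, 19)
    y <- rnorm(30)
    tab <- make_cohort_table(age, y)
    fit <- fit_age_model(tab, "CTh", "default_mode")
    expect_equal(fit$terms$beta[1], cor(age, y), tolerance = 1e-10)
  }
})

test_that("model AIC matches the closed-form least-squares expression", {
  set.seed(7)
  age <- runif(10, 8, 19)
  y <- 0.5 * age + rnorm(10)
  tab <- make_cohort_table(age, y)
  fit <- fit_age_model(tab, "CTh", "default_mode", terms = c("age", "sex"))
  X <- cbind(scale(age)[, 1], ifelse(tab$sex[1:10] == "M", 0.5, -0.5))
  expect_equal(fit$aic, aic_oracle(scale(y)[, 1], X), tolerance = 1e-8)
})

test_that("degenerate and undersized fits are rejected", {
  age <- runif(20, 8, 19)
  expect_error(fit_age_model(make_cohort_table(age, rep(1, 20)),
                             "CTh", "default_mode"), "degenerate|constant")
  expect_error(fit_age_model(make_cohort_table(age[1:5], age[1:5]),
                             "CTh", "default_mode"), "fewer than 10")
})

test_that("AIC selection picks the generating model and honours tie rules", {
  # strong age signal: the age-only candidate beats sex-only and pds-only
  wins <- vapply(1:50, function(i) {
    tab <- generate_cohort(cohort_spec(
      n_subjects = 88,
      effects = effect_spec("default_mode", "CTh", -0.59,
                            baseline_mean = 2.8, baseline_sd = 0.15),
      networks = "default_mode", seed = 300 + i))
    sel <- select_model_aic(tab, "CTh", "default_mode",
                            list("age", "sex", "pds"))
    identical(sel$terms, "age")
  }, logical(1))
  expect_gte(mean(wins), 0.9)

  # two identical candidates: the first listed wins
  tab <- generate_cohort(cohort_spec(n_subjects = 30, seed = 1))
  sel <- select_model_aic(tab, "CTh", "visual", list("age", "age"))
  expect_identical(sel$aic_table$selected, c(TRUE, FALSE))

  expect_error(select_model_aic(tab, "CTh", "visual", list("age")),
               "at least 2")
})

test_that("a strong sex-by-puberty interaction is selected by AIC", {
  set.seed(5)
  n <- 88
  age <- runif(n, 8, 19)
  sex <- rep(c("F", "M"), length.out = n)
  pds <- pmin(pmax(round(1 + (age - 8) * 4 / 11 + rnorm(n, 0, 0.68)), 1), 5)
  sexc <- ifelse(sex == "M", 0.5, -0.5)
  y <- 0.3 * scale(age)[, 1] + 1.5 * sexc * scale(pds)[, 1] + rnorm(n, 0, 0.5)
  tab <- make_cohort_table(age, y, sex = sex, pds = pds)
  sel <- select_model_aic(tab, "CTh", "default_mode",
                          list("age", c("age", "sex", "pds"),
                               c("age", "sex", "pds", "sex:pds")))
  expect_true("sex:pds" %in% sel$terms)
})

test_that("significance flagging applies the strict p < alpha rule", {
  fits <- tibble::tibble(term = "age", p = c(0.0049, 0.005, 0.5))
  flagged <- flag_significance(fits)
  expect_identical(flagged$significant, c(TRUE, FALSE, FALSE))
})

test_that("fit_networks returns a tidy flagged scan", {
  tab <- generate_cohort(cohort_spec(n_subjects = 40, seed = 2))
  res <- fit_networks(tab, metrics = c("CTh", "f_neurite"),
                      networks = c("visual", "limbic"))
  expect_setequal(names(res),
                  c("network", "metric", "term", "beta", "ci_lo", "ci_hi",
                    "p", "adj_r2", "aic", "bic", "n", "significant"))
  expect_equal(nrow(res), 4)
})

test_that("ICC(2,1) equals the brute-force ANOVA oracle on random grids", {
  set.seed(99)
  for (i in 1:20) {
    m <- matrix(rnorm(30, sd = runif(1, 0.5, 2)), nrow = 6, ncol = 5)
    tab <- tibble::tibble(
      subject_id = rep(sprintf("s%d", 1:6), 5),
      session = rep(1:5, each = 6),
      metric = "f_neurite",
      value = as.vector(m))
    res <- icc_absolute_agreement(tab)
    expect_equal(res$icc, icc_oracle(m), tolerance = 1e-12)
  }
})

test_that("ICC handles perfect agreement, disagreement and bad grids", {
  # identical values across sessions -> exactly 1
  tab <- tibble::tibble(subject_id = rep(sprintf("s%d", 1:6), 5),
                        session = rep(1:5, each = 6), metric = "m",
                        value = rep(rnorm(6), 5))
  expect_equal(icc_absolute_agreement(tab)$icc, 1)

  # independent sessions, many subjects -> near 0 (negative allowed, flagged)
  set.seed(3)
  tab2 <- tibble::tibble(subject_id = rep(sprintf("s%03d", 1:200), 5),
                         session = rep(1:5, each = 200), metric = "m",
                         value = rnorm(1000))
  res <- icc_absolute_agreement(tab2)
  expect_lt(abs(res$icc), 0.1)
  expect_identical(res$negative, res$icc < 0)

  expect_error(icc_absolute_agreement(tab2[-1, ]), "incomplete")
})
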