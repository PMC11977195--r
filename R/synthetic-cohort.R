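#' Canonical cortical network labels
#'
#' The seven functionally defined cortical networks used throughout the
#' imaging side of the pipeline.
#'
#' @return Character vector of 7 network labels.
#' @export
yeo7_networks <- function() {
  c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
    "limbic", "frontoparietal", "default_mode")
}

#' Effect specification for one network x metric
#'
#' Describes the generative age and sex effects for a single imaging metric in
#' a single network, on the standardized scale used by the cohort generator:
#' `beta_age` is the expected standardized (z-outcome on z-age) slope,
#' `beta_sex` a standardized male-minus-female contrast (sex coded +/-0.5),
#' and `r2_target` the expected adjusted R-squared of the full linear model.
#' Residual noise is scaled so that total variance is 1 on the standardized
#' scale, i.e. noise SD `sqrt(1 - r2_target)`.
#'
#' @param network Network label.
#' @param metric Metric label (e.g. `"CTh"`, `"f_neurite"`, `"MD"`).
#' @param beta_age Standardized age slope.
#' @param beta_sex Standardized male-female contrast (default 0).
#' @param r2_target Expected adjusted R-squared in `[0, 1)`; defaults to the
#'   variance implied by the coefficients, `beta_age^2 + beta_sex^2/4`.
#' @param baseline_mean,baseline_sd Location and between-subject scale of the
#'   metric in its native units.
#'
#' @return A one-row tibble; rows from several calls can be combined with
#'   [dplyr::bind_rows()] and passed to [cohort_spec()].
#' @export
effect_spec <- function(network, metric, beta_age, beta_sex = 0,
                        r2_target = NULL, baseline_mean = NA_real_,
                        baseline_sd = NA_real_) {
  implied <- beta_age^2 + beta_sex^2 * 0.25
  if (implied > 1) {
    abort(sprintf(
      "inconsistent effect for %s/%s: coefficients imply R^2 = %.3f > 1",
      network, metric, implied))
  }
  r2_target <- r2_target %||% implied
  if (!is_scalar_number(r2_target) || r2_target < 0 || r2_target >= 1) {
    abort("r2_target must lie in [0, 1)")
  }
  if (beta_sex == 0 && beta_age^2 > r2_target + 0.05) {
    abort(sprintf(
      "inconsistent effect for %s/%s: beta_age^2 = %.3f exceeds r2_target = %.3f",
      network, metric, beta_age^2, r2_target))
  }
  tibble(network = network, metric = metric, beta_age = beta_age,
         beta_sex = beta_sex, r2_target = r2_target,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd)
}

#' Packaged effect-size table for the developmental imaging cohort
#'
#' Returns the table of standardized age effects per network and metric that
#' the synthetic cohort generator uses by default. Rows carry either a
#' reported standardized coefficient (with `r2_target = beta_age^2`) or a
#' reported mean adjusted R-squared (with `beta_age = sign * sqrt(R^2)`).
#' Baseline means/SDs are plausible cortical values in native units; they do
#' not affect standardized-scale analyses.
#'
#' @return Tibble with columns `network`, `metric`, `beta_age`, `beta_sex`,
#'   `r2_target`, `baseline_mean`, `baseline_sd`.
#' @export
default_effect_table <- function() {
  path <- system.file("extdata", "effect_sizes.tsv", package = "cortexdev",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Default baseline location/scale per imaging metric
#'
#' Used for metrics generated without an explicit effect row (null age
#' effect). Values are plausible cortical magnitudes; the pipeline's
#' statistics are computed on the standardized scale and are insensitive to
#' them.
#'
#' @return Tibble with columns `metric`, `baseline_mean`, `baseline_sd`.
#' @export
default_metric_baselines <- function() {
  tibble(
    metric = c("CTh", "SA", "GMvol", "MD", "FA", "f_neurite", "f_soma",
               "f_extracellular", "R_soma", "v_ic", "ODI"),
    baseline_mean = c(2.8, 35000, 120000, 0.80, 0.15, 0.40, 0.30,
                      0.30, 11.0, 0.45, 0.45),
    baseline_sd = c(0.15, 3500, 12000, 0.04, 0.02, 0.04, 0.03,
                    0.03, 0.6, 0.05, 0.04)
  )
}

#' Cohort specification
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param age_range Length-2 numeric, min < max, in years.
#' @param male_fraction Probability a subject is male.
#' @param effects Tibble of effect rows (see [effect_spec()],
#'   [default_effect_table()]).
#' @param networks Network labels to generate.
#' @param seed Integer seed; identical spec + seed reproduce the table
#'   byte-identically.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 88, age_range = c(8, 19),
                        male_fraction = 42 / 88,
                        effects = default_effect_table(),
                        networks = yeo7_networks(), seed = 1L) {
  if (!is_scalar_number(n_subjects) || n_subjects < 3) {
    abort("n_subjects must be >= 3")
  }
  if (length(age_range) != 2L || !(age_range[1] < age_range[2])) {
    abort("age_range must be (min, max) with min < max")
  }
  if (!is_scalar_number(male_fraction) || male_fraction < 0 || male_fraction > 1) {
    abort("male_fraction must lie in [0, 1]")
  }
  effects <- as_tibble(effects)
  needed <- c("network", "metric", "beta_age")
  if (!all(needed %in% names(effects))) {
    abort("effects must have columns network, metric, beta_age")
  }
  effects$beta_sex <- effects$beta_sex %||% 0
  if (is.null(effects$r2_target)) {
    effects$r2_target <- effects$beta_age^2 + effects$beta_sex^2 * 0.25
  }
  # re-validate each row through effect_spec()
  for (i in seq_len(nrow(effects))) {
    effect_spec(effects$network[i], effects$metric[i], effects$beta_age[i],
                effects$beta_sex[i], effects$r2_target[i])
  }
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
         male_fraction = male_fraction, effects = effects,
         networks = networks, seed = seed),
    class = "cohort_spec")
}

# Standardized linear signal + noise with unit total variance:
# beta_age * z(age) + beta_sex * sex_contrast + N(0, 1 - r2).
# The sample-standardized slope estimator is the Pearson correlation, whose
# expectation is shrunk by a factor ~ (1 - (1 - rho^2) / (2n)); the generating
# slope is inflated by the first-order inverse so that the mean *recovered*
# standardized slope equals beta_age, which is the generator's contract.
std_linear_component <- function(zage, sexc, beta_age, beta_sex, r2) {
  noise_var <- 1 - r2
  if (noise_var < -1e-8) abort("effect specification implies negative noise variance")
  n <- length(zage)
  beta_eff <- beta_age * (1 + (1 - beta_age^2) / (2 * n))
  beta_eff * zage + beta_sex * sexc +
    rnorm(n, 0, sqrt(max(noise_var, 0)))
}

# Pubertal development score: monotone noisy function of age, rounded to the
# 1-5 scale. The latent-noise SD (0.68) is calibrated once so that, for the
# default 8-19 y range at n = 88, a linear regression of pds on age has
# expected R^2 of about 0.72.
generate_pds <- function(age, age_range) {
  slope <- 4 / diff(age_range)
  latent <- 1 + (age - age_range[1]) * slope + rnorm(length(age), 0, 0.68)
  pmin(pmax(round(latent), 1), 5)
}

#' Generate a synthetic imaging cohort table
#'
#' Draws ages uniformly over the specified range, assigns sex by
#' `male_fraction`, generates a pubertal stage score as a monotone noisy
#' function of age, and generates one value per subject x network x metric.
#' Non-compositional metrics follow
#' `value = baseline_mean + baseline_sd * (beta_age * z(age) + beta_sex * sex +
#' noise)` with noise scaled so the expected adjusted R-squared of the age
#' model equals `r2_target`. The three tissue signal fractions are generated
#' jointly on the 2-simplex by a multiplicative (stick-breaking)
#' logistic-normal: the `f_neurite` effect drives `logit(f_neurite)` and the
#' `f_soma`/`f_extracellular` effects drive the split of the remainder, so
#' the three fractions sum to 1 exactly on every row.
#'
#' @param spec A [cohort_spec()].
#' @return Long tibble with columns `subject_id`, `age`, `sex`, `pds`,
#'   `network`, `metric`, `value`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- ifelse(runif(n) < spec$male_fraction, "M", "F")
    pds <- generate_pds(age, spec$age_range)
    zage <- zscore(age, "age")
    sexc <- sex_contrast(sex)

    fractions <- c("f_neurite", "f_soma", "f_extracellular")
    metrics <- sort(unique(c(setdiff(spec$effects$metric, fractions))))
    baselines <- default_metric_baselines()

    lookup <- function(network, metric) {
      row <- spec$effects[spec$effects$network == network &
                            spec$effects$metric == metric, ]
      base <- baselines[baselines$metric == metric, ]
      any_row <- spec$effects[spec$effects$metric == metric, ]
      bm <- if (nrow(row) && is.finite(row$baseline_mean[1])) row$baseline_mean[1]
            else if (nrow(any_row) && any(is.finite(any_row$baseline_mean)))
              any_row$baseline_mean[is.finite(any_row$baseline_mean)][1]
            else if (nrow(base)) base$baseline_mean else 0
      bs <- if (nrow(row) && is.finite(row$baseline_sd[1])) row$baseline_sd[1]
            else if (nrow(any_row) && any(is.finite(any_row$baseline_sd)))
              any_row$baseline_sd[is.finite(any_row$baseline_sd)][1]
            else if (nrow(base)) base$baseline_sd else 1
      list(beta_age = if (nrow(row)) row$beta_age[1] else 0,
           beta_sex = if (nrow(row)) row$beta_sex[1] else 0,
           r2 = if (nrow(row)) row$r2_target[1] else 0,
           baseline_mean = bm, baseline_sd = bs)
    }

    out <- vector("list", length(spec$networks))
    for (ni in seq_along(spec$networks)) {
      network <- spec$networks[ni]

      # --- signal fractions on the simplex (exact closure) ---------------
      en <- lookup(network, "f_neurite")
      es <- lookup(network, "f_soma")
      ee <- lookup(network, "f_extracellular")
      lin_n <- std_linear_component(zage, sexc, en$beta_age, en$beta_sex, en$r2)
      b2_age <- es$beta_age - ee$beta_age
      b2_sex <- es$beta_sex - ee$beta_sex
      r2_2 <- min(b2_age^2 + b2_sex^2 * 0.25, 0.95)
      lin_2 <- std_linear_component(zage, sexc, b2_age, b2_sex, r2_2)
      b_n <- en$baseline_mean
      w0 <- es$baseline_mean / (es$baseline_mean + ee$baseline_mean)
      s1 <- en$baseline_sd / (b_n * (1 - b_n))
      s2 <- es$baseline_sd / ((1 - b_n) * w0 * (1 - w0))
      f_n <- plogis(qlogis(b_n) + s1 * lin_n)
      w <- plogis(qlogis(w0) + s2 * lin_2)
      f_s <- (1 - f_n) * w
      f_e <- (1 - f_n) * (1 - w)

      vals <- list(f_neurite = f_n, f_soma = f_s, f_extracellular = f_e)

      # --- remaining metrics on their native scale -----------------------
      for (metric in metrics) {
        e <- lookup(network, metric)
        lin <- std_linear_component(zage, sexc, e$beta_age, e$beta_sex, e$r2)
        vals[[metric]] <- e$baseline_mean + e$baseline_sd * lin
      }

      out[[ni]] <- tibble(
        subject_id = rep(sprintf("sub-%03d", seq_len(n)), times = length(vals)),
        age = rep(age, times = length(vals)),
        sex = rep(sex, times = length(vals)),
        pds = rep(pds, times = length(vals)),
        network = network,
        metric = rep(names(vals), each = n),
        value = unlist(vals, use.names = FALSE)
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Repeatability study specification
#'
#' A two-way random-effects generative model for a small test-retest study:
#' `value_ij = mu + subject_i + session_j + error_ij` with independent
#' zero-mean Gaussian components. The implied population ICC is
#' `sigma_subject^2 / (sigma_subject^2 + sigma_session^2 + sigma_error^2)`.
#'
#' @param n_subjects,n_sessions Grid dimensions (each >= 2).
#' @param sigma_subject,sigma_session,sigma_error Component SDs (>= 0).
#' @param mu Grand mean.
#' @param metric Metric label attached to the output rows.
#' @param seed Integer seed.
#' @return An object of class `repeatability_spec`.
#' @export
repeatability_spec <- function(n_subjects = 6, n_sessions = 5,
                               sigma_subject = 1, sigma_session = 0.1,
                               sigma_error = 0.1, mu = 0,
                               metric = "f_neurite", seed = 1L) {
  if (n_subjects < 2 || n_sessions < 2) {
    abort("need at least 2 subjects and 2 sessions (ICC undefined otherwise)")
  }
  sds <- c(sigma_subject, sigma_session, sigma_error)
  if (any(sds < 0)) abort("variance-component SDs must be >= 0")
  structure(
    list(n_subjects = as.integer(n_subjects), n_sessions = as.integer(n_sessions),
         sigma_subject = sigma_subject, sigma_session = sigma_session,
         sigma_error = sigma_error, mu = mu, metric = metric, seed = seed),
    class = "repeatability_spec")
}

#' Population ICC implied by a repeatability specification
#'
#' @param spec A [repeatability_spec()].
#' @return The variance ratio `sigma_s^2 / (sigma_s^2 + sigma_sess^2 + sigma_e^2)`.
#' @export
implied_icc <- function(spec) {
  stopifnot(inherits(spec, "repeatability_spec"))
  v <- c(spec$sigma_subject, spec$sigma_session, spec$sigma_error)^2
  if (sum(v) == 0) abort("all variance components are zero; ICC undefined")
  v[1] / sum(v)
}

#' Generate a synthetic session-indexed repeatability table
#'
#' @param spec A [repeatability_spec()].
#' @return Long tibble with columns `subject_id`, `session`, `metric`, `value`
#'   over the complete subject x session grid.
#' @export
generate_repeatability <- function(spec) {
  stopifnot(inherits(spec, "repeatability_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    k <- spec$n_sessions
    b <- rnorm(n, 0, spec$sigma_subject)
    s <- rnorm(k, 0, spec$sigma_session)
    e <- rnorm(n * k, 0, spec$sigma_error)
    grid <- expand.grid(subject = seq_len(n), session = seq_len(k))
    tibble(
      subject_id = sprintf("sub-%02d", grid$subject),
      session = as.integer(grid$session),
      metric = spec$metric,
      value = spec$mu + b[grid$subject] + s[grid$session] + e
    )
  })
}
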