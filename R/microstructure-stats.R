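# Network-level statistics: standardized linear models, AIC model selection,
# fixed-alpha significance flagging, and two-way random-effects absolute
# agreement ICC.

# Build the standardized model frame for one network x metric: one row per
# subject, outcome z-scored, age/pds z-scored, sex coded +/-0.5.
standardized_frame <- function(table, metric, network) {
  rows <- table[table$metric == metric & table$network == network, ]
  rows <- rows[!duplicated(rows$subject_id), ]
  if (nrow(rows) < 10) {
    abort(sprintf("fewer than 10 rows for %s/%s after filtering", network, metric))
  }
  if (stats::sd(rows$value) == 0) {
    abort(sprintf("constant outcome for %s/%s: degenerate fit", network, metric))
  }
  out <- tibble(
    subject_id = rows$subject_id,
    y = zscore(rows$value, metric),
    age = zscore(rows$age, "age"),
    sex = sex_contrast(rows$sex)
  )
  if (!is.null(rows$pds) && stats::sd(rows$pds) > 0) out$pds <- zscore(rows$pds, "pds")
  out
}

term_formula <- function(terms) {
  stats::reformulate(terms, response = "y")
}

#' Fit a standardized linear age model for one network and metric
#'
#' Ordinary least squares on the standardized outcome (z-scored per
#' network x metric) with z-scored age and pds and sex coded -0.5/+0.5, so
#' coefficients are standardized effect sizes and the age coefficient of a
#' single-predictor model equals the Pearson correlation. Confidence
#' intervals use t quantiles.
#'
#' @param table A cohort table from [generate_cohort()] (or read from TSV).
#' @param metric,network Labels selecting the outcome.
#' @param terms Character vector of model terms from `age`, `sex`, `pds` and
#'   their interactions (e.g. `c("age", "sex", "sex:pds")`).
#' @param conf_level Confidence level for coefficient intervals.
#' @return An object of class `cortex_model_fit` with elements `terms`
#'   (tibble: `term`, `beta`, `ci_lo`, `ci_hi`, `p`), `adj_r2`, `aic`, `bic`,
#'   `n`, `formula_terms` and `subjects`.
#' @export
fit_age_model <- function(table, metric, network, terms = "age",
                          conf_level = 0.95) {
  df <- standardized_frame(table, metric, network)
  fit <- lm(term_formula(terms), data = df)
  sm <- summary(fit)
  ci <- confint(fit, level = conf_level)
  coefs <- sm$coefficients
  keep <- setdiff(rownames(coefs), "(Intercept)")
  res <- tibble(
    term = keep,
    beta = coefs[keep, "Estimate"],
    ci_lo = ci[keep, 1],
    ci_hi = ci[keep, 2],
    p = coefs[keep, "Pr(>|t|)"]
  )
  structure(
    list(terms = res, adj_r2 = sm$adj.r.squared, aic = AIC(fit), bic = BIC(fit),
         n = nrow(df), formula_terms = terms, metric = metric,
         network = network, subjects = sort(df$subject_id), lm = fit),
    class = "cortex_model_fit")
}

#' @export
print.cortex_model_fit <- function(x, ...) {
  cat(sprintf("<cortex_model_fit> %s / %s (n = %d)\n", x$network, x$metric, x$n))
  cat(sprintf("  terms: %s\n", paste(x$formula_terms, collapse = " + ")))
  print(as.data.frame(x$terms), digits = 3)
  cat(sprintf("  adj R^2 = %.3f, AIC = %.2f, BIC = %.2f\n",
              x$adj_r2, x$aic, x$bic))
  invisible(x)
}

#' Tidy a standardized model fit into one row per term
#'
#' @param fit A `cortex_model_fit`.
#' @return Tibble with `network`, `metric`, `term`, `beta`, `ci_lo`, `ci_hi`,
#'   `p`, `adj_r2`, `aic`, `bic`, `n`.
#' @export
tidy_model_fit <- function(fit) {
  stopifnot(inherits(fit, "cortex_model_fit"))
  dplyr::mutate(fit$terms, network = fit$network, metric = fit$metric,
                adj_r2 = fit$adj_r2, aic = fit$aic, bic = fit$bic, n = fit$n,
                .before = 1)
}

#' Select among candidate models by AIC
#'
#' Fits every candidate term set on the same rows and returns the candidate
#' with the lowest AIC. Ties (within `tie_tol`) are broken in favour of the
#' model with fewer parameters, then by listed order.
#'
#' @param table,metric,network As in [fit_age_model()].
#' @param candidates List of character vectors of model terms (>= 2).
#' @param tie_tol Absolute AIC difference treated as a tie.
#' @return List with `terms` (the winning term set), `fit` (its
#'   `cortex_model_fit`), and `aic_table` (tibble of candidate AICs).
#' @export
select_model_aic <- function(table, metric, network, candidates,
                             tie_tol = 1e-8) {
  if (length(candidates) < 2) abort("need at least 2 candidate models")
  fits <- lapply(candidates, function(tm) fit_age_model(table, metric, network, tm))
  subj <- lapply(fits, `[[`, "subjects")
  if (!all(vapply(subj, identical, logical(1), y = subj[[1]]))) {
    abort("candidates were fit on differing row sets; AIC not comparable")
  }
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  npar <- vapply(candidates, length, integer(1))
  best <- which(aic <= min(aic) + tie_tol)
  best <- best[order(npar[best], best)][1]
  list(
    terms = candidates[[best]],
    fit = fits[[best]],
    aic_table = tibble(
      model = vapply(candidates, paste, character(1), collapse = " + "),
      n_terms = npar, aic = aic, selected = seq_along(aic) == best)
  )
}

#' Flag term-level significance at a fixed alpha
#'
#' Applies the strict rule `p < alpha` (a p-value exactly equal to alpha is
#' not significant).
#'
#' @param fits A `cortex_model_fit`, a list of them, or any data frame with a
#'   `p` column.
#' @param alpha Significance threshold (default 0.005).
#' @return The input with a logical `significant` flag added (for fits, on the
#'   `terms` tibble).
#' @export
flag_significance <- function(fits, alpha = 0.005) {
  if (is.data.frame(fits)) {
    if (!"p" %in% names(fits)) abort("data frame must contain a 'p' column")
    fits$significant <- fits$p < alpha
    return(fits)
  }
  if (inherits(fits, "cortex_model_fit")) {
    fits$terms$significant <- fits$terms$p < alpha
    return(fits)
  }
  if (is.list(fits)) return(lapply(fits, flag_significance, alpha = alpha))
  abort("unsupported input to flag_significance()")
}

#' Fit standardized age models across networks and metrics
#'
#' Convenience scan used by the pipeline: fits one model per network x metric
#' and returns the tidy stacked results with significance flags.
#'
#' @param table Cohort table.
#' @param metrics,networks Labels to scan (defaults: all present).
#' @param terms Model terms (see [fit_age_model()]).
#' @param alpha Significance threshold for [flag_significance()].
#' @return Tidy tibble, one row per network x metric x term.
#' @export
fit_networks <- function(table, metrics = unique(table$metric),
                         networks = unique(table$network), terms = "age",
                         alpha = 0.005) {
  res <- list()
  for (m in metrics) {
    for (nw in networks) {
      res[[paste(m, nw)]] <- tidy_model_fit(fit_age_model(table, m, nw, terms))
    }
  }
  flag_significance(dplyr::bind_rows(res), alpha = alpha)
}

#' Two-way random-effects absolute-agreement ICC
#'
#' Single-measure intraclass correlation ICC(2,1) from the two-way ANOVA mean
#' squares of a complete subject x session grid:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))` where MSR, MSC
#' and MSE are the subject, session and residual mean squares. Negative
#' estimates are returned as computed and flagged, not clipped.
#'
#' @param table Session-indexed table with `subject_id`, `session`, `metric`,
#'   `value` (see [generate_repeatability()]).
#' @param metric Metric to analyse.
#' @return An object of class `icc_result`: list with `icc`, `msr`, `msc`,
#'   `mse`, `n`, `k`, `negative`.
#' @export
icc_absolute_agreement <- function(table, metric = unique(table$metric)[1]) {
  rows <- table[table$metric == metric, ]
  if (!nrow(rows)) abort(sprintf("no rows for metric '%s'", metric))
  tab <- table(rows$subject_id, rows$session)
  if (any(tab != 1)) {
    abort("incomplete subject x session grid: ICC requires one value per cell")
  }
  wide <- tapply(rows$value, list(rows$subject_id, rows$session), identity)
  n <- nrow(wide)
  k <- ncol(wide)
  grand <- mean(wide)
  row_means <- rowMeans(wide)
  col_means <- colMeans(wide)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((wide - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (denom == 0) 1 else (msr - mse) / denom
  structure(
    list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k,
         negative = icc < 0),
    class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.4f (n = %d subjects, k = %d sessions)%s\n",
              x$icc, x$n, x$k, if (x$negative) " [negative estimate]" else ""))
  invisible(x)
}
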