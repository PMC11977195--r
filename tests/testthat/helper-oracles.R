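# Independent brute-force oracles and small fixture builders, kept free of
# the code paths they check.

# Benjamini-Hochberg step-up, written directly from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# One-sided (enrichment) Fisher p as an explicit hypergeometric tail sum:
# P(X >= a) for X = |query & set| with margins (a+b, c+d) and draw a+c.
hyper_tail_oracle <- function(a, b, c_, d) {
  n_set <- a + b
  n_other <- c_ + d
  n_query <- a + c_
  total <- choose(n_set + n_other, n_query)
  x <- a:min(n_set, n_query)
  sum(choose(n_set, x) * choose(n_other, n_query - x)) / total
}

# ICC(2,1) from explicit double-loop ANOVA sums of squares on an n x k matrix.
icc_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  ssr <- ssc <- sse <- 0
  for (i in seq_len(n)) {
    ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  }
  for (j in seq_len(k)) {
    ssc <- ssc + n * (mean(m[, j]) - grand)^2
  }
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
    }
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Gaussian AIC of a least-squares fit, from the closed form
# n log(2 pi RSS / n) + n + 2 (npar + 1).
aic_oracle <- function(y, X) {
  fit <- lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  npar <- ncol(X) + 1
  n * log(2 * pi * rss / n) + n + 2 * (npar + 1)
}

# Minimal single-gene expression dataset around explicit (age, y) pairs.
make_gene_dataset <- function(age, y, gene = "G1") {
  n <- length(age)
  structure(
    list(
      expr = matrix(y, 1, n, dimnames = list(gene, sprintf("s%04d", seq_len(n)))),
      samples = tibble::tibble(
        sample_id = sprintf("s%04d", seq_len(n)),
        donor = sprintf("d%04d", seq_len(n)),
        age = age, region = "DLPFC",
        sex = rep(c("F", "M"), length.out = n), rin = 8),
      scale = "normalized", dialect = "single_region_normalized",
      catalog = NULL),
    class = "expression_dataset")
}

# Catalog of all-flat genes (pure-noise expression after generation).
flat_catalog <- function(n_genes, regions = cortical_regions()) {
  cat_ <- tibble::tibble(
    gene = sprintf("NULL_%03d", seq_len(n_genes)),
    cell_type = rep(cortical_cell_types(), length.out = n_genes),
    shape = "flat", midpoint_age = NA_real_, rate = 0, amplitude = 0,
    baseline = 3)
  for (r in regions) cat_[[paste0("offset_", r)]] <- 0
  cat_
}

# Cohort-style long table built from explicit per-subject values.
make_cohort_table <- function(age, value, sex = rep(c("F", "M"), length.out = length(age)),
                              pds = NULL, metric = "CTh", network = "default_mode") {
  n <- length(age)
  tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    age = age, sex = sex,
    pds = pds %||% pmin(pmax(round(1 + (age - min(age)) / diff(range(age)) * 4), 1), 5),
    network = network, metric = metric, value = value)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
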