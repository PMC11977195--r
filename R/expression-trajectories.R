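# Per-gene penalized-spline age modelling, FDR gene discovery, cell-type
# trajectory summaries, peak-growth/crossover estimators, and Fisher-test
# gene-set enrichment.

#' Fit a penalized-spline age trajectory for one gene
#'
#' Models expression against age with a rank-`k` thin-plate regression spline
#' (second-derivative penalty; linear trends unpenalized), the smoothing
#' parameter chosen by GCV by default. For the multi-region RNA-seq dialect,
#' RIN, sex and region enter as linear/factor confounders and donor as a
#' ridge-penalized random intercept; the single-region normalized dialect
#' uses the smooth alone. The reported p-value is the approximate F-test of
#' the age smooth against the covariate-only null.
#'
#' @param dataset An `expression_dataset` (see [generate_expression()]).
#' @param gene Gene symbol (row of `dataset$expr`).
#' @param k Spline basis dimension (default 5).
#' @param method Smoothness-selection criterion passed to [mgcv::gam()]
#'   (`"GCV.Cp"` default; `"REML"` available).
#' @param sp Optional fixed smoothing parameter(s); `sp = 0` with `k >= n`
#'   interpolates the data.
#' @param by_region If `TRUE` (multi-region dialect), fit region-specific age
#'   smooths sharing one smoothing parameter (`by = region, id = 1`) instead
#'   of a single shared smooth.
#' @param grid_step Age-grid resolution in years (default 0.1).
#' @param predict_region Region at which the fitted curve/derivative grid is
#'   evaluated (multi-region dialect; default: first region level).
#' @return An object of class `age_spline_fit`: list with `gene`, `grid`
#'   (tibble `age`, `fit`, `deriv`), `p`, `edf`, `sp`, `aic`, `bic`, `n`,
#'   `k`, and the underlying `gam` object.
#' @export
fit_age_spline <- function(dataset, gene, k = 5, method = "GCV.Cp", sp = NULL,
                           by_region = FALSE, grid_step = 0.1,
                           predict_region = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!gene %in% rownames(dataset$expr)) {
    abort(sprintf("gene '%s' not present in dataset", gene))
  }
  s <- dataset$samples
  df <- data.frame(
    expr = dataset$expr[gene, ],
    age = s$age,
    rin = s$rin,
    sex = factor(s$sex),
    region = factor(s$region),
    donor = factor(s$donor)
  )
  if (nrow(df) < k) abort(sprintf("need at least k = %d samples", k))
  if (length(unique(df$age)) < 2) abort("singular design: a single distinct age")

  multi <- dataset$dialect == "multi_region_rpkm"
  smooth_term <- if (by_region && multi && nlevels(df$region) > 1) {
    sprintf("s(age, k = %d, bs = 'tp', by = region, id = 1)", k)
  } else {
    sprintf("s(age, k = %d, bs = 'tp')", k)
  }
  terms <- smooth_term
  if (multi) {
    terms <- c(terms, "rin")
    if (nlevels(df$sex) > 1) terms <- c(terms, "sex")
    if (nlevels(df$region) > 1) terms <- c(terms, "region")
    if (anyDuplicated(df$donor)) terms <- c(terms, "s(donor, bs = 're')")
  }
  fml <- stats::as.formula(paste("expr ~", paste(terms, collapse = " + ")))
  args <- list(formula = fml, data = df, method = method)
  if (!is.null(sp)) {
    nsm <- sum(grepl("^s\\(", terms)) + if (by_region && multi) nlevels(df$region) - 1 else 0
    args$sp <- rep(sp, length.out = max(nsm, 1))
  }
  fit <- do.call(mgcv::gam, args)

  ages <- seq(min(df$age), max(df$age), by = grid_step)
  nd <- data.frame(
    age = ages,
    rin = mean(df$rin),
    sex = factor(levels(df$sex)[1], levels = levels(df$sex)),
    region = factor(predict_region %||% levels(df$region)[1],
                    levels = levels(df$region)),
    donor = factor(levels(df$donor)[1], levels = levels(df$donor))
  )
  excl <- if ("s(donor, bs = 're')" %in% terms) "s(donor)" else NULL
  pred <- as.numeric(predict(fit, nd, exclude = excl))
  h <- 1e-3
  x1 <- predict(fit, transform(nd, age = age + h), type = "lpmatrix")
  x0 <- predict(fit, transform(nd, age = age - h), type = "lpmatrix")
  deriv <- as.numeric(((x1 - x0) %*% coef(fit)) / (2 * h))

  # zero-residual-df fits (k >= n, sp = 0) yield NaN p-values, legitimately
  st <- suppressWarnings(summary(fit))$s.table
  age_rows <- grepl("^s\\(age", rownames(st))
  p <- if (any(age_rows)) min(st[age_rows, "p-value"]) else NA_real_
  edf <- if (any(age_rows)) sum(st[age_rows, "edf"]) else NA_real_

  structure(
    list(gene = gene, grid = tibble(age = ages, fit = pred, deriv = deriv),
         p = p, edf = edf, sp = fit$sp, aic = AIC(fit), bic = BIC(fit),
         n = nrow(df), k = k, gam = fit),
    class = "age_spline_fit")
}

#' @export
print.age_spline_fit <- function(x, ...) {
  cat(sprintf("<age_spline_fit> %s: edf = %.2f, p = %.3g, AIC = %.1f (n = %d)\n",
              x$gene, x$edf, x$p, x$aic, x$n))
  invisible(x)
}

#' Fit age splines for a set of genes
#'
#' @inheritParams fit_age_spline
#' @param genes Gene symbols (default: all rows of the dataset).
#' @param ... Passed to [fit_age_spline()].
#' @return Named list of `age_spline_fit` objects.
#' @export
fit_age_splines <- function(dataset, genes = rownames(dataset$expr), ...) {
  fits <- lapply(genes, function(g) fit_age_spline(dataset, g, ...))
  names(fits) <- genes
  fits
}

# Extract the per-gene smooth-term p-values from fits or a (gene, p) table.
gene_pvalues <- function(fits) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("gene", "p") %in% names(fits)))
    return(tibble(gene = fits$gene, p = fits$p))
  }
  tibble(
    gene = vapply(fits, `[[`, character(1), "gene"),
    p = vapply(fits, `[[`, numeric(1), "p")
  )
}

#' Select age-associated genes by Benjamini-Hochberg FDR
#'
#' Applies the BH step-up procedure across all fitted genes and selects those
#' with adjusted q below `alpha`.
#'
#' @param fits Named list of `age_spline_fit` objects (from
#'   [fit_age_splines()]) or a data frame with columns `gene` and `p`.
#' @param alpha FDR level (default 0.05).
#' @return Tibble with `gene`, `p`, `q`, `selected`, ordered as supplied.
#' @export
select_age_genes <- function(fits, alpha = 0.05) {
  pv <- gene_pvalues(fits)
  if (!nrow(pv)) abort("no fitted genes supplied")
  pv$q <- p.adjust(pv$p, method = "BH")
  pv$selected <- pv$q < alpha
  pv
}

#' Cross-dataset replication overlap
#'
#' @param discovery Character vector of genes selected in the discovery
#'   dataset (non-empty).
#' @param validation Character vector of genes selected in the validation
#'   dataset.
#' @return List with `count` (intersection size) and `proportion`
#'   (`count / length(discovery)`, reported to 3 significant figures).
#' @export
replication_overlap <- function(discovery, validation) {
  discovery <- unique(discovery)
  validation <- unique(validation)
  if (!length(discovery)) abort("empty discovery set")
  count <- length(intersect(discovery, validation))
  list(count = count, proportion = signif(count / length(discovery), 3))
}

# Subset an expression dataset to one region (multi-region dialect).
subset_expression_region <- function(dataset, region) {
  keep <- dataset$samples$region == region
  if (!any(keep)) abort(sprintf("no samples in region '%s'", region))
  structure(
    list(expr = dataset$expr[, keep, drop = FALSE],
         samples = dataset$samples[keep, ],
         scale = dataset$scale, dialect = dataset$dialect,
         catalog = dataset$catalog),
    class = "expression_dataset")
}

#' Mean cell-type expression trajectory
#'
#' Fits a penalized age spline per gene of the given cell type, evaluates all
#' fitted curves on a common age grid, optionally normalizes each gene's
#' curve (z-score or demean across the grid) to remove overall expression
#' level differences, and averages across genes with a 95% band
#' (`mean +/- 1.96 SE` across genes). When `region` is given for the
#' multi-region dialect, only that region's samples are used so regional
#' timing is preserved.
#'
#' @param dataset An `expression_dataset`.
#' @param catalog Gene catalog with `gene` and `cell_type` columns.
#' @param cell_type One of the catalog's cell types.
#' @param region Optional region label (multi-region dialect).
#' @param normalize `"z"` (default), `"demean"`, or `"none"`.
#' @param k,method,grid_step Passed to [fit_age_spline()].
#' @return An object of class `celltype_trajectory`: list with `cell_type`,
#'   `region`, `n_genes`, `normalize` and `grid` (tibble `age`, `mean`, `lo`,
#'   `hi`, `deriv`).
#' @export
celltype_trajectory <- function(dataset, catalog, cell_type, region = NULL,
                                normalize = c("z", "demean", "none"),
                                k = 5, method = "GCV.Cp", grid_step = 0.1) {
  normalize <- match.arg(normalize)
  if (!cell_type %in% catalog$cell_type) {
    abort(sprintf("unknown cell type '%s'", cell_type))
  }
  genes <- intersect(catalog$gene[catalog$cell_type == cell_type],
                     rownames(dataset$expr))
  if (!length(genes)) {
    abort(sprintf("no genes of cell type '%s' present in dataset", cell_type))
  }
  ds <- if (!is.null(region)) subset_expression_region(dataset, region) else dataset
  fits <- fit_age_splines(ds, genes, k = k, method = method,
                          grid_step = grid_step)
  ages <- fits[[1]]$grid$age
  curves <- vapply(fits, function(f) f$grid$fit, numeric(length(ages)))
  derivs <- vapply(fits, function(f) f$grid$deriv, numeric(length(ages)))
  curves <- matrix(curves, nrow = length(ages))
  derivs <- matrix(derivs, nrow = length(ages))
  if (normalize != "none") {
    for (j in seq_len(ncol(curves))) {
      mu <- mean(curves[, j])
      if (normalize == "z") {
        sdev <- stats::sd(curves[, j])
        if (sdev < 1e-12) {        # constant curve: normalized curve is 0
          curves[, j] <- 0
          derivs[, j] <- 0
        } else {
          curves[, j] <- (curves[, j] - mu) / sdev
          derivs[, j] <- derivs[, j] / sdev
        }
      } else {
        curves[, j] <- curves[, j] - mu
      }
    }
  }
  m <- rowMeans(curves)
  se <- apply(curves, 1, stats::sd) / sqrt(ncol(curves))
  structure(
    list(cell_type = cell_type, region = region %||% "pooled",
         n_genes = length(genes), normalize = normalize,
         grid = tibble(age = ages, mean = m, lo = m - 1.96 * se,
                       hi = m + 1.96 * se, deriv = rowMeans(derivs))),
    class = "celltype_trajectory")
}

#' @export
print.celltype_trajectory <- function(x, ...) {
  cat(sprintf("<celltype_trajectory> %s in %s: %d genes, ages %.1f-%.1f y (%s)\n",
              x$cell_type, x$region, x$n_genes, min(x$grid$age),
              max(x$grid$age), x$normalize))
  invisible(x)
}

#' Age of peak expression growth
#'
#' Returns the age at the global maximum of the trajectory's first
#' derivative. Ties are broken toward the earliest age; a maximum at either
#' end of the grid is flagged as boundary-censored; a flat trajectory
#' (derivative within `tol` of zero everywhere) yields `NA`.
#'
#' @param traj A `celltype_trajectory` or `age_spline_fit` (anything with a
#'   `grid` tibble holding `age` and `deriv`).
#' @param tol Absolute derivative below which the curve counts as flat.
#' @return One-row tibble with `age`, `censored`, `flat`.
#' @export
peak_growth_age <- function(traj, tol = 1e-8) {
  g <- traj$grid
  if (max(abs(g$deriv)) < tol) {
    return(tibble(age = NA_real_, censored = FALSE, flat = TRUE))
  }
  i <- which(g$deriv >= max(g$deriv) - .Machine$double.eps^0.5 * abs(max(g$deriv)))[1]
  tibble(age = g$age[i], censored = i == 1L || i == nrow(g), flat = FALSE)
}

#' Astrocyte-to-oligodendrocyte expression-ratio crossover age
#'
#' Finds the first age at which the mean oligodendrocyte trajectory rises
#' above the mean astrocyte trajectory: the first grid interval where their
#' difference changes sign from negative to non-negative, refined by linear
#' interpolation between the bracketing grid points. No extrapolation: if the
#' curves never cross on the grid the crossover is `NA`.
#'
#' @param traj_oligo,traj_astro `celltype_trajectory` objects on the same age
#'   grid and region.
#' @return One-row tibble with `region` and `crossover_age` (`NA` if none).
#' @export
expression_ratio_crossover <- function(traj_oligo, traj_astro) {
  go <- traj_oligo$grid
  ga <- traj_astro$grid
  if (nrow(go) != nrow(ga) || max(abs(go$age - ga$age)) > 1e-8) {
    abort("trajectories are on mismatched age grids")
  }
  if (!identical(traj_oligo$region, traj_astro$region)) {
    abort("trajectories come from different regions")
  }
  d <- go$mean - ga$mean
  idx <- which(d[-length(d)] < 0 & d[-1] >= 0)
  if (!length(idx)) {
    return(tibble(region = traj_oligo$region, crossover_age = NA_real_))
  }
  i <- idx[1]
  a <- go$age[i] + (go$age[i + 1] - go$age[i]) * (-d[i]) / (d[i + 1] - d[i])
  tibble(region = traj_oligo$region, crossover_age = a)
}

#' Gene-set enrichment by one-sided Fisher's exact test
#'
#' For each annotation set, tests over-representation of the query genes with
#' a one-sided (greater) Fisher's exact test on the 2x2 overlap table against
#' the background universe, then applies Benjamini-Hochberg correction across
#' all sets. Sets with `q < q_alpha` (default 0.001) are flagged.
#'
#' @param query Character vector of genes of interest (subset of
#'   `background`).
#' @param annotation Named list of gene sets (each a subset of `background`),
#'   e.g. read from GMT via [read_gmt()].
#' @param background Character vector: the gene universe.
#' @param q_alpha Flagging threshold on BH-adjusted q.
#' @return Tibble with one row per set: 2x2 counts (`overlap`, `set_only`,
#'   `query_only`, `neither`), `odds_ratio` (conditional MLE), `p`, `q`,
#'   `significant`.
#' @export
enrichment_test <- function(query, annotation, background, q_alpha = 0.001) {
  background <- unique(background)
  if (!length(background)) abort("empty background universe")
  query <- unique(query)
  if (length(setdiff(query, background))) {
    abort("query contains genes outside the background universe")
  }
  res <- lapply(names(annotation), function(nm) {
    set <- unique(annotation[[nm]])
    if (length(setdiff(set, background))) {
      abort(sprintf("annotation set '%s' contains genes outside the background", nm))
    }
    a <- length(intersect(query, set))
    b <- length(set) - a
    c_ <- length(query) - a
    d <- length(background) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2), alternative = "greater")
    tibble(set = nm, overlap = a, set_only = b, query_only = c_, neither = d,
           odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- dplyr::bind_rows(res)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_alpha
  out
}

#' Default postnatal developmental stage windows
#'
#' @return Tibble with `stage`, `age_min`, `age_max` (years): infancy 0-1,
#'   childhood 1-12, adolescence 12-20, young adulthood 20-40.
#' @export
default_stage_windows <- function() {
  tibble(
    stage = c("infancy", "childhood", "adolescence", "young_adulthood"),
    age_min = c(0, 1, 12, 20),
    age_max = c(1, 12, 20, 40)
  )
}

#' Count age-genes active in each developmental stage, by cell type
#'
#' A gene overlaps a stage when the absolute value of its fitted age
#' derivative exceeds `activity_threshold` anywhere inside the stage's age
#' window (intersected with the fitted grid). Returns counts and within-stage
#' proportions per cell type.
#'
#' @param age_genes Character vector of selected genes, or the tibble from
#'   [select_age_genes()] (its `selected` rows are used).
#' @param catalog Gene catalog with `gene`, `cell_type`.
#' @param fits Named list of `age_spline_fit` objects covering the genes.
#' @param stage_windows Tibble of disjoint windows
#'   (see [default_stage_windows()]).
#' @param activity_threshold Minimum |derivative| (expression units / year)
#'   for a gene to count as active.
#' @return Tibble with `stage`, `cell_type`, `n_genes`, `proportion` (within
#'   stage).
#' @export
stage_gene_counts <- function(age_genes, catalog, fits,
                              stage_windows = default_stage_windows(),
                              activity_threshold = 0.01) {
  if (is.data.frame(age_genes)) age_genes <- age_genes$gene[age_genes$selected]
  sw <- stage_windows[order(stage_windows$age_min), ]
  if (nrow(sw) > 1 && any(sw$age_min[-1] < sw$age_max[-nrow(sw)] - 1e-12)) {
    abort("stage windows overlap; they must be disjoint age intervals")
  }
  rows <- list()
  for (si in seq_len(nrow(sw))) {
    active_types <- character(0)
    for (g in age_genes) {
      f <- fits[[g]]
      if (is.null(f)) abort(sprintf("no fit supplied for gene '%s'", g))
      idx <- f$grid$age >= sw$age_min[si] & f$grid$age <= sw$age_max[si]
      if (any(idx) && any(abs(f$grid$deriv[idx]) > activity_threshold)) {
        ct <- catalog$cell_type[match(g, catalog$gene)]
        active_types <- c(active_types, ct)
      }
    }
    total <- length(active_types)
    for (ct in unique(catalog$cell_type)) {
      n <- sum(active_types == ct)
      rows[[paste(si, ct)]] <- tibble(
        stage = sw$stage[si], cell_type = ct, n_genes = n,
        proportion = if (total > 0) n / total else 0)
    }
  }
  dplyr::bind_rows(rows)
}
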