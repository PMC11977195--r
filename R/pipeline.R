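# End-to-end orchestration: simulate -> fit -> summarize, with a
# machine-readable manifest and byte-reproducible outputs.

pipeline_stages <- function() {
  c("cohort", "repeatability", "network_stats", "icc", "expression",
    "age_genes", "trajectories", "crossover", "soma")
}

#' Default pipeline run configuration
#'
#' Returns the full configuration list for [run_pipeline()], with one block
#' per stage. All sizes and parameters mirror the emulated study conditions
#' (an 88-subject imaging cohort aged 8-19, a 6 x 5 repeatability study, a
#' 214-sample single-region and a 20-donor x 11-region expression dataset)
#' and can be overridden per run.
#'
#' @param out_dir Output directory.
#' @param seed Global seed; per-stage sub-seeds are derived from it.
#' @return Named config list.
#' @export
default_run_config <- function(out_dir = "cortexdev-run", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = as.list(pipeline_stages()),
    cohort = list(n_subjects = 88L, age_min = 8, age_max = 19,
                  male_fraction = 42 / 88),
    repeatability = list(n_subjects = 6L, n_sessions = 5L,
                         sigma_subject = sqrt(0.97),
                         sigma_session = sqrt(0.005),
                         sigma_error = sqrt(0.025)),
    network_stats = list(terms = list("age"), alpha = 0.005),
    expression = list(n_per_type = 20L, n_samples = 214L, n_donors = 20L,
                      noise_sd = 0.4, alpha = 0.05),
    trajectories = list(normalize = "z"),
    crossover = list(regions = list("M1", "V1", "DLPFC", "MFC")),
    soma = list(ages = as.list(8:19), n_samples = 100000L,
                calibration = 0.015, ref_age = 8)
  )
}

#' Validate a pipeline configuration
#'
#' @param config Config list (see [default_run_config()]).
#' @return The config, completed with defaults, or an error describing the
#'   violated field.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) abort("config must be a list")
  full <- default_run_config()
  unknown <- setdiff(names(config), names(full))
  if (length(unknown)) {
    abort(sprintf("unknown config block(s): %s", paste(unknown, collapse = ", ")))
  }
  # merge named parameter blocks field-by-field; replace unnamed list fields
  # (stages, region/age lists) wholesale
  merge_config <- function(base, override) {
    for (nm in names(override)) {
      if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
          length(names(base[[nm]])) && all(names(base[[nm]]) != "")) {
        base[[nm]] <- merge_config(base[[nm]], override[[nm]])
      } else {
        base[[nm]] <- override[[nm]]
      }
    }
    base
  }
  config <- merge_config(full, config)
  if (!is_scalar_number(config$seed)) abort("config$seed must be one integer")
  bad <- setdiff(unlist(config$stages), pipeline_stages())
  if (length(bad)) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  if (config$cohort$n_subjects < 3) abort("cohort$n_subjects must be >= 3")
  if (!(config$cohort$age_min < config$cohort$age_max)) {
    abort("cohort age_min must be < age_max")
  }
  config
}

stage_path <- function(config, name) file.path(config$out_dir, name)

require_upstream <- function(config, file, producer) {
  p <- stage_path(config, file)
  if (!file.exists(p)) {
    abort(sprintf("missing upstream output '%s'; run the '%s' stage first",
                  file, producer))
  }
  p
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order: synthetic data
#' (cohort, repeatability, expression), then network statistics, ICC and
#' per-gene trajectory analyses, then the soma composition sweep. Every
#' stage writes TSV outputs into `config$out_dir`, stamped with the config
#' hash; a `manifest.json` records the config hash, seed, package version
#' and an md5 per output. Re-running with the same config and seed
#' reproduces all outputs byte-identically; with `resume = TRUE`, stages
#' whose outputs already exist are skipped.
#'
#' @param config Config list or path to a YAML config
#'   (see [default_run_config()]).
#' @param resume Skip stages whose outputs are already on disk.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), resume = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific configuration only, not the output location
  hash <- object_md5(config[setdiff(names(config), "out_dir")])
  stages <- unlist(config$stages)
  seeds <- derive_seeds(config$seed, length(pipeline_stages()))
  names(seeds) <- pipeline_stages()
  outputs <- character(0)
  log <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  emit <- function(x, name, stage) {
    p <- stage_path(config, name)
    write_table_tsv(x, p, hash)
    outputs <<- c(outputs, name)
    log(stage, sprintf("wrote %s (%d rows)", name, nrow(x)))
  }
  done <- function(name) resume && file.exists(stage_path(config, name))

  if ("cohort" %in% stages && !done("cohort.tsv")) {
    spec <- cohort_spec(
      n_subjects = config$cohort$n_subjects,
      age_range = c(config$cohort$age_min, config$cohort$age_max),
      male_fraction = config$cohort$male_fraction,
      seed = seeds[["cohort"]])
    emit(generate_cohort(spec), "cohort.tsv", "cohort")
  }

  if ("repeatability" %in% stages && !done("repeatability.tsv")) {
    r <- config$repeatability
    spec <- repeatability_spec(r$n_subjects, r$n_sessions, r$sigma_subject,
                               r$sigma_session, r$sigma_error,
                               seed = seeds[["repeatability"]])
    emit(generate_repeatability(spec), "repeatability.tsv", "repeatability")
  }

  if ("network_stats" %in% stages && !done("network_stats.tsv")) {
    cohort <- read_table_tsv(require_upstream(config, "cohort.tsv", "cohort"))
    res <- fit_networks(cohort, terms = unlist(config$network_stats$terms),
                        alpha = config$network_stats$alpha)
    emit(res, "network_stats.tsv", "network_stats")
  }

  if ("icc" %in% stages && !done("icc.tsv")) {
    rep_tab <- read_table_tsv(
      require_upstream(config, "repeatability.tsv", "repeatability"))
    res <- icc_absolute_agreement(rep_tab)
    emit(tibble(metric = unique(rep_tab$metric)[1], icc = res$icc,
                msr = res$msr, msc = res$msc, mse = res$mse,
                n = res$n, k = res$k),
         "icc.tsv", "icc")
  }

  catalog <- make_gene_catalog(n_per_type = config$expression$n_per_type,
                               seed = config$seed)

  if ("expression" %in% stages && !done("single_region_expression.tsv")) {
    es <- derive_seeds(seeds[["expression"]], 2)
    ds1 <- generate_expression(expression_spec(
      "single_region_normalized", n_samples = config$expression$n_samples,
      catalog = catalog, noise_sd = config$expression$noise_sd, seed = es[1]))
    ds2 <- generate_expression(expression_spec(
      "multi_region_rpkm", n_donors = config$expression$n_donors,
      catalog = catalog, noise_sd = config$expression$noise_sd, seed = es[2]))
    write_expression_tsv(ds1, file.path(config$out_dir, "single_region"), hash)
    write_expression_tsv(ds2, file.path(config$out_dir, "multi_region"), hash)
    outputs <- c(outputs, "single_region_expression.tsv",
                 "single_region_samples.tsv", "multi_region_expression.tsv",
                 "multi_region_samples.tsv")
    log("expression", "wrote single- and multi-region expression tables")
  }

  load_expr <- function(prefix, scale, dialect) {
    require_upstream(config, paste0(prefix, "_expression.tsv"), "expression")
    ds <- read_expression_tsv(file.path(config$out_dir, prefix), scale, dialect)
    ds$catalog <- catalog
    ds
  }

  if (any(c("age_genes", "trajectories") %in% stages)) {
    ds1 <- load_expr("single_region", "normalized", "single_region_normalized")
    ds2 <- load_expr("multi_region", "log2rpkm", "multi_region_rpkm")
  }

  if ("age_genes" %in% stages && !done("age_genes.tsv")) {
    log("age_genes", "fitting per-gene age splines (discovery dataset)")
    fits1 <- fit_age_splines(ds1)
    sel1 <- select_age_genes(fits1, alpha = config$expression$alpha)
    log("age_genes", "fitting per-gene age splines (validation dataset)")
    fits2 <- fit_age_splines(ds2)
    sel2 <- select_age_genes(fits2, alpha = config$expression$alpha)
    emit(sel1, "age_genes.tsv", "age_genes")
    rep_ov <- replication_overlap(sel1$gene[sel1$selected],
                                  sel2$gene[sel2$selected])
    emit(tibble(discovery = sum(sel1$selected),
                validation = sum(sel2$selected),
                replicated = rep_ov$count, proportion = rep_ov$proportion),
         "replication.tsv", "age_genes")
    sgc <- stage_gene_counts(sel1, catalog, fits1)
    emit(sgc, "stage_counts.tsv", "age_genes")
    # enrichment of the selected genes in the cell-type sets
    sets <- split(catalog$gene, catalog$cell_type)
    write_gmt(sets, file.path(config$out_dir, "celltype_sets.gmt"))
    outputs <- c(outputs, "celltype_sets.gmt")
    if (any(sel1$selected)) {
      enr <- enrichment_test(sel1$gene[sel1$selected], sets, catalog$gene)
      emit(enr, "enrichment.tsv", "age_genes")
    }
  }

  if ("trajectories" %in% stages && !done("trajectories.tsv")) {
    log("trajectories", "computing cell-type mean trajectories")
    rows <- lapply(cortical_cell_types(), function(ct) {
      tr <- celltype_trajectory(ds2, catalog, ct,
                                normalize = config$trajectories$normalize)
      dplyr::mutate(tr$grid, cell_type = ct, region = tr$region, .before = 1)
    })
    emit(dplyr::bind_rows(rows), "trajectories.tsv", "trajectories")
  }

  if ("crossover" %in% stages && !done("crossover.tsv")) {
    ds2 <- load_expr("multi_region", "log2rpkm", "multi_region_rpkm")
    rows <- lapply(unlist(config$crossover$regions), function(r) {
      tro <- celltype_trajectory(ds2, catalog, "oligodendrocyte", region = r,
                                 normalize = "none")
      tra <- celltype_trajectory(ds2, catalog, "astrocyte", region = r,
                                 normalize = "none")
      cx <- expression_ratio_crossover(tro, tra)
      pk <- peak_growth_age(tro)
      dplyr::mutate(cx, peak_growth_age = pk$age, peak_censored = pk$censored)
    })
    emit(dplyr::bind_rows(rows), "crossover.tsv", "crossover")
  }

  if ("soma" %in% stages && !done("soma_sweep.tsv")) {
    log("soma", "running apparent-soma-radius age sweep")
    slopes <- slopes_from_catalog(catalog,
                                  calibration = config$soma$calibration)
    sw <- age_sweep(default_cell_populations(), slopes,
                    unlist(config$soma$ages),
                    n_samples = config$soma$n_samples,
                    seed = seeds[["soma"]], ref_age = config$soma$ref_age)
    emit(sw$table, "soma_sweep.tsv", "soma")
    emit(tibble(percent_change = sw$percent_change,
                percent_change_analytic = sw$percent_change_analytic),
         "soma_summary.tsv", "soma")
  }

  manifest <- list(
    config_hash = hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cortexdev")),
    stages = stages,
    outputs = lapply(stats::setNames(outputs, outputs), function(f) {
      list(md5 = file_md5(stage_path(config, f)))
    })
  )
  jsonlite::write_json(manifest, stage_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_run_config(config, stage_path(config, "config.yaml"))
  invisible(manifest)
}
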