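# Plain-text interchange: TSV tables (UTF-8, header row, '.' decimal) with an
# optional provenance comment, GMT gene sets, and YAML run configs.

#' Write a table as TSV with a provenance comment
#'
#' Writes a `# key: value` comment header (always including the generating
#' config hash when given) followed by a UTF-8 TSV with a header row.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config_hash Optional hash string recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path, config_hash = NULL) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  if (!is.null(config_hash)) {
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  }
  readr::write_tsv(x, con, progress = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_table_tsv()]
#'
#' @param path Input path.
#' @return Tibble (comment lines starting with `#` are skipped).
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Write an expression dataset as a TSV pair
#'
#' Writes `<prefix>_expression.tsv` (first column `gene`, one column per
#' sample) and `<prefix>_samples.tsv` (per-sample metadata).
#'
#' @param dataset An `expression_dataset`.
#' @param prefix Path prefix for the two files.
#' @param config_hash Optional provenance hash.
#' @return Character vector of the two paths, invisibly.
#' @export
write_expression_tsv <- function(dataset, prefix, config_hash = NULL) {
  expr <- dplyr::bind_cols(tibble(gene = rownames(dataset$expr)),
                           as_tibble(dataset$expr))
  p1 <- paste0(prefix, "_expression.tsv")
  p2 <- paste0(prefix, "_samples.tsv")
  write_table_tsv(expr, p1, config_hash)
  write_table_tsv(dataset$samples, p2, config_hash)
  invisible(c(p1, p2))
}

#' Read an expression dataset from a TSV pair
#'
#' @param prefix Path prefix used by [write_expression_tsv()].
#' @param scale Expression scale tag (`"normalized"` or `"log2rpkm"`).
#' @param dialect Dataset dialect tag.
#' @return An `expression_dataset` (without a generating catalog).
#' @export
read_expression_tsv <- function(prefix,
                                scale = c("normalized", "log2rpkm"),
                                dialect = c("single_region_normalized",
                                            "multi_region_rpkm")) {
  scale <- match.arg(scale)
  dialect <- match.arg(dialect)
  expr_tb <- read_table_tsv(paste0(prefix, "_expression.tsv"))
  samples <- read_table_tsv(paste0(prefix, "_samples.tsv"))
  expr <- as.matrix(expr_tb[, -1])
  rownames(expr) <- expr_tb$gene
  structure(list(expr = expr, samples = samples, scale = scale,
                 dialect = dialect, catalog = NULL),
            class = "expression_dataset")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("gene sets must be named")
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read or write a pipeline run configuration
#'
#' Run configurations are plain-text YAML; [validate_run_config()] checks the
#' schema before a run.
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config Config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
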