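# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG untouched (caller-controlled randomness).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed so that
# independent generators do not share a random stream.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# z-score a numeric vector; constant input is an error for model inputs.
zscore <- function(x, what = "x") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("cannot standardize '%s': zero variance", what))
  }
  (x - mean(x)) / s
}

# Sex factor -> centred +/- 0.5 numeric contrast (M = +0.5, F = -0.5).
sex_contrast <- function(sex) {
  code <- ifelse(sex == "M", 0.5, -0.5)
  if (any(!sex %in% c("M", "F"))) abort("sex must be coded 'M'/'F'")
  code
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# md5 of an on-disk file (used for run manifests).
file_md5 <- function(path) unname(tools::md5sum(path))

# md5 of an arbitrary R object via its canonical YAML serialization.
object_md5 <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(x, tmp)
  file_md5(tmp)
}
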