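#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Deterministic per-stage seed derived from a single top-level seed, so adding
# a pipeline stage never perturbs the random stream of an earlier one.
# Kept below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003L
  as.integer((abs(seed) %% 1000003L) * 2003L + h) %% .Machine$integer.max
}

with_substream <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

# Stable hash of an R object (for embedding a config fingerprint in outputs).
config_hash <- function(x) {
  rlang::hash(x)
}

assert_positive <- function(x, name) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    abort(sprintf(
      "`%s` must be positive and finite; offending rows: %s",
      name, paste(utils::head(bad, 10L), collapse = ", ")
    ))
  }
  invisible(x)
}
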