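# Shared fixtures, built in code at test time.

the_test_env <- new.env(parent = emptyenv())

# Default spec without the (expected, by-design) zinc anchor-conflict warning.
quiet_spec <- function(n = 150, seed = 1, ...) {
  suppressWarnings(default_cohort_spec(n = n, seed = seed, ...))
}

# One calibrated copula, shared across test files (calibration is the slow
# part and is itself under test in test-copula.R).
calibrated_copula <- function() {
  if (is.null(the_test_env$copula)) {
    spec <- quiet_spec()
    the_test_env$copula <- calibrate_copula(spec$copula, spec$marginals)
  }
  the_test_env$copula
}

calibrated_spec <- function(n, seed = 1, ...) {
  spec <- quiet_spec(n = n, seed = seed, ...)
  spec$copula <- calibrated_copula()
  spec
}

# A large default cohort, generated once and reused by the calibration and
# classification checks.
big_cohort <- function() {
  if (is.null(the_test_env$big)) {
    the_test_env$big <- generate_cohort(calibrated_spec(n = 50000, seed = 202))
  }
  the_test_env$big
}

# A one-row HFIAS response: freq is a length-9 vector of frequency codes 0-3.
hfias_df <- function(freq) {
  stopifnot(length(freq) == 9)
  out <- list()
  for (i in 1:9) {
    out[[sprintf("hfias%d_occ", i)]] <- as.integer(freq[i] > 0)
    out[[sprintf("hfias%d_freq", i)]] <- as.integer(freq[i])
  }
  tibble::as_tibble(out)
}

hfias_cat <- function(freq) {
  as.character(hfias_category(hfias_df(freq))$hfias_category)
}
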