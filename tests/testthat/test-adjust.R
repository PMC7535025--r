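test_that("the altitude correction term matches hand arithmetic", {
  expect_equal(altitude_correction_term(0), 0)
  # printed coefficients at 1000 m: -0.32*3.3 + 0.22*3.3^2
  expect_equal(altitude_correction_term(1000), 1.3398)
  # same arithmetic on the CDC-scale coefficients
  expect_equal(altitude_correction_term(1000, -0.032, 0.022), 0.13398)
  expect_error(altitude_correction_term(-5), "non-negative")
  expect_error(altitude_correction_term(100, altitude_factor = 0), "positive")
})

test_that("adjust_hemoglobin subtracts ten times the g/dL term", {
  df <- tibble::tibble(hb = c(140, 120), altitude = c(1000, 0))
  out <- adjust_hemoglobin(df)
  expect_equal(out$hb_adj, c(140 - 10 * 1.3398, 120))
  # flagged-as-adjusted data pass through unchanged
  attr(df, "hb_altitude_adjusted") <- TRUE
  expect_equal(adjust_hemoglobin(df)$hb_adj, df$hb)
  expect_equal(adjust_hemoglobin(df, force = TRUE)$hb_adj[1], 140 - 13.398)
})

test_that("inflammation-model fitting recovers known slopes", {
  # bias measured by averaging deviations over replicate fits of n = 5000,
  # separating estimator bias from single-draw Monte-Carlo noise
  withr::with_seed(42, {
    n <- 5000
    devs <- vapply(1:20, function(i) {
      crp <- exp(rnorm(n, 0, 0.9))
      agp <- exp(rnorm(n, -0.4, 0.35))
      fer <- exp(1.5 + 0.3 * log(crp) + 0.5 * log(agp) + rnorm(n, 0, 0.5))
      m <- fit_adjustment_model(fer, crp, agp, "ferritin")
      c(m$beta_crp - 0.3, m$beta_agp - 0.5)
    }, numeric(2))
    expect_lt(abs(mean(devs[1, ])), 0.02)
    expect_lt(abs(mean(devs[2, ])), 0.02)
    # null effects come back near zero
    crp <- exp(rnorm(n, 0, 0.9)); agp <- exp(rnorm(n, -0.4, 0.35))
    fer0 <- exp(rnorm(n, 3, 0.6))
    m0 <- fit_adjustment_model(fer0, crp, agp)
    expect_lt(abs(m0$beta_crp), 0.04)
    expect_lt(abs(m0$beta_agp), 0.08)
  })
})

test_that("the reference is the maximum of the lowest decile", {
  crp <- c(1:18, 100, 200)  # n = 20, decile = 2 smallest values
  agp <- seq(0.4, 2.3, by = 0.1)
  fer <- rep(30, 20) * exp(seq(0, 1.9, by = 0.1))
  m <- fit_adjustment_model(fer, crp, agp)
  expect_equal(m$ref_ln_crp, log(2))
  expect_equal(m$ref_ln_agp, log(0.5))
  expect_equal(m$n_fit, 20)
})

test_that("fitting preconditions are enforced", {
  expect_error(fit_adjustment_model(1:10, 1:10, 1:10), "fewer than 20")
  expect_error(fit_adjustment_model(c(-1, 2:20), 1:20, 1:20), "positive")
  expect_error(fit_adjustment_model(1:20, rep(2, 20), 1:20), "degenerate")
  expect_error(fit_adjustment_model(1:20, 1:19, 1:20), "equal length")
})

test_that("apply_adjustment evaluates the correction formula exactly", {
  m <- structure(list(name = "ferritin", beta_crp = 0.2, beta_agp = 0.3,
                      ref_ln_crp = 0, ref_ln_agp = 0, n_fit = 100),
                 class = "adjustment_model")
  # ln(crp) - ref = 1, ln(agp) - ref = 0.5 -> 30 * exp(-0.2 - 0.15)
  expect_equal(apply_adjustment(30, exp(1), exp(0.5), m), 30 * exp(-0.35))
  # identity at/below both references (the clamp)
  expect_equal(apply_adjustment(30, exp(0), exp(-1), m), 30)
  # zero slopes leave the value untouched
  m0 <- m; m0$beta_crp <- 0; m0$beta_agp <- 0
  expect_equal(apply_adjustment(30, exp(2), exp(2), m0), 30)
  # negative slopes are skipped by default but applied when asked
  mneg <- m; mneg$beta_crp <- -0.2
  expect_equal(apply_adjustment(30, exp(1), exp(0.5), mneg), 30 * exp(-0.15))
  expect_equal(apply_adjustment(30, exp(1), exp(0.5), mneg, positive_only = FALSE),
               30 * exp(0.2 - 0.15))
  # unclamped adjustment also corrects below-reference records
  expect_equal(apply_adjustment(30, exp(-1), exp(0), m, clamp = FALSE),
               30 * exp(0.2))
})

test_that("adjustment never inflates the biomarker when slopes are positive", {
  withr::with_seed(7, {
    n <- 2000
    crp <- exp(rnorm(n, 0, 1)); agp <- exp(rnorm(n, -0.4, 0.4))
    fer <- exp(3 + 0.25 * log(crp) + 0.4 * log(agp) + rnorm(n, 0, 0.6))
    m <- fit_adjustment_model(fer, crp, agp)
    adj <- apply_adjustment(fer, crp, agp, m)
    expect_true(all(adj <= fer + 1e-12))
    # identity on the sub-sample at/below both references
    idle <- log(crp) <= m$ref_ln_crp & log(agp) <= m$ref_ln_agp
    expect_true(any(idle))
    expect_equal(adj[idle], fer[idle])
  })
})

test_that("fit-then-apply removes the inflammation signal it models", {
  # data simulated from the correction's own generative form: once fitted and
  # applied (unclamped), inflamed and uninflamed records converge to the same
  # mean on the log scale
  withr::with_seed(11, {
    n <- 5000
    crp <- exp(rnorm(n, 0.2, 1))
    agp <- exp(rnorm(n, -0.3, 0.4))
    true_fer <- exp(rnorm(n, 3.2, 0.4))  # inflammation-free ferritin
    fer <- true_fer * crp^0.3 * agp^0.5
    m <- fit_adjustment_model(fer, crp, agp)
    adj <- apply_adjustment(fer, crp, agp, m, clamp = FALSE)
    # median split on CRP: adjusted means of the two halves converge
    inflamed <- crp > median(crp)
    bias <- mean(adj[inflamed]) / mean(adj[!inflamed]) - 1
    expect_lt(abs(bias), 0.03)
    # while the unadjusted means differ markedly
    expect_gt(mean(fer[inflamed]) / mean(fer[!inflamed]) - 1, 0.2)
  })
})

test_that("body iron follows the Cook formula and unit convention", {
  # zero crossing exactly at ratio 10^2.8229 (TfR in ug/L over ferritin in ug/L)
  expect_equal(body_iron(10^2.8229 / 1000 * 27.6, 27.6), 0)
  # at the cohort medians
  expect_equal(body_iron(3.5, 27.6), 5.9631, tolerance = 1e-4)
  # strict monotonicity: up in ferritin, down in TfR
  expect_gt(body_iron(3.5, 55.2), body_iron(3.5, 27.6))
  expect_lt(body_iron(7, 27.6), body_iron(3.5, 27.6))
  expect_error(body_iron(-1, 10), "positive")
  expect_error(body_iron(3, 0), "positive")
})

test_that("adjust_cohort appends adjusted columns and fit reports", {
  cohort <- generate_cohort(calibrated_spec(n = 400, seed = 21))
  out <- adjust_cohort(cohort)
  expect_true(all(c("hb_adj", "ferritin_adj", "tfr_adj", "body_iron") %in%
                    names(out)))
  expect_equal(out$hb_adj, cohort$hb)  # already on the adjusted scale
  expect_true(all(out$ferritin_adj <= out$ferritin + 1e-9 |
                    attr(out, "adjustment_models")$ferritin$beta_crp <= 0))
  fits <- attr(out, "adjustment_models")
  expect_s3_class(fits$ferritin, "adjustment_model")
  expect_equal(fits$ferritin$n_fit, 400)
})
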