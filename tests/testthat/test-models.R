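test_that("predictor transformation is log10 on the listed columns only", {
  df <- tibble::tibble(hb_adj = 130, ferritin = 100, crp = 10, muac = 24)
  out <- transform_predictors(df, skewed = c("ferritin", "crp"))
  expect_equal(out$ferritin, 2)
  expect_equal(out$crp, 1)
  expect_equal(out$hb_adj, 130)  # outcome untouched
  expect_equal(out$muac, 24)
  bad <- tibble::tibble(ferritin = c(100, 0))
  expect_error(transform_predictors(bad, "ferritin"), "rows: 2")
})

test_that("VIF matches closed forms and drops collinear predictors", {
  withr::with_seed(3, {
    n <- 4000
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  })
  # orthogonal pair: both VIFs ~1
  v <- vif_screen(tibble::tibble(a = x1, b = x2), c("a", "b"))
  expect_equal(v$vif_table$vif, c(1, 1), tolerance = 0.01)
  expect_equal(v$retained, c("a", "b"))
  # correlation 0.6 -> VIF = 1/(1-0.36) = 1.5625, both retained
  df <- tibble::tibble(a = x1, b = x3, c = x2)
  v2 <- vif_screen(df[c("a", "b")], c("a", "b"))
  expect_equal(v2$vif_table$vif, rep(1.5625, 2), tolerance = 0.05)
  expect_equal(v2$retained, c("a", "b"))
  # duplicated predictor: infinite VIF, one copy dropped
  v3 <- vif_screen(tibble::tibble(a = x1, dup = x1, b = x2), c("a", "dup", "b"))
  expect_true(any(is.infinite(v3$vif_table$vif[v3$vif_table$round == 1])))
  expect_length(v3$retained, 2)
  expect_true("b" %in% v3$retained)
})

test_that("squared semipartials match their algebraic identity to 1e-10", {
  withr::with_seed(8, {
    n <- 500
    df <- tibble::tibble(
      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
      y = 2 + 1.5 * x1 - 0.8 * x2 + 0.3 * x3 + rnorm(n, 0, 2)
    )
  })
  m <- fit_hb_model(df, outcome = "y", predictors = c("x1", "x2", "x3"))
  tt <- dplyr::filter(tidy(m), term != "(Intercept)")
  # independent oracle: sr2_j = t_j^2 (1 - R^2) / (n - p - 1)
  alg <- tt$statistic^2 * (1 - m$r.squared) / (n - 3 - 1)
  expect_equal(tt$sr2, alg, tolerance = 1e-10)
})

test_that("semipartial special cases hold exactly", {
  withr::with_seed(15, {
    n <- 300
    x1 <- rnorm(n)
    x1 <- x1 - mean(x1)
    x2 <- rnorm(n)
    x2 <- residuals(lm(x2 ~ x1))  # exactly orthogonal to x1
    y <- 1 + x1 + 0.5 * x2 + rnorm(n)
    df <- tibble::tibble(x1 = x1, x2 = x2, y = y)
  })
  # single predictor: sr2 equals R2
  m1 <- fit_hb_model(df, "y", "x1")
  expect_equal(tidy(m1)$sr2[2], m1$r.squared, tolerance = 1e-12)
  # orthogonal design: semipartials sum to R2
  m2 <- fit_hb_model(df, "y", c("x1", "x2"))
  expect_equal(sum(tidy(m2)$sr2, na.rm = TRUE), m2$r.squared, tolerance = 1e-12)
  expect_lte(m2$adj.r.squared, m2$r.squared)
})

test_that("the linear model recovers simulated coefficients", {
  # deviation averaged over replicates isolates bias from Monte-Carlo noise
  withr::with_seed(30, {
    n <- 2000
    devs <- vapply(1:10, function(i) {
      df <- tibble::tibble(
        ferritin = exp(rnorm(n, 3, 0.9)), zinc = exp(rnorm(n, 2.25, 0.2))
      )
      df$hb_adj <- 100 - 4 * log10(df$ferritin) + 15 * log10(df$zinc) +
        rnorm(n, 0, 8)
      tr <- transform_predictors(df, c("ferritin", "zinc"))
      m <- fit_hb_model(tr, "hb_adj", c("ferritin", "zinc"))
      tt <- tidy(m)
      c(tt$estimate[2] - (-4), tt$std.error[2],
        tt$estimate[3] - 15, tt$std.error[3])
    }, numeric(4))
  })
  expect_lt(abs(mean(devs[1, ])), 2 * mean(devs[2, ]) / sqrt(10))
  expect_lt(abs(mean(devs[3, ])), 2 * mean(devs[4, ]) / sqrt(10))
  tiny <- tibble::tibble(ferritin = 1:3, zinc = 4:6, hb_adj = c(1, 2, 3))
  expect_error(fit_hb_model(tiny, "hb_adj", c("ferritin", "zinc")),
               "predictors")
})

test_that("logistic MLE on a saturated 2x2 equals the cross-product odds ratio", {
  # a=10 exposed cases, b=20 exposed controls, c=30, d=40
  df <- tibble::tibble(
    x = rep(c(1, 1, 0, 0), c(10, 20, 30, 40)),
    y = rep(c(1, 0, 1, 0), c(10, 20, 30, 40))
  )
  m <- fit_anemia_model(df, "x", outcome = "y")
  expect_equal(tidy(m)$or, (10 * 40) / (20 * 30), tolerance = 1e-8)
  expect_equal(tidy(m)$or, 0.6667, tolerance = 1e-4)
})

test_that("the bivariate screen retains real signals and flags separation", {
  withr::with_seed(44, {
    n <- 500
    x <- rbinom(n, 1, 0.4)
    p <- plogis(qlogis(0.15) + log(5) * x)  # true OR 5
    y <- rbinom(n, 1, p)
    z <- rbinom(n, 1, 0.5)  # independent factor
    df <- tibble::tibble(x = x, z = z, anemic = y)
  })
  sc <- bivariate_screen(df, c("x", "z"))
  expect_true(sc$retained[sc$factor == "x"])
  expect_gt(sc$or[sc$factor == "x"], 1)
  # zero-cell table: continuity-corrected estimate with a warning
  sep <- tibble::tibble(x = c(rep(1, 10), rep(0, 30)),
                        anemic = c(rep(1, 10), rep(0, 30)))
  expect_warning(sc2 <- bivariate_screen(sep, "x"), "separation")
  expect_true(is.finite(sc2$or) && sc2$or > 1)
  expect_true(sc2$separation)
  expect_error(bivariate_screen(tibble::tibble(x = 0:1, anemic = c(1, 1)), "x"),
               "variation")
})

test_that("screening an independent factor has about the nominal type-I rate", {
  withr::with_seed(55, {
    hits <- vapply(1:400, function(i) {
      df <- tibble::tibble(x = rbinom(200, 1, 0.5), anemic = rbinom(200, 1, 0.3))
      suppressWarnings(bivariate_screen(df, "x")$retained)
    }, logical(1))
  })
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.10)
})

test_that("a strong factor is retained with high power", {
  withr::with_seed(66, {
    hits <- vapply(1:100, function(i) {
      x <- rbinom(500, 1, 0.4)
      y <- rbinom(500, 1, plogis(qlogis(0.15) + log(5) * x))
      suppressWarnings(bivariate_screen(tibble::tibble(x = x, anemic = y), "x")$retained)
    }, logical(1))
  })
  expect_gt(mean(hits), 0.9)
})

test_that("the multivariate model reports Wald intervals around the OR", {
  withr::with_seed(70, {
    n <- 2000
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.3)
    y <- rbinom(n, 1, plogis(-1.2 + log(3) * a - 0.5 * b))
    df <- tibble::tibble(a = a, b = b, anemic = y)
  })
  m <- fit_anemia_model(df, c("a", "b"))
  tt <- tidy(m)
  expect_true(all(tt$conf.low < tt$or & tt$or < tt$conf.high))
  expect_true(all(tt$or > 0))
  expect_equal(tt$or[1], 3, tolerance = 0.25)
  g <- glance(m)
  expect_true(g$converged)
  expect_false(g$separation)
  # factor identical to the outcome: separation warning
  df$same <- df$anemic
  expect_warning(fit_anemia_model(df, "same"), "separation")
  # few events: stability warning
  withr::with_seed(71, {
    tiny <- tibble::tibble(x = rbinom(60, 1, 0.5),
                           anemic = sample(c(rep(1, 5), rep(0, 55))))
  })
  expect_warning(fit_anemia_model(tiny, "x"), "events")
})

test_that("with the effects hook on, multivariate ORs land on the correct side of 1", {
  cohort <- generate_cohort(calibrated_spec(n = 2000, seed = 404,
                                            effects = cohort_effects()))
  cohort <- recode_covariates(classify_cohort(adjust_cohort(cohort)))
  m <- fit_anemia_model(cohort, c("tfr_low", "agp_normal", "muac_low", "illiterate"))
  tt <- tidy(m)
  expect_lt(tt$or[tt$term == "tfr_low"], 1)      # protective: sufficient iron
  expect_lt(tt$or[tt$term == "agp_normal"], 1)   # protective: no inflammation
  expect_gt(tt$or[tt$term == "muac_low"], 1)     # harmful: low muscle mass
  expect_gt(tt$or[tt$term == "illiterate"], 1)   # harmful: illiteracy
})
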