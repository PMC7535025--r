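test_that("anemia severity follows the WHO bands with documented boundaries", {
  expect_equal(as.character(classify_anemia(c(119, 120, 110, 109.99, 80, 79))),
               c("mild", "none", "mild", "moderate", "moderate", "severe"))
  # boundary audit: each cutoff +/- one ulp classifies per the inclusivity table
  for (cut in c(120, 110, 80)) {
    above <- classify_anemia(cut)
    below <- classify_anemia(cut * (1 - 1e-15))
    expect_true(above < below)  # ordered factor: lower hb, worse category
  }
  expect_error(classify_anemia(-1), "positive")
})

test_that("iron status flags follow the printed cutoffs", {
  f <- classify_iron_status(ferritin_adj = 14.9, tfr = 3, body_iron = 2,
                            hb_adj = 115)
  expect_true(f$iron_deficient && f$ida)
  # strict < at the ferritin boundary
  f2 <- classify_iron_status(15, 3, 2, 115)
  expect_false(f2$iron_deficient)
  expect_false(f2$ida)
  # TfR cutoff is inclusive
  expect_true(classify_iron_status(30, 8.3, 2, 130)$functional_iron_deficit)
  expect_false(classify_iron_status(30, 8.29, 2, 130)$functional_iron_deficit)
  # overload is strict >, and negative body iron is tissue deficiency
  expect_false(classify_iron_status(150, 3, 2, 130)$iron_overload)
  expect_true(classify_iron_status(151, 3, -0.01, 130)$iron_overload)
  expect_true(classify_iron_status(151, 3, -0.01, 130)$tissue_iron_deficient)
})

test_that("inflammation stages map the two markers to the four-stage reading", {
  s <- classify_inflammation(c(6, 0.8, 0.4, 6), c(0.8, 1.2, 0.6, 1.2))
  expect_equal(as.character(s$inflammation_stage),
               c("incubation", "late_convalescence", "reference",
                 "early_convalescence"))
  expect_equal(s$acute_inflammation, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(s$chronic_inflammation, c(FALSE, TRUE, FALSE, TRUE))
  # CRP boundary: strict by default, inclusive when configured
  expect_false(classify_inflammation(5, 0.5)$acute_inflammation)
  expect_true(classify_inflammation(5, 0.5,
    status_cutoffs(crp_inclusive = TRUE))$acute_inflammation)
  # AGP boundary is strict
  expect_false(classify_inflammation(1, 1)$chronic_inflammation)
})

test_that("zinc inadequacy is strictly below the cutoff", {
  expect_true(classify_zinc(9.5))
  expect_false(classify_zinc(10.7))
  expect_false(classify_zinc(11))
})

test_that("every flag is monotone in its biomarker", {
  hb <- seq(70, 140, by = 0.5)
  sev <- classify_anemia(hb)
  expect_true(all(diff(as.integer(sev)) <= 0))  # rising hb never worsens
  fer <- seq(5, 200, by = 1)
  expect_true(all(diff(classify_iron_status(fer, 3, 2, 130)$iron_deficient) <= 0))
  expect_true(all(diff(classify_iron_status(fer, 3, 2, 130)$iron_overload) >= 0))
})

test_that("classify_cohort appends a consistent status profile", {
  cohort <- adjust_cohort(generate_cohort(calibrated_spec(n = 2000, seed = 31)))
  cl <- classify_cohort(cohort)
  expect_equal(cl$anemic, cl$anemia_severity != "none")
  expect_true(all(!cl$ida | (cl$anemic & cl$iron_deficient)))
  expect_true(all(!cl$iron_overload | !cl$iron_deficient))
  expect_error(classify_cohort(dplyr::select(cohort, -agp)), "agp")
})

test_that("prevalence summaries count and partition correctly", {
  hb <- c(115, 118, 95, rep(130, 7))  # 2 mild + 1 moderate of 10
  df <- tibble::tibble(
    hb_adj = hb, ferritin_adj = 30, tfr_adj = 3, body_iron = 2,
    crp = 0.5, agp = 0.6, zinc = 12
  )
  ps <- summarize_prevalence(classify_cohort(df))
  get <- function(s) ps$percent[ps$status == s]
  expect_equal(get("anemic"), 30)
  expect_equal(get("anemia_mild"), 20)
  expect_equal(get("anemia_moderate"), 10)
  expect_equal(get("anemia_mild") + get("anemia_moderate") +
                 get("anemia_severe"), get("anemic"))
  # all-healthy cohort: zero everywhere
  healthy <- tibble::tibble(hb_adj = 130, ferritin_adj = 30, tfr_adj = 3,
                            body_iron = 2, crp = 0.5, agp = 0.6, zinc = 12)
  expect_true(all(summarize_prevalence(classify_cohort(healthy))$percent == 0))
  expect_error(summarize_prevalence(healthy[0, ]), "empty")
})
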