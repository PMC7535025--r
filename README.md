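# anemetrics

Anemia in women of reproductive age rarely has a single cause: iron
deficiency, other micronutrient shortfalls (notably zinc), infection-driven
inflammation and socio-economic deprivation all contribute, and the iron
biomarkers used to tell them apart are themselves distorted by inflammation.
`anemetrics` implements, as a tested and reusable R pipeline, the complete
analysis workflow of a cross-sectional biomarker survey of lactating women in
a highland rural setting:

* **Synthetic cohort generator** — a seeded Gaussian copula over
  quantile-anchored marginals that reproduces the survey's published
  biomarker medians/IQRs, threshold prevalences (anemia 19%, zinc inadequacy
  78%, chronic inflammation 13%, ...) and pairwise correlations, so every
  downstream stage can be exercised and tested without access to raw data.
* **Biomarker adjustment** — the UNICEF/UNU/WHO altitude correction of
  hemoglobin; regression-based (BRINDA-style) inflammation adjustment of
  ferritin and soluble transferrin receptor, with in-sample coefficient
  estimation; and Cook's body-iron index.
* **Status classification** — WHO anemia severity bands, iron deficiency /
  IDA / overload, functional iron deficit, tissue iron deficiency,
  acute/chronic inflammation with the four-stage CRP x AGP reading, and zinc
  inadequacy, plus cohort prevalence summaries.
* **Socio-economic scores** — HFIAS food-insecurity score and the FANTA
  four-level categorisation (table-driven), an asset-based PCA wealth index
  with quintiles, and the covariate recodes used in modelling.
* **Determinant models** — multiple linear regression for hemoglobin with
  squared semipartial correlations (by nested refit) and VIF screening, and
  a bivariate-screen-then-multivariate logistic regression for anemia with
  odds ratios and Wald 95% CIs.

Everything is data-frame-first and pipe-friendly: cohorts are tibbles, model
objects have `tidy()`/`glance()` methods, and result types have `autoplot()`
methods.

## The models at the core

**Inflammation adjustment.** For a positively-skewed iron biomarker *B*, OLS
slopes β₁, β₂ of ln *B* on ln CRP and ln AGP are estimated jointly in-sample,
and each record is corrected by

> B_adj = exp( ln B − β₁ · max(0, ln CRP − ref_CRP) − β₂ · max(0, ln AGP − ref_AGP) )

where each reference is the maximum observed ln value in the lowest decile of
that inflammation marker. Records at or below reference are untouched.

**Body iron.** With TfR converted from mg/L to µg/L,

> body iron (mg/kg) = −(log₁₀(1000·TfR / ferritin) − 2.8229) / 0.1207

Negative values flag tissue iron deficiency; the sign flips at ratio
10^2.8229 ≈ 665.

**Altitude correction.** Hb (g/L) is reduced by 10 × (c₁x + c₂x²) with
x = altitude(m) × 0.0033. Coefficients are configurable: both the survey's
printed scale (−0.32, 0.22) and the CDC scale (−0.032, 0.022) are supported.

**Squared semipartial correlation.** For predictor *j*, sr²ⱼ = R²(full) −
R²(without *j*), computed by explicit nested refit and cross-checked in the
test suite against the algebraic identity sr²ⱼ = t²ⱼ(1−R²)/(n−p−1).

## Worked example

```r
library(anemetrics)

spec <- default_cohort_spec(n = 2000, seed = 42, calibrate = TRUE,
                            effects = cohort_effects())
cohort     <- generate_cohort(spec)
classified <- classify_cohort(adjust_cohort(cohort))
summarize_prevalence(classified)
#>    status                  count denominator percent
#>  1 anemic                    570        2000   28.5
#>  2 iron_deficient            732        2000   36.6
#>  3 ida                       201        2000   10.0
#>  4 iron_overload              11        2000    0.55
#>  5 functional_iron_deficit   167        2000    8.35
#>  6 tissue_iron_deficient     239        2000   12.0
#>  7 acute_inflammation        111        2000    5.55
#>  8 chronic_inflammation      241        2000   12.0
#>  9 zinc_inadequate          1576        2000   78.8
#> 10 anemia_mild               357        2000   17.8
#> 11 anemia_moderate           213        2000   10.6
#> 12 anemia_severe               0        2000    0
```

With the optional effects hook on (low MUAC and illiteracy depress Hb, as
here), anemia runs above the survey's 19% and the logistic stage has
recoverable socio-demographic signal:

```r
classified |>
  recode_covariates() |>
  fit_anemia_model(c("tfr_low", "agp_normal", "muac_low", "illiterate")) |>
  tidy()
#>   term       estimate std.error  p.value    or conf.low conf.high
#> 1 tfr_low      -0.595     0.170 4.68e- 4 0.552    0.395     0.770
#> 2 agp_normal   -0.974     0.143 9.39e-12 0.378    0.285     0.500
#> 3 muac_low      0.718     0.131 3.91e- 8 2.05     1.59      2.65
#> 4 illiterate    0.538     0.109 8.13e- 7 1.71     1.38      2.12
```

Sufficient functional iron (TfR < 8.3 mg/L) and absence of chronic
inflammation (AGP ≤ 1 g/L) are protective (OR < 1); low muscle mass
(MUAC < 22 cm) and illiteracy raise the odds of anemia (OR > 1) — the
directions the survey reports. The hemoglobin regression on the
log₁₀-transformed biomarker panel:

```r
classified |>
  recode_covariates() |>
  transform_predictors() |>
  fit_hb_model() |>
  glance()
#>   r.squared adj.r.squared adj.r.squared.percent     n n.predictors
#> 1     0.262         0.259                  25.9  2000            8
```

`run_pipeline(run_config(spec = spec, seed = 42))` chains all stages and
writes the derived cohort CSV, prevalence/fit JSONs and a plain-text report;
a thin command-line wrapper with `generate`/`adjust`/`classify`/`score`/
`model`/`run` subcommands ships in `inst/cli/anemetrics.R`.

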