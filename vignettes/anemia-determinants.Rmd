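---
title: "Methods: synthetic cohorts, inflammation-adjusted iron biomarkers and anemia determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, inflammation-adjusted iron biomarkers and anemia determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anemetrics)
```

`anemetrics` packages the full analysis chain of a cross-sectional biomarker
survey of lactating women — synthetic cohort generation, biomarker
adjustment, status classification, socio-economic scoring and determinant
modelling. This vignette explains the models, their assumptions, the
parameters that matter, and the design choices made where the design was
genuinely open.

## 1. The synthetic cohort generator

### Quantile-anchored marginals

Published survey tables summarise each biomarker by a median and IQR, and
separately report threshold prevalences ("19% had Hb < 120 g/L", "78% had
zinc < 10.7 µmol/L"). Both kinds of statement are *quantile anchors*: pairs
(p, q) with F(q) = p. A `quantile_marginal()` is the monotone
piecewise-linear interpolation of its anchors — on the natural-log scale for
the right-skewed biomarkers (ferritin, TfR, plasma iron, hepcidin, CRP,
AGP), on the raw scale for hemoglobin, zinc and selenium, matching the
transform list used in the source analysis. Beyond the extreme anchors the
quantile function continues the slope of the outermost segment, floored at a
small positive value and capped at `cap_factor` (default 5) times the
largest anchor so extrapolated extremes stay physiological. Selenium is
additionally truncated to the observed (2.0, 5.0) µmol/L range.

Two consequences are worth spelling out:

* **Threshold prevalences are exact by construction.** Because the anemia,
  zinc, TfR, CRP, AGP and ferritin-overload cutoffs are themselves anchors,
  the generated prevalences converge to the published ones with pure
  Monte-Carlo error, which is what the calibration tests check.
* **Anchor conflicts are resolved by priority.** The printed zinc upper
  quartile (11 µmol/L at p = 0.75) is inconsistent with 78% of values below
  10.7 µmol/L; a quantile function cannot honour both. Prevalence anchors
  take precedence — the classification thresholds are the pipeline's core
  and must be exactly testable — so the conflicting quartile anchor is
  dropped with a classed warning (`anemetrics_anchor_conflict`).

The hemoglobin marginal deserves a note: its anchors (p = 0.066 at 110 g/L,
p = 0.191 at 120 g/L, plus the median/IQR) encode the published severity
split — 12.5% mild, 6.6% moderate, none severe. Linear extrapolation below
the lowest anchor bottoms out near 105 g/L, so the generator produces no
severe anemia, as observed.

### The Gaussian copula and its calibration

Dependence is imposed by a latent multivariate normal: draw Z ~ N(0, Λ),
set U = Φ(Z), and push each column through its marginal quantile function.
Any monotone transform of a coordinate preserves rank correlation but not
Pearson correlation, so a latent correlation of 0.33 does not generally
produce a Pearson 0.33 on the analysis scale. `calibrate_copula()` therefore
root-finds, for every target pair, the latent correlation at which the
empirical analysis-scale Pearson correlation (log scale for skewed
variables) equals the target. Calibration uses common random numbers — a
fixed stream of 10^5 deviate pairs — so the objective is deterministic and
`uniroot()` converges reliably; achieved correlations sit within 0.01 of
target. The assembled latent matrix is then repaired to positive
definiteness by eigenvalue clipping (floor 10^-6) and renormalisation to
unit diagonal; the maximum elementwise perturbation is reported. For the
default targets the matrix is already positive definite and repair is a
no-op. A target unattainable under the margins (the bound on attainable
Pearson correlation under non-normal margins) raises an error naming the
pair.

### Socio-demographic fields

Education, age band, household-size band and children band are drawn
independently from the published category frequencies (the printed
food-insecurity percentages sum to 99.9 and are renormalised). Age and
household size are completed uniformly within their band. Gravidity is set
equal to parity (`n_children`, clamped to 1–8): the women are six months
post-partum, so the two coincide up to pregnancy losses the survey does not
summarise. MUAC and BMI are truncated normal with the published means/SDs
(24.4 ± 2.4 cm, 20.7 ± 2.3 kg/m²). The site altitude defaults to a constant
1700 m — typical of the highland study region; the survey does not print
it — and is fully configurable.

HFIAS item responses are constructed *backwards* from a drawn four-level
category: one defining condition of exactly that severity is planted, and
other items independently receive responses of no greater severity, so the
FANTA most-severe-condition rule recovers the drawn category exactly and
category frequencies match the published ones.

Household assets are eight synthetic binary indicators (the survey does not
list its asset questionnaire); their Bernoulli rates are configurable and
`wealth_index()` is indicator-agnostic.

By default socio-demographic fields are independent of the biomarkers — the
joint distribution is not identifiable from the published summaries. The
optional `cohort_effects()` hook subtracts configurable amounts from the
hemoglobin of low-MUAC (default −6 g/L) and illiterate (default −4 g/L)
women. The defaults were chosen once, as plausible mid-sized effects that
make the multivariate odds ratios for those factors reliably exceed 1 at
n = 2000, and are not revisited. Protective TfR and AGP associations need no
hook: they flow from the copula's negative Hb–TfR and Hb–AGP correlations.

### What the generator does and does not emulate

It reproduces marginals, threshold prevalences, the printed pairwise
correlations and category frequencies. It does **not** model household
clustering, the true joint distribution of socio-economics with biomarkers,
missingness, or measurement error (HemoCue readings are effectively integer
g/L; the generator emits continuous values). Passing tests therefore
demonstrate that the pipeline's arithmetic and inference behave correctly on
data *shaped like* the survey's — not that the survey's own point estimates
(its Tables of coefficients and ORs) are recovered, which would require the
raw data.

### Determinism

A single top-level seed feeds named substreams (`biomarkers`, `socio`,
`hfias`, `assets`, `anthropometry`) via a string-hash offset, so adding a
stage never perturbs earlier draws; identical spec + seed gives
byte-identical CSV output. All derived seeds stay below 2^31.

## 2. Biomarker adjustment

**Altitude.** The correction term c₁x + c₂x² (x = altitude × 0.0033) is in
g/dL; adjusted Hb (g/L) = observed − 10 × term. The printed coefficients
(−0.32, 0.22) are tenfold the widely used CDC values (−0.032, 0.022) and
give ~5 g/dL corrections at 1700 m, which is implausibly large; with no
worked value available to disambiguate, both scales are supported via the
`coeff_linear`/`coeff_quad` arguments and neither is asserted correct. The
default cohort sidesteps the question: hemoglobin is generated directly on
the altitude-adjusted scale (the scale the published summaries are reported
on), and the correction is exercised by its own formula tests. Setting
`hb_altitude_adjusted = FALSE` inverts the correction to emit field-scale
Hb.

**Inflammation (BRINDA-style).** β₁ and β₂ are the joint OLS slopes of
ln(biomarker) on ln(CRP) and ln(AGP); the reference for each marker is the
maximum observed ln value among the lowest 10% of the sample ordered by that
marker (largest observed value in the bottom decile, not a fitted
percentile; ties at the boundary stay in the decile). Both the observed
marker and the reference are on the natural-log scale throughout —
a mixed-scale reading of the correction formula would be dimensionally
incoherent given the enclosing exp(·). Three switches matter:

* `clamp` (default TRUE): records at or below reference are not adjusted,
  the standard practice; turning it off adjusts every record for
  sensitivity analysis.
* `positive_only` (default TRUE): a term with β ≤ 0 is skipped — a negative
  slope would *inflate* the biomarker, which the correction is not meant to
  do.
* Both CRP and AGP terms apply to both ferritin and TfR, exactly as the
  single published formula states; variants that adjust TfR with AGP only
  can be had by refitting with the relevant flag combinations.

Fitting refuses samples below n = 20; slopes from such samples are noise.

**Body iron.** TfR (mg/L) is multiplied by 1000 before forming the ratio
with ferritin (µg/L), per the Cook convention the formula originates from;
the source text does not state the ratio's units, so the convention is
documented rather than silently assumed. At the cohort medians (TfR 3.5,
ferritin 27.6) the index is +5.963 mg/kg.

Body iron is computed from the *adjusted* ferritin and TfR, consistent with
iron deficiency being defined on adjusted ferritin.

## 3. Classification

All cutoffs live in `status_cutoffs()` so boundary audits can enumerate them
mechanically. Inclusivity follows the wording of each definition: anemia and
iron deficiency are strict `<`, overload and chronic inflammation strict
`>`, the functional-iron-deficit TfR cutoff inclusive `≥`. The CRP cutoff is
reported with both "> 5" and "≥ 5" wordings in the source; strict `>` (the
definition given first) is the default and `crp_inclusive = TRUE` switches
it — on continuous generated data the event CRP = 5 has probability zero, so
the choice is immaterial for the calibration targets. The severity bands are
read as half-open intervals on continuous values (119.5 g/L is mild), since
the printed integer bands reflect integer-valued field readings. Iron
overload is evaluated on adjusted ferritin, consistent with deficiency;
whether the survey used adjusted or raw ferritin for its 2% figure is not
stated.

## 4. Socio-economic scores

The FANTA HFIAS v3 category decision table ships as a CSV
(`inst/extdata/hfias_category_table.csv`): per (item, frequency) the implied
severity, with the household assigned its most severe condition. Tests are
table-driven rather than hard-coding the rules. The score is the plain sum
of the nine frequency codes (0–27).

The wealth index standardises indicators, projects onto the first principal
component, and orients the sign so the largest-|loading| indicator loads
positively (the first-PC sign is arbitrary; this makes quintile labels
reproducible). Quintiles are cut at the 20/40/60/80 rank percentiles with
first-occurrence tie-breaking: with binary assets many households share an
asset profile and hence a score, and average-rank handling would put whole
tied blocks into one quintile, violating the equal-size property that makes
quintiles interpretable. Zero-variance indicators are dropped with a
warning.

## 5. Determinant models

Predictors entering the hemoglobin regression are log₁₀-transformed (the
reporting convention for that model), while the BRINDA fit uses natural
logs (as its formula states); the two bases are deliberately not unified.
Values at or below `epsilon` (default 0.01 of the unit) are rejected, not
floored — silent flooring would distort the fits, and the generator never
emits such values.

The VIF screen regresses each predictor on the others, VIF = 1/(1 − R²),
dropping iteratively (highest first, recomputing each round) at the
threshold 2.5 used by the source analysis. Perfect collinearity reports an
infinite VIF.

Squared semipartials come from explicit nested refits (R² difference), with
p-values from the partial F-test; the test suite asserts agreement with the
algebraic identity t²(1−R²)/(n−p−1) to 10^-10, so two independent
computations guard each other. Adjusted R² is also reported as a percentage,
matching survey-report convention.

The logistic stage screens candidate binary factors one at a time (Wald
p < 0.05 retains; a zero cell in the 2×2 gets a Haldane +0.5
continuity-corrected OR with a warning) and fits the retained factors
jointly by maximum likelihood. ORs are exp(coef) with Wald 95% intervals —
the era-typical default; fewer than 10 events warns, and suspected
separation (|coef| > 10 or fitted probabilities at 0/1) warns without
silently altering the fit. Reference levels follow the survey's coding:
TfR < 8.3 vs ≥ 8.3 (reference), AGP ≤ 1 vs > 1 (reference), MUAC < 22 vs
≥ 22, illiterate vs literate, age ≤ 21 vs > 21, zinc < 10.7 vs ≥ 10.7,
gravidity 1–3 vs 4–8.

## 6. Verification strategy and problem sizes

The test suite checks each formula against frozen hand-computed values,
each statistical routine against an independent oracle (cross-product OR vs
logistic MLE on a saturated 2×2; semipartial identity; closed-form VIF), and
the generator against the published summaries at n = 50,000 (n = 100,000
for the correlation target, where the tolerance is tightest). Estimator-bias
checks average deviations over ~20 replicate fits of n = 5000, separating
bias from single-draw Monte-Carlo noise; Wald CI coverage is measured over
500 replicates at n = 2000. These sizes give Monte-Carlo error comfortably
inside each stated tolerance while keeping the whole suite under a minute.

## 7. Known limitations

* The survey's own regression tables cannot be reproduced without its raw
  data; no targets are set on them, and the generator makes no attempt to
  match conditional (model-based) structure beyond the pairwise
  correlations.
* Complete-case only: the pipeline validates but does not impute
  missingness.
* The published percentages imply n ≈ 152 while the abstract states
  n = 150; the generator takes n as a free parameter and does not resolve
  the discrepancy.
* Selenium is carried through every stage but no deficiency flag is
  computed — no accepted interpretive cutoff exists for plasma selenium.
* No household sampling weights, clustering, or malaria-stratified
  adjustment (no malaria biomarker was measured).
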