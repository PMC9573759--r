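---
title: "Estimating 24-hour urinary sodium and potassium excretion from spot urine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating 24-hour urinary sodium and potassium excretion from spot urine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spoturine24)
```

## The problem

Twenty-four-hour urine collection is the reference method for assessing
dietary sodium and potassium intake, but it is burdensome and error-prone.
Estimating equations instead combine a single casual spot-urine specimen
(sodium, potassium and creatinine concentrations) with demographics to
predict the 24 h excretion a complete collection would have measured. This
package implements, for stroke patients, the development and validation of
such equations: new sex-specific linear models, the published Kawasaki,
INTERSALT and Tanaka comparators, the specimen quality-control filters, the
train/test development step, and the agreement-metric suite used to judge
the result — together with a calibrated synthetic cohort generator so the
whole pipeline is exercisable without access to individual-level data.

## The estimating equations

All equations return mmol/day. Spot concentrations are in mmol/L as assayed.

**New sex-specific equations** (evaluated by `estimate_na_new()` and
`estimate_k_new()`), for males:

$$\widehat{24UNaV} = -0.191\,\mathrm{Age} + 4.349\,\mathrm{BMI}
  + 0.229\,\mathrm{Na} + 1.744\,\frac{\mathrm{Na}}{\mathrm{Cr}} + 41.492$$

$$\widehat{24UKV} = -0.052\,\mathrm{Age} + 0.410\,\mathrm{BMI}
  + 0.031\,\mathrm{K} + 33.280\,\ln\frac{\mathrm{K}}{\mathrm{Cr}}
  - 5.789\,\ln\frac{\mathrm{Na}}{\mathrm{Cr}} - 1.035$$

with female counterparts carrying their own printed coefficients. The
Na/Cr and K/Cr ratios use both concentrations in mmol/L: at typical cohort
values (Na 132, Cr 8.9 mmol/L) the ratio is ~15 and the 1.744 coefficient
contributes ~26 mmol/day, a plausible share of a ~185 mmol/day outcome;
with creatinine converted to mg/L the term would be negligible, so the
dimensionless mmol/mmol reading is adopted.

**Kawasaki and Tanaka** are power laws on the concentration ratio scaled by
a predicted 24 h creatinine excretion $\mathrm{PrUCr}_{24h}$ (mg/day) from
weight, height and age — sex-specific for Kawasaki, sex-free for Tanaka:

$$\widehat{24UNaV}_{Kawasaki} = 16.30\sqrt{\frac{\mathrm{Na}}
  {\mathrm{Cr}_{mg/L}}\,\mathrm{PrUCr}_{24h}},\qquad
\widehat{24UNaV}_{Tanaka} = 21.98\left(\frac{\mathrm{Na}}
  {\mathrm{Cr}_{mg/L}}\,\mathrm{PrUCr}_{24h}\right)^{0.392}$$

Here creatinine is converted to mg/L via the molar mass 113.12 g/mol
(`cr_mmol_to_mg()`). A non-positive predicted creatinine means the
anthropometry is outside the sub-model's domain and raises an error.
Exponent scaling is a structural invariant: doubling spot Na multiplies the
Kawasaki estimate by $\sqrt2$ and the Tanaka estimate by $2^{0.392}$, which
the tests assert to 1e-9.

**INTERSALT** is linear (spot creatinine stays in mmol/L; the female
equation has a $-0.03\,\mathrm{Age}^2$ term). No INTERSALT potassium
equation exists in this family, and `validate_all()` therefore reports
four sodium rows but three potassium rows.

Every printed coefficient lives in a single registry
(`equation_registry()`); a test compares it against an independently keyed
transcription so a typo in one place cannot silently propagate.

Negative estimates are arithmetically possible for extreme covariates in
the linear equations. They are returned unclipped with a warning (and a
`flag_negative` column in batch output): the source analyses describe no
clipping, and downstream agreement metrics must see what the formula
actually produces.

## Specimen quality control

`apply_exclusions()` screens paired spot/24 h records with five rules, in
order: (1) self-reported missed volume over 20% of the total volume, where
total = collected + missed (the self-report describes urine that never
reached the containers); (2) 24 h volume under 0.5 L; (3) 24 h creatinine
excretion outside 4–25 mmol/day (women) or 6–30 mmol/day (men); (4) 24 h
volume and (5) spot creatinine more than 3 SD from the population mean.
All printed inequalities are strict, so boundary values are kept. The 3-SD
rules are two-sided, computed in a single pass from the records surviving
rules 1–3, and evaluated only on those survivors (a specimen already
excluded is no longer part of the population those rules screen); whether
the original analysis iterated these statistics is not documented, and the
single-pass choice is the simplest defensible reading. With fewer than 3
survivors the SD rules are skipped and flagged. Records can accrue several
reason codes; the codes (`missed_fraction`, `volume_low`,
`cr24_out_of_range`, `volume_3sd`, `spotcr_3sd`) are stable strings for
machine-readable flowcharts, and `flowchart_counts()` turns a report into
the enrollment-retention summary (1287 enrolled and 970 kept is 75.4%).

## Development: split and stepwise regression

`split_train_test()` draws a uniform random 70/30 partition with
`round(n * fraction)` (round-half-even) training records; 970 records give
679/291. The historical development cohort reports 689/281 — not an exact
70% of 970 — so the realized historical allocation is treated as an
artifact of its software, not a contract.

`stepwise_lm()` is forward-selection/backward-elimination on the partial-F
p value of a single term: the best candidate enters while its p value is
below `entry_p` (default 0.05), the worst retained term leaves while its
p value exceeds `stay_p` (default 0.10) — the documented defaults of the
SPSS procedure used for the original development — followed by an ordinary
least-squares refit of the retained set. `entry_p <= stay_p` is enforced to
prevent enter/remove cycling. Aliased (rank-deficient) candidates are
dropped up front with a warning; with `entry_p = stay_p = 1` (or
`select = FALSE`) the result is plain OLS on the full candidate set, which
the tests verify against a direct normal-equations solve to 1e-8.
`fit_excretion_models()` applies this machinery per sex and outcome with
the published candidate sets (sodium: age, BMI, spot Na, Na/Cr; potassium:
age, BMI, spot K, ln(K/Cr), ln(Na/Cr)); if selection drops a published term
on a small training set this is reported, not an error.

## Validation metrics

All metrics treat differences as estimated − measured.

* **Mean bias** with a t-based 95% CI and the paired-t p value
  (`mean_bias_ci()`). Zero-variance differences degenerate the CI to a
  point and are flagged as exact agreement.
* **Pearson r**, plus a comparison of two estimators' correlations with
  the measured values (`pearson_with_comparison()`). Because both
  correlations share the measured series, the test is the
  Hittner–May–Silver modification of Dunn–Clark's z for dependent
  overlapping correlations (the default of the cocor tool named by the
  source analysis, which does not specify the exact variant); it is
  implemented from the published formula and cross-checked in the tests
  against a bootstrap of the correlation difference.
* **ICC(A,1)** (`icc_a1()`): two-way model, single measures, absolute
  agreement, with measured and estimated as k = 2 raters:
  $\mathrm{ICC} = (MS_R - MS_E)/(MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E))$.
  Unlike Pearson r it penalizes systematic offsets — adding a constant to
  the estimates leaves r unchanged and strictly lowers the ICC, which is
  property-tested. The CI is the McGraw–Wong F-based procedure (the SPSS
  output the source names); reliability labels use the 0.50/0.75/0.90
  bands. The implementation computes the mean squares directly and is
  tested against an independent `aov()` decomposition on random instances.
* **P30** (`p30()`): the percentage of estimates within 30% of the
  measured value, boundary inclusive ("within" is read as ≤), identical by
  construction to `proportion_within(..., "relative", 0.30)`.
  `proportion_within()` also provides the ±10% relative and ±17.1 (sodium)
  / ±12.8 (potassium) mmol/day absolute cutoffs and full cutoff curves.
* **Bland–Altman** (`bland_altman()`): bias ± 1.96 SD limits of agreement
  (the conventional normal-quantile multiplier, matching the published
  plots, not a t quantile) with exported (mean, difference) pairs.

`validate_all()` assembles these per analyte and method, dropping records
pairwise per method with the per-row n always reported, and applies no
multiple-testing adjustment (the source applies none; significance is
two-sided 0.05).

`sample_size_correlation()` implements the standard Fisher-z planning
formula $n = ((z_{1-\alpha/2}+z_{power})/\operatorname{atanh} r)^2 + 3$
with exclusion-rate inflation. With the stated planning inputs (r = 0.32,
α = 0.05, power 0.90, 10% exclusions) it gives 110 pairs; the source prints
435 from proprietary software whose configuration is not reproducible from
the stated inputs. The implementation keeps the standard formula and
documents the discrepancy rather than reverse-engineering an undocumented
setting.

## The synthetic cohort generator

`generate_cohort()` emulates the study population closely enough that every
pipeline stage — QC, split, fitting, estimation, validation — can be tested
end to end.

**Marginals.** Age 64.5 ± 7.9 y and BMI 24.85 ± 3.44 kg/m² are truncated
normals; spot Na 131.85 ± 62.88 mmol/L is a truncated normal above
5 mmol/L; spot K 55.79 ± 36.09 and spot Cr 8.93 ± 5.60 mmol/L are
log-normals; 24 h volume is 1.60 ± 0.60 L (the printed ±6.00 is read as a
typo for 0.60, which the training/testing SDs 0.62/0.56 bracket). All
truncated normals are *moment-matched*: the underlying mean and SD are
solved numerically so the truncated distribution reproduces the published
moments — otherwise the positivity guards alone would shift the spot Na
and K means by 3–5 mmol/L. The log-normal choice for K and Cr follows from
their coefficients of variation (0.65 and 0.63): a mean/SD pair that large
under a positivity constraint implies right skew, and modelling K as a
truncated normal instead leaves ~10% of its mass below 10 mmol/L in a
deep lower tail that produces physiologically impossible K/Cr ratios.

**Dilution structure.** The three spot concentrations share the urine's
dilution: a concentrated specimen is concentrated in everything. They are
therefore drawn from a Gaussian copula (marginals preserved exactly) with
pairwise correlations `na_k` 0.50, `na_cr` 0.60, `k_cr` 0.85. The values
were fixed once by anchoring to published quantities: with the reported
multiple correlations (below) the measured 24 h SDs implied by the
generator must approach the printed 72.8 (sodium) and ~21 (potassium)
mmol/day, which pins the spread of each linear predictor and hence the
correlation scale. With independent concentrations the K linear predictor's
SD would be ~33 mmol/day — more than twice what the printed measured-K SD
and correlation admit — and the generator could not be self-consistent.

**Outcomes.** Measured 24 h sodium and potassium are the published
sex-specific linear predictors plus Gaussian noise, truncated below at
10 mmol/day (a physiological floor; drawn by inverse CDF). The residual SD
per sex and outcome starts from the closed form
`calibrate_sigma(sd(lin), R) = sd(lin) * sqrt(1/R^2 - 1)` targeting the
reported multiple correlations (sodium 0.42 male / 0.33 female; potassium
0.71 both), then is refined by a one-dimensional root-find so that the
*expected* refitted correlation on the realized covariate sample — computed
deterministically from the truncated-normal conditional moments, so no
extra Monte-Carlo noise enters the calibration — hits the target under the
floor. Refitting the published term sets on an n = 20,000 cohort reproduces
all four correlations within ±0.02 and the sodium coefficients within
Monte-Carlo error. The potassium log-ratio coefficients are attenuated a
few percent (males) to ~11% (females): the few records the floor touches
sit at extreme low log-ratios and carry leverage. 24 h creatinine
(sex-specific normals inside the QC plausibility bands, reproducing the
overall 8.03 mmol/day mean) and height (normal 165/155 cm by sex; weight
derived from BMI) are *invented* marginals — not published — included only
so the QC and anthropometric sub-models have inputs; they carry no
fidelity claim.

**Contamination.** Optional per-rule violation rates inject QC failures
into disjoint record subsets with values that trip exactly one rule each,
so per-rule exclusion counts equal injection counts exactly — the basis of
the QC recovery tests. A clean cohort passes QC at ≥ 98%: the only
systematic clipping is the spot-creatinine 3-SD rule, which removes ~1.6%
because a log-normal with CV 0.63 keeps that much mass beyond mean + 3 SD.
That is a property of applying a normal-theory screen to a skewed marginal,
not a generator defect, and would equally affect the real cohort.

**What passing tests do not show.** The generator draws demographics
independently of concentrations, uses a single collection day, and ignores
intra-individual variation and the salt-substitute intervention arms.
Synthetic agreement tables are therefore *not* expected to reproduce the
published validation numbers (bias 5.17, P30 59.43%, etc.), and the
package makes no such claim; the tests establish arithmetic fidelity of
the equations, correctness of the metric implementations against
independent oracles, and self-consistency of the development pipeline.

## Numerical and design choices

* Creatinine molar mass 113.12 g/mol; NaCl 58.44 g/mol (so 17.1 mmol Na ≈
  1 g salt, and a 12.30 mmol/day sodium difference is 0.72 g).
* BMI is taken from the record when present, else derived from
  height/weight; a reported value disagreeing with the derived one by more
  than 0.5 kg/m² is an input error, not silently preferred.
* One integer seed governs everything random (generation, split); seeded
  functions restore the caller's RNG state, and reruns are byte-identical.
* Problem sizes in the shipped tests were chosen to keep the full suite
  around ten seconds while leaving Monte-Carlo error well inside the
  asserted tolerances: 200 replicates × n = 500 for coefficient recovery,
  n = 20,000 for generator self-consistency, 50 random instances against
  the ANOVA oracle, a 2,000-resample bootstrap for the correlation
  comparison.
* The Kawasaki equations were derived for second-morning urine; like the
  source analysis, the package applies them to casual daytime spot
  specimens, which is part of what the comparison measures.

## Limitations

Linear estimating equations overestimate at low excretion and
underestimate at high excretion (visible in Bland–Altman output here as in
the source); the package reports, and does not correct, this. The
dependent-correlations test and the ICC interval are asymptotic
procedures; at very small n their coverage is approximate. The pipeline
validates formulas at the population the generator emulates — northern
Chinese stroke patients — and says nothing about transportability.
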