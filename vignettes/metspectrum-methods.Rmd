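---
title: "metspectrum: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metspectrum: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metspectrum)
```

## The risk model

`metspectrum` scores adults on a metabolic-syndrome (MetS) risk *spectrum*
rather than a binary diagnosis. The instrument is a weighted sum over 23
binary risk indicators in three tiers, reflecting each factor's strength of
association with insulin resistance and cardiometabolic outcomes:

* **High-impact, weight 2** — the five clinical MetS components at South
  Asian cutoffs: waist circumference (≥ 90 cm men / ≥ 80 cm women), fasting
  glucose ≥ 100 mg/dL, triglycerides ≥ 150 mg/dL, HDL-C < 40 / < 50 mg/dL
  (men/women), blood pressure ≥ 130 systolic **or** ≥ 85 diastolic.
* **Moderate-impact, weight 1** — sixteen lifestyle, anthropometric and
  history items: BMI ≥ 23 kg/m² (the South Asian overweight threshold),
  waist-to-hip ratio above the WHO sex cutoff (> 0.90 / > 0.85), physical
  activity on ≤ 1 day/week, fruit intake "rarely", vegetables on ≤ 1
  day/week, frequent high-fat meals, sleep < 6 h, poor sleep quality,
  current smoking (daily or occasional), alcohol weekly or more, high
  perceived stress, family history of diabetes, family history of
  hypertension/CVD, and three female-specific factors (gestational diabetes
  history, PCOS, postmenopausal status).
* **Demographic, weight 0–1** — age > 40 years and male sex.

Items award their full tier weight when the risk condition holds and 0
otherwise. The source publication's appendix with the verbatim item text
was not obtainable, so the bundled matrix is a documented reconstruction
that reproduces the published tier memberships (5/16/2), the item count of
23, and a maximum attainable total of 28 — which keeps the top band
reachable. It ships as a versioned YAML config
(`default_matrix.yaml`) validated on load, so a refined item set can
replace it without code changes. Three open design points were resolved as
follows: items are binary (the tiers are described as fixed point values,
with no graded scale published); the three female-specific factors above
were chosen as the clinically standard set for MetS risk in women; and the
demographic weights are fixed single points (age > 40 → 1, male → 1) rather
than graded by age band.

Note one structural consequence: the female-specific items (3 points) and
the male-sex item (1 point) are mutually exclusive, so the highest total
one person can attain is 27 (a postmenopausal woman with every factor
adverse); 28 is the matrix-level maximum over all items.

### Risk bands

Totals map to bands low ≤ 9, moderate 10–17, high 18–25, very high ≥ 26.
The published cutoffs ("<9", "10–17", "18–25", ">26") leave the scores 9
and 26 unassigned; the package absorbs 9 into *low* and 26 into
*very high* so the intervals are contiguous. `assign_band()` documents
this prominently and the test suite enumerates every total 0–28.

### Units

Canonical internal units are mg/dL, cm, kg and mmHg. mmol/L is accepted at
I/O and converted with the standard factors (glucose × 18.0, TG × 88.5,
HDL-C × 38.67 mg/dL per mmol/L); round trips are exact to 10⁻⁹ relative.

## Reference classifiers and the TyG index

`classify_idf()`, `classify_ncep()` and `classify_who()` implement the
three established MetS definitions exactly as printed in the source
criteria: IDF = mandatory central obesity plus ≥ 2 of the four remaining
components; NCEP-ATP III = any ≥ 3 of the five; WHO = mandatory diabetes /
impaired glucose tolerance / insulin resistance plus ≥ 2 of hypertension
(≥ 140/90 mmHg or antihypertensive medication), dyslipidemia, obesity
(BMI ≥ 30 or WHR > 0.90/0.85), or microalbuminuria. Because the criteria
here share one component set, IDF positivity implies NCEP positivity; the
converse does not hold, and the test suite verifies the full 2⁵
truth table. Two conventions worth noting:

* WHO's insulin-resistance component is never operationalized in the
  source; it is caller-supplied, with a documented convenience default of
  FBG ≥ 126 mg/dL (diabetes-range fasting glucose). When the decidable
  factors cannot settle the count (e.g. microalbuminuria unknown and one
  factor positive) the classifier returns `NA` rather than guessing.
* The microalbuminuria threshold is quoted in the source as "≥ 20 mg/min";
  the standard WHO value is 20 **µg**/min and we treat the printed unit as a
  typographical slip. It enters only as a caller-supplied boolean, so the
  unit does not affect computation.

The TyG index, `ln(TG × FBG / 2)` with both analytes in mg/dL, serves as
the criterion-validity anchor: it is a validated surrogate of insulin
resistance and should rise across risk bands if the score orders people by
metabolic severity.

## The synthetic cohort generator

No participant-level data are published, so validation runs on synthetic
cohorts that emulate the published study's *marginal* structure (n = 148,
68.2% women, and the reported means/SDs and categorical frequencies for
every variable, sex-specific for WC, HDL-C and — as a modeling choice —
height and WHR) with dependence induced by a **single latent severity
factor** `z ~ N(0,1)` per subject:

* Continuous variables: `x = µ' + ρσ·z + σ√(1−ρ²)·ε`, truncated to
  physiological bounds by inverse-CDF sampling, with `µ'` solved
  numerically so the *truncated* marginal mean equals its target exactly.
  TG is generated log-normally (its published whole-sample and subgroup
  means imply strong right skew); its loading acts on the log scale.
* Categorical variables use a probit link: a latent
  `γ·z + √(1−γ²)·ε` is cut at the Gaussian quantiles of the target
  cumulative frequencies. Marginal frequencies are therefore exact by
  construction for every loading γ, which cleanly separates "match the
  tables" from "induce co-variation".
* Systolic and diastolic pressure share an additional residual correlation
  (0.55, giving a total SBP–DBP correlation ≈ 0.7) so that the record
  invariant SBP > DBP holds essentially always; the rare violating pair is
  swapped.
* One root seed spawns a named child stream per variable, so adding or
  reordering variables never perturbs existing draws, and identical specs
  yield byte-identical cohorts.

A full dependence copula is unidentifiable from published marginals; the
single-factor model is the weakest structure that produces the qualitative
pattern the validation needs (markers rising across bands, HDL-C falling,
a graded TyG index).

### Calibration and its limits

Frequencies not published anywhere (family histories, WHR distribution,
female-specific factors) were fixed once at values plausible for a South
Asian clinical population: family history of diabetes 60%, of
hypertension/CVD 55%, GDM 15%, PCOS 20%, postmenopausal 40% (women, mean
age 42), WHR 0.95 ± 0.06 (men) / 0.89 ± 0.065 (women). High stress and
poor sleep quality follow the published "approximately one-third" (34%).
The loadings were then calibrated in one pass at large n against the
published band-wise TyG gradient (8.3 / 8.7 / 9.4) and band occupancy, and
frozen: ρ = 0.55 for FBG and log-TG, 0.39 for WC and both pressures,
±0.33 for BMI/HDL-C, 0.26 for WHR, 0.23 for age; categorical γ between
0.11 and 0.28. Under these defaults a large cohort scores with mean total
≈ 11.0 (SD 3.7), band shares ≈ 35/61/4%, band TyG means
≈ 8.32/8.90/9.51 and cor(score, TyG) ≈ 0.64.

Two published quantities are *not* reproducible under this design, and
deliberately so:

* The exact band split 21/63/16%. With the published marginal trigger
  rates fixed, the expected total score is ≈ 11; a 21/63/16 split across
  the cutoffs at 9.5 and 17.5 would require a mean near 13. The published
  split presumably reflects item cutoffs in the unavailable appendix that
  differ from this reconstruction. The moderate-band share (≈ 61% at
  large n) still falls within ±10 points of the published 63% for almost
  every seed at n = 148.
* The real cohort's F statistics and p values, and the pilot's κ = 0.82,
  α = 0.84 and AUC = 0.86 — their raw data are unpublished. The package
  implements the *operations* and validates them against analytic cases
  and independent oracles instead.

Passing tests on synthetic cohorts therefore demonstrate that the
machinery is correct and that the documented latent-factor world produces
the published qualitative pattern — not that real patients do.

## Statistical conventions

* **Sample-size calculators.** The correlation design uses the Fisher-z
  formula `n = ceil((z₁₋α/₂+z₁₋β)²/atanh(r)²)+3` with exact normal
  quantiles (not 2-dp table values); at r = 0.30, α = 0.05, power 0.80 it
  returns 85 either way. The ANOVA design searches total N over equal
  allocations (N divisible by k), computing power from the noncentral F
  distribution with λ = f²N and df (k−1, N−k); at f = 0.25, k = 3 the
  smallest adequate N is 159 (power 0.8049; 156 gives 0.7967). Unequal
  allocation is out of scope.
* **ANOVA.** Classical fixed-effects one-way ANOVA (the published
  analysis), not Welch — the Welch correction is available behind a flag.
  Tukey HSD p-values come from the studentized-range distribution
  (`ptukey` via `stats::TukeyHSD`); η² = SS_between/SS_total. Two-sided
  α throughout. Raw p-values are reported; display thresholds are the
  caller's concern.
* **Reliability.** Sample (n−1) variance denominators throughout.
  Cronbach's α from the item/total variance identity; Cohen's κ unweighted
  by default (bands are few), linear weights behind a flag; item-total
  correlations use the corrected (rest-score) form by default, the
  uncorrected form behind a flag; ROC AUC by pair counting with ties at ½
  (equal to the trapezoidal area, asserted over 500 random instances) and
  a DeLong placement-value confidence interval, cross-checked against
  pROC.
* **Missing data.** Scoring treats a missing field as a hard error naming
  the field; an opt-in flag scores missing *moderate-tier lifestyle* items
  as 0 with a warning, never the clinical high-tier items. The CSV reader
  rejects invalid rows into a row-numbered log; counts always reconcile
  (`rows_in = rows_valid + rows_rejected`).

## Problem sizes used by the test suite

Marginal recovery is checked at n = 10⁵ (every continuous mean within ~3
Monte-Carlo SEs of its target); the ANOVA type-I rate under the
zero-loading generator uses 2000 replicate cohorts of n = 120, testing a
variable the instrument does not score (height) — scored markers enter the
total directly, so their band means differ even under the null; the
Monte-Carlo power cross-check uses 4000 replicates at N = 156 and 159.
The end-to-end gradient checks run at the study's own n = 148.

## Known limitations

* The default matrix is a reconstruction; per-item cutoffs may differ from
  the original instrument (see the band-split note above).
* The generator models cross-sectional marginals plus one latent factor:
  no measurement error, no missingness, no age-by-sex interactions beyond
  the sex-specific marginals, and postmenopausal status is linked to the
  severity factor rather than to the drawn age.
* WHO classification depends on caller-supplied insulin-resistance and
  microalbuminuria inputs; with the convenience FBG convention it is
  conservative.
* The package gives no clinical advice; bands are screening aids, not
  diagnoses.
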