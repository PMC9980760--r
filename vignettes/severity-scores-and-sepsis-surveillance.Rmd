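---
title: "Severity scores, Sepsis-3 phenotyping and administrative surveillance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity scores, Sepsis-3 phenotyping and administrative surveillance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisperf)
```

# The problem

Sepsis surveillance at scale needs two things that are usually in tension: a
clinically credible case definition (Sepsis-3: infection plus an acute rise
in SOFA of at least 2 points) and data that exist routinely for every
admission. `sepsisperf` implements both sides of that comparison as a tested
pipeline:

1. **Bedside severity scores** — SOFA, qSOFA, NEWS (RCP 2012) and SIRS —
   computed from timestamped vitals and laboratory results with the
   substitution rules a ward-based retrospective dataset requires, and
   evaluated for predicting 30-day mortality in patients with infection.
2. **Administrative proxies** — ICD-10 discharge codes and blood-culture
   sampling, singly and in Boolean combination — evaluated against the
   Sepsis-3 phenotype with standard diagnostic-accuracy statistics.
3. **A synthetic EHR cohort generator**, so every stage of the pipeline can
   be exercised, benchmarked and regression-tested without access to any
   patient-level dataset.

# Scoring model and substitution rules

All four instruments follow their published band tables. Three conventions
matter for ward data and are applied throughout:

* **Missing-as-normal.** Any absent parameter contributes 0 points. An
  observation with every field missing scores 0 on all four instruments.
  This mirrors how retrospective case-note scoring must treat unrecorded
  values, and it biases scores downward for sparsely observed patients —
  a property tests assert rather than hide.
* **SpO2 substitution for the SOFA respiratory component.** Ward patients
  rarely have arterial blood gases (in the motivating cohort ~87% of
  respiratory components would otherwise be missing). When no PaO2/FiO2
  pair exists in a period, oxygen saturation substitutes: 91-94% scores 1,
  below 91% scores 2, 95% and above scores 0. A blood gas, when present,
  takes precedence and is scored on the PaO2/FiO2 ratio in mmHg
  (kPa x 7.50062; thresholds 400/300/200/100, the two worst bands requiring
  respiratory support, proxied by the supplemental-oxygen flag).
* **AVPU-to-GCS surrogacy for the neurological components.** When GCS is
  unrecorded (~74% of observations in ward practice), AVPU maps to a
  surrogate GCS of A = 15, V = 13, P = 8, U = 3 before banding. The mapping
  is an argument of `sofa_cns_points()` so a different published surrogate
  can be swapped in.

Two SOFA components have inputs a ward dataset usually lacks.
Vasopressor dose categories (scoring 2-4 on the cardiovascular component)
and daily urine output (renal) are accepted as optional arguments of
`sofa_score()` but default to absent, capping the cardiovascular component
at the MAP criterion (MAP < 70 gives 1 point) and leaving creatinine to
carry the renal component. MAP is derived as `DBP + (SBP - DBP)/3` when
both pressures exist; with DBP missing the component scores 0
(missing-as-normal) — no published fallback exists for that case.

Units are fixed to UK laboratory convention: bilirubin and creatinine in
umol/L, platelets and WCC in 10^9/L, PaO2 in kPa, temperature in Celsius.

```{r scoring-example}
sofa_score(platelets = 90, bilirubin = 40, map = 65, avpu = "A",
           creatinine = 100, spo2 = 96)
```

# Sepsis-3 phenotyping

For each admission flagged as infected (a documented source plus at least
one antibiotic dose — the adjudication itself is upstream of this package),
`label_cohort()`:

1. locates **onset** as the earlier of the first blood culture and the
   first antibiotic dose;
2. finds the **point of highest acuity**: the vitals observation with the
   highest NEWS in the 48h before or after onset (ties broken by the
   earlier timestamp); NEWS, qSOFA and SIRS at that observation are the
   analysis scores, with nearest-to-onset values retained alongside;
3. computes **worst-per-24h-period SOFA** over the four periods
   `[-48,-24)`, `[-24,0)`, `[0,24)`, `[24,48)` hours from onset, taking the
   directionally worst value of each input per period (lowest platelets,
   MAP, SpO2, PaO2/FiO2, GCS; highest bilirubin, creatinine); the maximum
   over periods is the analysis SOFA;
4. classifies: ward patients are septic when max SOFA >= 2 (baseline
   assumed zero); patients in critical care within the window are septic
   when the **rise** in SOFA is >= 2.

Window edges are closed-open: the -48h edge is inclusive, the +48h edge
exclusive, so every observation belongs to exactly one period and nothing
outside the window can influence a label (a property test shifts all
timestamps by a year and requires identical output).

**The critical-care baseline.** The rise rule needs a baseline that the
24h-resolution data never state explicitly. The package's default,
`baseline_mode = "min_pre"`, takes the minimum per-period SOFA over the two
pre-onset periods (empty periods count 0), so the delta measures the acute
increase against the patient's best recent state — a conservative reading
of "acute change". `first_pre` (earliest pre-onset period) and `zero`
(treat critical care like the ward) are available for sensitivity
analyses. With onset early in the stay the pre-onset periods are usually
empty, and all three modes coincide.

Admissions with no infection flag are `no_infection` regardless of scores;
multiple infection episodes fold into the first qualifying one, since
results are reported per admission.

# Diagnostic-accuracy statistics

`accuracy_stats()` computes sensitivity, specificity, PPV and NPV from a
2x2 table with 95% CIs. **Clopper-Pearson exact intervals are the
default** because they reproduce, cell for cell, the printed intervals of
the published evaluation grids this package validates against (e.g. a
sensitivity of 65/78 gives 83.3% (73.2-90.8)); Wilson intervals are one
argument away. Display rounding is half-up to one decimal for percentages
and two for AUROCs, with full precision retained in every returned tibble.

For a **binary indicator** the ROC curve has one interior vertex, so its
AUROC is `(sensitivity + specificity)/2`. Its confidence interval uses the
Hanley-McNeil standard error by default: on the bundled reference counts
this reproduces five of the seven printed intervals exactly and the other
two within 0.01 at one bound, whereas the DeLong variance of a two-valued
score (available via `se_method = "delong"`) is materially narrower and
matches none of them. The point estimate is method-independent.

`empirical_auroc()` is the rank (Mann-Whitney) estimator —
P(case > control) + ½P(tie) — and `delong_test()` implements the
placement-value covariance estimator for comparing two correlated AUROCs.
Both are validated against independent oracles: brute-force pairwise
enumeration on a thousand small random instances, exhaustive sign-flip
permutation of the paired scores, a stratified bootstrap of the AUROC
variance, and pROC on shared data. One caveat the tests document rather
than smooth over: at n = 8 the exact permutation law is discrete with large
atoms, so the asymptotic DeLong p-value can differ from the exact
permutation p by up to ~0.1; at n = 40 the two agree within 0.02. Paired
scores that induce identical placements have zero difference variance and
return z = 0, p = 1 with a warning. P-values are two-sided and no
multiplicity adjustment is applied.

# Administrative indicators

`normalise_icd10()` canonicalises codes to dotted uppercase (`a419` ->
`A41.9`) and `icd10_in_list()` matches hierarchically, so `A41` covers
`A41.9`. The explicit-sepsis list is {A40, A41, R57.2}. The packaged
infection list (`inst/extdata/infection_codes.txt`) is a **documented
reconstruction**, seeded from the three chapters that dominate hospital
infection coding — respiratory (J), infectious and parasitic (A-B) and
genitourinary (N) — plus common site-specific infection categories from the
implicit-sepsis literature; it is plain text, one prefix per line, and
intended to be replaced by a locally validated list where one exists. The
two lists are made disjoint at load time. Code position (primary vs
secondary diagnosis) is ignored: any position counts.

Blood-culture results are `negative`, `positive` or `contaminated`;
contaminants count toward sampling but never toward positivity. Seven
indicators are evaluated: infection code, sepsis code, either code, culture
sampled, positive culture, code-or-culture, code-and-culture. Their Boolean
structure implies testable laws — an OR never has lower sensitivity, an AND
never higher, than its components — asserted on the bundled counts and on
random synthetic cohorts. The reference definition is the Sepsis-3 label by
default, or infection with NEWS >= 7 as the alternative high-risk
definition.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a
blood-culture-matched, infection-oversampled hospital cohort. Defaults are
the motivating study's conditions: 65.7% infection prevalence, 55.1% of
infected meeting Sepsis-3, 30-day mortality from admission of 19.9% /
5.3% / 4.0% by category, culture sampling of 66.0% / 70.3% / 15.5%,
positivity of 11.35% / 8.04% / 0 among sampled, explicit-sepsis coding
sensitivity 7.8% (2.46% in non-sepsis admissions), and infection-coding
probabilities (65.1% in sepsis; the published non-sepsis aggregate of 32.4%
is split 45% / 21.5% between infected-without-sepsis and uninfected so the
aggregate is preserved). Length of stay is lognormal with category medians
5.8 / 3.9 / 3.8 days and sigma 0.78 on the log scale (chosen to match the
published interquartile ranges); critical-care episode rates are 15.3% /
6.0% / 6.7%.

The **vitals model** is deliberately simple and documented as such: each
parameter is Gaussian noise around a normal baseline plus a
category-conditional derangement that follows an exponential pulse
`exp(-|t - onset| / tau)` with `tau = 30` h, sampled every 4-8 hours. Septic
admissions draw multi-organ derangements (SpO2 depression ~9%, platelets
toward 110, creatinine toward 190, plus hypotension, tachycardia, fever and
occasional altered mentation) so that the worst-per-period SOFA crosses 2
with near certainty; mild infections draw febrile, tachycardic,
tachypnoeic responses whose SpO2, blood-pressure and laboratory components
are kept **subclinical** — clear of the SOFA bands — because the category
*means* "infection without organ dysfunction". Critical-care admissions
additionally receive arterial blood gases whose hypoxaemia and oxygen
requirement track the same pulse, with room-air normal gases (PaO2/FiO2
well above 400 mmHg) away from onset; an early version of the model drew
"normal" gases on 30% oxygen, which silently scores 2 respiratory points
and mislabelled uninfected critical-care patients — the fixed model is the
one shipped. Under these defaults `label_cohort()` recovers the latent
category with error well under 1%, which is what makes the end-to-end
recovery checks meaningful.

What the generator does **not** emulate: organism distributions,
device-level FiO2, care processes that react to deterioration (observation
frequency is independent of state), coding that depends on documentation
quality, or correlated comorbidity. Passing recovery tests therefore show
that the pipeline is a consistent estimator of the quantities the generator
encodes — not that it would reproduce any particular hospital's numbers.

Randomness uses one master seed with a named substream per data domain
(admissions, onset, deaths, episodes, vitals, labs, cultures, antibiotics,
codes), so extending one domain never perturbs the draws of another, and
identical parameters and seed give byte-identical cohorts.

Study-design operations mirror the sampling frame: `apply_eligibility_filters()`
removes maternity admissions and stays under 24 hours (the generator
produces both at low rates, 2% and 4%, so the filters are exercised
in-pipeline); `match_culture_pairs()` greedily matches culture-sampled
admissions 1:1 to controls in the same ward within ±24h (±96h for critical
care) of the culture with length-of-stay tolerance ±24h (±48h), each
control used once, ties broken by smallest LOS difference then earliest
admission — greedy rather than optimal bipartite matching, mirroring
feasible manual practice, with tie-breaks fixed for reproducibility;
`sample_study_cohort()` keeps every critical-care pair and randomly samples
ward pairs to the target size, preserving pair integrity.

# Numerical and degenerate-input choices

* Band boundaries follow the published tables exactly; every threshold is
  tested at the value and one hundredth either side.
* A statistic with a zero denominator is returned as `NA` with a warning,
  never silently as 0; single-class AUROC inputs are errors.
* Empty acuity windows score 0 with a warning and are counted.
* Mortality windows are inclusive of day 30 (onset + 720 h exactly counts).
* 30-day, in-hospital and 30-day-from-admission endpoints are all computed;
  the score grid evaluates whichever the configuration selects.
* Physiologically impossible inputs (SpO2 > 100, negative rates, FiO2
  outside [0.21, 1]) raise a typed `invalid-input` error rather than
  scoring.

# Problem sizes

The bundled validation re-derives the published grids from their printed
2x2 counts (instantaneous), and the end-to-end recovery run uses a
20,000-admission synthetic cohort — large enough that three Monte-Carlo
standard errors on a 7.8% coding sensitivity are under one percentage
point, and small enough to generate and label in well under a minute on a
single CPU. The test suite uses cohorts of 120-400 admissions for
structural properties and the 20,000-admission run for recovery.

# Known limitations

* The infection-code list is a reconstruction; sensitivity analyses should
  swap in a validated local list.
* NEWS2 (the 2017 revision with the hypercapnic SpO2 scale) and paediatric
  or maternity scores are out of scope; maternity admissions are excluded
  by design.
* The Sepsis-3 labeller's time resolution is the 24h period; it does not
  attempt hour-level onset timing or real-time alerting.
* Patient-level discrimination of the scores for mortality (AUROCs near
  0.78 in the motivating cohort) is not reproducible from synthetic data:
  in the generator mortality depends on vitals only through the latent
  category, so synthetic AUROCs reflect category separation alone. The
  pipeline computes them; the tests assert only structure (all above 0.5,
  SOFA and NEWS at least as discriminative as SIRS).

# Worked example

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(params = cohort_params(n_admissions = 2000), seed = 1)
res <- run_pipeline(cfg)
format_performance(res$score_grid)
format_performance(res$admin_grid)
```

The printed-count validation needs no simulation:

```{r reference}
format_performance(reproduce_reference_grids()$admin)
```
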