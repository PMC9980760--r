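# sepsisperf

Evaluating bedside severity scores and administrative data for sepsis
surveillance.

## The problem

Sepsis under the Sepsis-3 consensus definition — infection plus an acute
rise in the Sequential Organ Failure Assessment (SOFA) score of at least 2 —
is a clinical phenotype that administrative data capture badly: explicit
ICD-10 sepsis codes (A40, A41, R57.2) are highly specific but miss most
cases, while infection codes and blood-culture sampling are sensitive but
unspecific. At the bedside, simpler scores (qSOFA, NEWS, SIRS) compete with
SOFA for identifying patients with infection at high risk of death.
`sepsisperf` implements both evaluations as a reusable, fully tested R
pipeline:

* **Scoring** — SOFA, qSOFA, NEWS (RCP 2012) and SIRS from timestamped
  vitals and labs, with the substitution rules ward data require: SpO2
  replaces the PaO2/FiO2 respiratory component when no blood gas exists
  (91–94% → 1 point, <91% → 2), AVPU maps to a surrogate GCS
  (A=15, V=13, P=8, U=3) when GCS is unrecorded, and every missing
  parameter scores 0 ("missing as normal").
* **Sepsis-3 phenotyping** — infection onset = min(first blood culture,
  first antibiotic); analysis scores at the highest-NEWS observation within
  ±48 h of onset; SOFA from the worst values per 24 h period over the four
  periods spanning that window; sepsis if max SOFA ≥ 2 (ward) or the rise
  in SOFA ≥ 2 (critical care within the window).
* **Diagnostic accuracy** — sensitivity, specificity, PPV, NPV with
  Clopper–Pearson exact 95% CIs; empirical AUROC by the rank estimator
  `P(score_case > score_control) + ½P(tie)`; binary-indicator AUROC
  `(sensitivity + specificity)/2` with Hanley–McNeil intervals; DeLong's
  placement-value test for paired AUROCs.
* **Administrative surveillance** — normalised ICD-10 code matching against
  configurable sepsis/infection code lists, blood-culture flags
  (contaminants count as sampled, never positive), and the seven Boolean
  indicator combinations, evaluated against the Sepsis-3 label or an
  infection-plus-NEWS≥7 reference.
* **Synthetic EHR cohorts** — a generator with latent truth
  (category, onset) whose defaults encode the motivating study conditions:
  65.7% infection prevalence, 55.1% sepsis among infected,
  category-conditional mortality (19.9/5.3/4.0%), culture sampling
  (66.0/70.3/15.5%) and coding probabilities (explicit-sepsis coding
  sensitivity 7.8%), plus the study-design operations (eligibility filters,
  greedy 1:1 blood-culture matching, critical-care-complete cohort
  sampling).

## Worked example

```r
library(sepsisperf)

coh <- generate_cohort(cohort_params(n_admissions = 2000, seed = 1))
lab <- label_cohort(coh)
table(lab$category)
#>        no_infection infection_no_sepsis              sepsis
#>                 723                 577                 700

format_performance(score_performance(lab)$grid)
#>  score cutoff n_positive       sensitivity       specificity               ppv               npv
#>   sofa      2        701 75.3% (67.6-82.0) 47.8% (44.9-50.8) 16.1% (13.5-19.1) 93.6% (91.3-95.4)
#>   news      5        833 83.3% (76.4-88.9) 37.2% (34.3-40.1) 15.0% (12.6-17.6) 94.4% (91.8-96.3)
#>   news      7        712 76.0% (68.4-82.6) 46.9% (44.0-49.9) 16.0% (13.4-18.9) 93.6% (91.3-95.5)
#>   sirs      2       1077 92.7% (87.3-96.3) 16.8% (14.6-19.1) 12.9% (11.0-15.1) 94.5% (90.4-97.2)
#>  qsofa      2        601 62.7% (54.4-70.4) 55.0% (52.1-57.9) 15.6% (12.8-18.8) 91.7% (89.4-93.7)

ind <- build_indicators(coh$codes, coh$cultures, lab$admission_id)
format_performance(evaluate_indicators(ind, lab$category == "sepsis"))
#>                 indicator       sensitivity       specificity  ...            auroc
#>            infection_code 64.6% (60.9-68.1) 70.0% (67.4-72.5)  ... 0.67 (0.65-0.70)
#>               sepsis_code    7.7% (5.8-9.9) 96.9% (95.8-97.8)  ... 0.52 (0.50-0.55)
#>           code_or_culture 89.7% (87.2-91.9) 43.6% (40.9-46.4)  ... 0.67 (0.64-0.69)
#>  ...
```

Each row is one test against one reference: the score grid reads "of the
2000 synthetic admissions, 700 + 577 had infection; a SOFA of ≥2 flagged 701
of them, catching 75.3% of the 30-day deaths from onset at 47.8%
specificity". The administrative grid shows the expected structure: the
explicit sepsis code is near-perfectly specific but 7.7% sensitive, while
code-or-culture is the most sensitive (89.7%) and least specific
combination.

The package also ships the 2×2 counts of a published 958-admission
evaluation cohort and re-derives every cell of its performance grids from
those counts alone:

```r
format_performance(reproduce_reference_grids()$scores)
#>  score cutoff       sensitivity       specificity               ppv               npv
#>   sofa      2 83.3% (73.2-90.8) 48.9% (44.7-53.2) 18.7% (14.8-23.2) 95.4% (92.3-97.5)
#>   news      5 84.6% (74.7-91.8) 51.1% (46.8-55.3) 19.6% (15.5-24.3) 95.9% (93.0-97.9)
#>   news      7 67.9% (56.4-78.1) 73.4% (69.5-77.0) 26.5% (20.5-33.2) 94.2% (91.5-96.2)
#>   sirs      2 89.7% (80.8-95.5) 39.3% (35.2-43.5) 17.3% (13.7-21.3) 96.4% (93.1-98.5)
#>  qsofa      2 42.3% (31.2-54.0) 90.0% (87.2-92.4) 37.5% (27.4-48.5) 91.7% (89.0-93.9)
```

See `vignettes/severity-scores-and-sepsis-surveillance.Rmd` for the full
account of the model, the substitution rules, the synthetic-data generative
model and its limitations.

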