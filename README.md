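# dxconcord

Diagnostic concordance of symptom-checker condition suggestions with
clinician ICD-10 diagnoses.

App-based symptom checkers emit a ranked list of condition suggestions;
in mental-health care the reference standard is a structured clinical
interview that typically yields *several* comorbid ICD-10 diagnoses per
patient. `dxconcord` is for researchers evaluating a checker against
such multi-diagnosis records. It provides:

* **Rule-based ICD-10 matching** — exact 4-digit comparison plus the
  clinically motivated equivalences used in this literature: 3-digit
  matching for disorders whose 4th digit only grades severity (F32,
  F33, F31, F42, F91, F20), recurrent ≡ nonrecurrent depression
  (F33.x ≡ F32.x), agoraphobia/panic credit for F40.01, abuse ≡
  dependence within a substance stem (F10–F19), and an editable
  free-text term map (*Burnout* → F32, functional somatic syndromes →
  F45, ...).
* **Agreement statistics** — top-1/top-5 percent agreement with
  Agresti–Coull 95% CIs
  (ñ = n + z², p̃ = (x + z²/2)/ñ, p̃ ± z·√(p̃(1−p̃)/ñ));
  per-category patient-level 2×2 tables with accuracy, sensitivity,
  specificity; and Gwet's first-order agreement coefficient
  AC1 = (pₐ − pₑ)/(1 − pₑ) with pₑ = 2π(1−π), a chance-corrected
  coefficient that stays stable under the skewed base rates where
  Cohen's κ collapses, with linearized variance, CI and benchmark
  label.
* **Usability scoring** — System Usability Scale scores
  (2.5 × Σ adjusted items, range 0–100) with Bangor benchmark labels,
  per-item feedback agreement frequencies, and flagged single
  imputation for sparse missingness.
* **A synthetic cohort generator** — reproducible cohorts with the
  study-like structure (≈2 comorbid diagnoses and ≈3.4 ranked
  suggestions per patient, configurable category prevalences and true
  top-1/top-5 match rates), with distractor suggestions guaranteed
  non-matching under the full rule set; used for end-to-end testing and
  parameter-recovery experiments.

## Worked example

The `analysis/` scripts run the whole pipeline as a narrative workflow:

```sh
Rscript analysis/01_simulate_cohort.R   # 49-patient synthetic cohort -> results/cohort.csv
Rscript analysis/02_concordance.R       # matching + agreement report -> results/report.{json,md}
Rscript analysis/03_recovery.R          # 400-replicate CI coverage   -> results/recovery.json
Rscript analysis/04_usability.R         # SUS + feedback scoring      -> results/usability.json
```

Step 2 prints (this exact output, seed 20260925):

```
Symptom-checker concordance report (n = 49 patients)
  top-1 agreement: 25/49 = 51.0% (95% CI 37.5-64.4)
  top-5 agreement: 34/49 = 69.4% (95% CI 55.4-80.6)
  diagnoses detected per patient: mean 0.69 (SD 0.47)
  affective_top1                   acc 0.61 (0.47-0.74)  sens 0.38  spec 0.87  AC1 0.26 (fair)
  affective_top5                   acc 0.65 (0.51-0.77)  sens 0.65  spec 0.65  AC1 0.31 (fair)
  anxiety_top1                     acc 0.65 (0.51-0.77)  sens 0.31  spec 0.82  AC1 0.42 (moderate)
  anxiety_top5                     acc 0.59 (0.45-0.72)  sens 0.69  spec 0.55  AC1 0.20 (poor)
  somatoform_associated_top1       acc 0.92 (0.80-0.97)  sens 0.20  spec 1.00  AC1 0.91 (very_good)
  somatoform_associated_top5       acc 0.78 (0.64-0.87)  sens 0.40  spec 0.82  AC1 0.70 (good)
  SUS: mean 80.32 (SD 6.11), acceptable
```

Reading it: the checker's first suggestion matched at least one
clinician diagnosis for 25 of 49 synthetic patients (51.0%, Agresti–
Coull 95% CI 37.5–64.4%); some top-5 suggestion matched for 34 of 49
(69.4%). Each category line is a patient-level 2×2 comparison —
e.g. for somatoform disorders with the top-1 window, accuracy
(TP+TN)/N is 0.92 and chance-corrected agreement AC1 is 0.91 ("very
good" band). The cohort was generated with true match rates
θ₁ = 0.51 and θ₅ = 0.69, so the pipeline recovers its generating
parameters here by construction of the experiment, not by fiat — step 3
quantifies this over 400 replicates (empirical CI coverage 0.917, mean
absolute error 0.057).

The same `evaluate_study()` call accepts any cohort CSV in the
documented long format (one row per patient × source × rank), so a
transcription of a real study's per-patient appendix produces the full
report without code changes:

```r
library(dxconcord)
cohort <- read_cohort("results/cohort.csv")   # or your own file
report <- evaluate_study(cohort, k = 5, conf_level = 0.95)
report_markdown(report)
```

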