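---
title: "Evaluating symptom-checker diagnostic concordance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating symptom-checker diagnostic concordance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxconcord)
```

## The evaluation problem

App-based symptom checkers return a ranked list of condition suggestions;
clinicians working from structured diagnostic interviews assign one or
more ICD-10 diagnoses per patient. `dxconcord` measures how well the two
agree in a mental-health outpatient setting, where the gold standard is
multi-diagnosis (about two comorbid disorders per patient) and the
checker's output is a short ranked list, often with a secondary "less
probable" tail.

Agreement is assessed at two levels:

* **Patient level.** Does the checker's first suggestion (top-1), or any
  of its first five suggestions (top-5), match at least one clinician
  diagnosis? The "less probable" suggestions fill the top-5 window when
  fewer than five main suggestions exist.
* **Category level.** For the most prevalent disorder categories
  (affective F30–F39, anxiety F40–F41, somatoform-associated F45), each
  patient is binarized on both sides — does the clinician record contain
  the category, does the checker's top-k list contain it — and the
  resulting 2×2 table yields accuracy, sensitivity, specificity and a
  chance-corrected agreement coefficient.

## ICD-10 matching rules

The default comparison is exact at 4-digit precision (`F40.1` ≠
`F40.2`). On top of this sit enumerated clinical equivalences, chosen
because the checker's vocabulary is coarser than a structured interview:

1. **3-digit exception set** — for depressive episode (F32), recurrent
   depression (F33), bipolar disorder (F31), OCD (F42), conduct disorder
   (F91) and schizophrenia (F20), the 4th digit grades severity or
   course, so codes agree at the 3-digit stem.
2. **Recurrent ≡ nonrecurrent depression** — checkers do not emit F33
   codes, so F33.x is folded onto F32.x before rules 1 and the exact
   rule apply.
3. **Agoraphobia with panic disorder (F40.01)** — a clinician diagnosis
   of F40.01 is credited to any agoraphobia suggestion (F40.0x) and to
   panic disorder (F41.0). This rule is deliberately asymmetric: it keys
   on the clinician side carrying F40.01.
4. **Abuse ≡ dependence** — within one psychoactive-substance stem
   (F10–F19), harmful use (.1x) and dependence (.2x) agree, because
   checkers do not distinguish abuse from addiction.

Free-text suggestion labels are resolved through an editable CSV term
map before matching. The shipped map carries the study conventions —
*Burnout* is coded as a depressive disorder (F32), functional somatic
syndromes (irritable bowel syndrome, fibromyalgia, chronic fatigue,
tension headache) as somatoform disorders (F45) — plus a conventional
label table for common mental-disorder terms. Unknown labels resolve to
an *empty* code set with a warning; the package never guesses.

Two deliberate strictness decisions, made where the design was open:

* A bare 3-digit code matches a 4-digit code only through the exception
  set; there is no generic prefix matching. Consequently a functional
  somatic syndrome label (mapped to bare `F45`) is only creditable
  against a clinician code of exactly `F45` at the patient-match level,
  while category-level analyses count it as somatoform regardless.
* "Somatoform and associated disorders" is F45.* (plus term-mapped
  labels) by default; broader readings (F44, F48) can be enabled via
  `icd10_category(extra_somatoform = )` but are off by default, since
  only F45 is anchored explicitly.

## Agreement statistics

**Percent agreement.** Top-1 and top-5 agreement are binomial
proportions with Agresti–Coull intervals: with \(z\) the normal quantile
(the exact value 1.959964 at 95%, for determinism),
\(\tilde n = n + z^2\), \(\tilde p = (x + z^2/2)/\tilde n\), and bounds
\(\tilde p \pm z\sqrt{\tilde p(1-\tilde p)/\tilde n}\), clipped to
[0, 1]. Printed percentages round half away from zero to one decimal.

**Gwet's AC1.** Cohen's kappa collapses under skewed base rates — the
somatoform category has prevalence below 10% here — so the headline
chance-corrected coefficient is AC1:
\[
\mathrm{AC1} = \frac{p_a - p_e}{1 - p_e}, \qquad
p_e = 2\pi(1-\pi),
\]
with \(p_a\) the observed patient-level agreement and \(\pi\) the mean
of the two raters' marginal probabilities. The variance uses Gwet's
first-order linearization for two raters and two categories (the
approach of standard agreement software); a leave-one-subject-out
jackknife is available via `gwet_ac1(variance = "jackknife")` for
verification. Interval bounds are truncated to [−1, 1], so a reported
interval always brackets its point estimate. With two categories
\(p_e \le 1/2\), hence AC1 is always in [−1, 1]. Benchmark bands are
poor (<0.20), fair (0.21–0.40), moderate (0.41–0.60), good (0.61–0.80),
very good (>0.81); the formal gaps between printed band edges are
assigned to the lower band, with a message.

Kappa is kept only as an internal test oracle: on tables whose two
marginals both equal one half, AC1 and kappa coincide exactly, which the
test suite exploits.

**Contingency statistics.** Accuracy is \((TP+TN)/N\) with an
Agresti–Coull interval on the agreement count; sensitivity
\(TP/(TP+FN)\) and specificity \(TN/(TN+FP)\) are reported as `NA`
("undefined") when a denominator is zero — never silently as 0/0. The
patient-level binarization used to build the 2×2 tables is a design
choice (the alternative — diagnosis-level units — is not adopted), and
both the top-1 and top-5 variants are always computed.

## Usability scoring

SUS scores use the standard formula: on the 1–5 response convention,
adjusted odd items are raw − 1, adjusted even items 5 − raw, and the
score is 2.5 times the adjusted sum, so scores span 0–100. Instruments
administered on a 0–4 convention are shifted up by one first (with a
message); the two conventions then score identically — only this reading
keeps the standard formula on the 0–100 range. Benchmarks: >70
acceptable, ≥85.5 excellent (strict at 70, inclusive at 85.5).

Missing questionnaire cells are handled by *flagged single imputation*
(item mean or person mean), refused when any item exceeds the
missingness ceiling (default: at most ⌈0.04·n⌉ responses per item, the
"infrequent, at most 4%" regime this pipeline is designed for).
Multiple imputation via MCMC is deliberately out of scope: imputation is
not the scientific contribution, missingness is tiny, and a flagged
deterministic fallback is auditable. McDonald's ω reliability is
likewise not computed.

Feedback items are aggregated per item as the share of "agree"/
"completely agree" answers (3 or 4 on the 4-point scale) among
non-missing responses. The default generator emulates eleven analyzed
items, matching the published item table.

## The synthetic cohort generator

No public per-patient dataset exists for this design, so the generator
is a first-class module: it produces cohorts with the study's structure
under a known truth, which is what every end-to-end test and the
recovery experiment run on.

* **Counts.** Diagnoses per patient are 1 + Binomial(14, 1.06/14)
  (mean 2.06, SD 0.99) and suggestion-list lengths 1 + Binomial(5,
  2.44/5) (mean 3.44, SD 1.12) — shifted binomials moment-matched to the
  reported means and SDs, since only summary statistics are available.
  SD matching for the suggestion count is approximate (1.12 vs 1.06):
  with the minimum at 1, no shifted binomial hits both moments exactly.
* **Categories.** Each diagnosis's category is drawn from the
  prevalence vector (0.337, 0.267, 0.089, 0.307); the code is then
  drawn within the category, resampling codes (keeping the category)
  when the candidate is equivalent to an already-assigned diagnosis.
  Comorbid diagnoses are drawn independently — the joint comorbidity
  structure of real records is not emulated.
* **Match construction.** With probability `theta_top1` the rank-1
  suggestion is built to match one diagnosis; with probability
  `theta_top5 − theta_top1` the match is placed uniformly on ranks 2–5
  (clipped to the drawn list length, so list-length moments are not
  distorted). The matching suggestion instantiates a uniformly chosen
  applicable rule — exact code, severity variant, F32↔F33 swap,
  agoraphobia/panic credit, abuse↔dependence swap, or a label-only
  suggestion (Burnout, panic disorder, functional somatic syndromes)
  routed through the term map — so the tricky equivalences are exercised
  constantly, not only in unit tests.
* **Distractor safety.** All remaining suggestions are rejection-sampled
  against the *full* rule set rather than drawn from curated "safe"
  lists, so the guarantee survives term-map edits. Because a patient's
  diagnoses are mutually non-equivalent and distractors never match,
  each patient detects exactly 0 or 1 diagnoses; the expected
  per-patient detection count equals `theta_top5`, which gives the
  generator an analytic oracle.

Reproducibility is contractual: the same seed and configuration give a
byte-identical cohort (`withr::with_seed` isolates the generator from
ambient RNG state). The usability generator draws SUS items
independently per item with an adjusted-contribution distribution whose
default mean yields scores around 81.5; real SUS items are positively
correlated, so synthetic score SDs run lower than real ones — a known
limitation that does not affect what the tests assert.

What passing tests on synthetic cohorts do **not** show: performance of
any real checker, realistic comorbidity patterns, or label vocabularies
beyond the shipped term map. They do show that the matching rules,
interval estimates and agreement coefficients are computed correctly
and that the pipeline recovers known generating parameters at study
scale.

## Numerical and scale choices

* The recovery experiment runs 400 replicates of 49-patient cohorts at
  a generating top-1 rate of 0.51 — the study's size and estimate — and
  checks interval coverage (expected near-nominal, between 0.91 and
  0.99 for Agresti–Coull at this n) and mean absolute error
  (below 0.08).
* Oracle-equivalence tests for AC1 run on 1,000 random 2×2 tables with
  n between 10 and 200. The point estimate is compared exactly (1e−12)
  against recomputation from raw binary vectors. The linearized
  variance is compared with the jackknife at 10% relative error; these
  two estimators genuinely differ at order 1/n, so extremely skewed
  tables near n = 10 can exceed that bound — the comparison is kept at
  its strict tolerance rather than widened, and the typical (median)
  disagreement is well below 1%.
* Property tests (SUS monotonicity, match monotonicity in k, code-pair
  oracle equivalence) run a few hundred randomized cases each under
  fixed seeds.
* Published interval targets (25/49, 34/49, 10/23, 14/23) reproduce at
  the printed 1-decimal rounding; the published per-category table
  itself is **not** desk-reproducible because the underlying per-patient
  records are not public — the end-to-end path is instead accepted on a
  bundled hand-verified 6-patient fixture plus the recovery experiment.
  A CSV transcription of the real per-patient appendix in the package's
  cohort dialect would produce the full report without code changes.

## Known limitations

* The term map beyond the explicitly stated conventions is an
  implementer-supplied vocabulary, not ground truth from any checker.
* Patient-level binarization for the 2×2 tables is one of two defensible
  readings of the published analysis; diagnosis-level units would give
  different sensitivity/specificity.
* The generator's independence assumptions (across patients, across
  comorbid diagnoses, across questionnaire items) are simplifications;
  estimates of variability on synthetic data are accordingly optimistic.
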