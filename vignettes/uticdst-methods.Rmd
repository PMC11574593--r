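---
title: "Methods: the 3-question UTI/ASB rule and its retrospective validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 3-question UTI/ASB rule and its retrospective validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uticdst)
```

## The clinical problem

Bacteria in the urine of a hospitalized adult are, more often than not,
asymptomatic bacteriuria (ASB) rather than a urinary tract infection (UTI).
Treating ASB with antibiotics confers no benefit outside a few specific
populations, yet it is common — driven by reflexive urine testing, elevated
white counts, and patients (elderly, demented, intoxicated, unstable) who
cannot give a reliable history. `uticdst` implements a sequential
three-question stewardship rule that gates urine testing and antibiotic
treatment, and the machinery needed to validate it retrospectively against
full-stay chart adjudication.

## The decision rule

`cdst_evaluate()` asks, in order, with short-circuiting:

1. **Special populations** — pregnancy, an impending endourological
   procedure, or renal transplantation within the past 60 days. These are
   the guideline indications for treating bacteriuria regardless of
   symptoms.
2. **Localized urinary symptoms** — urgency, frequency, dysuria, suprapubic
   pain, pelvic discomfort, or flank pain. Any one suffices.
3. **Systemic signs** — fever, clinical instability, or an acute change in
   mental status, *provided no alternate (non-urinary) explanation for
   those signs is documented*. A UTI is then a diagnosis of exclusion.

If no question fires, testing and treatment are not indicated. Design
choices worth stating explicitly:

* **Fixed precedence.** `fired_question` reports the lowest-numbered
  affirmative question, so attribution is deterministic. Since any
  affirmative answer yields the same recommendation, precedence does not
  change `indicated`.
* **Poor historians are not an automatic indication.** Question 2 evaluates
  *documented* localized flags only; a patient who cannot report symptoms
  reaches the rule through Question 3. The serialization format therefore
  distinguishes an empty cell (not documented) from an explicit `false`.
* **Clinical instability is an input flag**, not computed from vital signs;
  no vital-sign thresholds are part of the rule.
* **One joint output.** The affirmative branches make both urine studies
  and treatment appropriate; the engine does not separate the two, and the
  timing of empiric treatment under Question 3 (treat now versus await
  exclusion of other causes) is left to the caller.

## Syndrome adjudication and the reference standard

`cdst_adjudicate()` classifies each case with the precedence
other infection > pyelonephritis > cystitis > ASB:

* **other_infection** whenever a non-urinary source is documented. The
  source is resolved first because the pyelonephritis definition carries
  "without another etiology". A documented source with a *concurrent* true
  UTI (the pneumonia case that grew *E. coli* in blood and urine) keeps
  this label — the truth lives in the adjudicated reference standard, not
  in the syndrome.
* **pyelonephritis** on flank pain, or fever/instability without an
  alternate explanation.
* **cystitis** on localized urinary symptoms without fever. We broadened
  the narrow "dysuria without fever" definition to the full Question-2
  symptom list; dysuria alone still suffices. One edge this creates: a
  record with localized symptoms *and* fever explained by a non-urinary
  cause (but no documented source label) falls through to ASB. No record in
  the fixture or generator takes this path.
* **asb** is the residual: no urinary symptoms and no fever or instability
  attributable to the urinary tract. Systemic signs with a documented
  alternate cause (seizure, psychosis, metabolic derangement, shock)
  classify as ASB, mirroring how altered-mental-status episodes were
  attributed in the validation study.

`truly_needed` — whether treatment for a urinary pathogen was actually
needed on review of the complete hospitalization — is an **input field**,
never computed: the reference standard came from human chart review, and
computing it from the same flags the rule reads would make the validation
circular (a limitation the source data share, since the reviewers saw the
same chart). `inappropriate` marks ASB without a treatment indication,
without a documented non-urinary source, and without true need.

## Diagnostic accuracy

`cdst_validate()` cross-tabulates the rule's indication against
`truly_needed` and reports sensitivity TP/(TP+FN) and specificity
TN/(TN+FP) with exact Clopper–Pearson intervals, computed from beta
quantiles. Exact intervals were chosen because the validation estimates
specificity at 100%, where Wald intervals collapse to zero width.
Percentages print half-up at one decimal — so 73/74 = 98.648% prints as
98.6%, and exact halves round away from zero rather than to even.

Group comparisons (`compare_proportions()`, `compare_means()`) use the
Pearson chi-square without continuity correction and the Welch t-test by
default; both variants are one flag away, since the study does not state
which was used. Records missing the marker are excluded per comparison.
Degenerate tables (an empty margin) return statistic 0, p = 1: there is no
association to test. The published urinalysis subgroup percentages cannot
be reconstructed — their per-marker denominators are not recoverable from
the text — so `compare_urinalysis()` is validated by oracle equivalence on
toy data instead, and the published marker rates appear in this package
only as generator defaults.

## Antibiotic burden

Days of therapy (DOT) are **per-agent calendar days summed over agents**: a
patient on two drugs for three days accrues six. This is the only counting
rule under which the published class-level totals (203 cephalosporin days,
51 amoxicillin-clavulanate days within 787 overall) are coherent.
Appropriateness is a **record-level** property applied to all of a
record's courses, matching burden stratified by patient. Outpatient
continuation prescriptions count when present in the input.

One arithmetic wrinkle: 265/787 = 33.67%, which rounds to 33.7% at one
decimal, while 33.6% is reproduced only by truncation. `reduction_fraction()`
returns the unrounded proportion and the report layer offers both formatted
variants; the discrepancy is documented, not resolved.

## The fixture cohort

`build_fixture()` deterministically constructs a 124-record cohort
satisfying every published marginal simultaneously; an internal self-check
recomputes all of them at build time and errors on any failure. The
composition of the tool margins is forced: the 73 flagged cases can only be
50 pyelonephritis + 15 cystitis + 8 procedural-ASB, and the 51 unflagged
are 38 inappropriate-ASB + 13 other-infection records whose fever carries
an alternate explanation, one of which (the pneumonia/bacteremia case) was
truly needed — giving TP 73, FP 0, FN 1, TN 50.

Quantities the study does not pin down are fixed design choices:

* **Per-patient antibiotic durations** follow an even deterministic
  schedule within each stratum (`distribute_days()`); only the stratum
  totals are load-bearing.
* **Ages** are a fixed sequence pinned to median 64 and IQR 46–74.25 under
  type-7 quantiles, dealt through a fixed permutation so strata are not
  age-ordered.
* **Poor historians (36)** are allocated 10 to pyelonephritis, 2 to other
  infections, and 24 to ASB (including all 9 altered-mental-status
  records); the study prints only the total.
* The **kidney-laceration patient** with post-traumatic pelvic pain sits in
  the ASB stratum with localized flags `FALSE` and the trauma context in
  the free-text notes: documenting the pain as a urinary symptom would fire
  Question 2 and contradict the published 73/51 split, so the pain is
  treated as attributed to the laceration.
* **Urinalysis** is available for 58 UTI and 27 ASB records (the published
  comparison denominators) plus 6 other-infection records; marker values
  are deterministic patterns and are not asserted anywhere.

## The synthetic generator

`generate_cohort()` samples records whose symptoms, flags, urinalysis,
courses and adjudication are mutually consistent with a sampled syndrome.
Defaults are the study conditions: n = 124; syndrome probabilities
50/15/13/46 over 124; 8/46 procedural ASB; 36/124 poor historians; 9/38
non-procedural-ASB altered-mental-status rate; urinalysis availability
85/124; marker positivity at the published group rates; 1/13 of
other-infection records carry a concurrent true UTI. Leukocyte counts are
log-normal with group medians 170 (UTI) and 32 (ASB) cells/µL at sdlog 1.8,
giving means near the published 863 and 165 — the non-significant t-test on
strongly different means implies heavy right skew. Antibiotic courses use a
class mix near the published day shares with shifted-Poisson durations
(mean total ≈ 787/124 ≈ 6.3 DOT per patient). Within-syndrome symptom rates
(e.g. 70% flank pain in pyelonephritis) are unpublished and were fixed once
at clinically plausible values.

What the generator deliberately does **not** emulate: facility or
line-of-service structure, catheter-associated UTI, per-course
appropriateness, correlations between age/sex and syndrome, or the
unreconstructible urinalysis subgroup denominators. Passing tests on
generated data therefore demonstrate the pipeline's statistical behaviour
under the study's marginal structure, not performance on real EHR data.

## Numerical and testing choices

* Identical seeds give byte-identical cohorts; the generator is vectorised
  and a 124-record cohort generates in milliseconds.
* The rule engine is verified against an independently written
  nested-conditional oracle on the exhaustive truth table of all special ×
  localized × systemic × alternate-explanation combinations (7,680 cases).
* Clopper–Pearson intervals are checked against the exact binomial-test
  oracle; chi-square and Welch statistics against closed-form arithmetic.
* Simulation scale: parameter recovery uses 200 cohorts of n = 124 (the
  study size), convergence checks one cohort of n = 10,000 within 2%, and
  generator calibration 100 cohorts whose goodness-of-fit p-values are
  tested for uniformity in aggregate — a single sub-0.001 p among 100
  replicates is expected multiplicity, not miscalibration.

## Worked example

```{r example}
cohort <- build_fixture()
val <- cdst_validate(cohort)
val
glance(cdst_burden(cohort))
syndrome_counts(cdst_adjudicate(cohort))
```

## Limitations

The fixture is one cohort consistent with the published marginals, not the
study data; quantities the text does not constrain (per-patient durations,
marker patterns, stratum overlaps) are design choices and are never
asserted. The reference standard is taken at face value; any review bias in
the original adjudication propagates unchanged. The rule itself contains no
catheter-associated-UTI logic and applies to newly hospitalized adults
without indwelling catheters.
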