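# uticdst

Antimicrobial-stewardship decision support for distinguishing urinary
tract infection (UTI) from asymptomatic bacteriuria (ASB) in hospitalized
adults — and the machinery to validate it retrospectively.

Antibiotics prescribed "for a UTI" in hospital are frequently treating
ASB: bacteria in the urine of a patient whose symptoms, if any, point
elsewhere. `uticdst` implements a sequential **3-question rule** that
gates urine testing and antibiotic treatment at prescribing time:

1. **Special population?** Pregnancy, an impending endourological
   procedure, or renal transplant within 60 days → treat bacteriuria
   regardless of symptoms.
2. **Localized urinary symptoms?** Urgency, frequency, dysuria, suprapubic
   pain, pelvic discomfort, or flank pain → testing and treatment
   appropriate.
3. **Systemic signs without an alternate explanation?** Fever, clinical
   instability, or acute mental-status change, with no documented
   non-urinary cause → appropriate; UTI is a diagnosis of exclusion.

Questions are asked in order with short-circuiting; if none fires, testing
and treatment are not indicated. Around the rule the package provides the
full retrospective-validation pipeline, tidyverse-style (tibbles in,
tibbles out, `tidy()`/`glance()`/`autoplot()` on results):

* **Cohort model & I/O** — one row per suspected-UTI case; lossless CSV
  and JSON serialization that distinguishes "not documented" from
  explicit `false` (`read_cohort()`, `write_cohort()`,
  `apply_eligibility()`).
* **Rule engine** — `cdst_evaluate()`.
* **Syndrome adjudication** — ASB / cystitis / pyelonephritis / other
  infection, the guideline ASB-treatment indications, and the
  inappropriate-treatment flag (`cdst_adjudicate()`).
* **Diagnostic accuracy** — confusion matrix of tool indication versus
  full-stay adjudicated need, sensitivity/specificity = TP/(TP+FN),
  TN/(TN+FP) with exact Clopper–Pearson intervals, plus chi-square and
  Welch group comparisons for urinalysis markers (`cdst_validate()`,
  `compare_urinalysis()`).
* **Antibiotic burden** — days of therapy (per-agent calendar days)
  stratified by appropriateness and agent class (`cdst_burden()`,
  `reduction_fraction()`).
* **Cohorts** — a parameterised synthetic EHR-like generator
  (`generate_cohort()`) and a deterministic 124-record fixture cohort
  reproducing the validation study's published marginal counts
  (`build_fixture()`).

## Worked example

```r
library(uticdst)

cohort <- build_fixture()          # 124 records, published marginals
val <- cdst_validate(cohort)       # rule vs reference standard
val
#> Tool indication vs adjudicated true need (n = 124 )
#>                truth
#> tool            needed not_needed
#>   indicated         73          0
#>   not_indicated      1         50
#>
#> Sensitivity: 98.6% (95% CI 92.7-100.0)
#> Specificity: 100.0% (95% CI 92.9-100.0)
```

The rule flagged 73 cases; every one truly needed treatment. Of the 51 it
declined, exactly one — a pneumonia patient whose blood and urine later
grew *E. coli* — needed antibiotics for a urinary pathogen, giving
sensitivity 73/74 = 98.6% and specificity 50/50 = 100%.

```r
tidy(val)
#> # A tibble: 2 × 4
#>   metric      estimate conf.low conf.high
#>   <chr>          <dbl>    <dbl>     <dbl>
#> 1 sensitivity    0.986    0.927     1.000
#> 2 specificity    1        0.929     1

glance(cdst_burden(cohort))
#> # A tibble: 1 × 4
#>   n_records total_days unjustified_days reduction_fraction
#>       <int>      <int>            <int>              <dbl>
#> 1       124        787              265              0.337
```

Of 787 antibiotic days prescribed across the cohort, 265 (33.7% unrounded;
33.6% truncated) went to patients with no justified need — the potential
reduction from applying the rule prospectively. `autoplot()` on either
result draws the confusion-matrix tile plot or the per-class stacked
burden bars; `syndrome_counts(cdst_adjudicate(cohort))` tabulates the
50/15/13/46 syndrome mix.

A command-line front end over the same functions ships in
`inst/cli/cdst.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cdst.R",package="uticdst"))')" \
  fixture --output cohort.csv
```

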