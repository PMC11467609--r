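# triagecheck

Validation analytics for electronic symptom-checker (ESC) triage against
a nurse gold standard.

When a symptom checker and a triage nurse assess the same patient on the
ordinal urgency scale P0 (treat immediately) … P4 (doctor within 72 h)
plus self-care, every paired assessment falls into exactly one of five
concordance categories — exactly matched, overly conservative but
suitable (+1 level), overly conservative (≥ +2 levels), safe but
under-conservative (lower, without crossing the urgency boundary), and
potentially unsafe (nurse urgent, checker non-urgent). `triagecheck` is
for biostatisticians and digital-health evaluators who need to run,
audit or replicate such validation analyses:

* the five-category classifier and configurable safety rules;
* diagnostic accuracy after dichotomising at the urgency boundary
  (positive class = urgent, gold = nurse): sensitivity `TP/(TP+FN)`,
  specificity `TN/(TN+FP)`, `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`, and
  the Matthews correlation coefficient
  `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))` with
  interpretation bands;
* exact Clopper–Pearson binomial confidence intervals
  (`qbeta(α/2, x, n−x+1)` / `qbeta(1−α/2, x+1, n−x)`) and
  CI-width sample-size planning;
* recovery of integer confusion matrices from published summary rows
  (n, PPV, NPV, MCC) by exhaustive enumeration — a consistency audit for
  tables whose raw data are unpublished;
* a seeded synthetic-cohort generator (per-symptom sizes, nurse-level
  distribution, calibratable mis-triage kernel, rare event flags) so the
  whole pipeline is testable without patient data;
* per-symptom and pooled reports in CSV, lossless JSON and markdown,
  plus a small command line front end (`inst/cli/triagecheck.R`).

The methods vignette (`vignettes/triage-concordance.Rmd`) documents the
model, the default parameters and every numerically consequential
choice.

## Worked example

```r
library(triagecheck)

classify_concordance(nurse = c("P2", "P3", "P1"),
                     esc   = c("P2", "P2", "SELF_CARE"))
#> [1] "EXACT"                 "CONSERVATIVE_SUITABLE" "POTENTIALLY_UNSAFE"

# a synthetic 877-case study: calibrate a mis-triage kernel to a target
# concordance mix, generate the cohort, analyse it
kernel <- calibrate_kernel(c(EXACT = 0.537, CONSERVATIVE_SUITABLE = 0.129,
                             OVERLY_CONSERVATIVE = 0.162, SAFE_UNDER = 0.148,
                             POTENTIALLY_UNSAFE = 0.024))
cohort <- generate_cohort(cohort_config(kernel = kernel, seed = 42))
report <- summarize_study(cohort)
report
#> Study report: 877 paired assessments, 15 symptom(s)
#>   safe advice: 98.1% (96.9-98.9), 860/877
#>   exact match: 53.4% (50.0-56.7), 468/877
#>   sensitivity 96.1%, specificity 76.4% (urgent dichotomy)
#>   ratio suitable:over:under = 100:24:23
```

The cohort realises the requested category mix up to sampling noise:
860/877 = 98.1% of the checker's recommendations were safe (the exact
95% CI 96.9–98.9 is Clopper–Pearson), 53.4% matched the nurse's level
exactly, and for every 100 suitable evaluations there were 24
overtriages and 23 undertriages. Sensitivity and specificity describe
the urgent/non-urgent dichotomy only, not the full six-level agreement.

```r
clopper_pearson_ci(x = 856, n = 877)
#>     x   n  estimate     lower     upper conf.level
#> 1 856 877 0.9760547 0.9636291 0.9851178       0.95

# which confusion matrix produced PPV 0.75, NPV 0.875, MCC 0.625 at n = 12?
r <- recover_confusion_matrix(12, ppv = 0.75, npv = 0.875, mcc = 0.625,
                              decimals_pct = NULL, decimals_mcc = NULL)
r$candidates[1, c("tp", "fp", "tn", "fn", "residual")]
#>   tp fp tn fn residual
#> 1  3  1  7  1        0
```

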