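---
title: "Methods: triage concordance, safety and accuracy statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triage concordance, safety and accuracy statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagecheck)
```

## The problem

Electronic symptom checkers (ESCs) let patients self-triage: the software
maps reported symptoms to a care-urgency recommendation. Before such a
tool can be trusted in primary care, its recommendations have to be
validated against a clinical gold standard — typically the triage
decision of an experienced nurse who assesses the same patient. The
central questions are *safety* (does the checker ever send an urgent case
to self-care?) and *accuracy* (how often does it land on the nurse's
level, and in which direction does it miss?).

`triagecheck` implements the full analysis for paired
(nurse, checker) assessments on the Finnish primary-care urgency scale,
together with a seeded synthetic-cohort generator, so that every stage of
the analysis can be exercised and tested without access to raw patient
data — such paired datasets are rarely published.

## The ordinal scale and the urgency dichotomy

The scale has six levels, ranked by urgency:

| code | rank | meaning |
|---|---|---|
| `P0` | 5 | treat immediately (emergency centre, within 0 h) |
| `P1` | 4 | contact emergency centre services (within 2 h) |
| `P2` | 3 | emergency centre, but not overnight (within 10 h) |
| `P3` | 2 | doctor during office hours (within 24 h) |
| `P4` | 1 | doctor during office hours (within 72 h) |
| `SELF_CARE` | 0 | start self-care with instructions |

Two modelling choices are baked into the scale:

* **Self-care is one level.** The referral sub-classes L2–L4 all
  prescribe self-care with instructions and are nowhere distinguished in
  the analyses this package supports, so they collapse into `SELF_CARE`.
* **Urgent = {P0, P1, P2}.** The source classification never spells out
  which levels constitute "urgent or on-call duty"; P0–P2 are the
  emergency-centre levels by their own descriptions, while P3/P4 are
  office-hours referrals. This is an inference, so the boundary is a
  configuration argument (`urgent =`) throughout the package rather than
  a constant.

The dichotomy (positive class = urgent, gold standard = nurse) is what
turns the ordinal comparison into a 2×2 confusion matrix for
sensitivity, specificity, PPV, NPV and the Matthews correlation
coefficient (MCC).

## The five concordance categories

With `d = rank(checker) − rank(nurse)`:

1. `EXACT` — `d = 0`;
2. `CONSERVATIVE_SUITABLE` — `d = +1` (overly conservative but
   suitable);
3. `SAFE_UNDER` — `d ≤ −1` without crossing the urgency boundary;
4. `OVERLY_CONSERVATIVE` — `d = +2`, with `d ≥ +3` folded in by default
   (`fold_extreme_overtriage = FALSE` restores the literal
   two-levels-only reading, leaving `d ≥ +3` unclassified);
5. `POTENTIALLY_UNSAFE` — nurse urgent but checker non-urgent or
   self-care.

Rule 5 is evaluated *first*. This precedence matters: a pair like
(nurse `P2`, checker `P3`) has `d = −1`, which looks like rule 3, but it
crosses the urgency boundary and is therefore potentially unsafe. Making
the safety rule dominant keeps the classification a total partition of
all 36 level pairs (verified exhaustively in the tests) and makes the
unsafe count of a cohort equal its urgency-crossing count.

**Safety.** `is_safe()` defaults to "safe iff not potentially unsafe".
The stricter published threshold — advice at most one urgency level
below the nurse — additionally condemns `d ≤ −2` pairs that stay on the
non-urgent side (e.g. nurse `P3`, checker `SELF_CARE`); it is available
as `strict = TRUE`. The default was chosen because it reproduces the
arithmetic of validation reports in which the unsafe count equals the
number of urgency-crossing cases, and because whether any real cohort
contains a non-crossing `d ≤ −2` pair cannot be established from
published summaries. Both modes are tested; strict safety implies
default safety on every pair.

## Confidence intervals

All proportions carry two-sided exact (Clopper–Pearson) intervals from
Beta quantiles: `lower = qbeta(α/2, x, n−x+1)`,
`upper = qbeta(1−α/2, x+1, n−x)`, with the closed forms
`lower = (α/2)^(1/n)` at `x = n` and `upper = 1 − (α/2)^(1/n)` at
`x = 0`. The exact method was chosen over Wald/Wilson because the
`x = n` closed form reproduces, to one decimal, the printed lower bounds
of published per-symptom tables in which every assessment was safe
(91.4 at n = 41, 85.8 at n = 24, …) — a fingerprint the asymptotic
intervals fail. Exact intervals are conservative; the tests assert
analytic coverage `≥` the nominal level by summing binomial mass rather
than relying on simulation noise.

Two numerical conventions: intervals are computed and stored unrounded;
display rounding is half-away-from-zero to 1 decimal on the percent
scale (`round_half_up()`), matching how such tables are typeset. An
undefined statistic (zero denominator) is `NA` — serialised as an empty
CSV cell and JSON `null` — never silently 0 or 1, because a PPV of 0 and
an undefined PPV are different findings.

**Sample size.** `required_sample_size()` implements the
normal-approximation planning formula
`n = ⌈z² p(1−p) / d²⌉` (at p = 0.97 safe advice and d = 0.01 it gives
1118) and tags its output with the method, since planning texts rarely
state theirs; an exact-interval-width search is available as
`method = "exact"`.

## MCC and its interpretation bands

`MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, undefined
when a marginal is zero. Verbal interpretation tables for the absolute
value ("0.10–0.39 weak", "0.40–0.69 moderate", …) leave the boundary
values ambiguous; `interpret_mcc()` uses half-open bands on round decade
boundaries — [0, 0.10) negligible, [0.10, 0.40) weak, [0.40, 0.70)
moderate, [0.70, 0.90) strong, [0.90, 1] very strong — so every value
has exactly one band.

## Recovering confusion matrices from published summaries

Validation tables publish n, PPV, NPV and MCC per stratum but not the
underlying 2×2 matrices. `recover_confusion_matrix()` enumerates every
integer matrix with cells summing to n (an O(n³) sweep, guarded at
n ≤ 5000 and vectorised in slices of constant `tp`) and scores each
candidate against the reported values. Choices:

* **Commensurate weights.** Percentages enter the residual in
  percentage points; the MCC is scaled by 100 so that an MCC error of
  0.01 counts like a 1-point percentage error — comparable units in the
  last digits such tables print (1 decimal for percentages, 2–3 for
  MCC).
* **Rounding-aware matching.** Computed statistics are rounded to the
  source's precision before comparison, so a matrix is recoverable from
  its own rounded row with residual exactly 0.
* **Undefined ≠ zero.** A constraint passed as `NA` asserts the source
  printed no value; it matches only structurally undefined candidates
  (e.g. `tp + fp = 0` for PPV).
* **Determinism.** Ties are broken lexicographically on
  `(tp, fp, tn, fn)`.

The tool is an audit instrument: when no candidate reaches residual 0
the published row is internally inconsistent, and the ranked near-misses
show how close it can get. The test suite demonstrates both directions —
a 500-matrix round-trip from full-precision and from rounded summaries,
and a published-style row (n = 21, PPV 0, NPV 0.667, MCC −0.37) that no
integer matrix satisfies.

## The synthetic cohort generator

`generate_cohort()` emulates the data-collection layer of a walk-in
primary-care validation study:

* fifteen chief symptoms with the observed per-symptom sizes (877 cases
  in total) as the default `symptoms` table;
* nurse levels drawn per record from a configurable categorical
  distribution — published reports include no nurse-level marginal, so
  the default is uniform and analyses should set it deliberately;
* checker levels produced by a **mis-triage kernel**: per nurse level, a
  distribution over rank offsets −5…+5, truncated to the scale and
  renormalised;
* rare binary flags at their observed rates — nurse changed triage
  after seeing the checker (19/877), doctor consulted (80/877) — and a
  3-in-10 walk-in arrival rate, drawn independently of the levels
  because no joint structure is published;
* one RNG substream per symptom, derived from the seed and a stable
  hash of the label, so adding or removing a symptom leaves the other
  symptoms' draws untouched, and the caller's RNG state is restored.

`calibrate_kernel()` inverts target concordance-category rates into a
kernel: categories are allocated in safety-first priority order, each
spread over the nurse levels able to express it in proportion to their
remaining probability mass, then uniformly over that level's offsets in
the category. The induced category distribution — computed exactly by
`induced_category_rates()`, not by simulation — matches feasible targets
to well below 1e−6. Infeasible requests (unsafe mass with no urgent
nurse mass; under-triage from a self-care-only population) raise an
error naming the category and the mass available. The proportional
allocation is deliberately simple; for adversarial target/level
combinations a general transportation solver could succeed where it
reports infeasibility, a limitation accepted because realistic study
mixes sit far from those corners. Calibrated kernels are also not
unique — many kernels induce the same category rates — so they should
be read as *a* generating mechanism consistent with published rates,
never as the estimated mechanism.

What the generator does **not** emulate: symptom-questionnaire content,
patient covariates (the emulated study collected no age or sex),
between-nurse variability, or any dependence of flags on triage levels
(a hook for a custom dependence can be added by editing the generated
flags). Tests passing on synthetic cohorts therefore establish the
correctness of the *analysis*, not the clinical behaviour of any
checker.

## The analysis pipeline

`summarize_study()` produces per-symptom rows and a pooled total
(category counts, safe/exact proportions with exact CIs, confusion
matrix, PPV/NPV/MCC with band), overall sensitivity/specificity, two
subset accuracies, the over/under-triage ratio and nurse-form tallies.
Two operationalisations deserve note:

* **Non-urgent "match".** Below the urgency boundary the published
  phrasing — agreement on "whether medical care should be sought or
  self-care is sufficient" — is implemented as agreement on the
  indicator `level == SELF_CARE`, the only care-seeking dichotomy those
  levels support.
* **Ratio grouping.** `triage_ratio()` defaults to suitable = exact +
  conservative-but-suitable, overtriage = overly conservative,
  undertriage = safe-under + potentially-unsafe, reported per 100
  suitable. The grouping is configurable because published "100 : x : y"
  ratios are not always reconstructible from printed category totals
  under any grouping (the default grouping on the emulated study's
  totals gives 100 : 24.3 : 25.9, not the printed 100 : 25 : 22); the
  audit surfaces, but cannot resolve, such discrepancies.

No multiplicity adjustment is applied to the per-symptom intervals —
the emulated reports publish unadjusted CIs, and the pipeline follows
suit.

Reports serialise to a table-shaped CSV (cells like
`"97.6 (96.4-98.5)"`), a lossless JSON (unrounded values; round-trips
byte-identically through `report_from_json()`), and markdown. A thin
command-line front end over these functions ships in
`inst/cli/triagecheck.R` with `simulate`, `analyze`, `recover` and
`power` subcommands.

## Known irreproducibilities in published tables

Running the package against the printed numbers of the validation study
its defaults emulate surfaces four internal inconsistencies, asserted as
such in the test suite rather than papered over:

* two CI bounds (95.6 at n = 81; 57.1 as the upper bound of 471/877)
  differ by one final-digit unit from the exact computation (95.548 and
  57.046 — the pattern of rounding twice, 95.548 → 95.55 → 95.6);
* the abstract-style interval 49.2–55.9 for 471/877 matches no standard
  binomial interval centred at 53.7;
* no single 877-case confusion matrix yields sensitivity 62.6%,
  specificity 69.2%, PPV 49.4% and NPV 59.5% simultaneously (exhaustive
  check over all split points), so the pooled row of such a table must
  aggregate differently than its per-symptom rows;
* the n = 21 row with PPV 0, NPV 0.667, MCC −0.37 admits no integer
  confusion matrix (nearest candidate: MCC −0.354).

## Problem sizes used by the test suite

Property tests run at sizes chosen to make the statistical assertions
sharp while keeping the default suite quick: the generator-convergence
check uses one 100,000-record cohort (empirical category rates within
0.5 percentage points of the exact induced rates), the recovery
round-trip uses 500 random matrices with n ≤ 200, CI oracle equivalence
is exhaustive for all n ≤ 30, and coverage is computed analytically at
n ∈ {20, 100, 877}.
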