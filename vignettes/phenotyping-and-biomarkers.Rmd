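---
title: "Phenotyping febrile children and evaluating biomarkers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping febrile children and evaluating biomarkers: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(febrimark)
```

This vignette is the package's own account of the science it implements: the
classification model and its assumptions, the statistical machinery, the
synthetic-data model, and the choices made where the design was genuinely
open.

## 1. The classification model

### The eleven-category phenotype

Febrile children rarely come with a definitive microbiological answer. The
phenotyping rule tree therefore grades the *certainty* of a bacterial or
viral etiology rather than forcing a dichotomy. The engine
(`classify_cohort()`) fires a fixed sequence of decision nodes per child:

1. **Sterile-site bacterial detection** (culture or PCR in blood, CSF,
   urine, joint or pleural fluid, or bone) → `DEFINITE_BACTERIAL`. This node
   is evaluated first and dominates everything else, including co-detected
   viruses: a positive viral test does not exclude bacterial infection.
2. **Trivial illness** flag → `TRIVIAL`.
3. **Distinct other infection** (e.g., tuberculosis, malaria) →
   `OTHER_INFECTION`.
4. **Suspected inflammatory condition** → `INFECTION_OR_INFLAMMATION` when
   any infection evidence coexists, else `INFLAMMATORY_SYNDROME`.
5. **Consistent non-sterile bacterial isolate** (e.g., wound culture
   matching the clinical picture): with CRP at or above the cut →
   `PROBABLE_BACTERIAL`; below the cut the isolate alone is not considered
   sufficient and evaluation continues.
6. **Bacterial clinical phenotype** without an isolate: CRP at or above the
   cut → `BACTERIAL_SYNDROME`, otherwise `UNKNOWN`.
7. **Viral clinical phenotype**: with CRP below the cut, a clinically
   consistent virus gives `DEFINITE_VIRAL`, any virus `PROBABLE_VIRAL`, no
   virus `VIRAL_SYNDROME`. With an unexplained raised CRP, a detected virus
   still yields `VIRAL_SYNDROME` but no virus yields `UNKNOWN` — raised
   inflammation that the viral phenotype cannot explain withdraws certainty.
8. Anything else → `UNKNOWN`.

Each classification records the ordered nodes fired (`audit_path`), so the
transcription of the rule tree is testable node by node.

**CRP threshold.** CRP is the single quantitative node. The default cut is
60 mg/L — the decision value used by the published algorithm this engine
extends — but it is strictly a parameter (`classifier_thresholds()`).
Comparison is `crp >= cut` on the bacterial side: the tie at the cut must
fall somewhere, and assigning it to the raised side means a child exactly at
the threshold is treated as inflamed. A missing CRP at a CRP node yields
`UNKNOWN` with a `missing-CRP` audit flag rather than an error; this mirrors
the clinical reality that an unmeasured CRP leaves the phenotype genuinely
unresolved, and it keeps the pipeline total.

**Monotonicity.** For any record whose label depends only on the CRP node,
raising CRP never moves the label toward the viral end of the spectrum; the
test suite checks this across all CRP-consulting branches.

The four non-infection categories collapse into a single `OTHER` group for
analysis (`collapse_other()`); the remaining seven categories are ordered
1 (definite bacterial) … 7 (definite viral) by `spectrum_ordinal()`, with
`OTHER` excluded from spectrum correlations. We interpret the "full
spectrum" as these seven ordered infection groups; the non-infection
categories have no natural position on a bacterial→viral axis.

### The SBI reference standard

The dichotomous label (`classify_sbi()`) reflects the broader "serious
bacterial infection" definition used as the conventional comparator:
sterile-site isolation (urine included), a clinically consistent non-sterile
isolate with a compatible syndrome, bacterial-type imaging changes (e.g.,
consolidation defining bacterial pneumonia) with a compatible syndrome, or a
clinical bacterial diagnosis — a bacterial-type syndrome (pneumonia, UTI,
sepsis, meningitis, skin/soft tissue, bone/joint) adjudicated bacterial
without microbiological proof. Expert adjudication enters only through input
flags (`clinically_consistent`, `syndrome_suggests`); the engine never
infers it, and `clinically_consistent` defaults to `FALSE` when absent.

## 2. Group statistics

Summaries are medians with interquartile ranges, quartiles by linear
interpolation between order statistics (`quantile()` type 7) — reported
IQRs depend on this convention, so it is fixed and documented. Two-group
comparisons use the Wilcoxon rank-sum test: exact enumeration when both
groups have ≤ 10 observations and the pooled data are tie-free, otherwise
the tie-corrected normal approximation with continuity correction — a
reproducible small-sample rule rather than a size-dependent heuristic.
K-group comparisons use the tie-corrected Kruskal–Wallis H with a χ²(k−1)
reference. Spectrum association uses Spearman's ρ between concentrations and
the ordinal 1…7; higher concentrations at the bacterial end give negative ρ.
CRP–biomarker association uses Pearson's r (the pipeline computes it on log
concentrations, where the generator's copula correlation is defined). No
multiple-testing correction is applied, matching the source analysis; the
plot annotation threshold is two-sided 0.05.

## 3. Discrimination

`roc_auc()` computes the empirical AUC (Mann–Whitney form, ties
half-credited) with a DeLong 95% interval truncated to [0, 1]. The positive
class is always the bacterial side, so AUC > 0.5 means the marker rises in
bacterial illness. The DeLong estimator is the standard nonparametric
variance for the AUC and is the default of the ROC software family the
analysis mirrors.

The combined model (`fit_combined_model()`) enters each biomarker through a
restricted cubic spline — the truncated-power natural-spline basis, linear
beyond the boundary knots, k knots giving k−1 columns including the linear
term — inside a maximum-likelihood logistic regression. Defaults: 3 knots
per predictor at the 10th/50th/90th percentiles (the standard
spline-modelling convention; the original analysis states only that splines
were used "for optimal model fit", so knot count and placement are
configuration). Markers enter on the raw concentration scale by default —
the splines absorb the skew — with a log-scale option. The reported AUC is
apparent (in-sample), matching single-cohort fits without cross-validation;
it is therefore optimistic for out-of-sample use, which is a property of the
design being mirrored, not a claim of generalisation. Complete cases across
the whole panel are required per record. Perfect separation is flagged (from
the fitted probabilities, not the IRLS warnings, which also fire on routine
extreme fitted values with heavy-tailed markers) and the AUC is still
reported.

## 4. Meta-analysis of study-level AUCs

Published per-cohort AUCs arrive as estimate plus 95% CI. Standard errors
are recovered as `(ci_high − ci_low) / (2 z)` with the exact normal quantile
(z = 1.959964), not 1.96; a zero-width interval is rejected because it would
give an infinite weight. Effects are pooled on the raw AUC scale — the
printed summary intervals are symmetric about the pooled AUC, which is what
raw-scale pooling produces; a logit transform would skew them.

Two τ² estimators ship: DerSimonian–Laird (closed form; the default for
deterministic tests) and REML (iterative maximisation of the restricted
likelihood — the score equation is bracketed and solved to relative
tolerance 1e−8, floored at zero; the likely original, as standard
meta-analysis software defaults to it). The pooled summaries reported by the
acceptance script agree between the two at 2-decimal rounding. I² is
reported in both conventional definitions — Q-based `max(0, (Q−df)/Q)` and
variance-based `τ²/(τ² + s²)` with s² the typical within-study variance —
and the default shown matches the estimator (they coincide under DL).
Heterogeneity p-values come from the χ² upper tail of Q with df = k−1.
Because the table inputs are rounded to two decimals, third-decimal
agreement with published Q and I² captions is not expected and is not
targeted.

## 5. The synthetic cohort generator

No patient-level data are deposited for the five source cohorts, so the
generator (`generate_cohort()`) stands in for them. What it emulates:

* **Category mix**: per-cohort counts of the eight analysis groups,
  transcribed from the published per-category biomarker table (the analysis
  population, not the recruitment n; the OTHER group absorbs the
  remainder). Cells printed without a median/IQR fall back to the cohort's
  overall-column parameters; groups printed n/a get n = 0.
* **Biomarker marginals**: log-normal per category, fitted to the printed
  median and IQR. Concentrations are positive and right-skewed with IQRs
  spanning orders of magnitude, which the log-normal captures; the fit
  reproduces the median exactly and the IQR *ratio* exactly, but cannot
  match two asymmetric quartiles independently — a documented compromise.
* **CRP coupling**: a Gaussian copula on the log scale links CRP to the
  biomarkers at configurable Pearson correlations (defaults at the midpoints
  of the published ranges: PCT 0.33, NGAL 0.31, resistin 0.18); the copula
  preserves the marginals. Biomarker–biomarker correlation within category
  is a single exchangeable parameter, default 0.3 — the real within-category
  correlations are unreported, so this is a flagged assumption.
* **Generator–classifier consistency**: each category's clinical and
  microbiology fields follow a fixed template, and CRP is sampled from its
  marginal *truncated* to the side of the cut the phenotype requires
  (untruncated for categories whose label does not consult CRP). The
  classifier therefore recovers the intended group for 100% of records — a
  hard invariant of the suite. Truncation distorts the realised CRP
  correlation in truncated categories; correlation-recovery checks use the
  untruncated regimes, where the copula correlation is exact.
* **Missingness**: completely at random, per biomarker, with an exact count
  `round(p·n)` so preset complete-case counts match the printed
  per-biomarker N exactly. Only per-biomarker N's are published; no
  missingness mechanism is modelled.
* **Determinism**: one master seed expands into fixed substreams per
  category and per missingness stream, so adding a category leaves the
  others' draws untouched.

What it does **not** emulate: the joint distribution of biomarkers across
categories in real children (only marginals are published), real
within-category correlation structure, age effects, or informative
missingness. Passing pipeline tests on synthetic cohorts therefore
demonstrates the machinery and the qualitative patterns (ordering along the
spectrum, combined model ≥ best single marker), not the exact published
per-cohort AUCs — which is also why those AUCs are out of scope for direct
reproduction.

## 6. Numerical choices and degenerate inputs

* Quartiles: type 7; documented above.
* Wilcoxon exact/approximate switch at n ≤ 10 per group, tie-free.
* AUC confidence intervals truncated to [0, 1]; at AUC = 1 the DeLong
  variance degenerates and the interval collapses — reported as-is.
* REML τ²: score bracketed from the DL estimate and solved by root-finding;
  Q ≤ df short-circuits to τ² = 0, where DL and REML agree exactly.
* Empty contrast groups: evaluation skips with a warning; empty cohorts are
  refused by the summary functions with an "empty" error.
* Single-study meta-analysis returns the study unpooled with a warning.
* Spline fits refuse predictors with fewer distinct values than knots.
* The one apparently mistyped confidence bound in the packaged study table
  (combined-model SBI row, upper bound 0.84 beside an estimate of 0.71 and
  lower bound 0.67) is kept verbatim; a corrected variant (0.74, the
  symmetric value) ships alongside, clearly labelled
  (`table4_auc_path(corrected = TRUE)`). All shipped analyses use the
  verbatim table.

## 7. Problem sizes used by the test suite

The suite exercises the generator at n = 50,000 per group for distribution
and correlation recovery (median within 2%, IQR ratio within 5%, copula r
within ±0.02, empirical vs closed-form log-normal AUC within ±0.01), 1,000
random instances for the AUC/brute-force equivalence, 1,000 simulated
datasets for DeLong coverage (91–98% acceptance band at nominal 95%), and
roughly 1,000 children (143 per infection group) for the monotone-gradient
spectrum correlation. These sizes were chosen to make the Monte-Carlo error
comfortably smaller than each tolerance.

## 8. Known limitations

* The rule tree is a faithful but independent transcription of a published
  figure whose nodes are not restated in running text; the audit trail
  exists precisely so that any node-level discrepancy can be located and
  corrected in one place.
* The operational definition of "trivial illness" is an input flag; the
  framework does not define it.
* Resistin units are stored exactly as printed in the source tables, which
  are internally inconsistent (ng/mL vs ng/L); no silent conversion is
  performed.
* Pooling on the raw AUC scale keeps intervals symmetric but can in
  principle exceed 1 for extreme inputs; intervals are truncated only at
  the ROC level, not the meta level, matching the published summaries.
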