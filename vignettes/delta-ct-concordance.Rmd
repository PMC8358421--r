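---
title: "Delta-Ct biomarker calling, IHC concordance, and distant-recurrence models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-Ct biomarker calling, IHC concordance, and distant-recurrence models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strat4concord)
```

## The problem

In early breast cancer, treatment decisions hinge on four biomarkers —
estrogen receptor (ER), progesterone receptor (PR), HER2, and the
proliferation marker Ki67 — conventionally scored by immunohistochemistry
(IHC), with in situ hybridisation (ISH) resolving equivocal HER2 cases.
Cartridge-based RT-qPCR offers an automated alternative: it measures the
corresponding mRNAs (*ESR1*, *PGR*, *ERBB2*, *MKi67*) relative to a control
gene (*CYFIP1*) in FFPE tissue and dichotomises each marker by a delta-Ct
threshold. Before such an assay can substitute for IHC, its calls must be
shown concordant with central pathology, and its prognostic value for
clinical outcome must match. This package implements that whole evaluation:
the calling rules, the reference classification, the agreement statistics
with prespecified performance gates, time-to-distant-recurrence modelling,
and a synthetic cohort generator for end-to-end exercise of the pipeline.

## Delta-Ct calling rules

For each target gene, `delta_ct = Ct(control) - Ct(target)`; higher values
mean more target mRNA. A marker is **positive** when its delta-Ct meets or
exceeds the marker cut-off — read literally from the assay definition as an
*inclusive* comparison:

| marker | cut-off (delta-Ct) |
|--------|--------------------|
| ESR1   | -1.0 |
| PGR    | -3.5 |
| ERBB2  | -1.0 |
| MKI67  | -4.0 |

The control gene governs interpretability. Control Ct **> 35** means too
little intact material: all four calls are **invalid**. For a sub-cut-off
PGR or MKi67 result, a control Ct in the half-open window **(31, 35]** is
too weak to support a confident negative, so the call is **indeterminate**;
at control Ct <= 31 it is a confident **negative**. ESR1 and ERBB2 have no
indeterminate state. All comparisons are made at full floating precision —
nothing is rounded before thresholding.

A target reported "not detected" is mapped to delta-Ct `-Inf`, which sits
below every cut-off and therefore classifies negative (or indeterminate
under the weak-control rule). The assay definition is silent here; we chose
this because absent amplification of the target, with an amplifying
control, is the strongest available evidence of absent expression. The
schema cannot distinguish true non-detection from a target-channel assay
failure when the control is valid; both present as an empty cell and both
follow this rule.

## IHC/ISH reference classification

Percent-stained-nuclei scores are reported on the pathology grid
{0, 1, 5, 10, 20, ..., 100}. `normalize_percent()` snaps raw values to the
nearest grid value, ties rounding up. The reporting convention's wording
admits either nearest-value snapping or threshold binning; only grid
membership matters downstream, so the choice is isolated in this one
function and documented as a convention (an alternate rule is a one-line
change). Staining intensity is ignored throughout.

- ER/PR: positive at >= 1% stained nuclei.
- Ki67: <= 5% low, 10–20% intermediate, >= 30% high (the grid has no value
  between 20 and 30, so the bands are exhaustive). A binary >20% vs <=20%
  view (high vs rest) is also provided for the outcome models.
- HER2: IHC 3+ positive, 0/1+ negative; 2+ reflexes to ISH and is positive
  at ratio >= 2.0 or mean *ERBB2* copy number >= 6.0 per cell. A 2+ case
  with no ISH result is **missing** — an exclusion, not an error — and ISH
  values are never consulted for non-2+ scores.

## Agreement statistics and performance gates

Per marker, samples are cross-tabulated as reference+/test+ (a),
reference-/test+ (b), reference+/test- (c), reference-/test- (d) after
exclusions, tallied in a fixed order: invalid calls; indeterminate calls
(PGR/MKi67); then reference-side exclusions (intermediate Ki67, missing
HER2 reference). The order affects only tally attribution, never the
analysed n, and the identity `n + sum(exclusions) = N` is enforced by test.

- OPA = (a+d)/n, PPA = a/(a+c), NPA = d/(b+d); exact ratios internally,
  half-up rounding at 1 decimal (percent) only at rendering.
- 95% CIs by the Wilson score method without continuity correction; the
  implementation is checked against numeric root-finding of the score
  equation to 1e-10.
- Cohen's kappa with the simple asymptotic standard error
  `sqrt(po (1 - po) / (n (1 - pe)^2))`, interval truncated to [-1, 1].
  Variance formulas for kappa differ across software; this variant is the
  plainest and reproduces the bundled validation intervals to the printed
  precision for three of four markers (the PR lower bound differs by 0.01
  under any variant we tried; the kappa point estimates are unaffected).
- Performance gates: a target is met when the *unrounded* Wilson lower
  limit is at or above the prespecified minimum — ER (PPA 80, NPA 80), PR
  (70, 65), HER2 (75, 80), Ki67 (65, 65), percent scale. "Exceeds" is read
  as >= because the boundary case cannot be resolved from the study
  definition and the reproduced pass/fail pattern is unaffected.
- Baseline group comparisons: Pearson chi-square without continuity
  correction (r x c general), Fisher's exact test (two-sided, minimum
  likelihood), and a Wilcoxon rank-sum with midrank ties that enumerates
  exactly for pooled n <= 20 and otherwise uses the tie-corrected normal
  approximation without continuity correction.

Two bundled-fixture quantities deserve a note. On the ER row of the
validation counts (1045, 0, 12, 19), the kappa arithmetic gives 0.7546,
which renders as 0.75 at two decimals, and the Wilson lower limit for NPA
on 19/19 is 83.2%. The package reports these formula-true values; they are
what the stated formulas produce from the stated counts.

## Time-to-distant-recurrence models

The event is first distant recurrence; secondary carcinoma (including
contralateral breast cancer) and death of any cause censor at their time,
as does end of follow-up — a first-event analysis of the censoring rule as
stated. The Kaplan–Meier estimator and the Cox partial likelihood are
implemented in the package (Newton–Raphson with step-halving; convergence
at gradient max-norm < 1e-8 within 50 iterations, or when the likelihood
reaches its floating-point ceiling with an already negligible score; Wald
intervals and p-values).
Ties are handled by the Efron method by default — exact under light ties
and the standard modern default — with Breslow available via a flag; with
no ties the two coincide, which is tested. Monotone likelihood (complete
separation) is detected by coefficient divergence and reported as
non-convergence with a diagnostic rather than a silent estimate. The fits
are validated two ways: coefficient agreement with an independent
established implementation to 1e-6 on fixed datasets (ties included), and
parameter recovery — cohorts generated with a known binary-marker log-HR at
n = 1000 must have ~95% Wald CI coverage over 200 replicates.

`run_dr_models()` reproduces the study's model layout: univariable fits per
covariate, plus two multivariable models combining age (continuous,
per-year HR), tumour size (pT1 reference), nodal status (0 nodes
reference), and grade (G1 reference) with either the four delta-Ct call
statuses or the IHC/ISH reference statuses (3-level Ki67, low reference).
Records with any incomplete covariate — including invalid or indeterminate
calls — are dropped once for all models and tallied.

## The synthetic cohort generator

No patient-level data accompany the assay's published validation, so the
generator emulates the statistical structure the analysis assumes, and its
defaults *are* the study conditions:

- **Calls.** Control Ct is drawn uniform on [25, 31] (valid), (31, 35]
  (weak window) or (35, 40] (invalid), with invalid fraction 3.5%. Each
  marker's delta-Ct is a two-component Gaussian mixture conditional on a
  latent truth (any unimodal-per-class family with controllable overlap
  would do; Gaussian is the simplest). Components sit ~2.5 SD from the
  cut-off so each misclassifies under ~2% (e.g. ESR1: positive mean +3.0,
  negative -4.0, SD 1.5 against cut-off -1.0). Latent prevalences are then
  *solved* from the target call-positive margins (ESR1 93.7%, PGR 75.8%,
  ERBB2 3.8%, MKi67 45.6% of the cohort) and the mixture tails, so the
  generated margins match in expectation. Target Ct is back-solved as
  control Ct minus delta-Ct.
- **Indeterminates.** One shared control gene cannot hit the PGR (4.8%)
  and MKi67 (11.4%) indeterminate margins exactly at once, because an
  indeterminate requires both a weak-window control and a sub-cut-off
  delta-Ct, and the two markers have different sub-cut-off mass. The
  weak-window fraction 0.228 (of valid-control samples) splits the
  difference: expected margins 4.7% and 11.6%, both within sampling error
  of the targets at the cohort size; this is the one margin pair that is
  approximate by construction.
- **Reference.** IHC statuses are drawn conditionally on the latent call
  with probabilities taken from the published 2x2 row proportions — an
  equivalent reparametrisation of a truth-plus-misclassification model that
  reproduces the discordance structure directly, and lands the reference
  marginals near their published values automatically. Percent values and
  HER2 IHC/ISH fields are then rendered to realise those statuses through
  the actual classification rules (never assigned directly), including the
  0.2% HER2 2+-without-ISH missing fraction.
- **Outcomes.** Exponential proportional hazards on the latent marker
  truths and clinical covariates, with the published univariable log-HRs as
  generating effects; other-cause events (rate 0.015/yr, split between
  death and secondary carcinoma) and uniform administrative censoring on
  [5, 16] years mirror a maximum follow-up of 16 years with a median near
  11. The baseline hazard 0.0097/yr was calibrated once, by large-sample
  Monte Carlo against the 14.1% distant-recurrence fraction that the
  defaults are defined to reproduce, and is fixed thereafter.

What the generator does **not** emulate: the joint shape of delta-Ct and
percent staining (only the discordance rates are calibrated, not the
scatter), pre-analytic degradation trends, batch effects, inter-observer
scoring variability, or any randomised-treatment effect. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline's statistics are
correct and well calibrated under the assumed structure — not that the
assay itself would reproduce these numbers on new clinical material.

Deterministic fixtures complement the stochastic generator:
`expand_two_by_two_fixture()` turns published 2x2 counts into records whose
Ct and IHC values classify into the intended cells, verifies the round trip
at expansion time, and hard-errors on any drift in the call logic.

## Problem sizes and numerical conventions

Test and acceptance runs use cohorts of 1115 (the validation cohort size;
20 seeds for calibration checks), 50,000 for law-of-large-numbers margin
checks, and 200 replicates of n = 1000 for Cox recovery — sizes chosen to
make sampling error small relative to the tolerances being checked.
Rendering follows the study's conventions: percents half-up at 1 decimal,
kappa and HRs at 2; all comparisons (cut-offs, gates) happen on unrounded
values. Zero denominators yield `NA` statistics, not errors; degenerate
kappa margins yield `NA` kappa; zero-margin rows are dropped from the
chi-square with a warning.

## Known limitations

- The agreement engine is binary (after the prescribed exclusions); no
  3x3 Ki67 agreement, McNemar asymmetry test, or multiple-testing
  adjustment is provided, matching the prespecified analysis.
- The Cox implementation targets modest covariate counts (tens), not
  high-dimensional designs, and offers no time-varying covariates,
  competing-risks decomposition, or proportionality diagnostics.
- The generator's delta-Ct mixtures are a modelling convenience; their
  within-class shape should not be interpreted biologically.
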