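---
title: "Two-stage tree-stratified risk-factor analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage tree-stratified risk-factor analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septree)
```

## The problem

Postoperative sepsis in patients aged 65 and over is rare (around 5% of
admissions) but devastating, and the exposures a clinician might act on —
emergency versus elective surgery, surgical specialty, operation length,
preoperative laboratory abnormalities — are entangled with demographic and
comorbidity confounders (age band, diabetes, cerebrovascular disease,
malignancy, pneumonia, preoperative transfusion, and so on). Crude 2×2
comparisons are biased; a single main-effects logistic model assumes the
confounders act additively on the log-odds, which clinical experience
contradicts: baseline sepsis risk behaves like a small number of
qualitatively different patient profiles, not a smooth score.

`septree` addresses this with a two-stage design. First, a recursive
partition grown on the confounders *only* compresses all confounder
structure — including interactions — into a handful of homogeneous-risk
strata. Second, each putative risk factor is evaluated inside those strata
with the Mantel-Haenszel estimator, so its effect is compared only between
patients of similar baseline risk. A logistic sensitivity analysis checks
that conclusions do not hinge on the stratification device.

## Stage one: the confounder stratification tree

Discretized confounders are expanded to one-versus-rest binary indicators
(a K-level variable yields K−1 columns; `encode_confounders()`). For a 0/1
outcome $y$ at a node with $n$ subjects, a candidate split into children of
sizes $n_L, n_R$ with event proportions $p_L, p_R$ is scored by the
between-group sum of squares

$$\Delta = \frac{n_L\, n_R}{n} (p_L - p_R)^2,$$

which equals the reduction in the within-node error sum of squares and,
for a binary outcome, half the Gini-impurity reduction — so either
formulation can serve as an independent check, and the test suite uses an
explicit residual-sum oracle and `rpart`'s anova fit. The greedy split
search is deterministic: ties go to the leftmost indicator column.

Growth controls:

* `min_split = 20` — the smallest node still eligible for splitting. This
  is the conventional recursive-partitioning default and keeps leaf event
  counts meaningful at a 5% outcome prevalence.
* `min_leaf = 7` — the smallest permissible child (round(20/3), the
  companion default in the rpart family). Both are configurable.

A node that is pure, too small, or admits no positive $\Delta$ becomes a
leaf; a constant outcome yields a root-only tree rather than an error.

### Pruning and complexity selection

The full tree is reduced by weakest-link cost-complexity pruning: for each
internal node $t$ the per-leaf error-reduction rate
$g(t) = (R(t) - R(T_t)) / (|T_t| - 1)$ is computed ($R$ the error sum of
squares, $T_t$ the subtree under $t$), and nodes minimizing $g$ are
collapsed iteratively, producing a nested sequence of subtrees with
non-decreasing critical $\alpha$ values ending at the root
(`cost_complexity_path()`).

`cv_prune()` selects $\alpha$ by stratified k-fold cross-validation
(default `folds = 10`; fold assignment preserves outcome prevalence and is
governed by `seed`, default 20150901, recorded on the fitted object). Each
candidate $\alpha$ (geometric midpoints of successive path values) is
scored by the mean held-out binomial deviance. Two selection decisions
were genuinely open and are worth stating:

* **Deviance, not accuracy.** With a ~5% outcome every leaf incidence sits
  below one half, so every subtree predicts the majority class and
  held-out classification accuracy is *constant* along the pruning path;
  under the simplest-tree tie-break it would always return the root-only
  tree. Held-out deviance discriminates at any prevalence and is the
  default; `metric = "accuracy"` remains available and the fitted object
  records which was used.
* **One-standard-error rule (`se_rule = TRUE`).** Selecting the raw
  deviance minimum keeps spurious splits whose apparent gain is within
  cross-validation noise: on pure-noise simulations the minimum-deviance
  rule retained at least one fake split in roughly two thirds of seeds.
  The default therefore picks the simplest tree within one standard error
  (across folds) of the best score — standard CART practice — which
  roughly doubles the no-signal rejection rate while leaving recovery of
  a genuinely planted structure at full cohort scale intact (the
  acceptance study measures ≥95% first-splitter recovery over 100 seeds).
  `se_rule = FALSE` restores the plain optimum.

### Candidate models and AIC

Three nested confounder sets — demographics (model 1), plus preoperative
comorbidities (model 2), plus preoperative management (model 3) — each get
a cross-validated tree (`candidate_models()`), compared by

$$\mathrm{AIC} = -2 \sum_i \big[ y_i \ln p_{\ell(i)} + (1-y_i)\ln(1 - p_{\ell(i)}) \big] + 2L,$$

with one parameter per leaf ($L$ leaves, $p_{\ell(i)}$ the incidence of
subject $i$'s leaf). A leaf incidence of exactly 0 or 1 is clamped to
$1/(2n_\ell)$ from the boundary so the likelihood stays finite. Two exact
identities make this formula testable: a root-only tree has the closed
form $n[-2(p\ln p + (1-p)\ln(1-p))] + 2$, and a split that leaves both
children at the parent incidence raises the AIC by exactly 2.
`select_model()` takes the minimum-AIC candidate, ties going to the
smaller confounder set.

Each split's clinical meaning is summarized by `pairwise_node_effects()`:
the risk ratio between the two children (indicator-present child as the
exposed group) with the Katz log-scale interval
$\ln RR \pm 1.96\sqrt{1/a - 1/n_1 + 1/c - 1/n_0}$; any zero count adds 0.5
to all four implied cells for the interval only. The interval construction
behind the published per-split CIs could not be reverse-engineered from
the printed values, so only the point estimates are treated as
reproducible.

## Stage two: stratified effects

For each putative risk factor and each non-reference level,
`marginal_table()` builds the exposed-versus-reference 2×2 table (other
levels of a multi-level exposure are excluded — pairwise contrasts against
the printed reference, e.g. abdominal/urogenital surgery). Estimators:

* `crude_or()` — cross-product ratio with the Woolf interval; a zero cell
  triggers the Haldane-Anscombe correction (0.5 to all four cells),
  flagged in the output.
* `crude_rr()` — incidence ratio with the Katz interval.
* `mh_common_or()` — Mantel-Haenszel common odds ratio with the
  Robins-Breslow-Greenland variance (verified in tests against
  `stats::mantelhaen.test` to 10 significant digits).
* `mh_common_rr()` — Mantel-Haenszel risk ratio with the Greenland-Robins
  variance.

The adjusted column of the source analysis is labelled "RR" but is
reproducible from the printed counts *only* as the cross-product ratio
(e.g. 8.30 for emergency surgery, where the incidence ratio gives 6.46),
while the per-split tree values reproduce as risk ratios (6.01 for the
cerebrovascular split). Both measures are therefore implemented; the
effect-table pipeline defaults to odds ratios, the tree summaries to risk
ratios, and every output row carries an explicit `measure` tag.

Degenerate inputs are handled explicitly rather than silently: a stratum
empty at both exposure levels is dropped (the remaining tables still sum
to the marginal table); a series in which every stratum is uninformative
is an error; and when exactly one margin sum $\sum a_id_i/n_i$ or
$\sum b_ic_i/n_i$ vanishes — where the plain estimator would return 0 or
infinity — a flagged 0.5-per-cell continuity fallback keeps the estimate
and interval finite, mirroring the crude-table rule.

Odds ratios are non-collapsible: even without confounding, a
stratum-common OR differs from the marginal OR when baseline risk varies
across strata. The no-confounding agreement tests therefore hold stratum
risk constant, and the coverage studies evaluate the estimators against
the *conditional* planted effect, which is what the Mantel-Haenszel and
logistic estimators target.

## Logistic sensitivity analysis

`fit_logistic()` is a plain IRLS maximum-likelihood fit (convergence when
the largest absolute coefficient change drops below 1e-8, at most 100
iterations) that records the log-likelihood of every iteration — the suite
checks the sequence never decreases — and flags likely separation
(non-convergence or coefficients beyond ±15 on the log-odds scale)
instead of reporting a spurious fit. Rank-deficient designs are refused.
`stats::glm` serves as the independent oracle in tests (agreement to 1e-6
on a six-covariate fit).

`screen_interactions()` tests every unordered pair of the tree-selected
confounders by a likelihood-ratio test of main effects versus main
effects + interaction, flagging p < 0.05 and reporting pairs with empty
level combinations as untestable. `adjusted_or_lr()` then fits
exposure + confounder main effects + flagged interactions and returns
Wald intervals on the exponentiated exposure coefficients (profile
intervals are not provided; the Wald form matches the reported style).
Whether the original sensitivity analysis adjusted for all selected
confounders or only stepwise-retained ones is not recoverable from the
printed record; the default here adjusts for all of them, with the
forward-stepwise AIC search (`forward_stepwise()`, the natural reading of
a "positive stepwise" selection) reported separately as a trace.

## The synthetic cohort

Subject-level data behind the published tables are not publicly
deposited, so `generate_cohort()` provides the test bed. What it
emulates:

* confounder and exposure level prevalences equal to the published
  marginals (independent draws — the source reports marginals only; a
  dependence tilt is the single generator knob, below);
* a seven-leaf baseline-risk tree with the published splitter hierarchy
  (cerebrovascular disease, then transfusion, pneumonia, age ≥ 75,
  malignancy, diabetes). Two leaf risks are anchored by published stratum
  incidences (0.303 with cerebrovascular disease; age-split risk ratio
  1.92); the remaining leaf risks (0.16, 0.13, 0.0652, 0.07, 0.042,
  0.0237) are free parameters chosen once so the implied overall
  incidence is ≈ 5.44%;
* planted conditional exposure effects defaulting to the published crude
  log odds ratios, with exposure draws tilted toward high-risk strata
  (`weight = 0.6` on the centred baseline log-odds) so crude estimates
  are genuinely confounded;
* per-stratum intercept calibration: within each risk-tree leaf the
  intercept solves $\mathrm{mean}_i\, \mathrm{logit}^{-1}(c_\ell +
  \eta_i) = p_\ell$ over the realized exposure draws, so stratum
  incidences match their configured risks *exactly in expectation* while
  the planted log odds ratios remain exactly conditional effects.

What it does not emulate: raw (pre-discretization) laboratory values,
confounder-confounder dependence, longitudinal risk, or calibrated
*marginal* exposure effects — with seventeen exposures acting on the
log-odds scale, marginal associations in the synthetic cohort are
attenuated relative to the planted conditional values by non-collapsibility
and mutual confounding, exactly as in real data. Passing tests therefore
demonstrate that the estimators recover what they target under the stated
mechanism, not that the generator reproduces every joint property of the
original cohort.

`confounding_demo_config()` is the minimal recovery rig: one binary
confounder (40% prevalence) driving 5% vs 25% stratum risks, one exposure
with planted conditional OR 2.0 and a strong tilt (`weight = 1.5`), which
biases the crude OR upward by more than 30% (empirically to ≈ 4.4 at
large n). The acceptance study runs 200 seeds at n = 3000 and requires
≥93% CI coverage of 2.0 for the Mantel-Haenszel and logistic estimators
and ≤70% for the crude estimator.

## Problem sizes and seeds

Simulation scales were fixed once as study-design choices: oracle
equivalence for the Mantel-Haenszel estimators on all two-stratum tables
with cells ≤ 2 plus 500 sampled tables with cells ≤ 12; split-oracle
equivalence on random cohorts up to 200 × 8; coverage at n = 3000 over
200 seeds; structure recovery at the full n = 7302 over 100 seeds with
10-fold pruning. All randomness flows from explicit integer seeds (fold
assignment defaults to 20150901); `generate_cohort()` is bit-reproducible
given (config, seed), and the pipeline manifest records every seed and
file checksum.

## Known limitations

* The adjusted (Mantel-Haenszel and logistic) columns of the original
  analysis cannot be verified number-for-number without the raw cohort;
  the package substitutes oracle-equivalence and parameter-recovery
  evidence, and treats only the crude column, the root-split summaries
  and the cohort rates as exactly reproducible.
* Whether the published tree AICs penalized leaves or splits is not
  determinable from the printed values; the leaf-count convention is used
  consistently.
* One published row (the neutrophil-to-lymphocyte ratio) totals 7,192
  subjects rather than 7,302, an inconsistency in the source table that
  the packaged counts preserve as printed; its percentages confirm the
  smaller denominator.
* The albumin rows as printed give the *higher* sepsis incidence to the
  normal-albumin level, inverting the expected hypoalbuminemia effect;
  labels are kept as printed and `effect_table()` warns whenever a
  reference level carries higher incidence than an exposed level.
* No surrogate splits or in-tree missing-value handling: imputation
  (means/modes, mode ties to the lexicographically smallest label) happens
  strictly upstream of discretization.
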