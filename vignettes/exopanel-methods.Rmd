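---
title: "Methods: multiphase exosomal lncRNA panel discovery and risk-score validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiphase exosomal lncRNA panel discovery and risk-score validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exopanel)
```

## The study design this package implements

Circulating exosomal lncRNA fingerprint studies for hepatocellular
carcinoma (HCC) typically proceed in phases over four ordered clinical
groups — healthy controls (NC), chronic hepatitis (CH), HCC without
metastasis (HCC-N) and HCC with metastasis (HCC-M):

1. a tiny array-style **screen** (a few samples per group) filters
   thousands of assays down to a candidate list per group contrast, and a
   Venn intersection keeps markers elevated along the whole trajectory;
2. a **training** set quantifies the candidates by RT-qPCR, confirms the
   up-regulation, and fixes a binary-coded risk-score classifier;
3. a large **validation** set and a **double-blind** set are scored by the
   frozen classifier, yielding ROC/AUC, predictive values and blind
   accuracy for three clinically motivated contrasts (HCC vs NC, HCC vs
   CH, HCC-M vs HCC-N).

`exopanel` implements that chain as pipeable functions over long-format
tibbles (`assay_id`, `sample_id`, value, flag), with a fitted `risk_model`
object, `tidy()`/`glance()` summaries, `autoplot()`/`plot_*()` graphics,
and `run_pipeline()` to orchestrate the phases with a frozen-model
discipline.

## Relative quantification and nondetects

Quantification uses the comparative Ct method against an exogenous
spike-in (cel-miR-39), which every sample receives at a fixed dose before
RNA extraction. Within sample, `dCt = Ct_marker - Ct_reference` removes
per-sample recovery and input differences (adding any constant to all Ct
values of a sample, reference included, leaves `dCt` unchanged — a tested
invariance). Across samples, `ddCt` subtracts the per-marker arithmetic
mean `dCt` of a designated baseline group (NC by default), and relative
expression is `2^-ddCt`. Two consequences pinned by tests: the baseline
group's per-marker *geometric* mean expression is exactly 1, and
expression is strictly decreasing in marker Ct.

qPCR wells with no signal before the cycle limit are **nondetects**. The
package treats Ct = 35 as the quantification limit: censored wells are
imputed *at the limit* for `dCt` (the lowest expression consistent with
the observation — a conservative choice, since any later true crossing
would mean even less template) and flagged `censored`. The flag propagates
into every downstream summary (`n_censored` columns), is coded 0 in the
risk score, and the 75% detection-rate screening filter guards against
markers whose comparisons would rest mostly on imputed values. A nondetect
in the reference assay itself is an error, not a value: a failed spike-in
means a failed extraction, and no within-sample normalization can rescue
it.

## Screening filters and their readings

A marker passes a contrast's screen when all of the following hold, and
each reading below was a genuine design decision because the field's
verbal rules leave them open:

* **p < α (0.05)** from a two-sided pooled-variance Student's t test on
  log2 expression, with the direction then required to be *up*. A
  two-sided test plus direction filter (rather than a one-sided test) is
  used because the underlying test named in such protocols is the plain
  Student's t; under the null this makes the expected pass rate α/2, which
  the calibration tests verify. No multiple-testing correction is applied
  by default, mirroring the raw-p screening convention of this study
  family; `p_adjust = "BH"` is available for stricter use.
* **mean raw Ct < 35 in the higher-expression group.** The rule could be
  applied to either or both groups; the high group is where a biomarker
  claimed to be elevated must be reliably measurable, so the ceiling is
  applied there.
* **detection rate > 75% in both compared groups** — the strictest
  reading, preventing a "significant" fold change driven by one-sided
  censoring.
* optionally, a minimum |log2 fold change| (off by default: the screening
  convention lists none).

The Venn step intersects the pass sets of all supplied contrasts (three
adjacent group steps by default) and orders candidates by summed
-log10 p. Intersection semantics, roster consistency, subset and
idempotence properties are all property-tested against brute-force
enumeration.

The per-marker t statistics are computed vectorized from group means and
variances (as limma-style screens do for speed) and are verified
numerically against `stats::t.test` in the unit tests.

## The risk-score classifier

* **Thresholds.** θ_j is the upper 95% reference interval of control
  expression, read as the one-sided 95th percentile. The nonparametric
  estimate uses the linear-interpolation quantile (`stats::quantile`
  type 7, sample maximum at p = 1), pinned so that, e.g., controls
  1..100 give θ = 95.05 exactly; a parametric log-normal option
  (`exp(mean + 1.645 sd)` of log expression) is available. At least five
  controls are required; fewer is an error rather than a silent wide
  interval.
* **Coding.** `s_ij = 1` iff `expr_ij > θ_j`, strictly: a sample exactly
  at the threshold is inside the reference interval, hence negative.
  Censored wells code 0 — a nondetect is below the quantifiable range,
  hence below any positive threshold.
* **Weights.** `rsf_i = Σ_j W_j s_ij` with W_j = 1 by default, making the
  score the count of positive markers — the convention of this fingerprint
  literature, where weights are named but never derived. A named numeric
  vector (e.g. training |log2FC|) may be supplied; negative weights are
  rejected unless explicitly allowed, since they would break the
  monotonicity property (raising expression never lowers the score) that
  the tests enforce.
* **Cut-off.** Candidates are midpoints between adjacent distinct scores
  plus ±∞, classified by `rsf ≥ c`. The fitted cut-off maximizes
  sensitivity + specificity; ties prefer higher specificity (a screening
  classifier should err toward fewer false positives), then the smaller
  cut-off, making the rule deterministic. The objective is compared in
  exact integer counts (`tp·n_neg + tn·n_pos`), because float sums of the
  two rates can differ by an ulp between mathematically tied candidates
  and silently flip the tie-break. A median-score cut-off — the other rule
  this study family quotes — is available via `cutoff_rule = "median"`;
  the max(sens+spec) rule is the default because it is the stated
  selection criterion, while the median appears only descriptively.
* **AFP.** The combination with AFP is constructed by dichotomizing AFP
  with the same control reference-interval rule and appending it as a
  (J+1)-th coded marker with weight 1, so the extended score differs from
  the panel score by exactly 0 or 1 per sample (exhaustively tested).
  Single-marker and AFP-only ROC variants instead score the continuous
  value directly.

After `fit_risk_model()` the model is frozen: θ, weights and cut-offs are
never re-estimated on validation or blind data, the same training cut-off
is applied to every split, and sample-id overlap between fitting and
evaluation splits is a hard error (`exopanel_leakage`).

## Evaluation

ROC curves enumerate all distinct thresholds; the AUC is the trapezoidal
area, which on this step curve equals the Mann-Whitney statistic
`P(S_case > S_control) + ½P(tie)` — verified exactly against pair counting
on thousands of small instances, and against `pROC` on continuous scores.
A coded panel score takes at most J+2 distinct values, so its ROC is
honestly coarse; no smoothing or binormal fitting is applied. Scores are
never direction-flipped: an anti-predictive marker reports AUC < 0.5
as-is, because silently flipping would leak label information into the
score. Confusion summaries report the standard identities; PPV/NPV are
prevalence-dependent (a tested directional property), so they are
reported per contrast and split rather than pooled. No AUC confidence
intervals are attached by default.

Handling-condition stability (room-temperature incubation, freeze-thaw)
is assessed per marker by paired two-sided t tests on log2 expression
against the baseline condition. Because absence of significance is weak
evidence of stability, the worst-case mean |log2 ratio| is reported
alongside `stable = (min p > 0.05)`; identical replicates yield p = 1 by
convention (a zero-variance, zero-shift comparison).

## The synthetic cohort generator

`simulate_cohort()` emulates exactly the features downstream stages
assume, and is itself under test:

* four ordered groups with fixed splits of 3 (screen), 20 (train) and 180
  (validation) samples per group plus 100 blind samples — the multiphase
  design sizes;
* expression acting on the ΔCt scale: planted markers shift mean ΔCt down
  by `delta_dct_per_stage` (default 1.0 Ct) per group step with constant
  SD `sigma_dct` (default 1.0 Ct); null markers share one
  group-independent distribution. Location-only effects match the
  2^-ΔΔCt analysis scale, on which the planted shift is a log2
  fold-change per stage;
* right-censoring at the nondetect limit (35), a single mechanism that
  makes the nondetect fraction provably monotone in the limit; per-marker
  baseline ΔCt is uniform on 5–10 so typical Ct (≈25–30 against a
  N(20, 0.25²) spike-in) sits safely below the limit, and the reference
  is group-independent because the spike-in is exogenous;
* a log-normal AFP covariate with modest group separation (log-means
  2.30/2.60/2.85/2.95, log-SD 1.5), chosen so AFP alone discriminates HCC
  from NC at AUC ≈ 0.6 — deliberately mediocre, as serum AFP is in
  practice.

Because the source studies publish only log-scale group means for the
validated markers, the planted effect sizes are exercised defaults, not
calibrated estimates: passing tests demonstrate the machinery's
correctness and calibration under a realistic generating model, not the
clinical performance of any particular panel. Real plasma qPCR data also
differ in ways the generator deliberately omits: amplification-efficiency
variation, inter-plate batch effects, heavy-tailed or skewed within-group
expression, correlated markers, and informative (non-censoring) dropout.

## Numerical and procedural choices

* Quantile convention type 7 everywhere a percentile is taken (pinned by
  exact-value tests).
* Cut-off search in exact integer counts; deterministic lexicographic
  tie-break (objective, specificity, smaller threshold).
* Strict `>` at the coding threshold; censored cells code 0.
* Degenerate inputs fail loudly: single-class labels, empty or too-small
  control groups, unpaired stability data, unknown groups, reference
  nondetects, and fit/eval sample overlap are all typed errors.
* Cohorts serialize to TSV with nondetects as the sentinel `"ND"` (never a
  fake numeric Ct) and full-precision decimal numbers, so a write/read
  round trip is bit-exact; fitted models serialize to JSON and restore to
  identical classifications.
* All simulation flows from a single integer seed; the pipeline stamps
  every artifact with the configuration hash and seed, and re-running a
  configuration reproduces byte-identical numerical outputs. Splits are
  fixed in the annotation and never re-randomized inside stages.

## Statistical power across the phases, and a known limitation

The screen phase at 3 samples per group is severely underpowered for
realistic effects: for a 1-Ct (one log2 unit) per-stage shift at
`sigma_dct = 1`, the per-contrast two-sample t power at α = .05 is about
0.16 (`power.t.test(n = 3, delta = 1, sd = 1)`), so a marker survives the
three-way Venn intersection only a fraction of a percent of the time, and
the package's multi-seed recovery simulations (see
`tests/testthat/test-acceptance.R`) find the de-novo screen→Venn chain
recovering a full 3-marker planted panel in essentially no seeds at those
design sizes. This is a property of the design being modeled, not of the
implementation: historical screens of this shape pass hundreds of markers
per contrast largely by the null pass rate, and the burden of discovery
falls on the later confirmation phase. The training confirmation at
n = 20/group against pooled HCC (40 vs 20) has near-unit power for the
same effects, which is why the pipeline also supports
`candidate_panel = ...` in `pipeline_config()` to carry a prespecified
candidate list into training, mirroring studies where candidates are
fixed upstream. Users planning a real screen should either enlarge the
screen split or relax `alpha` at that phase and rely on confirmation to
control false positives.

Test-suite and acceptance-script problem sizes (e.g. 1,000-marker null
cohorts over 10–20 seeds, 50-seed recovery runs, 2,000-per-group binormal
checks) were chosen as the smallest sizes at which the binomial /
Monte-Carlo error bands in the assertions are decisive; the assertions
state their bands explicitly.
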