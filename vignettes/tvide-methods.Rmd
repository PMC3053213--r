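---
title: "Time-varying intercept models for longitudinal differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying intercept models for longitudinal differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvide)
```

## The problem

After bare-metal stent implantation, a subset of patients develops in-stent
restenosis (ISR): re-narrowing of the treated artery driven by inflammatory
and proliferative wound-repair responses. Because circulating leukocytes
interact with the injured vessel wall, peripheral-blood mononuclear cell
(PBMC) transcript levels sampled repeatedly after stenting may separate
patients who go on to develop ISR from those who do not.

The designs `tvide` targets draw blood at irregular times: a baseline draw
immediately before stenting (day 0), an early follow-up inside a 2–4-week
window, and a late follow-up inside a 5–7-month window (or near 12 months
when the 6-month visit is missed). Because the actual collection days vary
between patients, timepoints cannot be treated categorically; the model
works on the continuous day scale.

## The model and the test

For one probe, let $y_{ij}$ be log2 expression of subject $i$ at day
$t_{ij}$. The time-varying intercept model writes the mean trajectory as a
B-spline expansion

$$ y_{ij} = \sum_{k=1}^{d} \beta_k B_k(t_{ij}) + \varepsilon_{ij}, $$

with a single interior knot placed at the median follow-up day (about day
14 in the three-draw design, the centre of the early window). Two basis
choices are provided:

* **degree 1** (default, $d = 3$): the normalized piecewise-linear
  B-spline basis including the intercept. Rows of the design matrix are
  non-negative and sum to one, and fitted trajectories are continuous and
  non-constant between draws.
* **degree 0** ($d = 2$): two indicator segments split at the knot. The
  fit reduces to per-segment means, which gives a closed-form oracle used
  throughout the test suite.

The reported "dimension 2" of the original description is ambiguous (a
one-knot degree-0 basis has dimension 2; a one-knot degree-1 basis has an
overall intercept plus a 2-dimensional spline part). We default to degree 1
because published fitted trajectories change between adjacent draws, and
keep degree 0 as a config option and exact oracle; both modes are tested.

The null hypothesis fits one curve to both groups pooled; the alternative
fits separate curves to the ISR and no-ISR samples. The statistic is the
relative RSS improvement

$$ T = \frac{\mathrm{RSS}_0 - \mathrm{RSS}_1}{\mathrm{RSS}_1},
   \qquad \mathrm{RSS}_1 = \mathrm{RSS}_{\mathrm{ISR}} +
   \mathrm{RSS}_{\mathrm{no\text{-}ISR}}, $$

which is sensitive both to a group main effect (parallel curves at constant
offset) and to a group-by-time interaction (curves that separate or cross
over time). Since the pooled fit is a special case of the separate fits,
$\mathrm{RSS}_1 \le \mathrm{RSS}_0$ and $T \ge 0$; $T$ is invariant to
shifting and rescaling $y$. Fits use minimum-norm least squares so that
rank-deficient designs — e.g. a two-draw replication cohort under the
degree-1 basis — have a well-defined RSS.

### Bootstrap null distribution

Significance comes from a residual bootstrap under the null: each resample
is the pooled fitted mean plus resampled null-fit residuals, with group
labels held fixed, and $T^*$ is recomputed. The resampling unit is not
specified in the original description; because the data are repeated
measures, the default resamples residuals in whole subject blocks (each
subject receives a uniformly drawn donor subject's residual block, recycled
in within-subject time order when block lengths differ), preserving
within-subject correlation. Plain iid residual resampling is available for
comparison. P-values use the add-one convention
$p = (1 + \#\{T^* \ge T\}) / (B + 1)$, so $p > 0$ always — required by the
downstream FDR step.

The study-scale presets are $B = 10^7$ (discovery) and $B = 10^5$
(replication); these are honoured as documented configuration presets, not
defaults. Desk-scale runs use $B$ in the hundreds to tens of thousands;
the smallest attainable p-value is $1/(B+1)$, which bounds how small a
q-value a scan can produce.

Per-probe bootstrap streams are seeded from a hash of the probe identifier
plus the master seed, so scan results are invariant to probe ordering and
identical between serial and parallel execution.

### Multiplicity and selection

Benjamini–Hochberg step-up adjustment is the default
(`fdr_qvalues(method = "bh")`), with Storey's smoother-estimated null
proportion available; the original analysis cites a q-value method without
estimator details, and BH is reproducible and conservative. Selection uses
the strict rule $q < 0.05$. In the replication stage the adjustment runs
over the selected set only, since each replication test addresses a
pre-specified hypothesis; within-set BH q-values are never larger than
their genome-wide counterparts.

### Pattern taxonomy

Selected probes are labelled by comparing the two fitted curves on a
101-point grid over the observed time range: **consistent** when the sign
of (ISR − no-ISR) is strictly constant over the grid, **divergent** when
signs vary (including curves that coincide at baseline and then separate —
a boundary touch counts as divergence, matching the published use of the
label), with the divergent direction given by the sign of the time-averaged
difference; exactly equal curves are undetermined. The zero tolerance is
1e-12; the published labels were assigned visually, and the grid rule makes
them computable.

## Preprocessing

* **Floor filter**: probes with log2 values below 6.0 in strictly more than
  two thirds of samples are removed (`filter_low_expression`); missing
  values do not count as below-floor. The rule is idempotent.
* **Covariate adjustment** (`adjust_age_sex`): per probe, OLS of expression
  on intercept + centred age + 0/1 sex over *all* samples (the adjustment
  precedes the longitudinal analysis, which pools timepoints); output is
  residuals plus the fitted intercept, which equals the probe's grand mean
  under centring, so levels are preserved while the output is exactly
  orthogonal to age and sex. Constant covariates are dropped with a
  warning.
* **Sex concordance** (`sex_check`): nearest shrunken centroids (soft
  thresholded class centroids on standardized marker expression, threshold
  chosen by internal cross-validation since none is published) or two-class
  LDA, trained on all recorded sexes. Mismatches are flagged, not dropped;
  `drop_sex_mismatch` controls exclusion. The original marker list is not
  published, so markers are an input.

## The synthetic cohorts

No public accession exists for the original expression data, so the
generator stands in for it with the structure the analysis assumes:

* **Designs**: the `cardiogene` template enrols 312 subjects (ISR fraction
  52/312, female fraction 100/312, age ~ N(65.6, 10.4²)) with baseline for
  everyone, early follow-up uniform in [14, 28] days for 203/312, and late
  follow-up nested within early follow-up for 166/203, uniform in
  [150, 210] days or, with probability 0.2, in [350, 380] days (the
  12-month fallback; the exact fallback rate is unpublished, 0.2 reflects
  the reported long right tail of late draws). The `decode` template
  enrols 97 subjects (ISR 28/97, female 19/97, age ~ N(64.8, 10²)) with one
  ~6-month follow-up for 86/97. Named templates fix retention, group and
  sex counts at `round(n × fraction)` so profile totals (681; 183) are
  deterministic; Bernoulli retention is available via `exact = FALSE`.
* **Signals**: per probe, value = baseline mean + per-probe age and sex
  effects (drawn N(0, sd)) + subject random effect + group effect + iid
  noise. Group effects are zero (null), a constant ISR offset
  (`delta_main`, the "consistent" shape), or a divergence accruing
  linearly from zero at baseline to `delta_interaction` at the latest
  follow-up (the "divergent" shape). Linear divergence is the simplest
  shape qualitatively matching the published divergent trajectories; the
  test must not depend on the exact alternative shape. Defaults
  (`sigma_noise` 0.5, `sigma_subject` 0.3, deltas 0.75/1.0 log2) are chosen
  for test power at desk scale, not estimated from the original cohorts —
  no variance components were published.
* **Detection floor**: designated floor probes get baseline means ~1.5
  log2 units below the 6.0 floor anchor and all values are left-censored
  2.5 units below it, so floor probes fall below the QC threshold in
  essentially all samples while regular probes (means uniform in [7, 12])
  never do; the QC filter therefore removes exactly the designated set.
  (Censoring exactly *at* the threshold would defeat the strict `< 6`
  rule.)
* **Sharing ground truth**: passing one cohort's truth table to
  `simulate_expression` fixes the signal partition, so a replication
  cohort carries signal on the same probes — required for end-to-end
  replication tests.

What a green test establishes: calibration and power of the test under
independent Gaussian noise with subject random effects and the stated
retention structure. What it does not: robustness to batch effects,
probe-probe correlation (unless `shared_subject_effect = TRUE`),
heavy-tailed noise, or RMA normalization artefacts — none of which the
generator emulates.

## Replication, sensitivity, enrichment

`replicate_selected` reruns the test on the replication cohort with its own
median-follow-up knot (the replication design differs, so the knot is not
carried over); absent probes are skipped and excluded from the replicated
fraction's denominator. `sensitivity_null_sets` repeats the replication on
random probe sets (default 46 probes × 100 iterations, echoing the original
protocol) with per-iteration sub-seeds `seed + i`; by default the sampling
universe excludes the discovery hits (whether the original procedure did is
unstated; a flag includes them). `fisher_overrepresentation` tests
annotation categories by the one-sided hypergeometric upper tail, with the
EASE variant (recompute after removing one in-term selected gene) and BH
across terms; the universe is the QC-surviving probes deduplicated at gene
level, and unannotated genes count toward the out-of-term margin.

## Numerical choices and edge cases

* Minimum-norm least squares via SVD with tolerance
  `max(dim) * eps * d_max`; RSS is solution-invariant.
* `RSS_1 = 0` with `RSS_0 > 0` (perfect alternative fit) reports
  `T = Inf` with a degenerate flag; both zero reports `T = 0`. The zero
  test is relative (`1e-12 ×` the centred sum of squares), preserving scale
  invariance.
* Probes with missing values are fitted on complete samples (pairwise
  deletion); probes left without both groups or two distinct times are
  reported `NA` and excluded from FDR.
* Configuration round-trips through JSON (no YAML parser is assumed);
  exit codes of the CLI are 0/2/3 for success/validation/stage failure.

## Known limitations

* The bootstrap approximates the null through pooled-fit residuals; with
  very few subjects per group the subject-block scheme's donor recycling
  flattens some within-subject structure.
* Storey's estimator is unstable below ~20 p-values and falls back to a
  single-lambda estimate there.
* The pattern taxonomy depends on fitted curves only; with the degree-0
  basis, "divergent" can only arise from a sign change between the two
  segments.
* Sensitivity-analysis counts on synthetic null cohorts characterize the
  procedure, not the original deCODE data, whose published summary
  (median 2, mean 3.04, max 14) depends on unreleased measurements.
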