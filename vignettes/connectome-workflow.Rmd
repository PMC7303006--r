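---
title: "Methods: connectome-wide outcome analysis with connbs"
author: "connbs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-wide outcome analysis with connbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connbs)
```

`connbs` analyses intrinsic functional connectomes — subject-level matrices
of Fisher-z transformed Pearson correlations between parcellated brain
regions — to identify and evaluate subnetworks that separate clinical
groups, with the motivating design being an antidepressant trial contrasting
remitters, non-remitters and healthy controls at baseline and week 8. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic data do and do not establish.

## 1. From region time series to connectomes

The package takes *region-level* time series as its input boundary
(`RegionTimeSeries`: a T × N frames-by-regions matrix with a repetition
time and a censor mask). Image-volume preprocessing (realignment,
normalisation, smoothing) is out of scope.

**Volume censoring.** Framewise displacement (`framewiseDisplacement()`) is
the sum of absolute frame-to-frame changes of the three translations (mm)
plus the three rotations converted to arc length at an assumed head radius.
DVARS (`dvars()`) is the root-mean-square across regions of the
frame-to-frame signal change. Frames exceeding either threshold are
censored, and censoring is extended one frame to each side by default
(`extendFrames = 1`), since motion artifacts bleed into neighbouring
frames. Defaults (`denoiseConfig()`):

| parameter | default | unit | rationale |
|---|---|---|---|
| `fdThresholdMm` | 0.3 | mm | common scrubbing threshold for task data |
| `dvarsThreshold` | 1.5 | % signal change | conventional DVARS cut-off on percent-signal-change units |
| `headRadiusMm` | 50 | mm | standard adult head-radius convention for rotation-to-mm conversion |
| `bandLowHz`, `bandHighHz` | 0.009, 0.08 | Hz | canonical intrinsic-connectivity passband |
| `minRetainedFrames` | 30 | frames | below this a subject's correlation is too unstable to report |

These censoring thresholds are *assumptions*, flagged as such in the
pipeline manifest: they are conventional values from the volume-censoring
literature, and all of them are configurable.

**Nuisance regression.** `residualize()` fits ordinary least squares of
every region on a design assembled by `nuisanceDesign()`: intercept, task
regressors (task-evoked structure is treated as nuisance so that the
residuals estimate *intrinsic* coupling), the 24-parameter Volterra
expansion of the realignment parameters (`[R, R², R lagged, lagged R²]` —
stated explicitly because other "Volterra" conventions exist), optional
tissue-signal regressors, and one one-hot spike regressor per censored
frame. The fit uses retained frames only; residuals are orthogonal to every
design column over retained frames (tested to 1e-8), and a rank-deficient
design raises an error naming the collinear columns rather than silently
pivoting.

**Order of operations.** Censor-mask computation → regression → band-pass.
Censored frames are linearly interpolated before filtering and re-flagged
afterwards, so spike energy cannot leak through the filter, and they are
excluded from the final correlation. Filtering after regression keeps the
regression well-posed (spike regressors would be distorted by the filter).

**Band-pass realisation.** A second-order Butterworth band-pass applied
forward and backward (`signal::filtfilt`), i.e. zero phase and no group
delay. The contract is behavioural, not coefficient-level: passband
sinusoids (e.g. 0.04 Hz at TR 2.5 s) retain at least 90% amplitude,
stopband sinusoids (0.15 Hz) retain at most 10%, DC vanishes, and the
operator is linear — all asserted by tests.

**Correlation and Fisher z.** `correlateRegions()` concatenates the
retained frames of all runs, mean-centring each run per region first so
run-specific offsets do not masquerade as coupling, and computes one
Pearson correlation matrix per subject. Concatenation (rather than
averaging per-run matrices) is the default reading of "one matrix per
individual"; with runs of equal length the two differ little, and per-run
use is available by correlating runs separately. Correlations are clipped
to |r| ≤ 0.999999 before `atanh` so degenerate duplicates stay finite, the
diagonal is fixed at zero, and the matrix is symmetrised against rounding.

## 2. The Network Based Statistic

`nbs()` controls family-wise error at the level of connected components of
suprathreshold edges rather than individual connections:

1. a pooled-variance two-sample t-test at each edge independently
   ("two-sample t-test" is read as the classical pooled form; Welch is not
   used — group SDs on this scale are similar by construction);
2. edges with p below the component-forming threshold (default 0.001) are
   kept;
3. connected components of the kept edges are measured by *extent* (edge
   count; *intensity*, the sum of suprathreshold |t| − t_threshold, is
   available);
4. group labels are permuted (default 1000 times), the maximal component
   size stored per permutation — permutations with no suprathreshold edge
   contribute zero;
5. each observed component's corrected p is
   `(1 + #{null ≥ observed}) / (1 + K)`.

Numerical and design choices:

- **Tail handling.** The motivating contrast is directional (remitters >
  non-remitters), and the default runs a one-tailed contrast at the
  component-forming p per tail; `two_sided` is available. Which convention
  the field uses varies, so the configuration is echoed into every result.
- **Add-one smoothing.** The plain proportion of larger null sizes can be
  zero; `(1 + b)/(1 + K)` guarantees a valid p in `[1/(K+1), 1]`. The raw
  proportion is available (`pMethod = "raw"`), and in exhaustive mode the
  proportion over all assignments (which includes the identity) is used.
- **Ties.** Null maxima exactly equal to the observed size count toward the
  numerator (≥), the conservative choice.
- **Covariates.** When supplied, edges are residualized on the covariates
  once and labels are permuted over residuals (a Freedman–Lane-style
  scheme), with degrees of freedom reduced accordingly; covariates stay
  bound to subjects.
- **Exhaustive mode** enumerates every group assignment for small designs
  and is cross-checked in the tests against a hand-enumerated null built
  from naive t-tests and union-find component search.

The permutation loop reduces to two matrix–vector products per permutation
(group sums of `z` and `z²`), which keeps 200-cohort calibration studies at
desk scale.

## 3. Signature summaries and reports

Given a significant component, each subject's biomarker value is the
arithmetic mean of Fisher-z connectivity over its edges
(`meanSignature()`), and per-network-pair means map each edge to the
unordered pair of its endpoints' intrinsic-network labels
(`networkPairMeans()`). The overall mean always equals the
edge-count-weighted mean of pair means (a class invariant, enforced at
1e-10). Template labels are translated to the reporting vocabulary via a
configurable alias table (`networkAliases()`): the two somatomotor
subdivisions merge to "Somatomotor" and unassigned parcels become
"Unspecified".

A transcription of the published signature table ships in
`inst/extdata/remission_signature_table.tsv` (86 connections across 59
nodes in 15 network pairs). The printed source lists fewer rows than some
per-pair header counts; the header counts are treated as authoritative and
carried in `n_in_pair`, while the row list is illustrative — this is why
`countConnections()` sums one count per pair rather than counting rows.

## 4. Staged group statistics

- **Outcome × drug** (`anovaOutcomeByDrug()`): two-way between-subjects
  ANOVA with marginal (Type-III) sums of squares under sum-to-zero coding —
  the hypothesis of interest is the interaction, and Type-III keeps it
  invariant to cell imbalance (58 vs 105 split over three arms). Empty
  cells are an error naming the cell.
- **Case–control** (`anovaGroup()`): one-way ANOVA, with ANCOVA-style
  covariate adjustment (e.g. age) via the same Type-III machinery.
- **Longitudinal** (`mixedAnovaTimeGroup()`): split-plot ANOVA with time
  (two paired scans) within subjects and group between subjects. With two
  timepoints sphericity holds trivially, so no correction is applied (or
  needed). Applied per network-pair measure, the interaction p-values form
  one BH-FDR family across the network-pair measures (the overall mean is
  reported unadjusted — it is a single pre-specified summary, not part of
  the multiplicity family).
- **Post-hoc contrasts** (`posthocContrasts()`): within-group paired
  pre/post t-tests and pairwise between-group contrasts per timepoint
  (age-adjustable). The emitted contrast family (nine contrasts for three
  groups) is Bonferroni-corrected by default. An uncorrected variant
  (`adjust = "none"`) exists, but the package defaults to correcting
  because the family is reported as a unit; with two true-null groups an
  uncorrected 0.05 rule would flag a spurious within-group change in ~10%
  of datasets, which would misdescribe a "non-remitter-only" pattern.
- **BH-FDR** (`bhFdr()`): the step-up rule `p(i) ≤ i·q/m`, i.e. rejection
  at adjusted p ≤ q. Tests verify it against an exhaustive search over
  rejection sets for m ≤ 10.
- **Remission labeling** (`labelRemission()`): week-8 HRSD17 ≤ 7, with the
  boundary value counted as remission; missing scores get
  "not-applicable" with a warning.

**Predictive value** (`cvModelComparison()`): two classifiers under
identical stratified k-fold partitions (folds are a pure function of
labels, fold counts and seed) — a base model on demographic/clinical
features and the same model plus the signature mean. The default
classifier is maximum-likelihood logistic regression; an L2-regularized
variant (glmnet ridge) is available where separation or many features
demand it. The improvement test permutes the *added feature* across
subjects and refits the augmented model under the same folds each time; the
p-value is `(1 + #{perm accuracy ≥ observed}) / (1 + B)`. Permuting the
added feature (rather than the labels) tests exactly the added value of
the signature while holding the base model's performance fixed. The
original study's classifier and scheme are not fully specified in public
text, so these defaults are the package's own and are configurable.

## 5. The synthetic cohort generator

`generateEdgeCohort()` samples Fisher-z edges directly:

`z(subject s in group g, edge e, time t) = mu[g, t, e] + b_s + eps[e, t]`

with a subject offset `b_s ~ N(0, subjectSD)` shared across edges and
timepoints (inducing realistic inter-edge correlation), edge noise of SD
`edgeSD`, and a retest correlation (default 0.7) between the two
timepoints' noise. The defaults encode the emulated study design: 333
nodes with the 13-network template composition, groups of 62/58/105
(control/remitter/non-remitter), base edge mean 0.2 and edge SD 0.25 (the
scale of the published per-connection means ± SDs, which span roughly
−0.3…0.8 ± 0.16…0.32), a planted 86-edge connected subnetwork, a
remitter elevation of 0.15 z on planted edges at *both* timepoints (the
trait-like pattern), and a non-remitter-only increase of 0.05 z at the
second timepoint (the published non-remitter post-treatment rise of the
whole-network mean is of this order). The within-subject retest
correlation is a free parameter — no public value exists — and 0.7 is a
typical connectome test–retest figure.

The planted component is grown as a random tree over a node subset
(guaranteeing connectedness, which NBS requires of any detectable ground
truth) and augmented with random edges to the requested count; the subset
size targets ~0.7 nodes per edge, matching the density of an 86-edge /
59-node signature.

`simulateSubjectTimeSeries()` generates the region-level analogue: latent
Gaussian series with a specified correlation matrix on a BOLD-like
baseline of 1000 units, plus boxcar task effects, polynomial drift, white
noise, and a motion-coupled artifact. Smooth motion couples into the
signal through fixed region loadings (recoverable by the motion
regressors); motion *spikes* couple through frame-specific random loadings
— like spin-history effects, not a linear function of the realignment
parameters — which is precisely the part only censoring can remove, and
what makes the censoring-on/off comparison in the acceptance suite
meaningful rather than circular.

`generateClinicalTable()` draws the demographics and severity scores
(baseline HRSD17 21.7 ± 4.0 truncated at the entry criterion of 16;
week-8 scores 4.9 ± 1.7 for remitters and 13.3 ± 3.9 for non-remitters,
truncated to the outcome-consistent ranges so the remission rule and the
group labels can never disagree; group-specific ages; 51% female; 1:1:1
exact allocation over three drug arms; naivety rates 64%/33%).

**What passing tests show, and what they do not.** The generator's edges
are Gaussian with homogeneous means and a single shared subject factor;
real connectomes have heavier tails, edge-dependent means and SDs,
spatially structured noise, and site/motion confounding. Calibration and
recovery results on these cohorts validate the *machinery* (the
permutation engine is exact under exchangeability regardless of the
generating distribution) but do not certify power or error rates on real
clinical data, and the planted-effect sizes are not estimates of real
effect sizes.

## 6. Problem sizes and numerical details

Simulation studies in the tests and acceptance script run at 50 nodes with
20–50 subjects per group, 200 NBS permutations, 200 null cohorts for FWE
calibration, 50 seeds for recovery, 100 seeds for the longitudinal and
classifier studies, and T = 600 frames for the denoise chain — sizes
chosen so the whole suite runs in a few minutes on one CPU while keeping
Monte-Carlo error well inside the asserted bounds. Other numerical
choices: correlation clipping at 10^-6 from ±1; component ordering is
deterministic (decreasing size, then smallest node id); zero-variance
edges get t = 0, p = 1 and can never seed a component; permutation seeds
are explicit everywhere, and the pipeline derives all stage seeds from one
global seed (simulate: seed, clinical: +1, NBS: +2, CV: +3).

## 7. Known limitations

- No voxel-level processing: region time series are the input boundary.
- No graph-theoretic summaries (degree, modularity, efficiency) — the
  analysis is deliberately confined to component identification and mean
  connectivity.
- The NBS implementation offers extent and intensity only, not
  threshold-free variants.
- Classical ANOVA only; no mixed-effects longitudinal models.
- The exhaustive permutation mode is limited to designs with at most
  2 × 10^5 assignments.
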