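---
title: "Simulating therapeutic inference in focal brain injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating therapeutic inference in focal brain injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whether a randomized trial detects a treatment for focal brain injury
depends not only on the treatment's true effect but on how well the outcome
model absorbs the other determinants of outcome — above all the interaction
between the spatial pattern of damage and the brain's functional anatomy.
Conventional trial models reduce that anatomy to a single number, lesion
volume. `therinf` quantifies what this reduction costs. It simulates
hypothetical interventions of known effect size on a lesion cohort, runs
many randomized "trials" per effect size, and estimates the *therapeutic
function*: the probability that a trial is positive (intervention p < 0.05)
as a function of effect size. The function's 0.5 crossing is the
*therapeutic threshold* — the smallest effect the inferential method would
reliably identify; a meta-analysis of such trials would only just declare
the treatment effective there. Comparing thresholds between a
*low-dimensional* model (intervention, age, sex, lesion volume) and a
*high-dimensional* one (the same model plus a lesion-pattern-based
prediction of the natural outcome) measures the value of modelling anatomy.

Two intervention classes are simulated:

* **Lesion non-altering** (e.g. neurorehabilitation): a fixed proportion of
  the treated arm has its outcome normalized; the lesion is untouched.
* **Lesion-altering** (e.g. thrombolysis): each treated lesion is shrunk by
  iterative surface erosion to a fixed fraction of its volume, and the
  counterfactual outcome is read off a recovery classifier applied to the
  changed lesion.

The behavioural outcome is the preferred direction of gaze, a clinically
standard deficit after large hemispheric stroke: *eligibility* is a
leftward deviation of more than 12 degrees at the first time point,
*recovery* a deviation within 3 degrees of the midline at the second. Both
boundaries follow the clinical definition literally: eligibility is strict
(`gaze_t1 < -12`), recovery inclusive (`|gaze_t2| <= 3`), and both are
unit-tested at the boundary.

## The synthetic cohort generator

No patient-level clinical dataset ships with the package; a synthetic
generator (`generate_cohort()`) provides cohorts with the statistical
structure the analysis depends on. It is first-class, tested code, and its
defaults define the study conditions used throughout the tests.

**Grid.** All patients share one registered analysis lattice
(`build_brain_grid()`), by default a 24 x 28 x 22 array of 6 mm isotropic
voxels whose ellipsoidal in-brain mask holds 5768 voxels — the scale of a
clinical lesion-mapping dataset parameterized at 6 mm with several thousand
binary variables per patient. A half-linear-size "desk" grid
(`desk_brain_grid()`, 716 voxels) supports fast experimentation; all
spatial parameters of the generator scale with grid size, so the two grids
produce equivalent cohort structure. In-mask voxels are linearized in
column-major order; the first array axis is left–right, with the midline
plane (odd-width grids) assigned to the left hemisphere by convention.

**Lesions.** Each patient has a single 6-connected lesion grown by
stochastic boundary accretion from a uniform in-mask origin, confined to
one hemisphere with probability 0.95, with volume drawn from a log-normal
(median 4% of the in-mask volume, sdlog 0.6, truncated at 60% of the
hemisphere). This mimics contiguous, predominantly unilateral ischaemic
lesions; it does not attempt vascular-territory realism, multi-focal
disease, or partial-volume boundaries.

**Functional ground truth.** Two smooth voxel weight fields stand in for
the unknown functional anatomy. *Deficit weights* map damage to gaze:
admission gaze is minus the sum of deficit weights over lesioned voxels
plus Gaussian noise (SD 4 degrees). Weights are sums of Gaussian foci (two
per hemisphere, SD 14% of brain width, centres rejection-sampled to be
mutually separated and comparably central), positive on the right
(right-hemisphere damage drives leftward gaze) and negative on the left,
with right mass 200 versus left 170 degrees. The slight rightward
asymmetry reproduces the clinical picture — severe leftward deviation
dominates — while keeping the population circular mean within about two
degrees of the midline, as observed in admission cohorts. *Recovery
weights* map damage to the log-odds of non-recovery through a logistic
link: one of the two right-hemisphere deficit foci carries a
recovery-critical focus (SD 7% of brain width, total log-odds mass 80,
intercept -2.5), so gaze-deviated patients persist when their lesion
extends into that region and otherwise mostly recover. The second time
point draws gaze near the midline (SD 1 degree) for recoverers and around
the admission angle (SD 5 degrees) for persisters.

Two design points deserve emphasis. First, the generator's outcome model
(logistic in a spatial weight field) deliberately differs from the linear
models used for inference, so high-dimensional gains cannot be an artefact
of model match. Second, age and sex truly have no effect: they are pure
confound candidates, keeping the ground truth for the intervention
coefficient clean.

Calibration of these defaults was done once, against the regime the
framework assumes: an eligible fraction near 20–25%, natural recovery among
the eligible near one half, a circular mean within two degrees of midline
at large n, laterality dependence with |z| well above 3, and a linear
classifier reaching held-out sensitivity and specificity of at least 0.70
(typically 0.80–0.90) when trained on half the eligible patients. What
passing tests under this generator show is that the *inferential machinery*
behaves as claimed where anatomy genuinely determines outcome; they cannot
show that any particular clinical dataset has such structure, and
real-data thresholds are expected to differ from the synthetic ones.

## The recovery classifier

The high-dimensional component is a linear support vector machine (libsvm
C-SVC, linear kernel, class-weighted for imbalance) on the binary lesion
vector. The fitted voxel weights and bias are extracted so prediction is a
dot product: positive score favours recovery. Regularization defaults to
nested 5-fold selection of C over 10^-3..10 on the training pool only,
by balanced accuracy (consistent with the class weighting). A
*transductive* mode implements self-training — label the unlabelled
vectors with the current model, refit on the union, iterate to a fixed
point (at most 10 rounds) — as a reproducible operationalization of
transductive linear SVMs; the inductive mode is the default in all tests,
since the framework's claims do not hinge on the transduction variant.

The independence contract is enforced, not assumed: the classifier records
its training ids, and every trial run asserts an empty intersection with
the trial pool before any randomization is seen.

## The trial engine

Eligible patients outside the classifier pool are repeatedly randomized
1:1 (`round(allocation * n)` treated, round-half-up). The treated arm
receives the intervention:

* non-altering: exactly `round(p * n_treated)` seeded-uniformly chosen
  responders have their outcome forced to recovery (a natural recoverer
  chosen as responder stays recovered, so effective effects are diluted by
  the natural recovery rate exactly as in a real trial); a Bernoulli
  per-patient variant is available by configuration.
* lesion-altering: each treated lesion is eroded to
  `round((1 - f) * V)` voxels and the outcome is the classifier's
  prediction on the changed lesion. Control outcomes default to the
  classifier applied to the *unchanged* lesion, which makes the
  zero-reduction null exact by construction; the observed natural outcome
  is available as an alternative control rule, since the clinical
  description of such models leaves the control side ambiguous.

Each iteration fits an ordinary-least-squares linear probability model of
binary recovery on intercept, intervention, age, sex and (pre-intervention)
lesion volume — the faithful reading of "linear regression predicting
recovery"; a logistic link is available by configuration but never the
default. The high-dimensional model adds one covariate: the classifier's
predicted recovery label on the pre-intervention lesion. The label (rather
than the continuous score) is used because the added factor is defined as a
prediction of *whether* the patient would recover regardless of treatment;
the continuous decision score remains available
(`hd_covariate = "score"`). Within an iteration the two models see
identical randomization and outcomes — the only difference is the covariate
column — so low/high-dimensional comparisons are paired.

A trial is positive when the two-sided t-test p-value of the intervention
coefficient is below 0.05. No multiplicity correction is applied across
iterations: each iteration stands for an independent trial in a
meta-analytic frame. Rank-deficient designs are recorded as failed,
non-positive iterations; a point with more than 5% failures aborts the
batch. Per-iteration seeds come from a single master-seeded table of
independent draws indexed by (effect level, iteration), so iterations
behave as independent replicates — the null detection rate then shows
binomial dispersion, which the calibration test relies on — while any cell
can be re-run in isolation and results are independent of execution
order.

## Erosion

One erosion pass removes every lesioned voxel with at least one unlesioned
6-neighbour (26-connectivity is a configuration option; 6 is the most
conservative surface definition). Rather than stopping at whole passes, the
procedure hits the target volume `round((1 - f) * V)` exactly: full shells
are removed while they fit, and the final partial shell is removed by
seeded uniform choice among the current boundary voxels. This makes the
simulated effect size exact and testable; under 6-connectivity the removal
depth equals the city-block distance to the lesion exterior, which the test
suite checks against a brute-force distance-transform oracle. Disconnected
remainders are eroded as a whole and may vanish. The trial engine uses a
cached formulation (per-patient shell decomposition plus weight sums) that
is bit-identical to explicit erosion followed by prediction — an equality
the tests assert directly.

## The therapeutic function

Mean detection probabilities per effect level are fitted with a monotone
shape-constrained spline: an I-spline (integrated B-spline) basis of degree
3 with interior knots at the observed effect sizes, non-negative
coefficients and intercept (fitted by non-negative least squares with a
10^-6 Tikhonov augmentation for numerical rank), and iteratively
reweighted Huber loss (k = 1.345 MAD units) as the robustness scheme. The
fit is clipped to [0, 1]. The basis is overcomplete relative to the nine
points; the monotonicity constraint acts as the regularizer, and the
resulting curve behaves like a robust monotone interpolant, which is what
threshold estimation needs. The threshold is the smallest effect size at
which the fitted curve reaches 0.5, found by bisection to 1e-4; a curve
that never attains 0.5 reports "not reached" (`NA`).

Confidence intervals resample the per-iteration binary trial outcomes
within each effect level, refit, and take the percentile 95% interval of
the re-estimated thresholds (1000 replicates at full scale, 400 at desk
scale). When more than 10% of replicates do not reach 0.5 the interval is
reported censored. The spline family, robustness scheme and CI construction
are declared package choices: the underlying methods literature names a
"robust spline fit" with 95% CIs without specifying basis, loss or
resampling scheme.

Monotonicity of a detection curve is tested with an isotonic violation
statistic (squared distance to the best non-decreasing fit) compared
against its permutation distribution over random reorderings: the curve
passes when its violation is smaller than that of 95% of permutations.

## Problem sizes and what the experiments show

The packaged experiments use, as the package's own choices: a 500-patient
desk-grid cohort of 800 patients with 600 iterations for null calibration (the detection
rate at effect 0 must fall in the central 95% binomial band, [0.033,
0.070]); nine effect levels at 100 iterations for monotonicity; and for
the left-shift comparison a cohort at the clinical scale of 1172 patients
(on the desk grid), nine levels and 300 iterations per level with 400
bootstrap replicates — large enough that the threshold CIs are a few
percentage points wide and the paired comparison is meaningful. The `desk` preset (300 patients, five levels, 100
iterations) is for interactive exploration; `paper_scale` (1172 patients,
full grid, nine levels, 600 iterations) reproduces the full experiment
layout at clinical scale.

Under the default ground truth the high-dimensional model shifts both
therapeutic functions left, with non-overlapping bootstrap CIs, and the
shift is larger for lesion-altering interventions — where the classifier
links the anatomical change itself to outcome — than for non-altering
ones. These orderings are properties of the generator regime, not of every
random cohort: with small cohorts, classifier quality and the depth at
which the recovery-critical region sits inside lesions vary from draw to
draw, and individual seeds can produce compressed gains. The packaged
experiment sizes were chosen so the orderings are stable; the residual
simulation variability is the honest price of a fully synthetic benchmark.

## Numerical and degenerate-input policy

Round-half-up (`floor(x + 0.5)`) is used for every integer target derived
from a fraction — erosion targets, responder counts, arm sizes — so the
counting rules match their documented examples exactly. Angles are wrapped
to (-180, 180]; the circular mean of an antipodally balanced set is
undefined and returns `NA` with a warning, as does the laterality ratio of
an empty lesion (never 0). Empty-lesion patients are excluded, with a
message, from the laterality curve. Ties in the final erosion shell are
broken by a seeded uniform draw. All stochastic components take explicit
seeds; cohort generation, trial batches, bootstrap CIs and whole
experiments are bit-reproducible from one master seed, and result bundles
carry a manifest (config hash, seed, versions).

## Known limitations

* The generator's anatomy is a two-focus Gaussian caricature per
  hemisphere; real functional anatomy is far more distributed, and real
  lesions follow vascular territories.
* The erosion model shrinks lesions geometrically; real reperfusion does
  not peel tissue uniformly from the surface.
* The transductive mode is a self-training approximation, not a margin
  optimizing transductive SVM.
* Thresholds estimated on real clinical cohorts depend on the particular
  dataset's anatomy and outcome noise; the synthetic results here support
  only the qualitative orderings — high-dimensional left of
  low-dimensional, and a larger lesion-altering gain — not any particular
  threshold value.
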