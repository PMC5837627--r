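# therinf

Simulation-based therapeutic inference for focal brain lesion cohorts.

## The problem

Trials of treatments for focal brain injury — thrombolysis,
neurorehabilitation — judge an intervention by its behavioural outcome,
deconfounded by a handful of covariates such as age, sex and lesion volume.
But outcome after a focal lesion is driven by *where* the damage falls on
the brain's functional anatomy, a high-dimensional interaction such models
cannot see. `therinf` measures what this costs. It simulates hypothetical
interventions of known effect size on a lesion cohort, runs hundreds of
randomized "trials" per effect size, and estimates the **therapeutic
function**

> f(effect size) = Pr(trial positive at α = 0.05),

a monotone curve whose 0.5 crossing is the **therapeutic threshold**: the
smallest effect a given inferential method would reliably detect (where a
meta-analysis of such trials would only just call the treatment
effective). Comparing thresholds between a *low-dimensional* outcome model
(`recovery ~ intervention + age + sex + lesion volume`, a linear
probability model) and a *high-dimensional* one (the same model plus a
linear-SVM prediction of recovery from the full voxel-wise lesion pattern,
trained on held-out patients) quantifies the sensitivity gained by
modelling anatomy.

Two intervention classes are simulated on the treated arm:

* **lesion non-altering** — a chosen proportion of treated patients has
  its outcome normalized (responder model);
* **lesion-altering** — each treated lesion is shrunk by morphological
  surface erosion to an exact volume fraction, and the counterfactual
  outcome is the recovery classifier applied to the changed lesion.

The behavioural outcome is the direction of gaze: eligibility is a
leftward deviation > 12° at admission, recovery a deviation within 3° of
the midline at the second time point. A synthetic cohort generator
(contiguous stroke-like lesions, anatomy-dependent gaze and recovery)
makes every stage testable without any clinical data; see the methods
vignette (`vignettes/therapeutic-inference.Rmd`) for the generative model
and all defaults.

## Worked example

```r
library(therinf)

grid   <- desk_brain_grid()                         # 716-voxel 6 mm grid
cohort <- generate_cohort(n = 300, grid = grid, seed = 7)
cohort
#> cohort: 300 patients on 716-voxel grid; 50 eligible (gaze < -12), 16/50 recovered

circular_mean(cohort$covariates$gaze_t1_deg)
#> [1] -0.81                                  # admission gaze sits near midline

gaze_laterality_curve(cohort)
#> gaze-laterality curve (n = 300): slope -0.0193 per degree (z = -15.26)
```

The laterality slope says leftward gaze deviation goes with
right-hemisphere damage — the dependence the high-dimensional model will
exploit. Now run randomized responder-model trials (the classifier is
trained automatically on a held-out half of the eligible patients; the
trial pool never overlaps it):

```r
curves <- run_trial_batch(cohort, "non_altering",
                          effect_sizes = seq(0.1, 0.9, by = 0.2),
                          n_iterations = 100, master_seed = 7)
curves
#> detection curves (non_altering, 100 iterations, 25 trial patients):
#>          kind model_kind effect_size ... detection_probability
#>  non_altering    low_dim         0.5 ...                  0.38
#>  non_altering    low_dim         0.9 ...                  0.97
#>  non_altering   high_dim         0.5 ...                  0.46
#>  non_altering   high_dim         0.9 ...                  1.00

for (mk in c("low_dim", "high_dim")) {
  tf <- fit_therapeutic_function(curves$table[curves$table$model_kind == mk, ])
  ci <- bootstrap_threshold_ci(curves, model_kind = mk, n_boot = 400, seed = 7)
  cat(sprintf("%s threshold: %.3f ", mk, tf$threshold)); print(ci)
}
#> low_dim threshold: 0.637 threshold 95% CI: [0.5297, 0.7347]
#> high_dim threshold: 0.525 threshold 95% CI: [0.4662, 0.5699]
```

At this small interactive scale the low-dimensional model needs ~64% of
treated patients to respond before half of the trials are positive; adding
the lesion-pattern covariate moves the threshold to ~53% — the
high-dimensional left-shift. `run_experiment(experiment_preset("desk"))`
runs both intervention classes end to end (cohort → classifier → trials →
fitted functions, thresholds, bootstrap CIs) and `make_figures()` renders
the gaze polar histogram, the laterality curve, the paired therapeutic
functions and the classifier weight-map montage.

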