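# cinempca

Tensor-based prognostic modelling of time-resolved cardiac cine MRI in R.

A cine cardiac MR study is a short movie of the beating heart: a
mid-chamber slice imaged at ~20 time points over one cardiac cycle, in two
standard views (short-axis, SA, and four-chamber, 4Ch). `cinempca`
implements a fully transparent machine-learning chain that predicts 1-year
mortality from these image tensors and — because every stage is linear —
maps the learned evidence back onto the anatomy, frame by frame. It is
aimed at researchers in cardiovascular imaging who want an interpretable
alternative to deep-learning prognosis models, and at methodologists who
need a leak-free reference implementation of the pipeline.

## The method

For cine tensors $X_i \in \mathbb{R}^{H \times W \times T}$ (z-scored,
landmark-registered, masked, downsampled), multilinear principal component
analysis (MPCA) learns one orthonormal basis per mode and encodes each
study by its core

$$C_i = (X_i - \bar X) \times_1 B_1^\top \times_2 B_2^\top \times_3 B_3^\top ,$$

preserving the spatial-by-temporal structure that vectorised PCA destroys.
Features are ranked by Fisher's discriminant ratio
$(\mu_1-\mu_0)^2/(\sigma_1^2+\sigma_0^2)$, a top-$k$ set is chosen by
stepwise inclusion against a held-out tuning set (~50 cases), and a linear
SVM per view — plus a dual-scan SVM on the concatenated selected features
of both views — produces calibrated mortality probabilities. Evaluation
uses Cox proportional hazards, Harrell's c-index, AIC, likelihood-ratio
tests against clinical baseline models, Kaplan–Meier curves split at the
training-median risk, and a fixed-horizon ROC. Back-projecting the SVM
weight vector through the MPCA bases yields a signed voxel-frame saliency
map (positive = mortality evidence, negative = survival evidence), which
is thresholded, cleaned by morphological closing with a radius-2 discrete
sphere over (x, y, t), and summarised per anatomical region and cardiac
frame.

A synthetic cine-cohort generator (two views, beating two-ellipse heart,
jittered landmarks, 10% 1-year event prevalence, survival times from a
proportional-hazards model on a latent risk that also drives a planted
septal image signal) makes the whole chain testable against known ground
truth without patient data.

## A worked example

```r
library(cinempca)

# a synthetic cohort with a planted end-systolic septal signal
cfg <- run_config(
  n_subjects = 250, views = "SA", effect_size = 2,
  image_size = 32, cv_rounds = 0, seed = 5, n_frames = 20
)
report <- run_full_study(cfg)

report$evaluation$roc$auc          # held-out 1-year AUC
report$evaluation$validation_c_index
report$evaluation$lrt$p            # does the image model add to the clinical score?
audit_provenance(report)           # no validation subject entered any fitting stage
```

On this configuration the run prints (seed 5):

```
> report$evaluation$roc$auc
[1] 0.9356618
> report$evaluation$validation_c_index
[1] 0.9282443
> report$evaluation$lrt$p
[1] 0.0002664643
```

i.e. the held-out 1-year AUC is 0.94, the validation c-index 0.93, and
adding the image-based probability to the clinical covariate model
improves the Cox fit significantly (likelihood-ratio p = 4e-4). With
`effect_size = 0` the same quantities fall to chance level — the null
calibration asserted in the test suite.

At full study conditions (n = 500 subjects, 64×64×20) the `simulate`,
`preprocess`, `mpca` and `train` stages together take a few minutes on one
CPU; single-study inference through a fitted model is milliseconds.

A thin command-line wrapper is installed at `inst/cli/cinempca.R`:

```sh
Rscript inst/cli/cinempca.R simulate --n 100 --out cohort/ --seed 1
Rscript inst/cli/cinempca.R run-all  --n 300 --out results/ --effect 2
```

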