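---
title: "Simulating disease-related gray-matter change with cycle-consistent adversarial translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating disease-related gray-matter change with cycle-consistent adversarial translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Case-control neuroimaging tells us *which* brain regions differ between a
patient group and controls, but it cannot show what a particular healthy
brain would look like *if it had the disease*. An unpaired image-to-image
translation model can: trained on two cohorts of modulated gray-matter (GM)
density maps — one healthy, one diseased — it learns a voxel-wise
transformation that imposes the disease's morphometric signature on an
individual anatomy while preserving everything else about that subject.
`cyclemorph` implements this "disease brain generator" for 3D GM volumes,
together with the voxel-based-morphometry (VBM) statistics used to validate
it and a synthetic phantom cohort generator so the whole pipeline can be
exercised, tested, and calibrated without any clinical data.

## The model

The translation model is a CycleGAN: two generators
(`G1`: healthy → disease, `G2`: disease → healthy) and two patch
discriminators (`D_A`, `D_B`), trained with

* an **adversarial log-loss** per direction,
  `L_adv = E[log D(y)] + E[log(1 − D(G(x)))]`, which the discriminator
  maximizes, and
* an **L1 cycle-consistency loss**,
  `L_cyc = E‖G2(G1(x)) − x‖ + E‖G1(G2(y)) − y‖`, weighted by
  `lambda_cycle` (default 10, the standard choice), which ties each
  translated volume back to its source subject.

For the generator update we use the *non-saturating* form of the same
log-loss (maximize `E[log D(G(x))]`) by default. It has the same fixed
points as the literal second term of `L_adv` but provides usable gradients
when the discriminator confidently rejects early fakes; the saturating form
is available via `cyclegan(..., saturating = TRUE)`. The discriminator's
objective is always the equation above.

**Generators** are 3D U-Nets: `n_encode_blocks` (default 3) encoding blocks
of two kernel-3 convolutions with instance normalization and ReLU followed
by 2× max-pooling; a bottleneck of `n_resblocks` (default 6) residual
blocks; and a mirror decoder per level — a stride-2 transposed convolution
for upsampling, concatenation with the skip connection, and two further
convolutions. (A "stride-1 transposed convolution" is mathematically an
ordinary convolution, which is how the two post-upsampling layers are
implemented.) The final kernel-3 convolution maps to one channel through a
tanh, matching the `[−1, 1]` intensity mapping of the inputs.
Convolutions followed by instance normalization carry no bias: the
normalization removes any per-channel constant exactly.

**Discriminators** are patch classifiers: `n_blocks` stride-2 kernel-3
convolutions with instance normalization and leaky ReLU (slope 0.2), then a
stride-1 convolution to a single-channel score map under a sigmoid. Each
score summarizes one receptive-field patch, so the adversarial signal is
local rather than global. Five blocks need at least 64 voxels per axis;
the desk-scale configuration uses 4 blocks on 32-voxel grids.

The networks are implemented natively in C++ (RcppArmadillo, single
precision). Stride-1 convolutions are computed as 27 shifted GEMM
accumulations on a zero-padded grid; training is plain backpropagation with
Adam (lr 2e-4, betas 0.5/0.999 — the usual CycleGAN settings; the update
alternates generators and discriminators once per volume pair, batch
size 1). All stochastic choices (weight initialization, epoch shuffling,
phantom sampling) draw from seeded R RNG streams, so a fit is exactly
reproducible from its seed on a fixed platform.

### Intensity mapping and model state

Volumes enter the network through the affine map `[0, data_max] → [−1, 1]`,
where `data_max` is the maximum voxel value over the training volumes of
both domains (a single shared scale, so the two domains stay comparable).
Every call of `transform_volume()` / `predict()` applies the map, runs the
generator, inverts the map, and clips at zero. A fitted model stores its
weights as exact single-precision values; save → load → transform is
bit-identical to transforming before saving.

Because instance normalization standardizes every channel using statistics
of the input itself, there is no parameter setting that makes the network
an exact identity. Where a fixed-point control is needed (null and
progression controls), `identity_model()` provides an explicit
identity-transform model instead.

## The phantom cohorts

`phantom_spec()` defines the study conditions. The anatomy template is a
sum of `n_structures` (default 8) smoothed ellipsoid indicators on a
`32³` grid of 1.5 mm voxels, peak-normalized to 1. Each subject then gets

* per-structure amplitude jitter (`subject_jitter_sd`, default 0.05) —
  a crude but controllable stand-in for inter-subject anatomy;
* a global age factor `1 − atrophy_per_year × (age − age_low)` with
  `atrophy_per_year = 0.004` over ages 18–65 — about 0.4 % density loss per
  year, the order of magnitude of reported adult GM decline; ages are drawn
  uniformly and independently of group, so age and disease are orthogonal
  *by construction* (real cohorts cannot guarantee this; the covariate
  probe requires it);
* additive voxel noise (`noise_sd`, default 0.02) confined to the anatomy
  support. Real modulated GM maps are exactly zero outside tissue;
  background noise would also dominate the SPM-style "global" (mean/8)
  mask on a mostly-empty desk-scale grid. The noise is unsmoothed by
  default (`noise_smoothness_mm = 0`), which keeps voxel-wise test
  calibration exactly binomial; smoothed noise is available but inflates
  the variance of any suprathreshold-rate statistic far beyond the
  binomial band, so calibration checks use the independent-noise setting.

The disease effect is **multiplicative**: inside a union of spherical ROIs
(centred on template structures so they always lie in tissue), density is
scaled by `1 − δ_s`, with `δ_s` drawn per subject from a normal truncated
to `[0, 1)` (mean 0.25, sd 0.05 in the headline configuration). A
multiplicative loss matches the volume-reduction semantics of modulated GM
maps, and the subject-level spread gives the adversarial model a
distribution to learn rather than a constant offset.

What the phantoms deliberately do *not* emulate: cortical folding,
registration error, site effects, nonlinear age trajectories, or spatially
correlated physiological noise. Passing tests on phantoms therefore
demonstrates that the implementation recovers a known injected effect under
controlled conditions — not that the model resolves the much harder
ambiguities of real data.

## VBM-style validation

`paired_t_map()` and `two_sample_t_map()` compute voxel-wise t statistics
(paired across states of the same subjects, or pooled-variance between
groups) with two-sided p-values; zero-variance voxels are `NaN`.
`threshold_map()` applies the "combined voxel level" convention: an
uncorrected voxel threshold `p < 0.001` plus a 26-connected cluster-extent
filter (default 10 voxels at desk scale). Direction is gated by the map's
contrast, so a `post<pre` map only reports decreases. Recovery is scored
with `dice_overlap()` against the injected ROI union.

Before any voxel-wise comparison, every image is globally scaled
(`global_scale()`) so its in-mask mean is a common constant (default 50, an
arbitrary SPM-like value — any positive target is equivalent under the
linear statistics). The default mask rule is the SPM convention, voxels
above one eighth of the whole-volume mean. For *generated* volumes this
rule fails on desk-scale grids: a tanh-output generator cannot produce
exact zeros, and the vast near-zero background floods a mean/8 mask and
explodes the scale factor. The experiment pipelines therefore compute the
global within the anatomy support mask (template density above
`stats$support_threshold`, default 0.05), which is also the analysis mask
of the t-maps.

The **covariate probe** (`predict_age_cv()`) checks that translation
preserves subject identity: PCA reduction with as many components as
training subjects (capped at matrix rank), ordinary least squares on the
scores, 5-fold cross-validation with both PCA and regression fitted per
training fold only. Predictions pre vs post transformation are compared
with a paired t-test and Cohen's d, and across iterated transformations
with a one-way ANOVA and partial eta-squared. The probe runs on
**unscaled** volumes: proportional global scaling would divide out the very
age gradient the probe is meant to detect. Two design points the source
conventions leave open, decided here: PCA is fitted per fold (the leaky
all-subjects variant would contaminate the out-of-fold error), and the
ANOVA is one-way between state labels (a repeated-measures variant would
need explicit subject blocking; with identical subjects per state the
one-way test is the conservative reading).

## The experiments

* `run_recovery()` — generate a cohort (30 + 30 at desk scale), train the
  model on the two groups, transform the healthy group, and test whether
  the paired `post<pre` t-map recovers the injected ROIs (Dice, in-ROI mean
  change) and whether age predictions survive translation.
* `run_comorbidity()` — apply a generator trained on dataset 1 to a second
  cohort carrying its own baseline effect in *different* regions. The
  paired comparison (baseline originals vs their virtual comorbid states)
  should land in the trained-effect regions regardless of the baseline;
  the two-sample comparison between the two virtual states should land in
  the baseline regions, which persist through translation.
* `run_progression()` — apply the generator 1..5 times; the suprathreshold
  extent against the originals should grow with iteration while the age
  ANOVA stays null.

Models for the simulation experiments are trained on all available phantom
data; cross-validation (`stratified_kfold_split()`, per-group folds of
near-equal size) is reserved for recovery-style validation. Each state
entering a comparison is globally scaled independently; no comparison mixes
scaled and unscaled states.

## Numerical choices and problem sizes

Desk-scale defaults: `32³` voxels at 1.5 mm, base 8 generator channels,
4 discriminator blocks, 12 training epochs over 30 volume pairs (one
alternating update per pair). These sizes make a full recovery experiment
— cohort, training, transformation, statistics, probe — run in a few
minutes on one CPU core while leaving the learned effect comfortably
detectable; the full-scale configuration mirroring a real study (crop
96×120×104 of a 121×145×121 map, 5 discriminator blocks) is expressible
with the same configuration objects. Epoch count and learning rate were
fixed by pilot runs during development; neither is stated by any reference
convention for this architecture.

Other conventions: discriminator scores are clamped to
`[1e-7, 1 − 1e-7]` inside the log-losses; instance normalization uses
eps 1e-5; max-pool ties resolve to the first-scanned voxel; the t-map
treats zero-variance voxels as undefined rather than zero; Dice of two
empty masks is 1 (agreement on "nothing"), and 0 when exactly one is
empty; cluster connectivity is 26 (3D SPM convention). Training aborts
with a diagnostic if any loss becomes non-finite.

## Known limitations

* The adversarial objective is a min-max game: convergence is not
  guaranteed, and at desk scale a small fraction of seeds can yield weaker
  localization (the acceptance properties are therefore stated over
  multiple seeds).
* The phantom's global, linear age effect makes age prediction far easier
  than brain-age estimation on real data; probe MAEs here say nothing
  about real-world accuracy.
* `data_max` is computed on the training cohorts; volumes with brighter
  voxels than any training volume are mapped slightly above 1 and rely on
  tanh saturation.
* Batch size is fixed at 1 (the standard cycle-consistent setting); there
  is no replay buffer and no identity-mapping loss by default, as neither
  is part of the core formulation here.
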