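---
title: "A convolutional surrogate for regional brain strain estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A convolutional surrogate for regional brain strain estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Finite-element head injury models convert a measured head impact into a
field of brain tissue strains, the quantity most directly implicated in
concussion.  A single impact takes on the order of an hour to simulate, which
rules the models out of any on-field or clinical use.  strainnet implements a
learned surrogate: a small convolutional network that maps a head
rotational-velocity time history directly to a scalar regional strain summary
in well under a millisecond, together with the complete experimental protocol
needed to train and evaluate such a surrogate — geometric data augmentation,
peak-aligned input encoding, cross-validation, and the statistics for
comparing cross-validated models.

Only rotational velocity is used: the contribution of linear acceleration to
brain strain is negligible, and angular velocity is the kinematic quantity
most predictive of strain.  The three channels are angular velocity (rad/s)
about the anatomical axes — `x` anterior, `y` left, `z` superior.

Three regression targets are supported, each at the 95th percentile over its
region: maximum principal strain of the whole brain (`MPS_WB_95`), maximum
principal strain of the corpus callosum (`MPS_CC_95`), and fiber strain —
stretch along white-matter tracts — of the corpus callosum (`FS_CC_95`).
One network is trained per target.

## Geometric augmentation

Measured impact datasets are small (tens to low hundreds of impacts), far
below what a convolutional network needs.  `augment_dataset()` expands a base
dataset by exploiting the geometry of rigid head rotation:

1. **Channel permutation.** The three velocity components are permuted into
   all `3! = 6` orderings (`xyz`, `xzy`, `yxz`, `yzx`, `zxy`, `zyx`).  Each
   permuted copy is a legitimate rotational motion with a different axis.
2. **Random rigid rotation.** Each copy is rotated about a random axis
   through the head's center of gravity (direction uniform on the unit
   sphere, angle uniform in 0–90°).  Uniformity is the least-informative
   choice where no distribution is prescribed.  Rotation never changes the
   resultant magnitude profile.
3. **Conjugate-axis folding.** The head is symmetric about the mid-sagittal
   plane, so a rotation axis `Ω(θ, α)` (azimuth `θ` from +x toward +y,
   elevation `α` toward +z, taken at the peak-resultant sample) and its
   conjugate `Ω″(180° − θ, −α)` produce mirror-image strain fields with
   identical scalar summaries.  Only the half-space `|θ| ≤ 90°` therefore
   needs sampling: any copy whose post-rotation axis falls outside it is
   replaced by its mirror image.  Because angular velocity is a pseudovector,
   the mirror image through the plane with normal `y` is
   `(wx, wy, wz) → (−wx, wy, −wz)`; this is the unique reflection whose
   peak axis is exactly the conjugate axis under the angle convention above,
   which is how the coordinate convention of the package was fixed.
4. **Magnitude scaling.** Each copy is rescaled so its peak resultant
   velocity falls uniformly in the open band (21.9, 40) rad/s — above the
   median concussive peak observed in football and below the 95th-percentile
   envelope — concentrating the training distribution on injury-relevant
   severities.  Bounds are strict on both sides.

Conjugation is applied after rotation and before scaling; scaling commutes
with reflection, so this ordering is a convention rather than a choice with
consequences.  One independent rotation and one scale are drawn per permuted
copy per batch.  A dataset of `n` impacts augmented with `k` batches yields
exactly `6nk` samples, each with full provenance (parent, permutation,
rotation axis/angle, mirroring flag, scale factor) recorded.

## Input encoding

`encode_profiles()` reformats every motion into a fixed 3 × 201 matrix:
201 samples at 1 ms spanning 0–200 ms.  One millisecond is the native
resolution of the pipeline; finer sampling adds no information the network
can use, and coarser sampling discards some.  All three channels are shifted
*synchronously* so the resultant peak lands exactly at 100 ms — peak strains
do not depend on when the motion happens, so pinning the peak removes
nuisance temporal variation and reduces the training data required.  The
borders are padded by replicating each channel's first/last recorded value,
i.e. with exactly zero angular acceleration, so the padding adds no spurious
motion.  A profile that cannot be placed without truncation (a recorded span
over 200 ms, or a peak so late that samples would spill past the window) is
rejected rather than truncated.  No normalization is applied: the network
consumes raw rad/s values.

## Network and training

The architecture (`cnn_spec()`) is a three-layer valid-padded convolutional
stack — 32 filters per layer with kernels 3 × 10, 1 × 10, 1 × 5 and strides
1 × 2, 1 × 2, 1 × 1 — followed by flatten, dropout 0.2, and two fully
connected layers (64, then 1).  The first kernel spans all three channel
rows, collapsing the channel axis immediately; each later kernel spans all 32
feature channels and slides along time.  On the 3 × 201 input the feature
maps are 1 × 96, 1 × 44 and 1 × 40 (32 channels each), so the flattened
width is 1280 and the network has 98,465 parameters.  Rectified linear
activations are used throughout *including the output*: strains are
non-negative, so the head's codomain matches the target's.

Training (`train_cnn()`) minimizes mean squared error with Adam
(β₁ = 0.9, β₂ = 0.999) over mini-batches of 64 for up to 250 epochs, with a
10% validation split, early stopping after 25 epochs without improvement,
and the best-validation weights restored.  Two numerical choices deserve
comment:

* **Learning rate (default 1e-3).** Adam's per-step parameter movement is
  bounded by the learning rate, so a run of `E` epochs with `B` batches per
  epoch can move each weight by at most about `E·B·lr`.  A configuration in
  the low thousands of updates therefore needs a rate on the order of 1e-3 —
  Adam's customary default — for the convolutional features to train at all;
  rates several orders smaller leave the network an essentially frozen
  random-feature model, which measurably caps accuracy well below what the
  trained network reaches.  The rate is exposed in `training_config()`.
* **Output-head initialization.** Hidden layers are Glorot-uniform.  The
  output layer starts at zero weights with its bias at the mean training
  label, so optimization starts from the best constant predictor.  This is
  not cosmetic: with a symmetric random initialization the ReLU output head
  can start with negative pre-activations on every sample, in which case its
  gradient is identically zero and training never moves — the classic dead
  output unit.  Starting at the label mean guarantees a live gradient.

Training runs in single precision (the deep-learning convention) in compiled
code; weights are stored and exchanged as doubles.  For a fixed seed, runs
are bit-reproducible on a given BLAS; across BLAS implementations the usual
floating-point caveats apply.

## Evaluation protocol

`kfold_cv()` implements repeated k-fold cross-validation: per trial, samples
are shuffled with the trial seed, split into `k` folds, and each fold is
predicted by a network trained on the other `k − 1`; the held-out
predictions are then pooled and scored once, giving one R² and RMSE per
trial.  Pooled scoring (rather than averaging per-fold scores) matches how a
single held-out test set would be scored.  Metrics are reported for the full
sample and for the within-range subset — impacts whose peak resultant lies
strictly inside (21.9, 40) rad/s — because the augmented training
distribution deliberately concentrates there.

Two significance tests accompany the protocol, both one-tailed at α = 0.05:

* `corrected_cv_ttest()` for comparing repeated-CV score vectors.  Repeated
  CV scores are positively correlated across trials because training sets
  overlap; the naive paired t-test therefore rejects far too often.  The
  corrected resampled t-test inflates the variance by the test/train size
  ratio ρ = 1/(k − 1): `t = d̄ / sqrt(s_d² (1/n + ρ))` with `n − 1` degrees
  of freedom.  Under a simulated null with exactly this correlation
  structure the corrected test holds close to the nominal level while the
  naive test rejects several times too often (verified in the test suite at
  2000 replicates).
* `welch_ttest()` for comparing independent score samples with unequal
  variances (Welch–Satterthwaite degrees of freedom); this delegates to
  `stats::t.test()`.  Degenerate zero-variance inputs return p = 0.5 when
  the means also agree.

## The synthetic generator and strain oracle

The packaged generator (`generate_profiles()`) emulates the features of
measured contact-sport impacts that matter for this pipeline: a raised
sin²-shaped resultant pulse lasting 10–60 ms with peak 5–40 rad/s along a
random direction, followed 30% of the time by a counter-rotating pulse at
40% amplitude (velocity reversal, the shape feature that distinguishes
on-field recordings from laboratory reconstructions).

The strain oracle (`oracle_strain()`) stands in for the finite-element
solver.  It is built to be what a head model looks like from the outside — a
smooth, nonlinear, saturating map from motion to strain:

```
eps = eps_max(measure) · H(p) · D(u) · S
H(p) = p^n / (p^n + v50^n)          (Hill saturation in peak velocity p)
D(u) = (1 + a·u²) / (1 + max(a))    (direction modulation, u at peak)
S    = 1 + b · min(1, TV / (2p))    (waveform total-variation term)
```

with defaults `eps_max` = 0.45/0.35/0.25 for the three measures, `v50` = 30
rad/s, `n` = 3, `b` = 0.3, per-measure direction weights `a` so the three
regression tasks differ, and optional Gaussian label noise (sd 0.005).
Only *squared* direction cosines enter `D`, so the oracle is exactly
invariant under mid-sagittal mirroring — the property the conjugate-axis
augmentation relies on — and `H` and `S` make it monotone in uniform
magnitude scaling.  The constants are artifact choices: the oracle makes no
claim of biofidelity, and labels are recomputed for every augmented motion
(as a solver would re-simulate it), not copied from the parent impact.

What passing tests on oracle-labelled data do show: the augmentation,
encoding, network and evaluation machinery can recover a smooth nonlinear
impact–strain map to high fidelity from realistic sample sizes.  What they
cannot show: performance on real measured impacts labelled by a real
finite-element model, whose strain surface is higher-dimensional and whose
measured kinematics carry sensor noise and richer temporal shapes than the
two-parameter pulse family here.

## Problem sizes used in the packaged runs

The packaged verification runs use 110 synthetic base impacts with two
augmentation batches (1320 samples) for the headline 10-fold
cross-validation — one trial, noiseless labels, whole-brain measure — and a
one-batch (660-sample) run on matched seeds for the sample-size
monotonicity check.  The band checks use 200 base impacts (2400 augmented
samples).  These sizes exercise every stage at the same per-sample scale as
a full study while keeping a complete run in the minutes range on a single
CPU.

## Known limitations

* The temporal-shape diversity of the synthetic pulses is narrow by
  construction; no temporal-shape augmentation is attempted (a parametric
  descriptor of rotational-velocity pulse shape is an open problem).
* The surrogate inherits whatever model generated its labels; a network
  trained on oracle labels estimates the oracle, not brain strain.
* Out-of-band impacts (peaks outside 21.9–40 rad/s) are extrapolations; the
  within-range partition exists precisely to keep reporting honest about
  this.
* One network per strain measure; no multi-output head.
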