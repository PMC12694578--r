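---
title: "Explainable 3D classification and atlas-based saliency analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable 3D classification and atlas-based saliency analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voxsal)
```

# The problem

Structural (T1-weighted) MRI carries subtle, distributed signatures of
early Parkinson's disease, but a 3D convolutional classifier that detects
them is opaque: a diagnosis score says nothing about *where* in the brain
the evidence sits. `voxsal` implements a complete, testable version of the
analysis chain that turns such a classifier into regional, statistical
statements: build a compact 3D residual network by inflating 2D kernels,
train it with k-fold cross-validation, attribute each held-out subject's
prediction to voxels with GradCAM, average the attribution over a
probabilistic atlas into per-area scores, and relate those scores across
areas (correlation networks, node scores) and to clinical metrics.

Because the imaging data this style of study uses is restricted-access, the
package ships a synthetic cohort generator that reproduces the *statistical
structure* the analysis assumes, so every stage runs and is tested end to
end with no download.

# The classifier

## Architecture

The model family is a 3D residual network: a 7×7×7 single-channel stem
convolution with stride 2, an optional 3×3×3 stride-2 max pool, stages of
basic residual blocks (two 3×3×3 convolutions, batch normalization after
every convolution, identity shortcuts, and strided 1×1×1 projection
shortcuts where shape changes), then spatial dropout, global average
pooling and a fully connected layer with one output per class
(CT, PD). Two reference variants matter:

* the truncated 12-learnable-layer variant — stages of (2, 2, 1) blocks at
  64/128/256 channels with a 256→2 head — has 4,711,746 trainable
  parameters (4.7M);
* the full 18-layer variant — (2, 2, 2, 2) blocks at 64/128/256/512 with a
  512→2 head — has 33,161,026 (33.2M).

Learnable layers follow the standard residual counting convention (stem +
two convolutions per block + the fully connected layer; projection
shortcuts excluded from the count, included in the parameter total).
Convolutions carry no bias because batch normalization follows each one;
that convention is what makes the two printed parameter totals come out
exactly. The stage layout (2, 2, 1) is the unique truncation of the
18-layer plan that simultaneously yields 12 learnable layers, a 256-wide
head and a 4.7M total, which is why the package fixes it.

## 2D→3D weight inflation

`inflate_2d_to_3d()` replicates a k×k 2D kernel at every one of k depth
slices, multiplying the parameter count by k. On a depth-constant input the
inflated layer responds with k times the 2D response; an optional 1/k
rescaling (`scale = TRUE`) preserves activation scale instead. Plain
replication is the default because it is the minimal reading of
"replicated"; the rescaled variant is kept behind the flag. No pretrained
2D weights ship with the package — the desk-scale default is Glorot
initialization everywhere, and `build_model(init = "inflated-from-2d")`
accepts user-supplied 2D kernel stacks.

## Training protocol

All training uses one fixed hyperparameter set: ADAM, mini-batch 10, 20
epochs, static learning rate 3×10⁻⁴, L2 regularization 5×10⁻⁴ (applied to
convolution and fully connected weights, not to normalization parameters or
biases), data reshuffled each epoch, and a learning-rate scalar of 5 on the
fully connected layer. Inputs are rescaled from [0, 255] to [0, 1]. Each
epoch every training volume is re-augmented with the harmonization chain:
Gaussian blur with sd ~ U(0, 1.5) voxels on a 16-voxel window, a 2%
intensity drop, and an additive per-voxel noise mask ~ U(0, 5). The chain
is implemented as one compound augmentation re-drawn per epoch;
`augment_reps` exposes the alternative reading in which multiple
independent draws of the chain each contribute a training sample.

Folds are class-stratified (sizes within one, class balance within one).
The stratification keeps the 50/50 case-control design intact at small n,
which a plain random split does not guarantee.

### Batch-norm recalibration

With mini-batches of 10 and augmented training inputs, the exponential
running moments that batch normalization accumulates are a poor estimate of
the statistics that clean evaluation inputs have; at desk scale the
mismatch compounds across layers and can push evaluation-mode predictions
to one class even when batch-statistics accuracy is high. After the last
epoch the package therefore recalibrates: one forward pass over the full,
un-augmented training set with momentum 1 and dropout off replaces the
running moments with exact population moments under the trained weights.
This is a post-training statistics refresh only; no parameter changes.

### Determinism

Every run is a pure function of its seed: initialization, shuffling,
dropout masks and augmentation draws all come from R's RNG seeded from the
training configuration, and the compiled kernels are deterministic. Two
runs on one machine give bit-identical loss traces.

# GradCAM saliency

For a class channel h, the designated layer is the output of the final
residual stage (the deepest spatial feature map, before dropout and
pooling). The channel weight is the spatial mean of the gradient of the
*pre-softmax class score* with respect to that layer, computed by
backpropagation through the head; the map is the half-rectified weighted
sum of feature maps, upsampled to the input grid. The score (not the
loss) is the gradient target because only that choice makes maps of
misclassified subjects mirror the predicted class; `grad_target = "loss"`
preserves the alternative. Rectification is applied once, to the weighted
sum — not to the weights.

Because the head is linear after global average pooling, the channel
weights have a closed form (the head weight row divided by the feature
voxel count), which the test suite uses both as an exactness check and as
the target of a finite-difference audit.

## Geometry of upsampling

A feature voxel at index i (0-based) of a network with cumulative stride s
(stem stride × pool × one stride-2 block per later stage) is centered at
input voxel s·i when every convolution uses centered odd kernels with
same-padding, as here. Upsampling therefore maps input voxel v to feature
coordinate v/s with trilinear interpolation and edge clamping. The
corner-aligned convention — mapping the *last* input voxel to the *last*
feature voxel — stretches the map by about 11% at 32³ over a stride-4
grid, which displaces saliency by several voxels at the far corner and
measurably corrupts per-area scores; the package deliberately does not use
it for saliency (a generic corner-aligned kernel remains available).

## Per-map normalization

Whether to rescale each subject's map before atlasing is a genuine design
choice, and the package resolves it per analysis rather than globally:

* **Group profiles and cross-area correlation** (class/lobe profiles,
  pairwise Kendall, node scores, network contrasts) use maps divided by
  their own mean over the brain mask. Subjects and folds then contribute
  on a common scale, regional means sit near 1, and the correlation
  structure reflects *relative* regional co-variation rather than each
  subject's overall evidence magnitude.
* **Clinical associations** use raw maps. Dividing by the map mean turns
  regional scores into shares of a fixed budget: when a more severe
  subject's evidence concentrates in the model's preferred regions, every
  other region's share mechanically falls, which can flip the sign of a
  genuine saliency–severity relation. The subject-level evidence
  magnitude is precisely the quantity a clinical association asks about,
  so it must not be normalized away.

Both conventions are exposed (`normalize` in [holdout_maps()],
`normalize_map()` applied on demand), and the association stage of the
workflow consumes the raw regional matrix while the profile and
correlation stages consume the normalized one.

Each subject's map comes from the model of the fold where the subject was
held out, on the channel of the subject's *predicted* class. Misclassified
subjects thus carry wrong-channel maps, which is exactly why the analysis
stage excludes them.

# Parcellation

A regional score is the probability-weighted average of the map over an
area: Σ p·M / Σ p. Dividing by the area's total probability mass is the
only normalization under which a constant map scores that constant in
every area, which pins the convention down. Areas are scored independently
and may overlap (probabilistic atlas semantics); areas with zero mass score
NA with a warning; a grid mismatch between map and atlas is an error rather
than a resample, because the pipeline assumes co-registered inputs.

Lobe profiles average member areas per subject without probability
weighting, then summarize per class as mean ± 1.96·SEM. All 95% intervals
in the package are the normal approximation; this is a uniform choice made
once, since the upstream convention is unstated.

# Group statistics

* **Exclusion rule** — subjects whose prediction disagrees with their label
  are excluded from all group analyses, symmetrically for both classes.
* **Inter-fold regression** — ordinary least squares of fold-j mean area
  saliency on fold-i means for every unordered pair, using each fold's test
  subjects; slope near 1 and intercept near 0 indicate the folds learned
  similar regional representations.
* **Pairwise Kendall correlation** — tau-b (tie-corrected) for every area
  pair over retained PD subjects. P-values use the exact permutation null
  (via the inversion-count distribution) for untied samples with n ≤ 10 and
  the tie-corrected normal approximation otherwise. Significance filtering
  happens downstream at raw p < 0.05; no multiple-testing correction by
  default, to reproduce the reference procedure, with a Benjamini–Hochberg
  flag available.
* **Node score** — the signed sum of an area's significant correlations
  with all other areas; a centrality proxy over the saliency network.
* **Network contrast** — per network, the mean correlation of member areas
  with other members (intra) versus with all areas (brain-wide), each ±
  1.96·SEM across members. Signed tau over all pairs is the default;
  absolute-value and significant-only variants cover the ambiguous
  readings.
* **Clinical associations** — Pearson (t-test p, n−2 df) and Kendall
  correlation of each area's saliency with UPDRS-P3, MoCA, LEDD and
  years-since-onset over retained PD subjects, pairwise-complete, LEDD
  restricted to medicated subjects; plus the metric-by-metric pairwise
  table overall and split by medication status.

# The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
not anatomy:

* **Atlas** — Gaussian-blob probability fields placed as mirrored
  left/right pairs (centers snapped to voxels; mirrored pairs share a
  width; an odd leftover area sits midline), renormalized per voxel where
  the stacked sum exceeds 1. Mirroring guarantees homologous lobes in both
  hemispheres, as in a real bilateral parcellation. Lobes rotate over
  pairs, networks rotate over areas.
* **Volumes** — a shared smooth template plus subject-specific smooth
  texture, intensities in [0, 255] like rescaled preprocessed MRI. For PD
  subjects each effect area a is darkened by δ·(s + f_net(a) + ε)·p_a(v),
  with latent severity s log-normal (median 1 by default — severity is
  positive and right-skewed, like early-disease cohorts skewed to less
  severe symptoms), a per-network factor f (sd 0.3) inducing
  within-network correlation, and per-area jitter ε (sd 0.1). Every volume
  is then blurred (sd ~ U(0, 1.5) voxels) and gets uniform noise with a
  per-volume amplitude ~ U(2, 8), emulating heterogeneous scan quality;
  the heterogeneity ranges are free parameters of the emulation, set once
  to plausible values since no quantitative reference exists.
* **Clinical scores** — PD only (association analyses run across the PD
  cohort): UPDRS-P3 = 20·s + N(0, 5) floored at 0; MoCA = 28 − 2·s −
  N(0, 1.5) clamped to [0, 30]; years-since-onset = 2.3·s + N(0, 0.8);
  LEDD = 250 + 200·s + N(0, 60) for the medicated fraction (0.36 by
  default, the reference cohort's rate). A configurable fraction (10%) of
  UPDRS/MoCA values is set missing, mirroring per-metric n that varies in
  real tables. Controls carry no clinical scores.

Everything is a pure function of (specification, seed).

What passing tests on this generator do **not** show: recovery on real
MRI. The phantoms have no anatomy, no registration error, no scanner/site
batch structure beyond blur/noise amplitude, and the planted effect is an
additive intensity change — real atrophy moves boundaries rather than
darkening tissue. The generator validates the *pipeline logic and
statistics*, not the clinical claim.

# Desk-scale recovery settings

The end-to-end recovery study (`run_recovery()`) uses a 60-subject cohort
(30 per class) on a 32³ grid with a 40-area, 8-network atlas (blob sd
1.8–2.6 voxels, centers ≥ 6 voxels apart), the planted effect on every
area of the first network, and 4-fold training at the fixed
hyperparameters. These sizes keep a full five-seed replication on one CPU
within a coffee break while leaving the planted effect detectable.

The classifier for this setting is a reduced-width member of the same
family: stem of 6 channels (kernel 7, stride 2), no stem pool, stages
(1, 6), (1, 12), spatial dropout 0.2. Two of those choices deserve
comment. Dropping the stem pool keeps the designated GradCAM layer at 8³
on 32³ inputs — at 4³ the attribution cannot separate neighboring areas.
The dropout probability is 0.2 rather than the full model's 0.4 because
channel dropout scales badly to very narrow heads: at 12 channels, p = 0.4
silences five expected feature maps per sample, and at this width that
stalled optimization entirely in most seeds. The printed optimizer
settings are used unchanged.

## What the recovery study can and cannot show

`run_recovery()` checks four things per seed: held-out accuracy, whether
*every* planted area reaches the top 20% of the PD-class mean profile,
whether the pooled raw saliency over planted areas associates positively
and significantly with the UPDRS analogue, and whether the planted
network's intra-network correlation exceeds its brain-wide correlation.
The first and last are robust at this scale. The two per-area criteria
are not, for reasons that are properties of the method rather than bugs:
a cross-entropy-trained classifier needs only *sufficient* evidence, so
individually redundant planted areas (their effects share one latent
severity) can legitimately receive weak saliency; and with roughly 26
retained PD subjects, a true saliency–severity correlation of about 0.4
is detected at p < 0.05 only about half the time. The sign of the pooled
association and the elevation of most planted areas are the reliable
desk-scale signatures; demanding every area, every seed, exceeds the
information the 60-subject design carries.

# Known limitations

* The convolution engine is written for clarity and desk-scale volumes
  (vol2col + GEMM in double precision); it is not a GPU framework and full
  224³ training, while expressible, is not practical in it.
* GradCAM at a coarse feature grid attributes evidence at the resolution
  of that grid; areas closer together than the cumulative stride share
  saliency. A classifier needs only sufficient evidence, so planted areas
  that are individually redundant for the decision can receive weak
  saliency — regional rankings from small models are noisy even when group
  profiles are clearly elevated.
* Exact Kendall p-values are enumerated only for untied n ≤ 10; larger or
  tied samples use the tie-corrected normal approximation.
* The normal-approximation 95% intervals are used throughout for
  comparability, including at small k (4 folds), where they are rough.
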