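---
title: "Hierarchical attention MIL for multi-modal brain MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical attention MIL for multi-modal brain MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Predicting a glioma's genotype (for example IDH-mutant versus IDH-wild)
from structural MRI is a weakly supervised problem: the label is known per
subject, but nobody annotates which part of the volume carries it. habmil
casts each subject's co-registered T1w/T2w/FLAIR volume as a *bag* of
spatial *instances* under the classic multiple-instance-learning (MIL)
assumption: a bag is positive iff at least one instance is positive
(`bag_label_rule()`).

The pipeline has four stages:

1. **Instance encoder.** A small 3-D fully convolutional network
   (3×3×3 kernels; each stage is convolution → batch normalization → ReLU
   → max pooling → dropout) followed by a 1×1×1 projection to the
   embedding dimension D and an adaptive max pooling to an exact instance
   grid H\*×W\*×S\*. The reference-scale configuration
   (`reference_encoder_config()`) maps a 240×240×155 input to a 2×2×2×64 grid;
   each of the N = 8 grid cells is one instance.
2. **Collateral location encoding (CLE).** Instance-cell centers
   p = (x, y, z) ∈ [0,1]³ pass through a learnable two-layer GELU network
   F̂(p) = a₂·GELU(a₁p + b₁) + b₂; instance features and position features
   are each standardized and concatenated, H′ = [std(F) ‖ std(F̂)]; an
   importance attention A = softmax(H′w + b) over instances (so ΣA = 1)
   rescales the fused rows, O = H′ ⊙ A. Comparators: `spe` (fixed
   sinusoidal features, fused the same way), `npe` (the GELU network
   without the importance weighting), `none`.
3. **Dynamic gated attention (DGA) pooling.** Two per-instance signals are
   combined: a Tanh attention branch (affine → tanh → dropout → affine →
   tanh, values in (−1,1), carrying signed evidence) and a sigmoid gate
   from the **learnable SVD (LSVD)** layer: α = softmax-rows(XWₐ + bₐ),
   Â = α·diag(σ)·αᵀ with a trainable diagonal σ, gate =
   sigmoid(rowmean(Â)). The final weights are
   aₙ = softmax(Linear(a_LSVD·a_Tanh)) and the bag embedding is
   z = Σₙ aₙ·hₙ. Baselines: coordinate-wise max, mean, and plain
   attention (the Tanh branch alone — exactly DGA with its gate clamped
   to 1).
4. **Bag head.** An affine map plus sigmoid gives the bag probability;
   the decision threshold is fixed at 0.5 and never tuned on test data.

Training minimizes mean binary cross-entropy over bags with Adam
(defaults: learning rate 1e-4, weight decay 1e-5, 100 epochs, batch
size 2). All layers — including every backward pass — are implemented in
base R on BLAS matrix products; the test suite verifies each configuration
against central finite differences.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `stage_channels` | 32, 64, 64 (reference scale) | encoder capacity; first stage fixed at 32 channels |
| `embed_dim` (D) | 64 (reference), 32 (desk) | instance embedding width |
| `target_instance_grid` | 2×2×2 | instances per bag (N = 8) |
| `d_pos` / `pos_hidden` | 16 / 32 | positional-encoding width; kept small relative to D so position augments rather than dominates |
| `lsvd_rank` (r) | 4 | latent components of the gate; must satisfy r ≤ min(N, d) |
| `att_hidden` | 32 | Tanh-branch hidden width |
| `att_dropout` | 0.25 | dropout in encoder stages and the Tanh branch |
| `learning_rate` / `weight_decay` | 1e-4 / 1e-5 | Adam protocol defaults |
| `epochs` / `batch_size` | 100 / 2 | protocol defaults |

The desk-scale encoder (`desk_encoder_config()`) is a single stride-2
convolution stage with 16 channels. Its receptive field — 5 input
voxels — is a deliberate choice, not merely a speed one: it is wide
enough to detect a cross-sequence lesion conjunction locally, but too
narrow to reach the volume border from any interior lesion. During
development we measured that a deeper desk encoder (receptive field ≈ 17
voxels) let a *position-encoding-free* model solve the location-only
octant task through border-clipped convolution responses, which are a
permutation-invariant position signature; the shallow encoder removes
that covert channel so positional information can enter only through the
location encoding, which is precisely what the octant experiment is
meant to isolate.

## The synthetic phantom cohorts

No MRI data ships with the package; `generate_cohort()` builds NIfTI
phantom cohorts with known lesion masks:

- **Background:** constant base intensity plus white Gaussian noise
  (sd 0.5 on contrast units), per modality. No anatomy, bias fields or
  partial-volume effects — the classification signal is attributable
  solely to the implanted lesions.
- **Lesions:** axis-aligned ellipsoids (radii 10–18% of the grid per
  axis) with a sigmoid-smoothed boundary. A *positive* lesion is bright
  in T1w, T2w and FLAIR at one location (contrasts 1, 2, 3), like the
  cross-sequence conjunction a glioma presents.
- **Presence rule:** positives carry one positive lesion (plus,
  with probability ½, a partial distractor); negatives carry a spatially
  separated complementary pair — a T1w/T2w-only lesion and a FLAIR-only
  lesion — whose summed contrast equals one positive lesion. Global
  per-modality statistics therefore match across classes and only the
  instance-level co-location of sequences carries the label; a bag-mean
  shortcut cannot solve the task, which is what makes attention
  localization meaningfully testable. The pair is kept farther apart
  than the encoder's receptive field and in different instance cells.
- **Octant rule:** every subject carries one positive lesion; the label
  is 1 iff its center lies in the all-upper-half octant. Lesions are
  fully contained in their octant (no boundary straddling) and their
  smoothed profile stays clear of the volume border, so spatial position
  is the *only* informative signal.

What passing on these phantoms shows: the architecture can recover an
instance-level conjunction rule from bag labels, its attention
concentrates on the responsible instance, and the location encoding adds
exactly the positional information the backbone lacks. What it does not
show: robustness to anatomy, registration error, scanner effects or
class imbalance of real cohorts — those claims would need real data.

## Numerical and design choices

- **Normalization in the fusion step.** The two fused blocks are
  standardized *per instance across features* (epsilon-guarded). We
  first implemented the other natural reading — per feature across the
  bag's instances — and rejected it after measurement: bag-wide
  standardization leaks global bag statistics into every instance, so a
  trained model could classify perfectly while attending to an arbitrary
  cell, which defeats the MIL semantics and empties the key-patch
  interpretation. Per-instance normalization keeps the blocks
  scale-commensurate without coupling instances.
- **Batch normalization** is computed per volume over spatial voxels
  (one volume per forward pass; running statistics for evaluation).
  At evaluation time the statistics are frozen, so instances are not
  coupled through them.
- **Softmax axes.** LSVD factors are normalized rowwise (each instance's
  mixture over r components sums to 1); importance and attention weights
  are normalized over instances (they are comparisons between
  instances). Ties in key-patch weights break by instance index.
- **The LSVD layer is SVD-shaped, not an SVD.** Softmax rows cannot be
  orthonormal, so the exact decomposition serves as motivation and as a
  test oracle: the Frobenius error of the rank-r truncated SVD
  (Eckart–Young) is an unbeatable lower bound, asserted on every
  `fit_to_matrix()` run. Empirically the softmax-constrained factors
  plateau some tens of percent above that bound on random symmetric
  targets — a genuine expressiveness limit of row-stochastic factors
  (multi-restart probes with a direct logit parametrization reach the
  same plateau), not an optimization defect. `fit_to_matrix()` supports
  restarts because the loss surface is nonconvex.
- **Gate reduction.** The N×N reconstruction Â is reduced to one scalar
  per instance by its row mean (an instance's learned affinity mass),
  then a sigmoid. Clamping the gate to 1 reproduces the plain attention
  baseline exactly; this degenerate case is asserted numerically.
- **Tanh branch range.** The final scalar score is wrapped in a tanh so
  the branch stays in (−1,1) — signed evidence for the gate product.
- **Grad-CAM variant.** The default saliency is the elementwise
  gradient×activation sum over channels. The classic channel-mean
  weighting is available (`method = "channel"`) but under max pooling
  the spatially averaged gradients cancel almost exactly and the classic
  map is uninformative; the elementwise variant stays faithful to the
  max-pooled computation graph.
- **Degenerate inputs.** All-zero modalities skip the z-score with a
  warning; flat saliency maps min-max-scale to zero; probabilities are
  epsilon-clamped in the loss; single-class test sets flag AUC as NA.
- **Determinism.** Every stochastic step (phantom sampling, splits,
  initialization, shuffling, dropout, augmentation) derives from one
  seed; identical configuration and seed reproduce identical cohorts,
  models and metrics.

## Desk-scale experimental protocol

The bundled experiments run on 48×48×32 grids: a presence cohort of
40 + 40 subjects (20 epochs) and an octant cohort of 30 + 30 subjects
(30 epochs), five repeats each, Adam at 3e-3 for the small single-stage
network, subject-level 60/20/20 splits with the best-validation-AUC
checkpoint. These sizes keep a full repeat-5 experiment in a few minutes
of CPU time while leaving every structural property of the reference-scale
setup intact (three modalities, 8 instances, the same pooling and
encoding machinery). The reference-scale configuration is exercised as a
forward-pass shape contract (240×240×155 → 2×2×2×64).

## Known limitations

- The phantom generator emulates bag structure, not MRI physics; results
  on it are architectural sanity checks, not clinical evidence.
- With N = 8 instances the LSVD rank is effectively capped at 4; larger
  instance grids would allow richer affinity structure.
- The pure-R engine is single-volume (batching accumulates gradients
  sequentially); it is CPU-practical at desk scale and forward-only
  practical at reference scale, not a GPU training stack.
- Attention localization is identifiable only when the task cannot be
  solved by bag-global statistics; on tasks with globally separable
  classes the attention map may legitimately stay diffuse.
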