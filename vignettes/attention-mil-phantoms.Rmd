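---
title: "Attention-based multi-instance learning on FDG-PET phantom cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multi-instance learning on FDG-PET phantom cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Autoimmune encephalitis (AE) produces subtype-specific patterns of regional
glucose hypo- and hypermetabolism on brain FDG-PET: broadly, medial temporal
lobe (MTL) and basal ganglia (BG) involvement, with occipital hypometabolism
in anti-NMDA-receptor disease and right-lateralized MTL hypometabolism in
anti-GAD65 disease. Diagnostic labels exist per patient, not per image
slice, so supervised slice-level training is impossible. `petmil` treats
each subject's volume as a *bag* of K = 79 axial slices (multi-instance
learning): a convolutional encoder maps every slice to a 512-dimensional
instance embedding $h_i$, clinical covariates (age, sex) are optionally
fused into each embedding, and a learned attention mechanism pools the bag,

$$a_i = \frac{\exp\{w^\top \tanh(V h_i)\}}{\sum_{j=1}^{K} \exp\{w^\top \tanh(V h_j)\}},
\qquad s = \sum_{i=1}^K a_i\, h_i ,$$

followed by a sigmoid head on $s$ for the AE-versus-control decision. The
attention weights form a probability simplex over slices; exported as a
patients-by-slices heatmap they show *which* slices drove each decision. A
second, four-way softmax head performs subtype classification after
*attention gating*: the top-r fraction of slices by attention weight
(default r = 0.2, at least one slice) is re-pooled with renormalized
weights and classified. Training uses bag labels only — weighted binary
cross-entropy for the diagnosis stage and weighted cross-entropy for the
subtype stage — with Adam and inverse-frequency class weights.

Two deliberate readings of under-specified design points are worth naming.
First, the attention score inserts a trainable projection $V$ (hidden size
L = 128) before the tanh, with the projection-free variant ($V = I$)
available via `identity_V`; the score formula above is otherwise literal.
Second, "a layer with higher attention weights" feeding the multiclass
stage is read as top-r instance selection with renormalization; `top_r` is
configuration, and `top_r = 1` reduces exactly to pooling over all slices.
This is the single most interpretive decision in the package.

## The phantom cohort generator

No patient data ship with (or are reachable by) this package; the generator
is first-class code that emulates the study conditions instead. A smooth
brain-shaped ellipsoid with a brighter cortical rim on the fixed
79 x 95 x 79 grid (2 mm voxels) serves as the baseline uptake field.
Ellipsoidal region templates — bilateral MTL (inferior-middle slices),
bilateral BG (middle slices), occipital cortex (posterior) — carry
multiplicative class signatures:

| class | MTL left | MTL right | BG | occipital |
|-------|----------|-----------|----|-----------|
| NMDAR | 0.7 | 0.7 | 1.4 | 0.7 |
| LGI1  | 1.4 | 1.4 | 1.4 | 1 |
| GABAB | 0.7 | 0.7 | 1.4 | 1 |
| GAD65 | 1 | 0.7 | 1 | 1 |
| HC / DC | 1 | 1 | 1 | 1 |

Hypo/hyper factors default to 0.7/1.4 — strong enough for desk-scale
training to succeed and configurable for difficulty sweeps; they are free
parameters of the phantom, not estimates of the clinical effect sizes,
which no quantitative source pins down. Disease controls (DC) receive a
small global multiplicative jitter (SD 0.05) instead of a regional pattern.
Rendering composes baseline x regional factors, then per-site scanner gain
and offset, then additive Gaussian noise, clipped at zero, all
deterministic per subject seed. The default noise level sets the
within-region voxel SNR of the weaker (hypometabolic) MTL effect to about
2 before smoothing. Covariates follow the cohort demographics the design
targets: AE ages ~ Normal(48.51, 16.21), HC ~ Normal(49.43, 10.04),
DC ~ Normal(42.96, 19.31), truncated to [6, 85], with male fractions
0.60/0.63/0.46. "External" sites draw gain ~ Uniform(0.9, 1.1) and offset
~ Uniform(+/- 5% of the in-brain baseline mean), emulating a multi-center
external validation without modeling scanners.

What the phantom does *not* emulate: anatomy beyond an ellipsoid, scanner
point-spread and partial-volume effects, tracer kinetics, age-related
atrophy, or any correlation between covariates and image signal. Passing
tests therefore demonstrate that the method recovers planted, spatially
structured signal under noise and site shift at desk scale — not clinical
performance.

## Preprocessing

Volumes are smoothed in 3D with an 8-mm FWHM Gaussian
($\sigma_{vox} = \mathrm{FWHM} / (2\sqrt{2\ln 2}) / 2\,\mathrm{mm} \approx 1.699$),
separable implementation, sampled kernel truncated at $4\sigma$ and
normalized to unit sum, reflect boundaries. Each of the 79 axial planes is
then resized bilinearly (no anti-aliasing) and intensity-standardized.
Standardization is proportional scaling by default, and two choices here
were made deliberately after observing their failure modes:

* **Scaling target.** Dividing by the whole-volume mean lets regional
  hypometabolism depress the denominator, imprinting a *global* class
  signal on every slice — the classifier then succeeds while attention has
  nothing regional to find. The pipeline therefore scales by the mean over
  a *reference region* (brain minus all atlas regions), the phantom
  analogue of pons/cerebellar reference normalization in clinical FDG-PET.
  Whole-volume scaling (`norm_mask = NULL`) and per-slice z-scoring
  (`standardize = "zscore"`, zero-variance slices mapping to zeros) remain
  available.
* **Reference-image centering.** All subjects share the same baseline
  anatomy, so raw slice intensities are dominated by a common component
  that dwarfs between-subject variation and stalls stochastic-gradient
  training (a convex solver separates the same features easily — the
  problem is conditioning, not information). `reference_image()` averages
  the training-split bags per slice index and `center_bags()` subtracts it
  everywhere, so the model sees deviation images — the analogue of
  normal-database comparison in clinical PET reading. The reference is
  computed from the training split only and reused unchanged for
  validation and external data.

## Encoder, fusion, and normalization

The trainable backbone is deliberately small (four 3x3 convolution blocks
with channels 8-16-32-32, three 2x2 average poolings, 32x32 inputs): an
ImageNet-scale ResNet18 at 224x224 over 79 slices per subject is not a
desk-scale CPU job, and nothing in the method depends on backbone
capacity. A ResNet18-style residual backbone (7x7 stem, four stages of
basic blocks, 224x224 inputs) is included and shape-compatible for
inference, so the full-size configuration can be exercised; it is not used
in training runs. In both, the final *global* average pooling is replaced
by default with a 2x2 *local* average pooling (window boundaries at
`floor(n*i/2)`) followed by a linear map to the embedding dimension — a
single global average washes out focal regional abnormalities, which are
exactly the signal of interest.

Normalization inside the encoder is *instance normalization* (per slice,
per channel, over space). Batch-style normalization over the bag's slices
was rejected after it demonstrably leaked bag-level class statistics into
every instance embedding: classification stayed perfect while the
attention anti-localized, because every slice carried the bag's class
signature through the shared statistics. Instance normalization is
slice-pure — each embedding depends only on its own slice and the weights —
which keeps the heatmap an honest record of where the evidence lies.
Convolutions directly followed by a normalization layer carry no bias term.

Clinical fusion one-hot encodes sex (2) and age (10-year bins, edges
0-90, half-open `[lo, hi)`), compresses the image embedding 512 -> 128,
concatenates the 11-dimensional clinical block, and expands back to 512
with a ReLU — compressing first redresses the dimensional imbalance between
the image and clinical blocks. The same clinical vector is appended to
every slice, and the fused embedding dimension equals the unfused one, so
the attention head is modality-agnostic and the single-modal MIL arm is
just `enabled = FALSE`. Whether age should be binned or continuous is not
externally fixed; binning is the default and the bin edges are
configuration.

## Training and numerical choices

Adam (lr 1e-3, betas 0.9/0.999), minibatches of 4 bags with averaged
gradients, global gradient-norm clip at 5, inverse-frequency class
weights, decision threshold 0.5 (all ROC metrics are threshold-free).
Softmax scores are stabilized by max subtraction; the binary loss uses the
softplus form of cross-entropy. The reference study sizes are 8 epochs for
the diagnosis stage and 5-6 for the subtype stage — on the phantom
difficulty the loss reaches ~1e-5 within 4 epochs, and the extra epochs are
margin. All randomness (cohort, weights, shuffling) descends from explicit
seeds; two runs under one master seed agree bitwise. Degenerate cases are
defined, not special-cased at call sites: empty bags error; single-class
training sets error; zero-variance slices standardize to zeros; precision
and F1 are 0 when there are no positive predictions; AUC with single-class
truth is `NA`, never 0.5. Backpropagation through every layer (convolution,
instance norm, pooling, fusion, attention with top-r gating, both heads) is
hand-derived and checked against central finite differences in the test
suite.

The classical comparison arms consume mean-pooled instance embeddings from
the trained multimodal encoder (optionally with the clinical one-hot block
appended). What classical baselines should consume is itself a design
decision — the package picks the canonical attention-free MIL reduction,
a stand-in rather than a reproduction of any particular study's feature
set, which isolates the value of attention pooling while sharing
byte-identical splits and metric code with the MIL arms. Logistic regression is ridge
(fixed lambda 0.01, no CV, for determinism); the random forest uses 500
trees.

## The reference studies and what the numbers mean

The package's acceptance studies, regenerated by `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R` from scratch at fixed conditions:

* **Diagnosis study** — 160 subjects (20 per AE subtype, 52 HC, 28 DC),
  internal site with 75% of subjects split 70/30 into training and internal
  validation (stratified by class), one shifted external site with 25%.
  Internal-validation ACC and AUC of the m-MIL arm are the headline
  figures; external ACC is compared directionally against internal
  (the site shift survives preprocessing by design — see the scaling-target
  note above).
* **Localization** — over positive internal-validation bags, the mean
  summed attention on slices intersecting the planted regions is compared
  to the uniform expectation (signal slices / 79), and the fraction of bags
  whose highest-attention slice falls inside the recorded region slice
  ranges.
* **Subtyping study** — 40 bags per AE subtype plus 40 HC and 20 DC (the
  controls exist because the subtype head is trained on top of a
  binary-trained model, mirroring the two-stage design), one site, 70/30;
  macro accuracy over the four subtypes on internal validation.

Axial convention, fixed for heatmap comparability: the slice axis is the
third array axis, slice 0 is most inferior, and all slice ranges are
0-based inclusive.

## Known limitations

The phantom's geometric simplicity makes the planted task easier than
clinical reality; the backbone used in training runs is far smaller than
ResNet18; site shift is a two-parameter affine model; attention-gated
subtyping inherits whatever the binary stage's attention missed; and the
baselines' input representation is a package decision, not a reproduction.
None of the numbers produced here are comparable to performance on real
patient cohorts.
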