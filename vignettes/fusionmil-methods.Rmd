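---
title: "Methods: weakly supervised fusion prediction from whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised fusion prediction from whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ROS1, ALK and NTRK gene fusions are rare, actionable drivers in non-small
cell lung cancer: each produces a constitutively active kinase, each has an
approved targeted therapy, and each occurs in only roughly 1–3% of
patients. Confirmatory molecular testing (FISH, IHC, RNA sequencing) is
accurate but expensive and tissue-consuming, so a cheap pre-screen that
ranks routine H&E slides by fusion likelihood has direct clinical value:
cases the screen confidently calls negative can be deprioritized for
confirmatory testing, while likely positives are fast-tracked.

The obstacle is supervision. A whole-slide image is gigapixel-sized, only a
slide-level label ("this patient's tumor harbors an ALK fusion") is
available, and the morphological correlate of a fusion — if present at all —
occupies an unknown subset of the tissue. This is the classic multiple
instance learning (MIL) setting: a slide is a *bag* of tile *instances*,
labels exist only at bag level, and the model must both locate and use the
informative instances.

`fusionmil` implements the full pipeline at desk scale: tissue masking and
tiling, self-supervised contrastive pretraining of a tile encoder,
transformer aggregation of tile-feature bags, a two-step composite-label
training strategy for rare targets, screening-oriented evaluation, and
attention-rollout interpretability — plus a synthetic data generator that
makes every stage testable without clinical images.

## Pipeline and model

### Tissue masking and tiling

A low-resolution thumbnail is filtered by a sequence of stages that refine
one shared binary mask:

1. **Sharpness** (`blur_mask`): keep pixels whose Gaussian-smoothed
   Laplacian magnitude reaches a threshold; out-of-focus patches and flat
   background fail it.
2. **Texture** (`flat_mask`): drop pixels whose local RMS deviation from
   the window mean is small (uniform background).
3. **Morphology** (`refine_mask`): remove connected components below a
   minimum size, fill enclosed holes below a maximum size.
4. **Artifacts** (`remove_fat_and_dark`): remove enclosed near-white
   regions (fat-like low-density areas) and near-black, highly rectangular
   regions (printed slide labels), each with a small dilation margin.
5. **Edge trim**: a final one-pixel erosion strips the high-gradient
   transition halo along tissue–background boundaries that the sharpness
   filter would otherwise keep.

Non-overlapping 224-px tiles (at the working magnification, nominally 10x)
are emitted wherever the mask covers at least `coverage_min` (default 0.5)
of the tile footprint; coverage is computed exactly from the mask geometry
with fractional edge-pixel weights.

Numerical choices worth stating: the sharpness and texture thresholds are
fractions (defaults 0.09 and 0.03) of the thumbnail's dynamic range, which
makes the chain invariant to overall brightness; the dynamic range has a
floor of 0.5 so a blank slide's sensor noise is never promoted to
"texture". No stage parameter comes from a published value — none were
published — so all of them live in `mask_config()`. Coordinates are 0-based,
x right / y down, with half-open tile footprints.

### Tile encoder

The tile encoder is a small vision transformer trained with a dual-encoder
momentum-contrast objective. Two augmented crops of the same tile form a
positive pair; the query encoder is trained by gradient descent on the
InfoNCE loss with in-batch negatives

$$\mathcal{L} = -\frac{1}{B}\sum_i \log
  \frac{\exp(q_i \cdot k_i / \tau)}{\sum_j \exp(q_i \cdot k_j / \tau)},$$

while the key encoder never receives gradients and instead tracks the
query through momentum updates $k \leftarrow m\,k + (1-m)\,q$ (default
$m = 0.99$, $\tau = 0.2$). Features (default 384-d) are taken from the
query encoder, unnormalized, and stacked into an `n_tiles x d` FeatureBag
per slide. In-batch negatives (no memory queue) and a single output head
keep the implementation faithful to the modern momentum-contrast design
while staying small; both hyperparameters are config, not claims.

### MIL aggregator

The aggregator projects each tile vector to `d_model` (default 512),
prepends a learned CLS token, runs the token set through `n_layers = 2`
pre-norm transformer encoder layers with `n_heads = 8`, and maps the final
CLS embedding through a one-hidden-layer MLP to a single logit.

Two deliberate design points:

* **No positional encodings.** A bag is an unordered set; the slide logit
  is exactly permutation invariant.
* **The CLS token is a pure readout query.** It is excluded from every
  attention key/value set (its column of each attention matrix is zero).
  With the CLS token competing as a key, duplicating every tile changes
  the softmax renormalization against the CLS self-key and therefore the
  logit — the bag model would not be an exact set function. Masking the
  CLS key restores exact duplication and permutation invariance while
  keeping the `(n_tiles+1) x (n_tiles+1)` row-stochastic attention
  matrices that rollout needs.

Per-tile classification scores are produced by the singleton-bag pathway:
tile *i*'s score is the model's output on the bag containing only tile
*i*. The alternative reading — bypassing the transformer and applying only
projection and head — was rejected because it scores tiles with a pathway
never used at training time; the singleton-bag pathway is at least the
model's own prediction for a slide consisting of that tile.

### Cohorts, labels, and the two-step strategy

The composite **RAN** label is positive if a sample carries any ROS1, ALK
or NTRK fusion; since positives are mutually exclusive in practice, RAN
positives are the sum of the three marginal counts. Pooling is justified
biologically — the three fusion proteins activate overlapping oncogenic
signaling pathways — and practically: it multiplies the positive count for
the first training stage roughly fourfold.

The experimental design: 15% of slides are held out before any training
(including self-supervised pretraining); the remainder forms the CV set,
from which five *independent* stratified 60/20/20 train/val/test splits
are drawn (stratified on RAN; largest-remainder rounding preserves class
totals within one sample). Training negatives are downsampled once per
fold to five times the positive count; validation and test sets are never
touched. The holdout draw is plain random sampling — whether the original
design stratified it is unstated, and random sampling is the weaker
assumption.

Training minimizes class-weighted binary cross-entropy
$-[W y \log p + (1-y)\log(1-p)]$ with `pos_weight` W = 5 by default
(the sweep of interest is W in {5, 10, 20, 30}). *Direct* training fits the
aggregator on the target label; *two-step* training first fits on RAN,
selects the checkpoint with the best validation AUC, and fine-tunes on the
rare target at a ten-times smaller learning rate on the same fold's
splits. Batch gradients are normalized by the batch's total example
weight (not its size), the standard practice that keeps the optimizer
step scale independent of W. The best-validation rule is also used to
pick the RAN checkpoint
that seeds stage 2 (the alternative — fine-tune from the last step — is
not stated in the design we follow; the best-validation checkpoint is the
model one would actually deploy, so it is the one worth transferring).
Checkpoint ties resolve to the earliest step. The optimizer is Adam with
decoupled weight decay (default 0.01), which keeps the desk-scale
aggregator's logits from saturating on a few hundred training bags.

### Evaluation

`summary_metrics` reports ROC AUC (computed as the Mann–Whitney rank
statistic, ties counted one half), PR AUC (step-wise interpolated
precision at distinct recall points), and the threshold metrics accuracy,
PPA (sensitivity), PPV (precision), NPA (specificity) and F1 at the fixed
rule "positive iff score >= t" with t = 0.5 (ties positive; the original
operating threshold is unstated, so 0.5 is a documented choice, not a
claim). The screening trade-off curve sweeps all distinct scores and
records FN/n, TN/n and PPA — the axes on which a pre-screening deployment
would be costed. Fold aggregation uses the arithmetic mean and sample
(n−1) standard deviation; specimen-type stratified reports run the same
metrics on biopsy-only and resection-only subsets.

### Interpretability

Attention rollout head-averages each layer's attention, mixes it
half-and-half with the identity (the residual path), and multiplies the
mixed matrices across layers; the CLS row of the product over tile columns
attributes the slide logit to tiles. The ½ coefficient and head averaging
follow the cited rollout method; the attention vector is left unnormalized
(CLS self-mass excluded, no rescaling), and min–max scaling happens only
at render time, keeping math and display separate. Combined maps are the
element-wise product of attention and tile classification scores: a tile
matters when it both looks fusion-positive and is attended to.

### Specimen-type classifier

Biopsy-versus-resection is a coarse-morphology problem — many small
scattered fragments versus one large contiguous region — so a small CNN on
thumbnails suffices at desk scale (two strided conv layers, global average
pooling, softmax; a deeper VGG-style stack is available via config).
Training uses cross-entropy, Adam at learning rate 0.001, batch size
32 (16 at desk scale) and 25 epochs, with flip/rotation and *mild* gain
jitter: strong luminance jitter would corrupt the tissue-area fraction
that the distinction rests on. Augmentation is never applied at inference.

## The synthetic data generator

The generator is first-class, tested code; it emulates exactly the
statistical structure the pipeline assumes and nothing more.

**Slides** (`gen_synthetic_slide`): textured tissue blobs (union of random
ellipses, high-frequency pink-purple texture) on a near-white background,
plus the artifact classes the mask chain must reject — Gaussian-blurred
patches over tissue, near-black label rectangles on background, and
enclosed near-white fat-like holes inside tissue — each with a
ground-truth mask. The "tissue" ground truth is the sharp, artifact-free
tissue. No attempt at photorealism or stain simulation is made: the
generator reproduces the intensity and texture statistics each filter
keys on, which is what makes the mask tests meaningful and no more.

**Feature bags** (`gen_bag_dataset`): per seed, four orthonormal signal
directions are drawn (one shared "fusion" direction, one per sub-label).
Each slide is assigned at most one fusion by a multinomial draw at the
configured prevalences (defaults 1% / 2% / 1% — the rare regime), making
the three labels mutually exclusive by construction. Negative bags are
isotropic Gaussian noise; in a positive bag a random subset of tiles is
shifted by `shared_effect` (standardized by the noise SD) along the shared
direction plus `specific_effect` along the sub-label's own direction. The
single scalar `shared_effect` therefore controls exactly how much RAN
pretraining can transfer to a rare target.

The per-bag signal-tile fraction is drawn uniformly from a range (default
0.05–0.4), emulating slide-to-slide variation in tumor content. This
heterogeneity matters: with a fixed fraction, every positive bag is
equally hard, trained models either catch all positives or none at a
given threshold, and the PPA/NPA response to the loss weight degenerates
to a step function decided by training noise. A continuum of bag
difficulty is what makes the screening trade-off a curve — which is how
the clinical data behave (PPA around 0.5 at W = 5, rising smoothly with
W).

What the generator does *not* emulate: spatial correlation between tiles,
batch effects between scanners, stain variation, label noise in the
molecular assay, and any real histomorphology. Tests passing on this
generator show the pipeline's mechanics are correct and its directional
claims hold under the assumed structure; they do not certify clinical
performance.

## Benchmark problem sizes

The two packaged benchmarks run the full pipeline end to end at sizes
chosen for a single CPU:

* **Two-step benefit** (`run_twostep_benchmark`): 8 seeds; per seed 800
  slides, 16-d features, bags of 15–40 tiles, prevalences 1% / 2.5% / 1%,
  `shared_effect` 2 >= `specific_effect` 1, aggregator with `d_model` 16,
  2 layers x 4 heads; 10 epochs at learning rate 2e-3 per stage. The
  comparison statistic is the maximum validation AUC per arm — the same
  selection surface used for checkpointing.
* **Weight sweep** (`run_weight_sweep`): the same generator conditions,
  training on the RAN label at W in {5, 10, 20, 30} and evaluating
  test-set metrics at t = 0.5. Three measurement-design choices keep the
  small adjacent-W effects above the noise floor: the split is 30/10/60
  of 1600 slides, so the training set matches the two-step benchmark's
  while the test set carries ~40 positives; batch gradients are
  normalized by total example weight, so the optimizer step does not
  scale with W (otherwise high-W runs are unstable and their calibration
  erratic); and the sweep uses a lower-capacity aggregator (`d_model` 8,
  2 heads, batch 16, 12 epochs), because a larger model's run-to-run
  calibration variance at threshold 0.5 exceeds the effect of adjacent
  weights when only ~20 training positives exist.

The moderate effect sizes place trained models at ROC AUC around 0.85 —
the overlap regime the clinical task occupies — because in the separable
regime threshold metrics stop responding to W and the trade-off is
invisible. With a 1% target, an RAN-stratified split can leave a
validation set without any target positive; the benchmarks redraw the
(seeded) split until validation and test contain both classes, a
condition that applies equally to both training arms.

## Known limitations

* All neural components are plain-R matrix code: correct (verified by
  finite-difference gradient checks) but slow beyond desk scale; the
  full-size configurations (384-d features, `d_model` 512) are provided
  for completeness, not speed.
* One slide per patient is assumed; patient-level grouping across slides
  is not modeled.
* The bag container is a plain-text directory (manifest plus per-slide
  feature/coordinate CSVs) rather than a binary hierarchical file.
* Scanner-specific pyramid handling is out of scope: images are assumed
  supplied at (or rescaled to) working magnification.
* Tile-level classification maps use the singleton-bag approximation and
  are not trained for tile-wise prediction; they are an interpretive aid.
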