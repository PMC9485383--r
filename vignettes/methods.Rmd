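---
title: "Hybrid network + GLCM texture segmentation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid network + GLCM texture segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

glcmseg segments glioma subregions (edema, necrosis/non-enhancing,
enhancing tumor) in co-registered multi-modal MRI by fusing two feature
families at the pixel level:

* **Machine-learned features**: the per-class probability maps ("score
  maps") of a SegNet-style encoder–decoder. The encoder alternates 3×3
  convolutions (ReLU) with 2×2 max pooling that records the argmax index
  of every pooled cell; the decoder upsamples by writing values back to
  exactly those indices and convolving again. Only indices cross from
  encoder to decoder — no feature-map concatenation — which is the
  architecture's low-memory signature. A per-pixel softmax places the
  final class maps on the probability simplex (each pixel's scores sum to
  1 within 1e-5, enforced by construction and asserted in tests).
* **Hand-crafted features**: Haralick statistics of gray-level
  co-occurrence matrices (GLCMs). For a pixel, the 8×8 window of the T1ce
  slice centered there (rows y−4..y+3 — an even window cannot be centered
  symmetrically, so the pixel sits just below-right of center; fixed
  convention) is quantized to L = 8 gray levels, and one symmetric GLCM
  per direction θ ∈ {0°, 45°, 90°, 135°} at distance 1 is accumulated.
  From the normalized joint distribution p(i,j): ASM = Σp², contrast =
  Σ(i−j)²p, correlation = Σ(i−μᵢ)(j−μⱼ)p/(σᵢσⱼ).

Each pixel inside a whole-tumor region of interest (ROI) is described by
7 numbers — 4 score-map values (background, edema, necrosis, enhancing)
plus (ASM, contrast, correlation) — and classified by a CART decision
tree. Pixels outside the ROI are never classified; this is both the
pipeline's cost-reduction device and a structural invariant the tests
assert (nonzero predictions ⊆ ROI, always).

The ROI itself comes from a binary (tumor/background) network trained per
modality; the modality with the best validation whole-tumor F-measure is
selected. Tumor-vs-brain contrast is strongest and cleanest on FLAIR
because CSF — bright on T2, the main whole-tumor confounder — is
suppressed there, and the selection recovers exactly that.

## Assumptions

* Inputs are skull-stripped and co-registered; background voxels are
  exactly zero (the brain mask defaults to the union of nonzero voxels
  across modalities).
* 2D processing: volumes are iterated slice-wise along the first axis.
* BRATS label conventions: {0, 1, 2, 4}; evaluation regions WT = {1,2,4},
  TC = {1,4}, ET = {4}.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| clip percentiles | 1% / 1% | standard MRI outlier winsorization before z-scoring; computed over in-brain voxels only (background zeros would dominate otherwise), per volume and modality |
| crop target | 192×192 | fixed network input; center crop, offsets stored for mapping predictions back; no padding (padding would invent intensities) |
| GLCM levels L | 8 | the common default of standard texture toolboxes; quantization range = in-ROI min/max of the slice (per-image, not per-window, for stability) |
| GLCM window | 8×8 | small enough to be local, large enough for ~56 pixel pairs per direction; clipped (not padded) at image borders |
| direction handling | mean over 4 angles | the fused vector has exactly 3 texture slots while GLCMs come in 4 directions; averaging each feature over directions is the rotation-tolerant reduction. Per-direction (12-feature) variants can be built from `compute_glcm`/`haralick_features` directly, but carry no fidelity claim and are not the pipeline default |
| net depth / width | 2 / 8 | desk-scale: ~2.5k–13k parameters, trains in seconds per subject on one CPU while exercising the full pooling-index mechanism |
| epochs / lr | 20 / 0.01 (Adam) | converges on phantoms (loss typically drops 10–100×); deterministic: fixed image order, one image per step, seeded init |
| loss | unweighted per-pixel cross-entropy | `class_weights = "inverse"` available; unweighted suffices on phantoms where tumor occupies ~10–25% of the brain |
| tree depth | 100 ("fine tree") | the depth sweep of interest is {4, 20, 100}: coarse, medium, fine; Gini, min_leaf 1, no pruning |
| train split | 0.75, grade-stratified | with 210 HGG + 75 LGG this reproduces the canonical 158/57 train, 52/18 test counts; per-stratum train count is `ceiling(fraction·n)` — the only rounding rule consistent with those printed counts |

## The phantom generator

Each synthetic subject is a brain ellipse containing a nested lesion:
edema ring ⊃ core, core = necrotic interior + enhancing rim, plus a pair
of ventricle-like CSF ellipses. Geometry uses radially perturbed ellipses
(low-order cosine perturbation of the radius — irregular but controllable
boundaries); nesting is guaranteed by construction (each inner region is
intersected with its parent) and verified exhaustively in tests. Default
modality contrasts encode the clinical pattern: whole tumor (especially
edema) hyperintense on FLAIR and T2, CSF bright on T2 but suppressed on
FLAIR, enhancing rim bright and necrosis dark on T1ce, weak contrast on
T1. Each region additionally carries stationary Gaussian noise with its
own (sd, smoothing length), so co-occurrence statistics genuinely
discriminate tissue — necrosis is the noisiest region by default, which
matches its heterogeneous appearance.

What the phantoms do **not** emulate: anatomy (no atlas, no gyri), partial
volume, multi-focal lesions, acquisition artifacts beyond an optional
smooth multiplicative bias field, and inter-scanner variation. A green
test therefore establishes that the mechanisms work and interact as
specified — not clinical-grade accuracy. Benchmark-scale results for this
family of methods (BRATS cohorts, fine-tuned VGG-based backbones, GPU
training) are out of reach at desk scale by design.

## Numerical choices and degenerate cases

* GLCM of an empty raster or zero-total window → zero matrix → features
  (0, 0, 0). Correlation with σᵢσⱼ = 0 (e.g. constant window) → 0, so a
  constant window yields exactly (1, 0, 0) and nothing NaN ever reaches
  the classifier.
* Quantization: explicitly supplied degenerate ranges error; a constant
  raster under the default data-derived range maps to level 0.
* Argmax ties (score maps) break to the lowest class index; max-pool ties
  break to the first element in column-major cell order; decision-tree
  split ties break to the lowest feature index. All three rules exist for
  determinism.
* F-measure: both masks empty → 1 (nothing to find, nothing claimed);
  exactly one empty → 0. Cohort standard deviations use the population
  (n) denominator, matching a mean±sd table over a fixed test set.
* Empty predicted ROI → all-background prediction for that subject.
* Checkpoints (networks, trees) serialize to JSON; weights round-trip at
  ~1e-15 relative error (not bit-exact), trees exactly.

## Design decisions that were genuinely open

* **Training from random init** instead of fine-tuning a pretrained
  VGG-16 encoder: keeps the package self-contained and CPU-sized while
  preserving the mechanism under study (pooling-index unpooling, score
  maps, fusion). Width/depth are config.
* **Score maps = softmax probabilities.** The published example values of
  near-tied class scores (≈0.42 for two competing classes) lie in [0,1]
  and nearly sum to 1 with the remaining classes, which is consistent
  with post-normalization maps; probabilities also make the 7-element
  vector scale-free.
* **Modality selection on a validation carve-out** (last 25% of the
  shuffled training split), not on the test set: selecting on test data
  would leak; the report logs which subjects every training stage saw and
  a test asserts the test split is never among them.
* **ROI source for downstream stages = predicted masks** (config
  `roi$source`, `"oracle"` available): the pipeline should be evaluated
  end-to-end on its own ROI, imperfections included.
* **Per-volume percentile clipping** (not per-slice): keeps slices of one
  subject mutually consistent; flagged in config.
* **Slices with empty ROI are kept** (config default) and simply produce
  all-background predictions.
* **JSON configs and manifests** rather than YAML: the target environment
  ships `jsonlite` but no YAML parser, and the manifest gains nothing
  from YAML.
* **Decision tree implemented in-package**: the fine-tree setting needs
  depth 100 (beyond `rpart`'s hard cap of 30), and a flat JSON node table
  lets an independent re-descent oracle verify every prediction.

## Scaling of the acceptance runs

The acceptance criteria state generous per-criterion budgets; the test
suite keeps the whole run well inside a 25-minute single-CPU budget by
running the structural-invariant/reproducibility criterion at the default
192×192 and the repeated-training criteria (modality-selection recovery,
hybrid-benefit trend) at 96×96 with 20-epoch schedules. Image size is an
ordinary config field; nothing about the mechanisms changes with
resolution. The hybrid-benefit world makes the three tumor subregions
share mean intensity on every modality while differing in noise texture —
in that world the score maps carry almost no subregion signal, the
net-only arm lands in an unstable middling-F regime for core and
enhancing tumor, and the texture features restore separability, which is
precisely the published motivation for the fusion.

## Known limitations

* Pure-R training: fine at 192×192/depth-2 scale, not meant for larger
  networks or 3D convolutions.
* Windowed GLCM maps cost O(|ROI| · window² · angles); ~1–2 s per
  192×192 slice. Acceptable here; a compiled kernel would be the next
  step if ROIs grew.
* No orientation/registration handling in I/O: NIfTI axes are taken as
  stored (round-trip exact; cross-tool axis conventions are the caller's
  responsibility). No DICOM.
* Bias-field correction is a pass-through hook
  (`preprocess$bias_correction = "external:<cmd>"`, default `"off"`):
  phantoms are generated bias-free by default, and re-implementing
  published correction algorithms is out of scope.
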