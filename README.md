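# glcmseg

Hybrid brain-tumor segmentation for multi-modal MRI: a compact
encoder–decoder segmentation network fused with windowed gray-level
co-occurrence matrix (GLCM) texture features, classified per pixel by a
decision tree inside a whole-tumor region of interest (ROI).

## Who this is for

Researchers in medical image analysis who want a fully inspectable,
desk-scale implementation of the classic "machine-learned + hand-crafted
feature fusion" recipe for glioma subregion segmentation — every stage is
pure R, seeded, and testable without clinical data, thanks to a built-in
multi-modal phantom generator.

## The method

Input is a co-registered stack of four MRI sequences (FLAIR, T1, T1ce, T2)
with BRATS-convention labels (0 background, 1 necrosis/non-enhancing,
2 edema, 4 enhancing tumor). Four stages:

1. **Preprocess** — per-volume, per-modality: clip in-brain intensities to
   [p1, p99], z-score over the brain mask, optional center crop to
   192×192.
2. **ROI generation** — a binary (tumor / not-tumor) SegNet-style network
   is trained on each modality separately; the modality with the highest
   whole-tumor F-measure on a validation carve-out (FLAIR, in practice —
   it suppresses the bright-CSF confounder) supplies the ROI mask. The
   mask zeroes the combined [FLAIR, T1ce, T2] image outside the tumor.
3. **Feature extraction** — a 4-class network on the ROI images yields
   per-class score maps `p(c | pixel)` (softmax, one map per class); for
   each ROI pixel the three Haralick features

   ASM = Σᵢⱼ p(i,j)², contrast = Σᵢⱼ (i−j)² p(i,j),
   correlation = Σᵢⱼ (i−μᵢ)(j−μⱼ) p(i,j) / (σᵢσⱼ)

   are computed from symmetric GLCMs (distance d = 1, directions
   θ ∈ {0°, 45°, 90°, 135°}, averaged) over an 8×8 window of the T1ce
   slice quantized to 8 gray levels.
4. **Classification** — the fused 7-element vector (4 scores + 3 texture
   features) is classified by a CART decision tree ("fine tree", Gini,
   depth ≤ 100); predictions are written back inside the ROI only and
   evaluated as whole tumor (WT = {1,2,4}), tumor core (TC = {1,4}) and
   enhancing tumor (ET = {4}) F-measures.

The encoder–decoder uses 2×2 max pooling that records argmax indices and a
decoder that unpools values back to exactly those positions (the memory
trait that distinguishes SegNet from skip-concatenation designs). Networks
here are trained from random initialization at desk scale (depth 2, base
width 8 by default) — no pretrained weights, no GPU.

## Worked example

```r
library(glcmseg)

cfg <- pipeline_config(
  phantom = phantom_config(image_size = c(96L, 96L), n_subjects = 8L,
                           seed = 11L),
  split   = list(fraction = 0.75, seed = 11L),
  roi_net = net_config(1L, 2L, epochs = 25L, seed = 11L),
  net     = net_config(3L, 4L, epochs = 25L, seed = 12L),
  dt      = dt_config(max_depth = 100L, seed = 13L))
rep <- run_pipeline(cfg, verbose = TRUE)
#> cohort: 8 subjects (6 train / 2 test)
#> roi: best modality T2 (FLAIR=0.99, T1=0.93, T1ce=0.94, T2=0.99)
#> dt: 279 nodes, train accuracy 1.000
print(rep$comparison$table, quote = FALSE)
#>          WT            TC            ET
#> net_only 0.990+/-0.002 0.964+/-0.010 0.860+/-0.001
#> hybrid   0.993+/-0.000 0.970+/-0.012 0.874+/-0.013
```

`rep$selection$table` is the per-modality ROI F-measure table; the
comparison table shows the 4-class network alone (`net_only`) versus the
fused network+GLCM+tree pipeline (`hybrid`) on the held-out test subjects,
mean ± sd across subjects per region. On default phantoms both arms are
strong (contrast separates most tissue); the hybrid's advantage grows
as subregions become distinguishable mainly by texture — see the
methods vignette and `tests/testthat/test-acceptance.R`.

A command-line interface wraps the same calls:

```sh
Rscript inst/cli/glcmseg.R phantom --config cohort.json --out cohort_dir
Rscript inst/cli/glcmseg.R run --config pipeline.json
Rscript inst/cli/glcmseg.R eval --pred preds/ --gt labels/ --out metrics.json
```

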