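---
title: "Automatic exophthalmometry on orbital CT slices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic exophthalmometry on orbital CT slices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(exoct)
```

## The measurement

Exophthalmos — abnormal anterior protrusion of the eyeball — is quantified
clinically as the distance between the corneal apex and a reference line
anchored on the bony orbital rim. On an **axial** CT slice the reference is
the line through the most protruding (most anterior) points of the two
lateral orbital rims, and one distance is reported per eye; on a
**sagittal** slice it is the line through the most protruding (most
anterior, i.e. leftmost in image coordinates) points of the superior and
inferior orbital rims, with a single distance for the visible eye. `exoct`
automates both measurements on single 2D slices rendered in a soft-tissue
window:

1. **Eye segmentation.** A U-Net++ convolutional network produces a
   per-pixel eye probability; pixels at probability ≥ 0.5 form the eye
   mask. An *oracle* segmenter (a known ground-truth mask) can be
   substituted so the geometry can be validated independently of learning.
2. **Rim extraction.** Bone is the only tissue rendered above grayscale
   200 in a soft-tissue window, so the rim mask is obtained by strict
   thresholding (`> 200`), a 3×3 morphological opening (which removes the
   thin watermark strokes burned into many exported CT images), and removal
   of 8-connected components smaller than 100 px (residual noise).
3. **Landmarks.** Rim apexes are extremal set pixels: on axial slices the
   minimum-row pixel within the leftmost and rightmost thirds of the image;
   on sagittal slices the minimum-column pixel within the upper and lower
   halves. The corneal apex is the minimum-column mask pixel (sagittal) or
   the minimum-row pixel of each of the two largest mask components
   (axial). Ties are broken lexicographically (minimum secondary
   coordinate), which makes every landmark deterministic.
4. **Distance.** The rim line `a·col + b·row + c = 0` is normalized to
   `a² + b² = 1` (sign convention `a ≥ 0`, `b > 0` when `a = 0`), so the
   perpendicular distance of apex `(r, c)` is simply `|a·c + b·r + c₀|`,
   converted to millimetres by the isotropic in-plane pixel spacing.

Coordinates throughout are 1-based `(row, col)` with the origin at the
top-left pixel, matching R matrix indexing: "smallest y" in image
coordinates is the smallest row, "smallest x" the smallest column. With
image width `W`, the outer thirds are columns `1..⌊W/3⌋` and
`⌈2W/3⌉+1..W` (the middle third is discarded); halves split after row
`⌊H/2⌋`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bone_threshold` | 200 (strict >) | grayscale above which only bone renders in a soft-tissue window |
| `opening_radius` | 1 (3×3 square) | smallest element that removes width-1 watermark strokes |
| `min_component_area` | 100 px | "small connected domain" cutoff, inclusive, 8-connectivity |
| `learning_rate` / decay | 1e-4 / 0.99 per epoch | full-size training recipe (Adam, soft Dice loss) |
| `depth` / `base_channels` | 5 / 32 | full-size U-Net++; the phantom benchmark uses 3 / 8 |
| probability threshold | 0.5 | binarization of the network output |
| window (HU) | center 40, width 400 | standard soft-tissue window for `window_hu()` |
| `pixel_spacing_mm` | 0.5 | phantom default; real slices carry their own spacing |

`min_component_area` is resolution-dependent: it scales with pixel area,
so for phantoms rendered at 64 px instead of 256 px the benchmark passes
`min_component_area = 6` (≈ 100 × (64/256)²).

The empty-vs-empty Dice loss is defined as 0 (perfect agreement on an
empty slice) so the metric is total; zero-denominator overlap metrics
return 0 with a warning, keeping corpus averages defined.

## The U-Net++ segmenter

The network is the nested-skip encoder–decoder: node `X(i,j)` at
resolution level `i` consumes all earlier nodes of its level and the
upsampled `X(i+1, j-1)`; each node is two (3×3 convolution → batch
normalization → ReLU) stages, with 2×2 max-pooling between levels,
nearest-neighbour upsampling, and a 1×1 convolution + sigmoid head.
Weights use Kaiming-normal initialization; training minimizes the soft
Dice loss

$$\mathcal{L} = 1 - \frac{2\sum_i p_i t_i}{\sum_i p_i + \sum_i t_i}$$

with Adam, averaging gradients over mini-batches of 4 images and decaying
the learning rate by 0.99 each epoch. Deep supervision is not implemented.
The engine is written in plain R: convolutions are im2col gathers feeding
BLAS matrix products, batch-norm statistics are per-image (per-channel
over the spatial dimensions, with running averages for inference), and
the backward pass is validated against central-difference numerical
gradients to ~1e-7 relative error in the test suite. Training with a
fixed seed is bit-deterministic because every operation is ordinary
double-precision BLAS arithmetic evaluated in a fixed order.

Inputs are scaled to [0, 1]; grids not divisible by `2^(depth-1)` are
reflection-padded and the output cropped back, so the probability map is
always on the input grid. One model is trained per view: nothing ties the
two views' intensity statistics together, and the anterior direction
differs, so sharing weights would be an unforced assumption.

### The scaled-down benchmark

The package's end-to-end learning benchmark — used by the test suite and
`scripts/acceptance.R` — trains depth 3 / base 8 on twenty noise-free
64×64 axial phantoms for 30 epochs (network seed 7, batch 4), i.e. 150
optimizer steps in total, then evaluates Dice on ten held-out phantoms
and the distance error of the full pipeline run with the learned masks.
At 150 steps the full recipe's learning rate of 1e-4 cannot move the
weights appreciably (Adam steps are bounded by the learning rate), so the
benchmark sets its learning rate to 0.01 — a step size proportionate to a
run some hundred times shorter than the full recipe — and keeps every
other recipe element unchanged. Typical results are held-out Dice ≈ 1.00
and sub-pixel mean distance error.

## The phantom generator

`random_phantom_spec()` emulates the content of a soft-tissue-window
orbital slice: a mid-intensity head ellipse (tissue level 90) on a dark
background (level 20), eye globes as filled ellipses at level 150, bone
at level 230 — the only structure above the 200 threshold — optional
width-1 watermark strokes at bone intensity, and additive Gaussian noise
(SD 5 by default) clipped to [0, 255], never wrapped, so tissue cannot
cross the bone threshold. The canonical 256 px layout at 0.5 mm/px draws
the corneal protrusion from the clinical population range — about
18 ± 3 mm anterior of the lateral-rim line on axial slices and about
8 ± 2.7 mm relative to the superior–inferior rim line on sagittal
slices — and all positions, radii and arc depths take seeded integer
jitters scaled with image size. A realistic between-subject spread
matters beyond appearances: agreement statistics (CCC/ICC) compare
measurement error against population variance, so a corpus with an
unrealistically narrow spread would misrepresent how the method behaves
on a clinical cohort.

Three deliberate constructions make the phantom a *calibrated* oracle
rather than a pretty picture:

- **Ground truth is continuous.** Landmarks and the true distance come
  from the closed-form geometry (ellipse extreme points, point-to-line
  distance), not from any raster. Rasterization happens at pixel centers,
  and all jittered geometry lands on integer coordinates, so the
  rasterized corneal apex coincides with the continuous one.
- **Bone arcs are slender with a capped tip.** Rim arcs are solid
  elliptical lobes whose minor semi-axis (~5 px at 256 px) keeps the
  digital apex sharp, plus a 3×3 cap at the continuous apex so the mask
  is morphologically open *with its extremal row/column at the continuous
  apex*: the extremal-pixel rule with lexicographic tie-break lands
  within 1 px (Chebyshev) of the continuous apex and without systematic
  bias along the protrusion axis. Wide flat-topped shapes would let the
  tie-break drift several columns along the top row, and an uncapped
  slender tip loses its apex pixel to the opening, biasing every
  measurement by one pixel.
- **The rendered bone mask is morphologically open.** The rasterized arcs
  are regularized by one 3×3 opening before painting, and watermark
  strokes keep a 2 px Chebyshev clearance from bone. The pipeline's own
  opening is then exactly the identity on bone and exactly annihilates
  the strokes, which is what makes the rim stage's *exact* recovery
  testable (`extract_rim_mask()` ≡ true bone mask on noise-free
  phantoms).

The resulting error budget for the full pipeline with oracle masks is
±1.5 px per eye (±1 px rim-apex discretization plus a small line-tilt
term; with the capped arcs the observed error is ~0.05 px). What the phantoms do *not* emulate —
Hounsfield-unit physics, partial-volume blur, anatomical variation,
pathology, incomplete or displaced rims — bounds what passing tests
mean: they certify the geometry, the morphology and the learning
machinery, not clinical performance on patient CT.

## Agreement statistics

Automatic-vs-manual comparisons use:

- **Lin's CCC**, `2·s_xy / (s_x² + s_y² + (x̄−ȳ)²)` with the 1/n (biased)
  variance convention of Lin's original estimator (the 1/(n−1) variant
  changes the value slightly; the convention is echoed in every report).
- **ICC(A,1)**: two-way model, absolute agreement, single measurement,
  `(MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE))` with `k = 2` from
  the two-way ANOVA decomposition. "Absolute agreement" is the variant
  that penalizes a systematic offset between methods; the consistency
  variant would not. The random- and mixed-effects readings of the
  two-way model share this point estimate, which is what is implemented;
  the ambiguity is recorded in the report's conventions field.
- **Bland–Altman** bias and limits `bias ± 1.96·sd(d)` (sample SD), with
  no confidence intervals on the limits.

The test suite cross-checks the ICC against an independent `aov()`-based
ANOVA decomposition and against frozen reference values from an external
implementation, and verifies Lin's inequality `|CCC| ≤ |r|` on random
pairs.

Self-closure: feeding the pipeline's oracle-mask measurements against
phantom ground truth through this module yields CCC and ICC above 0.99 on
50-phantom corpora per view — the qualitative behaviour expected of a
geometry whose errors are bounded by ~1 px on ~30 px distances.

## Numerical and degenerate-input choices

- Strict `>` at the bone threshold: a pixel of exactly 200 is tissue.
- Component areas are compared inclusively (`≥ min_area`).
- Landmark ties break to the smallest secondary coordinate; documented
  and deterministic.
- Millimetre output requires isotropic spacing; anisotropic spacing is an
  error (a perpendicular distance has no per-axis mm decomposition) and
  missing spacing yields `NA` mm with a warning.
- Degenerate inputs error with named causes: empty rim thirds/halves,
  empty eye masks, merged eye components, all-dark slices ("no bone found
  above threshold"). Batch runs record such failures per image and
  continue; the run's exit status reflects them.
- Slices with incomplete, missing or displaced orbital rims are out of
  scope by design: the landmark rules would silently latch onto the wrong
  bone, so such inputs should be excluded upstream.
- HU windowing rounds half away from zero after the linear map and clips
  to [0, 255]; windowing is monotone.

## Problem sizes

The shipped benchmarks are sized for a single CPU: 50 phantoms per view
at 256 px for the rim and oracle-recovery checks, 1 000 random
point/line instances (each checked against a brute-force minimization
over 10⁶ sampled line points), and the 20/4/10-phantom training benchmark
at 64 px described above. The full-size training recipe (depth 5,
base 32, 200 epochs) is exposed through the same functions and the
`exoct train` CLI verb but is not exercised by the tests.

## Known limitations

- No DICOM container parsing: `window_hu()` implements the rescale +
  window + 8-bit mapping on pixel matrices, and PNG is the supported file
  format; real DICOM pixel data must be extracted upstream.
- The CNN engine is CPU-only and single-threaded beyond BLAS; it is built
  for the package's slice sizes, not for high-throughput training.
- Landmarks are integer pixel centers; no subpixel refinement is
  attempted.
- Slice selection (the "thickest lens" slice) is the caller's
  responsibility; the package measures the slice it is given.
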