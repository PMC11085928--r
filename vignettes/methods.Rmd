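---
title: "Methods: quantifying cell migration in scaffold z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cell migration in scaffold z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucstack)
```

This vignette documents the models, numerical choices and known limitations
behind `nucstack`. It is the place where design decisions that were
genuinely open are recorded, in the spirit of a lab methods section.

## The measurement model

A confocal z-stack of a nuclear stain scans a fibrous scaffold in steps of
`layer_spacing_um` (default 7 µm). Each physical nucleus appears in several
consecutive planes: sharp in the plane closest to its true depth,
increasingly blurred and dimmer away from it. The pipeline's job is to
invert this: detect blobs per layer, decide which blobs in different layers
are the same nucleus, and count that nucleus once, in its in-focus layer.

The stages are:

1. **Segmentation** (`segment_stack`): intensity threshold, hole filling,
   distance-map watershed to split touching nuclei, area filter.
2. **Focus scoring** (`focus_score`): variance of the 4-neighbour Laplacian
   by default; Tenengrad (mean squared Sobel magnitude) as an alternative.
   Both are zero on constant patches and decrease monotonically under blur;
   the Laplacian variance is the default because it is the classic
   autofocus measure and is cheapest to compute on small patches.
3. **Linking** (`link_and_assign`): detections in nearby layers whose
   centroids lie within `max_centroid_shift_px` and whose patches score at
   least `ssim_threshold` under SSIM are chained into one group; the group
   is assigned to its maximal-focus member.
4. **Counting and kinetics** (`build_count_profile`, `conversion_curve`,
   `fit_conversion_model`, `migration_activity_curve`): described in the
   README; details and caveats below.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `layer_spacing_um` | 7 | µm | typical confocal z-step for mat scans |
| `pixel_size_um` | 0.5 | µm/px | 20x objective class imaging |
| `min_area_px` / `max_area_px` | 64 / 50000 | px | brackets fibroblast nuclei (7–18 µm axes at 0.5 µm/px give ~250–1000 px in focus; defocused appearances above threshold are smaller, hence the low floor) while rejecting noise speckle |
| `tile_size_px` / `tile_overlap_px` | 1024 / 64 | px | tile edge for large fields; the overlap exceeds one nucleus diameter so border objects are whole in at least one tile |
| `max_centroid_shift_px` | 36 | px | one nucleus major axis at the reference calibration; a nucleus's centroid moves far less between adjacent planes |
| `ssim_threshold` | 0.5 | – | permissive enough to survive defocus between adjacent planes, strict enough to reject unrelated neighbours |
| `ssim_window_px` | 7 | px | the standard SSIM sliding window |
| `max_layer_gap` | 1 | layers | one missed intermediate detection may be skipped |
| `t_d` | per study design | days | observation-interval length for the proliferation rate |

## Design decisions

**One threshold per stack, not per layer.** `segment_stack` resolves the
Otsu threshold once on the pooled intensities of all layers.
A z-stack is a single acquisition with one intensity scale; per-layer Otsu
gives sparsely populated deep layers erratic thresholds that truncate dim
defocused appearances into fragments, which then fail the SSIM gate and
surface as duplicate nuclei. For the same reason `segment_layer_tiled`
resolves the threshold on the whole layer before tiling, so empty tiles do
not threshold their own noise. `segment_layer` keeps per-layer Otsu for
standalone use.

**Patch normalisation before SSIM.** Defocus attenuates brightness, and the
linker should compare structure, not intensity: each detection's bounding
box (padded 4 px) is cropped, resized to a 32 px square window, and divided
by its own maximum before SSIM. Without normalisation the luminance term
penalises exactly the dim appearances the linker needs to capture.

**Chain optimisation.** Within each connected component of the candidate
graph, the partition into layer-increasing chains maximising total link
SSIM is found exactly by branch and bound for components of up to 12
detections (in practice a component is one nucleus: the acceptance run
measures about 3 raw detections per nucleus), with a per-layer greedy
best-match fallback for larger components. Ambiguities resolve by highest
SSIM, then smaller layer index; focus ties within a chain resolve to the
smaller layer. Exactness for small components makes the behaviour
independent of detection enumeration order.

**Depth convention.** Layer index 0 is the first acquired (seeding-surface)
plane. The cumulative count through layer *k* includes every cell down to
that layer's bottom boundary, so conversion values are reported at
boundary depths `z_k = (k+1) × spacing` rather than layer midpoints;
midpoints would bias the fitted Hill half-depth by half a z-step.

**The closure point is excluded from kinetic fits.** Any profile-derived
conversion curve ends at exactly 1 — the deepest layer absorbs all
remaining cells by normalisation, whatever the true depth law. That final
point is a constraint, not data, and including it biases fits whenever the
scaffold truncates the depth distribution's tail; `fit_conversion_model`
therefore drops it (and requires at least 4 remaining points).

**Fit numerics.** Levenberg–Marquardt (`minpack.lm::nlsLM`, at most 200
iterations) with starts `K` = median depth, `n` = 2, `k` = 1/median depth,
and positivity lower bounds. Non-convergence sets `converged = FALSE` with
the optimiser's diagnostic attached — never a silent answer. Model
selection (`model = "best"`) compares residual sums of squares among the
converged candidates only.

**Inverting the conversion curve.** `z(alpha)` uses monotone
piecewise-linear interpolation with `(0, 0)` prepended. A flat segment
spanning a requested `alpha` (layers with zero counts) resolves to the
segment midpoint and flags the point. The activity slope is the ordinary
least-squares coefficient through the nine activity points.

**Degenerate inputs.** Empty stacks produce zero-count outputs and skip the
kinetics with a logged reason. Blank layers segment to empty masks. Objects
with a zero minor second moment (pixel-wide lines) get their minor axis
floored at one pixel and a `degenerate` flag. Empty-vs-empty masks score
IOU = dice = 1 (perfect agreement of two empty predictions).

**Trainable segmenter.** The optional trainable path is a multiscale
filter bank (identity, Gaussians at σ = 1, 2, 4, difference-of-Gaussians,
Laplacian and Sobel magnitudes) feeding a pixel-wise logistic decoder,
trained full-batch with momentum on binary cross-entropy plus a soft
dice-loss term, with a mandatory held-out validation split and per-epoch
training/validation IOU. It honours the same mask contract as the classical
path (`seg_config(method = "cnn", model = ...)`) and is deterministic under
a fixed seed. It is a linear-in-features model: sufficient for
intensity-separable nuclei, and not a substitute for a deep segmenter on
textured real-world backgrounds. The classical path remains the default and
the test oracle.

## The synthetic-stack generator

`generate_stack` emulates the reference acquisition: 14 layers at 7 µm,
1024 px square fields at 0.5 µm/px, 200 nuclei, 2% Gaussian intensity
noise. Nuclei are filled ellipses (full axes: major 12–18 µm, minor
7–11 µm — fibroblast-nucleus scale) placed with a minimum centre separation
of 1.1 major axes; depth follows one of three regimes (`surface`
exponential settling, shifted `exponential`, `hill`) so kinetics fitting
has in-distribution test data. Out-of-focus appearances are the in-focus
ellipse convolved with an isotropic Gaussian of σ = `blur_growth` ×
layer distance (default 1 px/layer) and attenuated by 1/(1+σ²);
appearances attenuated below 1% are omitted. All randomness flows from one
seed; identical parameters give bit-identical stacks.

What it deliberately does **not** emulate: fibre/scaffold background
texture, photobleaching, multi-channel stains, true 3D nucleus shapes (the
ellipse is repeated with blur, not an ellipsoid sectioned), laterally
overlapping nuclei, or instrument-calibrated optics — the defocus law was
chosen so that "in focus" is well defined and recoverable, not fitted to a
microscope. Passing the end-to-end tests therefore demonstrates that the
algorithmic chain is correct under controlled conditions, not that the
default thresholds are optimal for any particular instrument's data.

The count-scenario generator (`generate_count_scenario`) perturbs
cumulative fractions with Gaussian noise, re-monotonises, anchors the
deepest layer at 1, and converts to integer counts by largest-remainder
rounding, so counts always sum exactly to the requested total.

## Validation problem sizes

The test suite validates each stage against independent oracles: analytic
ellipse moments, hand-counted overlap metrics, closed-form migration
activity on linear conversion curves, brute-force enumeration of all
consistent chain partitions, and generator ground truth. The reference
study conditions — three 14-layer, 1024 px, 200-nucleus stacks for
end-to-end recovery; 50 three-layer mini-stacks for the deduplication
oracle; 1000 random profiles for conversion algebra; 100 noisy replicates
for Hill recovery; 200 pairs of 128 px images for segmenter training — were
chosen as the largest sizes that keep the whole suite comfortably
desk-scale while leaving no stage untested at realistic density.

## Known limitations

* SSIM-gated linking assumes nuclei are stationary between planes of one
  stack (fixed endpoints); it is not a cell tracker for time-lapse data.
* The conversion/activity summaries need `C_summ > 0` and an invertible
  conversion curve over the requested `alpha` range; sparse profiles with
  long zero runs produce flagged midpoint inversions.
* Watershed splitting of densely clumped nuclei is only as good as the
  distance transform; heavily overlapping cell layers (confluent day-7
  surfaces) will under-count within a layer.
* The proprietary CZI format is not read; convert to OME-TIFF/multi-page
  TIFF or per-layer PNGs first.
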