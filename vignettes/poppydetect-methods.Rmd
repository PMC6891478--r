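---
title: "poppydetect: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poppydetect: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model, the tunable parameters, the behaviour of
the synthetic-data generator, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Problem and model

Poppy plots in UAV survey frames are small (a single plant is ~30 cm
across), sparse, and embedded in cluttered vegetation. The package
implements a one-stage detector in the YOLOv3 family:

* a backbone taps feature maps at strides 8/16/32; for a 416×416 input
  the three prediction grids are 52², 26² and 13²;
* each grid cell holds 3 anchor-conditioned predictors emitting raw
  activations `(t_x, t_y, t_w, t_h, t_c, t_{class...})`, decoded as
  `b_x = (σ(t_x) + c_x)/S`, `b_w = a_w e^{t_w}`, confidence `σ(t_c)`;
* a spatial-pyramid-pooling (SPP) unit enriches a stage with multiscale
  *local* maxima: stride-1 max pools at filter sizes `⌈S_map/n⌉`,
  `n = 1..levels`, concatenated with the input (channel count
  ×(levels+1)), followed by a 1×1 reduction convolution;
* the loss is `Coord + Conf + Class`, with `Coord = Σ(1 − GIoU)` over
  responsible predictors. GIoU extends IoU with an enclosing-box penalty
  so that disjoint boxes still receive a useful gradient; its range is
  (−1, 1] and the coordinate term is therefore bounded in [0, 2).

Assumptions inherited from this family: axis-aligned boxes, one
responsible predictor per ground truth (best shape-IoU anchor at the
centre cell), nadir imagery with approximately uniform ground sampling
distance across the frame.

## 2. Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `input_size` | 416 | px | divisible by 32; grids 13/26/52 |
| `width_mult` | 1 (0.25 for smoke runs) | — | channel scaling; 0.25 ≈ 12k parameters, CPU-trainable in minutes |
| `spp`, `spp_levels` | `"first"`, 3 | — | single SPP unit in the coarsest stage; filter sizes in the finer stages nearly repeat the coarser maps, so extra units buy little |
| `anchors` | k-means (IoU distance) on training boxes | normalized w,h | 9 clusters, largest three serving the 13×13 grid; a standard preset is available |
| `lambda_noobj` | 0.5 | — | the classical weight for the no-object confidence term (configurable; see §5) |
| learning rate | 0.001, ×0.1 after 20 stagnant epochs | — | Adam (0.9/0.999, weight decay 1e-4); early stop after 50 stagnant epochs; max 500 epochs; batch 8 |
| `warm_start_epochs` | 0 | epochs | >0 trains an MSE-coordinate phase first; the GIoU phase starts from those weights (GIoU from random weights is prone to vanishing gradients) |
| `conf_thresh`, `nms_iou` | 0.3, 0.45 | — | detection score cut and greedy per-class NMS threshold |
| window, stride | 416, 416 | px | non-overlapping tiling of full frames; remainder strips get edge-anchored windows |

## 3. The synthetic-scene generator

`generate_scene()` emulates the *geometry and statistics* of the survey
imagery, not its radiometry: frames of configurable size; object pixel
diameter `30 cm / GSD` (±20% jitter) from the camera preset and flying
height, so the 0.8/1.6/2.0 cm GSD ladder maps to ~37/18/15 px objects;
1–3 objects per frame by default; a vegetated background with low-
frequency mottling, building-like rectangles and shrub-like blobs as
distractors. Growth stages differ texturally: seedlings are grey-green
speckled disks, flowering plots carry red/white dots.

What a green test therefore establishes: the pipeline, loss, optimizer,
tiling and metrics are correct and a small detector can learn this
scene family end to end. What it does not establish: accuracy on real
UAV imagery — real poppies vary in shape, texture and illumination,
backgrounds contain look-alike flowering crops, and frames carry sensor
noise and blur none of which are modelled. The generator's defaults were
chosen once from the stated survey conditions (camera presets, heights,
object size, stage mix) and are not tuned to test outcomes.

## 4. Numerical choices

* **Degenerate boxes.** IoU of a zero-area box against a non-degenerate
  one is 0 (keeps losses finite); both degenerate raises a typed error.
* **GIoU gradient.** Analytic piecewise derivative (subgradient at
  kinks), validated against central finite differences at 1e-4 relative
  tolerance.
* **Even pooling windows.** Stride-1 'same' pooling pads
  `floor((k−1)/2)` on top/left, remainder bottom/right — the common
  framework convention; edge windows are clipped to the valid map, so
  the `k = S_map` level is a *local* global max (exactly global at the
  centre pixel), not a broadcast.
* **AP integral.** All-points interpolation: monotone precision
  envelope, exact rectangle sum — the modern VOC/COCO convention. Score
  ties break by detection index.
* **Split rounding.** Largest-remainder rounding, so 4250 images at
  70/10/20 give exactly 2975/425/850.
* **VOC coordinates.** 1-based inclusive integer corners on disk
  (labelImg dialect); continuous 0-based internally; integer boxes
  round-trip exactly.
* **Initialization.** He-normal weights, zero biases; objectness biases
  start at −2 so a fresh detector predicts mostly background without
  saturating the sigmoid (squared-error confidence loses its gradient
  when saturated).
* **Size logits** are clamped at 12 before exponentiation during loss
  evaluation to avoid overflow in early training.

## 5. Open design points and how they were decided

* **Crop dequeue rule.** The cropping algorithm drops a queued object
  when its "intersection over union" with the freshly cut window
  exceeds 0.5. A literal window/object IoU of a 416² window with a
  ~40 px object can never reach 0.5, making the rule a no-op; the
  default therefore reads it as *fraction of the object's area inside
  the window*, which preserves the rule's evident purpose (clustered
  objects share one crop). The literal reading stays available via
  `criterion = "iou"`.
* **Augmentation loop bound.** "2–4 derivatives per image" is read as
  `aug_num` draws with an exclusive loop bound (the conservative
  reading); `aug_range` makes the inclusive reading available.
* **Mixup pool.** Fused images supplement rather than replace the
  originals (the source protocol is silent); both modes work via the
  CLI.
* **Confidence target.** Default: IoU of the decoded box with its
  ground truth (the definition of confidence in this model family),
  treated as a constant per step. A constant-1 target is available and
  is what the desk-scale smoke training uses: with a from-scratch
  network the IoU target is initially tiny and the squared-error
  confidence channel collapses toward zero before localization
  improves.
* **`lambda_noobj` at desk scale.** The 0.5 convention was calibrated
  for ~10² predictors; a three-scale 416² head has ~10⁴, so the
  no-object sum otherwise dwarfs every other term and drives feature
  collapse. The smoke configuration uses 0.01 (≈ 0.5 scaled by the
  predictor-count ratio). The package default remains 0.5.
* **Classification loss** is the printed squared error on sigmoid
  scores, applied at responsible predictors; with a single class it is
  near-degenerate but kept for structural fidelity.
* **Loss normalization.** All three terms are sums (as printed); the
  per-predictor bound `< 2` on the coordinate term applies to
  `coord / n_obj`.
* **Warm start** re-initializes nothing and freezes nothing: phase 2
  simply continues from phase-1 weights with the GIoU term switched in,
  with a fresh optimizer state and schedule.
* **Cross-seam NMS** after sliding-window tiling is an addition (the
  source procedure does not state one); without it an object straddling
  a window boundary is reported twice. Defaulted on.

## 6. Known limitations

* No batch normalization; very deep or wide configurations may train
  poorly. The backbone's inverted-residual expansion defaults to 2
  (not 6) and depth is reduced — deliberate desk-scale choices.
* Training is single-image-at-a-time on one CPU core; minutes for
  quarter-width models, impractical for full-width ones.
* Rotation augmentation is restricted to 90° multiples (lossless box
  transform); arbitrary angles would need enclosing-box labels.
* PPM is the only raster format (no JPEG/PNG codecs in the supported
  dependency set); mosaicked multi-frame products are accepted only as
  pre-built single frames.
* The synthetic world is schematic (§3); reported AP/F2 values on it do
  not transfer to field imagery.
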