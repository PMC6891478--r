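# poppydetect

Single-stage detection of opium poppy plots in UAV imagery, in R.

Illicit poppy cultivation is monitored with low-altitude UAV surveys, but
the frames are huge (e.g. 5472 × 3648 px) and the plots are sparse —
visual interpretation takes a skilled expert ~20 s per image.
`poppydetect` implements a complete CPU-scale detection stack for this
problem: a YOLOv3-style one-stage detector with a MobileNetv2-style
backbone, a padded stride-1 spatial-pyramid-pooling (SPP) unit, and a
GIoU-based coordinate loss, together with the camera geometry, dataset
construction, sliding-window inference and evaluation machinery around
it. Because no suitable UAV poppy corpus is publicly deposited, a
synthetic-scene generator stands in for field imagery and makes every
stage runnable and testable offline.

## The model in brief

**Camera model.** The ground sampling distance is `GSD = H · a / f` with
flying height `H`, pixel pitch `a = S_pe / S_p` (sensor width over photo
width) and focal length `f`. A single poppy (~30 cm across) therefore
covers `30 / GSD` pixels: ≈ 37 px at 30 m with a 1-inch-class sensor.

**Detector.** Three prediction grids at strides 32/16/8 (13², 26², 52²
for a 416² input), three anchors per scale; each predictor emits
`(b_x, b_y, b_w, b_h, confidence)` plus class probabilities, decoded with
sigmoid cell offsets and exponential anchor scaling. The SPP unit
max-pools a stage's feature map at filter sizes `⌈S_map/n⌉` (stride 1,
shape-preserving padding; 13/7/5 on the 13×13 map), concatenates the
input with all pooled maps, and is placed in the first prediction stage
(`spp = "first"`, the default), all three (`"all"`), or omitted.

**Loss.** `Loss = Coord + Conf + Class` where the coordinate term is
`Σ (1 − GIoU)` over responsible predictors,
`GIoU = IoU − (|C| − |B ∪ G|)/|C|` (`C` the smallest enclosing box,
range (−1, 1], so the coordinate term lives in [0, 2)); confidence and
classification are squared errors with weight `λ_noobj` on object-free
predictors. An MSE coordinate switch supports both the ablation and the
warm start: GIoU training is initialized from MSE-trained weights to
avoid vanishing gradients.

**Evaluation.** Greedy IoU-0.5 matching, all-points-interpolated AP
(AP50), and the recall-weighted `F2 = 5PR/(4P + R)`, reported as the
maximum over confidence cutoffs.

## Worked example

```r
library(poppydetect)

dji <- camera_preset("dji")
round(gsd(dji, 30), 2)                     # 0.82  (cm per pixel at 30 m)
round(object_pixel_diameter(gsd(dji, 30))) # 36    (px per 30-cm poppy)

spec <- scene_spec(frame_w = 416, frame_h = 416, height_m = 30,
                   n_objects = 2L)
sc <- generate_scene(spec, seed = 7)
sc$annotations
#>   x_min y_min x_max y_max label
#> 1   338   300   372   334 poppy
#> 2   199   367   238   406 poppy

nrow(plan_windows(5472, 3648))             # 126 windows tile a full frame

det <- build_detector(detector_config(width_mult = 0.25), seed = 1)
det
#> <poppy_detector> backbone mobilenetv2 (width x0.25), input 416,
#>   SPP 'first', 12068 parameters
sapply(1:3, spp_filter_size, map_size = 13)  # 13 7 5
```

The numbers mean: one pixel covers 0.82 cm of ground at 30 m, so the two
generated plots span ~34–39 px; a full UAV frame needs 126
non-overlapping 416-px windows (13 + 1 edge columns × 8 + 1 edge rows);
the quarter-width detector has 12,068 trainable scalars — small enough to
train on a laptop CPU in minutes. A full train/detect/evaluate round trip
is in `tests/testthat/test-acceptance.R` (criterion 6) and via the CLI:

```sh
inst/cli/poppydetect simulate --config run.json
inst/cli/poppydetect train    --config run.json
inst/cli/poppydetect detect   --config run.json
inst/cli/poppydetect evaluate --config run.json
```

with a JSON config holding one section per stage (see `?run_stage`).

## Scope notes

The package trains and evaluates at desk scale on synthetic scenes; it
does not attempt to reproduce field-data accuracy figures, which require
the original (undeposited) UAV corpus and GPU-scale training. Rasters are
read and written as portable pixmaps (PPM); annotations use the
Pascal-VOC XML dialect written by labelImg. See
`vignettes/poppydetect-methods.Rmd` for the full methods discussion.
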