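---
title: "A simplified anchor-free detector for fruit counting: model, training and audits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A simplified anchor-free detector for fruit counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the design

Fruit detection in orchards has to cope with dense clusters, leaf and
branch occlusion, changing light, and — if the model is to run on a phone
or an embedded board — a tight budget of parameters and of operator types
that the deployment runtime must support. `simplifruit` implements a
detector designed around that budget: the backbone and neck use only four
primitive blocks (convolution, max-pooling, channel concatenation, one
SPPF pyramid-pooling block), arranged in 32 indexed blocks, with a
decoupled anchor-free head at strides 8, 16 and 32. Replacing composite
blocks (residual/CSP-style units) with plain convolutions and pooling
makes the exported compute graph short and uniform, which is what makes
the network easy to convert and fast on small CPUs.

## Topology

Blocks are declared as data ([`layer_spec()`], assembled by
[`build_simplified()`] or read from `inst/extdata/simplified.yaml`):
stride-2 3×3 convolutions at blocks 0, 1, 26 and 29; 2×2 downsampling
max-pools at 4, 10 and 16; 1×1 convolutions at 2, 5, 7, 9, 11, 13, 15,
17, 22, 25, 28 and 31; 3×3 stride-1 convolutions at 3, 6, 12 and 18;
backbone concatenations at 8 (joining 5 and 7) and 14 (joining 11 and
13); SPPF at 19; nearest-neighbour upsamples at 20 and 23. The neck is a
standard FPN + PAN fusion: concatenation 21 joins the upsampled SPPF
output with the stride-16 backbone skip (block 15), 24 joins the next
upsample with the stride-8 skip (block 9), 27 joins the stride-2
downsample 26 with neck block 22, and 30 joins downsample 29 with the
SPPF output 19. Blocks 25, 28 and 31 (80×80, 40×40 and 20×20 cells at a
640-pixel input) feed the head.

Two wiring choices were genuinely open. First, block 30 could
concatenate either the SPPF output directly or an intermediate 1×1
projection; both leave the operator census unchanged, but only the direct
connection is consistent with the calibrated parameter budget, so it is
canonical (and noted in the YAML config). Second, the published
description fixes block kinds and totals but not per-block channel
widths. The widths are therefore *calibrated free parameters*: a
conventional halving/doubling schedule (stem 16/32; stage outputs 64, 128,
256; SPPF hidden 128; neck fuse widths equal to the scale widths; head
branch width 64) with the two bottleneck hidden widths set to 64
(stride-8 stage) and 96 (stride-16 stage) so that the assembled network's
totals reproduce the published figures. The schedule was frozen once in
`simplified.yaml` and is not a tuning surface.

## Parameter and layer accounting

`count_params()` follows the convention `i·k²·o + o` per convolution,
with the bias slot realized as the batch-norm scale/shift pair (2·o) on
normalized convolutions — batch norm is folded into the convolution at
deployment, but its affine parameters are trainable and belong in the
budget — and as a plain bias (o) on the six final prediction
convolutions. The assembled 3-class detector has 1,789,657 parameters
(1.8 M at one decimal). A test cross-checks this against a brute-force
enumeration of every initialized weight container in the engine.

"Layers" is a convention-bound quantity, so `module_census()` pins the
convention by calibration: it enumerates unique modules of the fused
model tree (batch norms folded, the shared activation object counted once
per model), which reproduces the published 168 for the reference YOLOv8n
assembled from its block table (`reference_module_census()`). One freedom
remains that the calibration cannot pin — whether a top-level downsampling
pool is a bare pooling primitive (1 module) or a named block wrapping it
(2 modules); YOLOv8n has no top-level pools. The wrapper convention is
adopted, mirroring how every other named block wraps its primitives, and
yields 104 for the simplified network.

## The exported graph

`export_graph()` writes the full compute graph in an interchange JSON
with ONNX operator vocabulary: one `Conv` node per convolution, each SiLU
decomposed into `Sigmoid` + `Mul`, `MaxPool` per pooling, `Resize` per
upsample, `Concat` per concatenation, and the head's
`Reshape`/`Concat`/`Transpose` output plumbing. The exported graph stops
at the raw head outputs (class logits, bin logits): decoding and NMS are
host-side, which keeps `Add` and `Slice` out of the graph entirely.
`read_graph_census()` recounts operators from the file so the on-disk
graph can be audited independently of the in-memory topology.

## Losses and assignment

Box regression uses the complete-IoU loss in its cited closed form,
`1 − IoU + ρ²/c² + αv` with `α = v/((1 − IoU) + v)`. A bare sum of an
overlap *area*, a *distance* and an aspect term would be dimensionally
inconsistent, so the schematic three-term description is read as this
standard form. The training gradient treats `α` as a constant
(detached-alpha convention); the test suite verifies the analytic
gradient against finite differences of the alpha-frozen loss.

Each box side is a discrete distribution over `reg_max = 16` bins; the
distribution focal loss places mass on the two bins bracketing the
continuous offset, and decoding takes the softmax expectation. With the
stated weights the objective is
`7.5·L_CIoU + 0.5·L_BCE + 1.5·L_DFL`. (The weighted sum of unit
components is 9.5.) Probabilities are clamped to `[1e−7, 1 − 1e−7]`
before logarithms; DFL targets are clipped to `[0, reg_max − 1.01]`.

Anchor-free assignment is not specified by the architecture description,
so the reference framework's task-aligned scheme is used: anchors sit at
cell centers (half-cell offset, strides 8/16/32); for each ground truth
the top-10 in-box anchors by `score^0.5 · IoU^6` become positives; an
anchor claimed twice keeps the higher-alignment truth. Losses are
normalized by the number of positive anchors in the batch; classification
targets are hard one-hot labels (the soft, alignment-weighted variant is
a known alternative; hard targets keep the BCE definition exact).

## Training recipe

Defaults in [`train_config()`] are the study's recipe: 640×640×3 input,
batch 9, 100 epochs from scratch, SGD momentum 0.937, weight decay
0.0005, NMS IoU 0.7, mosaic probability 1.0, HSV gains 0.015/0.7/0.4,
scale ±0.5, translate ±0.1. The learning rate is not part of that recipe;
the reference default is adopted (0.01, short linear warmup, linear decay
to 1% over the run) and surfaced in the config rather than asserted as
the authors'. The inference confidence threshold defaults to 0.25;
tabulated precision/recall are reported at that threshold, while the AP
sweep uses all detections. All randomness (initialization, shuffling,
augmentation draws) flows from a single seed, and runs are
single-threaded deterministic.

The engine is written from scratch: feature maps are `C × (H·W)`
matrices, convolution is im2col + GEMM (BLAS), batch norm is computed
over the whole batch with running statistics (momentum 0.1) used at
inference, and backpropagation is hand-derived per primitive. A
finite-difference test validates the end-to-end gradient through
concatenation, SPPF, pooling, upsampling and batch norm.

## What the synthetic scenes do and do not show

`generate_scene()` renders elliptical fruit with class-specific palettes,
shading, leaf-shaped occluders, background clutter and a directional
lighting gradient; labels are the tight ellipse boxes *before* occlusion,
matching the practice of annotating the whole fruit even when hidden.
`generate_video()` translates the same targets rigidly over a fixed
background. The scenes exercise geometry end to end — exact labels make
mAP and counting decidable — but they are not photorealistic: no
perspective, no within-class shape variety, no motion blur, no exposure
changes. A detector that overfits these scenes demonstrates that the
architecture, losses, assignment, decoding, NMS, metrics and tracker are
wired correctly; it says nothing about accuracy on real orchard imagery,
which requires the real dataset and GPU-scale training.

Test-scale problem sizes, chosen once: scenes are rendered at 160 px with
5 targets and trained at a 128-px network input. The memorization check
fits 8 independent scenes for 300 iterations without augmentation and
evaluates on those same images (mAP@50 reaches 1.0). The counting check
overfits a 12-frame video's own frames (200 iterations, batch 9) and then
tracks all frames; a detector overfit to *other* scenes emits
near-duplicate boxes on translated targets that the loose NMS (IoU 0.7,
as specified) does not merge, which inflates unique-track counts — a
faithful reproduction of why trackers need detectors that are reliable on
the footage they count.

## Tracking and counting

`update_tracks()` is a deliberately minimal tracker: greedy highest-IoU
association above a 0.3 gate, same class only, one detection per track;
unmatched detections spawn tracks, tracks missing for 30 frames retire,
and a track counts once it has been matched in 3 frames. Counts are
unique confirmed track identities over the whole video, which is
monotone non-decreasing by construction. No motion model or appearance
embedding is used; the counting semantics only require stable identities
under small inter-frame displacements.

## Numerical choices and degenerate inputs

* Boxes are pixel corners, 0-based, half-open; degenerate (zero-area)
  boxes are rejected by the losses.
* Empty label files, images with no targets, frames with no detections,
  and classes with no ground truths are all legal; the last are excluded
  from mAP with a message rather than scored zero.
* Average precision uses 101-point interpolation over the monotone
  precision envelope, with a trapezoid rule available as a cross-check.
* Matching and NMS break confidence ties by higher IoU, then input
  order, making results order-independent.
* Mosaic drops a clipped label when less than 10% of its area survives;
  letterbox metadata records the exact inverse transform.

## Limitations

The engine is CPU-bound R/C++ and intended for audits, method study and
small-scale experiments, not for training on real datasets at 640 px.
Videos are handled as image-sequence directories; no codec I/O is
included. The exported graph is an operator-level audit format, not a
binary runtime format.
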