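---
title: "Surrogate porosity learning on soil-core CT volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate porosity learning on soil-core CT volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Undisturbed cylindrical soil cores scanned by clinical X-ray CT yield stacks
of slices whose voxel values are Hounsfield units (HU): a linear transform of
X-ray attenuation with water at 0 and air at -1000. Deep learning on such
volumes is usually blocked by annotation cost — nobody labels hundreds of
slices per core by hand. The pipeline in `soilpore` sidesteps that with
*surrogate learning*: the training annotation is a quantity that can be
computed mechanically from the image itself, the per-slice porosity of a
selected material band. The network is then asked to regress that scalar from
a band-stacked slice image, the bet being that to do so it must internalise
the spatial structure of the soil — which is what makes the convolutional
stack reusable for other targets via transfer learning, verifiable by
grad-CAM.

## The working HU range and object classes

Scanner values in `[-2048, 4096]` HU (stones exceed the medical range) are
shifted by +2048 into `[0, 6144]`; out-of-range readings are clamped rather
than rejected, because a stray value must not abort a pipeline run. The range
is partitioned into six contiguous inclusive bands of width 1024 —
`[0,1023], [1024,2047], ..., [5120,6144]` (the top band absorbs 6144) —
called object classes 1..6. Low bands hold air/water-filled pores and organic
matter, the middle bands the soil matrix, high bands stones. Volumes are
cropped to a centered inner region (default `(400, 200, 200)` of a
640x512x512 scan) to avoid edge effects from the core cylinder; the crop is
centered on the volume midpoint with floor division for odd differences,
since no per-sample placement information exists.

## Porosity, in the wide sense

For a chosen solid class selection, a volume is binarized (selected classes
= 1 = solid, everything else = 0 = void) and each slice's porosity is

P_slice = Area(void) / (Area(void) + Area(solid)),

i.e. the fraction of 0-coded pixels, whatever fills them — air, water or
roots. The sequence of P_slice along the core axis is the porosity profile,
and it is the surrogate annotation. Before profiling, connected solid
clusters smaller than `min_size` voxels (default 60) are reassigned to void.
Three conventions here were genuinely open and are package decisions,
configurable in every call:

* **Boundary**: "smaller than" is strict — a cluster of exactly `min_size`
  voxels survives.
* **Trimmed phase**: the filter operates on the *solid* phase of the current
  mask (small solid fragments such as root pieces are dropped), because it
  is applied after the selected object has been declared solid. Trimming the
  void phase instead is possible by inverting the mask.
* **Connectivity and scope**: 26-connectivity in 3D (8 in 2D) by default —
  diagonal grain contacts are common in granular media — and trimming runs
  once on the 3D mask before profiling, so clusters spanning slices are
  sized in 3D.

Trimming can only turn solid into void, so it never decreases any slice's
porosity; with `min_size = 1` it is the identity. Both facts are asserted as
properties in the test suite, and the whole filter is checked
voxel-for-voxel against an independent connected-component implementation
built on igraph.

## The synthetic world

No real scan ships with the package; every downstream stage is exercised on
a seeded generator (`synthetic_spec()` / `generate_volume()`) that emulates
what a clinical CT of a soil core contains: a soil-matrix background
(band 3), embedded low-HU pores (band 1) as small spheres and axis-meandering
tunnels (burrow analogues), organic blobs (band 2) as ellipsoids, dense
mineral (band 4), and stones (bands 5 and 6) as spheres. Shapes are
rasterized in declared order, later shapes overwriting earlier ones, so every
voxel carries exactly one material label. Voxel HU is then drawn uniformly
inside the material's interval; since each interval lies inside its declared
band(s), band classification of the generated volume reproduces the labels
*exactly*, which keeps the ground-truth oracle exact while inputs remain
non-constant. The pipeline-fidelity property — untrimmed annotation equals
the label-derived profile to integer-count equality — is the core acceptance
check of the generator.

Two generator choices deserve explanation:

* **Size separation of organic matter and pores.** Organic bodies default to
  semi-axes of 4–10 voxels while resolved pores are spheres of radius
  1.5–3. This mirrors the physics (at ~0.35 mm resolution, visible organic
  aggregates span many voxels while individual pores sit near the resolution
  limit) and it is also what makes band-2 porosity *decodable* from the
  network input at all: bands 1 and 2 share one input channel, so the only
  route to separating them is shape. With overlapping size ranges the
  transfer target would be unlearnable by construction, at any training
  scale.
* **Depth structure.** The `heterogeneous` preset concentrates organic
  matter in the upper core and stones below it (a layered forest-soil
  analogue); `homogeneous` is a uniform sandy-grassland analogue;
  `organic_rich` and `stony` are the two contrasting regimes used in the
  compatibility experiment.

What the generator does *not* emulate: reconstruction noise, partial-volume
effects, beam hardening, or any continuous HU texture within a material. A
green test therefore establishes that the algorithms are correct and that
the protocol behaves as described on idealised data — not that the trained
desk-scale models would transfer to real scanner output.

## The regression network

The reference topology is the 16-layer VGG configuration (13 stacked 3x3
convolutions with 2x2 max pooling, then three dense layers) with the 1000-way
classification head replaced by a single linear unit so porosity can be the
target; `build_model(scale = "full")` constructs exactly that. All training
in the package's tests uses `scale = "mini"` — two conv blocks (8,8 / 16,16
filters) and a 64-unit dense layer — because the full network is a GPU-scale
object and the package must train on one CPU. The engine (forward, backward,
Adam, early stopping, layer freezing) is implemented in the package with
Rcpp/RcppArmadillo im2col kernels; no external DL framework is involved.

The network input is a 3-channel image per slice: channel 1 is the union
solid mask of object classes 1+2, channel 2 of 3+4, channel 3 of 5+6 — the
"RGB" the reference topology expects. The union-of-binary-masks convention
is a package decision (the alternative, HU min-max scaled within the band
pair, is available as `mode = "hu"`); binary is the default because the rest
of the pipeline operates on binary masks. Rather than padding inputs to the
full network's canonical 224x224, `build_model()` adapts the first dense
layer's width to whatever extents the input has (any size the pooling depth
allows: >= 32 at `scale = "full"`, >= 4 at `scale = "mini"`), which preserves
the conv topology exactly while avoiding an arbitrary padding convention.

Training minimises mean squared error with Adam (default learning rate 1e-3,
batch 32, up to 80 epochs) and early stopping on held-out RMSE (patience 10,
best weights restored); the reported metric is RMSE. The output unit is
linear; predictions are clipped to `[0, 1]` at inference only. The 80/20
split defaults to slice level — the protocol's wording mentions no grouping —
with a per-volume grouped split available (`by_volume = TRUE`) for
leakage-free experiments. Optimiser, rate, batch and patience are
unspecified in the source protocol and are desk-scale package defaults,
fully exposed in `train_config()`.

The negative control used in the acceptance suite deserves a note: the
shuffled-target control permutes targets everywhere the control model can
see them — training *and* early-stopping validation — and only the final
evaluation uses true targets. Validating the control on true targets would
let epoch selection leak the very signal the control is supposed to be blind
to, biasing its RMSE below the constant-predictor baseline.

## Transfer learning

`freeze_conv()` marks the convolutional stack non-trainable;
`transfer_train()` then retrains only the dense head on a different
surrogate target. Conv weights are bit-identical before and after (asserted,
not assumed). Because the frozen stack is a fixed function, its features are
precomputed once per dataset, which is why dense-only runs are much cheaper
than full training — the same asymmetry the original protocol reports. The
dense head is re-initialised (seeded) before transfer by default: the
protocol is silent on this, and warm-starting from the old head risks
trivial carry-over when the two targets correlate. Fine-tuning of the top
conv block is deliberately not part of the default protocol (it is mentioned
in the source only as an option). Transfer is expected to fail sometimes;
failures surface as RMSE numbers, never as hidden exceptions.

## Compatibility screening

With one trained model per core, `rmse_matrix()` evaluates every model on
every core's full surrogate dataset. `select_representatives()` then runs
the greedy loop: model i is compatible with sample j iff RMSE(i,j) < 0.04
(strict, the stated convention); each round picks the model covering the
most remaining samples, removes them, and repeats; samples no model covers
are reported explicitly as uncovered — the original summary's counts do not
add up to the sample count, and uncovered samples are the natural reading.
Ties (equal coverage) break by lowest mean RMSE over the covered set, then
by model name; a model's own core counts toward its coverage (both
configurable). Greedy is reproduced deliberately; no optimal set-cover
solver is attempted.

## Grad-CAM for a scalar head

Classic grad-CAM differentiates a class score; with a (1x1x1) head the
scalar porosity output is differentiated directly — the only consistent
reading. For a chosen conv layer (default: the last one), per-channel
weights are the spatial means of the gradient of the output with respect to
that layer's post-activation maps; the map is the rectified weighted sum,
bilinearly upsampled to the input extents and then max-normalised (an
identically zero map is returned as-is, and normalisation after upsampling
guarantees the delivered map peaks at exactly 1). The implementation is
checked against a symbolic hand computation on a fixed one-conv-layer model,
and a localisation property on the trained model: with all target-band
material confined to one half-plane of a probe slice (the other half inert
stone), at least 60% of heatmap mass falls in that half.

## Numerical and degenerate-input conventions

* `shift_hu` is total (clamping) and monotone; verified over a range sweep.
* Odd trailing rows/columns are dropped by 2x2 pooling (valid-pooling
  convention); `build_model` rejects inputs smaller than the pooling depth
  allows.
* Non-finite training loss aborts with diagnostics (epoch, batch,
  prediction range) rather than being swallowed.
* Zero-size slices, empty class selections, empty datasets and empty RMSE
  matrices are errors, not silent results.
* All randomness (generation, splits, initialisation, shuffling) is seeded
  through function arguments; a seeded end-to-end run reproduces history
  bit-for-bit on one thread.

## Known limitations

* The DICOM codec reads/writes the Explicit-VR-Little-Endian tag subset the
  pipeline needs (geometry, rescale, 16-bit pixel data); it is not a
  general DICOM implementation and will refuse exotic transfer syntaxes.
* Desk-scale (`mini`) results demonstrate protocol behaviour, not
  full-scale model quality; the full topology is constructed and
  shape-checked but never trained in the tests.
* The generator's materials are piecewise-uniform in HU; nothing in the
  package models scanner physics.
* Training is single-threaded CPU; there is no GPU path.
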