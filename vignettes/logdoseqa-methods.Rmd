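---
title: "Log-file based 3D dose QA: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-file based 3D dose QA: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logdoseqa)
```

## The problem

Pre-treatment patient-specific QA asks whether the dose an accelerator will
actually deliver matches the dose the treatment planning system (TPS)
computed. Delivery log files record the machine state at every control
point — both MLC leaf banks, the cumulative monitor units (MU), the gantry
angle — and therefore carry everything needed to reconstruct the delivered
fluence without any measurement hardware. `logdoseqa` implements the full
chain from such records to quantitative 3D dose comparison, plus a
volumetric network that learns the mapping from delivery geometry to dose.

This vignette documents the models, the conventions that are *choices*
rather than physics, and the reasoning behind each choice, so a maintainer
can tell contract from accident.

## Delivery records

A plan is `plan -> beams -> control points`. Leaf positions are isocenter-
plane coordinates (cm) along the leaf-travel axis; pair *i* is open on the
interval `[bank_b[i], bank_a[i]]`, so *closed* is a zero-length interval —
a convention chosen because it makes emptiness testable exactly. Cumulative
MU must be non-decreasing; validation (`validate_delivery()`) reports every
violation with beam, control point and rule rather than stopping at the
first.

**MU weighting.** Logs store *cumulative* MU. A fluence map per segment is
weighted by the *increment* ΔMU over that segment, not the cumulative
value: cumulative weighting would count early apertures once per subsequent
segment, breaking the linearity that lets a beam's total fluence equal the
sum of its segments. Step-and-shoot delivery also fixes the segment's
gantry angle to its starting control point (the gantry is static while the
beam is on).

**Interchange formats.** Vendor binary trajectory logs are deliberately out
of scope; the canonical interchange is a documented CSV dialect (one row
per control point, 4-decimal positions) and an equivalent JSON mirror of
the types. Positions are rounded to the dialect's precision by the plan
generator so that `read(write(p))` is exact.

## Fluence model

The aperture is rasterized on a beam's-eye-view grid (default 0.25 cm —
the finest HD120 leaf width — 160×160 pixels) by *exact area weighting*:
each pixel's value is the fraction of its area inside the aperture,
computed separably as the product of 1D interval overlaps (leaf gap × leaf
band), summed over pairs. Compared to pixel-centre membership tests this
removes grid-alignment artifacts and makes the rasterization testable
against a closed form: the pixel sum times pixel area equals
`sum_i (a_i − b_i) · width_i` to 1e-9 (it is exact up to float rounding).

Two consequences of the defaults are worth stating:

* The default 40×40 cm grid is wider than the 22 cm leaf bank on the
  leaf-width axis. Pixels beyond the bank have no leaves to open and are
  treated as blocked (zero) — erroring there would make the default grid
  unusable with the default geometry.
* No transmission, tongue-and-groove, rounded leaf ends or output factors:
  the fluence is purely geometric. That is the model this pipeline is
  defined on, not an approximation we intend to refine.

## Projection: 3D-DDA with inverse-square deposit

The patient frame is fixed: x lateral, y longitudinal, z up; lengths in cm.
The source sits at `iso + SAD·(sin g, 0, cos g)` for gantry angle `g`
(gantry 0 = source above the isocenter), SAD = 100 cm (the standard C-arm
geometry; configurable). The BEV leaf-travel axis rotates with the gantry;
the leaf-width axis is the longitudinal axis. Couch and collimator are
assumed zero: the targeted plans are coplanar step-and-shoot.

For every open pixel a ray runs from the source through the pixel's
isocenter-plane position. An Amanatides–Woo incremental traversal
enumerates the voxels the ray crosses in order, with chord lengths that sum
to the in-grid path length to 1e-9 relative. Each visited voxel accumulates
`w · (SAD/d)²`, `d` the source-to-voxel-centre distance — deposition *at
the voxel centre without chord weighting* is the default because the model
assigns each traversed voxel an attenuated pixel value; a chord-weighted
mode (`deposit_mode = "chord"`) and sub-pixel supersampling (1/2/4 per
axis) exist as config options, default off. There is deliberately no
CT-density-dependent attenuation: the projected volume is a geometric
encoding of the delivery, and the CT enters the model as its own channel.

Numerical edge cases: a ray that misses the grid yields an empty traversal
(not an error); a source inside the grid is rejected as degenerate;
boundary ties in the traversal resolve by the smallest next-crossing axis,
and sub-sample-width corner slivers are the one place where the dense-
sampling oracle used in tests cannot distinguish implementations (the test
treats chords below the oracle's own resolution accordingly).

## Registration, resampling, normalization

All inputs from one planning session are assumed to share a frame of
reference, so "registration" is resampling within that frame — no rigid or
deformable estimation is attempted (no algorithm is defined for it in this
scope). Scalar volumes resample trilinearly, masks by nearest neighbour
(so they stay binary and never acquire labels absent from the source);
out-of-grid points take −1000 HU (CT), 0 (dose/projected/mask).

The common cubic grid is derived from the *body mask*: cube side = largest
bounding-box extent plus one voxel, centred on the body centroid, split
into n³ voxels (n = 128 at full scale; 24–32 desk scale). When the inputs
already sit on a shared cubic n-grid the sample is returned unchanged —
this explicit shortcut is what makes assembly exactly idempotent;
recomputing the grid from a resampled body mask would drift by fractions
of a voxel each time.

For the network, CT is clipped to [−1000, 1000] HU and mapped to [0, 1];
the projected volume is scaled by its own maximum (recorded, so the
transform inverts); dose is divided by the prescription so "1.0" always
means "prescription dose". The dose transform inverts exactly, which the
round-trip test asserts at 1e-12.

## The network

An 18-ConvBlock volumetric encoder-decoder with *group supervision*:
blocks 1–12 form the encoding group, 13–18 the decoding group. Each block
additionally feeds a 1×1×1 convolution, upsampled to input resolution,
into its group's feature pyramid; the group fuses its pyramid into a
prediction that carries its own loss, so gradients reach every block by a
short path regardless of depth. The total objective is

```
loss = w_enc·[L1+MSE](enc_pred) + w_dec·[L1+MSE](dec_pred) + w_f·[L1+MSE](final)
```

with unit weights by default (no weighting is prescribed anywhere
authoritative). L1 and MSE are *summed*: the two are reported together as
the training criteria, and summing is the one reading that uses both in
training; treating one as a monitor-only metric would leave the choice of
which unexplained.

Internals that are design choices (config-exposed, defaults below):

* ConvBlock = one 3×3×3 convolution → instance norm → ReLU. Instance
  normalization because the batch size is 1, making batch statistics
  degenerate.
* Encoder stages of three blocks; resolution halves via a stride-2
  convolution entering blocks 4, 7 and 10; channels double per stage from
  `base_channels` (16 full scale, 4 desk scale). The decoder mirrors this
  with trilinear 2× upsampling before blocks 13, 15 and 17.
* Pyramid fusion is a learned linear combination (a 1×1×1 convolution over
  the stacked side outputs), initialized to the uniform average.
* The final head is a 1×1×1 convolution on block 18.
* Skip connections, attention, depthwise-separable convolutions, pyramid
  pooling and data augmentation are *not* in the default model: they are
  mentioned only loosely in the source material, with no specification to
  implement faithfully.

Training uses Adam at lr 6e-4, batch size 1, cycling through the samples;
everything (initialization included) derives from one config seed, so a
fixed-seed run is bit-reproducible on one machine. There is no GPU path:
the forward/backward passes are hand-written R (im2col gathers + BLAS
multiplies, sparse upsampling operators) because no deep-learning
framework is available in the target environment. At the desk-scale
profile (24³, 4 base channels) a 200-step overfit run takes ~2.5 minutes
on one CPU; the full-scale profile type-checks but is not a practical CPU
training target, and reproducing any clinical-scale result is explicitly
out of scope.

## Comparison metrics

* `MAE`/`RMSE` over a mask; `MAE ≤ RMSE` always (asserted property).
* DVH: the plotted curve is binned (default 0.05 Gy), but point indices
  D<sub>x</sub> are computed on the *sorted voxel doses* (the
  `ceil(x/100·n)`-th largest) to avoid binning bias; V<sub>x</sub> is the
  exact fraction ≥ x Gy. The reported clinical set is PTV
  D95/D98/D99/Dmax/Dmean; V5/V20 + mean dose per lung and combined; cord
  Dmax; heart V30/V40 + mean heart dose.
* Isodose Dice: at each level k (% of prescription D_P), threshold both
  distributions at `h = k·D_P/100` inside a region mask and compute
  `2|A∩B|/(|A|+|B|)`, defined as 1 when both sets are empty. The region
  defaults to the *body*: published isodose comparisons extend far outside
  any PTV (5 Gy isodoses span the thorax), so a PTV-bounded region — which
  one reading of the defining text suggests — is supported via the mask
  argument but is not the default.
* Mean relative deviation per index = mean over cases of `|pred − ref|/ref`
  (0/0 counted as 0) — the printed quantity has no published formula, and
  this is its plainest reading.
* The paired test across cases is a two-sided Wilcoxon signed-rank test:
  DVH index differences are small-sample and non-normal, and no test is
  named by the source; with one case the p-value is NA by construction.
* Bland–Altman: mean difference ± 1.96·SD (sample SD). The empirical
  coverage check in the tests allows ≥93% on large Gaussian samples
  (sampling noise around the nominal 95%).

## The synthetic world

The phantom is a geometric thorax: elliptical-cylinder body (semi-axes
11×9 cm), two ellipsoidal lungs (3.6×8×5 cm), a 2 cm-radius spherical PTV
inside the left lung, a 3 cm-radius heart, a 0.5 cm-radius spinal-cord
cylinder; HU body 0, lung −700, PTV 20, cord 300, heart 50. Default grid
64³ at 0.4 cm (the 24³ desk profile uses 1 cm voxels — at that spacing the
0.5 cm cord voxelizes to empty, which downstream code must and does
tolerate). The plan is 7 equi-spaced coplanar beams (a typical thoracic
IMRT class solution), 5 segments each, 600 MU total (a realistic
per-fraction output for a 2 Gy fraction), apertures conformal to the PTV's
divergent BEV projection with a 0.5 cm margin and 0.1 cm per-segment leaf
modulation.

The pseudo-reference dose is the projected volume smoothed with an
isotropic 0.8 cm Gaussian (a typical thoracic beam-penumbra scale), then
scaled so PTV D95 equals the prescription exactly — the clinical plan
normalization rule ("95% of the PTV receives 100% of the prescription").
It has dose-like gradients and exact DVH anchors, but it is **not** a
physical dose: no depth dose, no build-up, no heterogeneity. Consequently
a green end-to-end test establishes that the *pipeline and metrics* are
correct and self-consistent — conservation, normalization, identity
comparisons, monotone degradation under log perturbations — and does not
establish dosimetric accuracy against a TPS, which would require clinical
data this package cannot ship.

The perturbation generator (`make_actual_log()`) injects seeded Gaussian
MLC errors (clamped to keep every pair ordered), a global MU scale and
per-beam gantry jitter, supporting the sensitivity analysis pattern:
projected-volume isodose agreement at the 50% level degrades monotonically
as MLC noise grows through 0 / 0.1 / 0.5 / 1.0 cm.

## Numerical conventions

* Geometry identities (area conservation, chord totals, opposed-beam
  symmetry) are tested at 1e-9; exact-arithmetic identities (round-trips,
  normalization inverses, idempotency) at 1e-12 or bitwise.
* Voxel membership: a voxel belongs to an ROI iff its centre is inside the
  shape, consistent with nearest-neighbour resampling.
* D<sub>x</sub> tie-break: the greatest dose whose coverage still reaches
  x% — on ties this is the sorted-order voxel value itself, so uniform
  regions return their dose exactly.
* Predicted dose is clamped at 0 Gy after denormalization.
* NIfTI-1 I/O is implemented in-package (no R NIfTI package exists in the
  target stack): 3D volumes, diagonal sform affines, little-endian write,
  both endiannesses on read, uint8/int16/int32/float32/float64, mm units
  (internal cm are converted). An independent Python reader verifies the
  format in the test suite.
* All randomness (plan modulation, perturbations, weight initialization)
  flows from explicit integer seeds; generators restore the caller's RNG
  state.

## Known limitations

No physical dose engine; no DICOM-RT import (voxel masks and NIfTI only);
no dynamic (sliding-window) delivery — segments are static by assumption;
no gamma-index analysis; the network's full-scale profile is untrainable
on CPU within reasonable time and is provided for completeness of the
architecture, not for use.
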