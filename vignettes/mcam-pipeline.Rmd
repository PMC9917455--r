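---
title: "Models and methods behind the mcamtk pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the mcamtk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mcamtk)
```

`mcamtk` models a multi-camera array microscope (MCAM): a rectangular grid
of micro-cameras with partially overlapping fields of view whose raw frames
are computationally combined into one large mosaic, and from which organism
positions, depths, identities and behavioural statistics are extracted.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the simulator does and does not capture.

## Optical model

Every geometric conversion uses a thin lens: an object at distance $u$ from
a lens of focal length $f$ images with lateral magnification
$m = f/(u-f)$. The default hardware description is a 10-megapixel sensor
(4320×2432 px of 1.4 µm) behind a 25 mm, NA 0.03 lens at roughly 150 mm
working distance, on a 19 mm grid pitch. At $u = 150$ mm, $m = 0.2$, one
pixel samples 7 µm of object space, a camera sees 30.24 mm × 17.02 mm, and
an 8×12 array spans roughly 24 cm × 15 cm.

Resolution metrics follow the Rayleigh forms: lateral $0.61\,\lambda/NA$
and axial $\lambda/(2\,NA^2)$. The illumination wavelength is a parameter
of `camera_spec()` with default $\lambda = 0.50$ µm (mid-visible green);
with NA = 0.03 this gives a 0.278 mm axial depth of field and a 10.2 µm
lateral limit. The thin-lens model deliberately excludes aberrations,
distortion, and f-number-based depth-of-field formulas.

Overlap between adjacent cameras is reported honestly as
$(\mathrm{FOV}-\mathrm{pitch})/\mathrm{FOV}$ per axis and may be negative
(a coverage gap). With the printed geometry at $u = 150$ mm the long-axis
overlap is 37% and the short axis has a small gap; stereo depth needs at
least 50% long-axis overlap so that every point is seen by two cameras.
Because no working distance reproduces all of the hardware's quoted overlap
percentages simultaneously under a thin lens, the package ships two
presets: `paper96` ($u = 165$ mm, both axes non-negative: ~43% / ~0.2%) and
`paper96_u150` ($u = 150$ mm exactly as printed). `desk6` is a 2×3 toy
array (200×150 px at 20 µm, 100 µm object pixels, 50%/33% overlap) that
keeps every end-to-end experiment seconds-fast; the methods are scale-free
so nothing but pixel counts changes at full size.

## Stereo disparity

Two adjacent cameras with parallel axes and baseline $B$ see a point at
object distance $u$ displaced on the sensor by
$s = fB/(u-f)$, hence $u = f\,(1 + B/s)$ — the two functions are exact
inverses and disparity decreases monotonically with distance. At the
printed geometry the focal-plane disparity is 3.8 mm (2714.3 px) and one
pixel of disparity corresponds to about 46 µm of depth, which sets the
scale for the expected ~100 µm-class depth accuracy.

## The simulator

`render_frameset()` projects world points into each camera as
$s = -m(u)\,(p - c)$ about the image centre, where $c$ is the camera centre
and $u = u_0 - z$ (z positive toward the cameras). Within one camera the
model is locally telecentric — perspective parallax enters only *between*
cameras through the baseline, which is exactly the disparity model above.
Rendering adds, in order: a cos⁴ field-angle vignette, band-limited
value-noise background texture (a deterministic function of world
coordinates, so all cameras see consistent texture), organisms as
multiplicative absorbance layers, per-organism Gaussian defocus with
$\sigma_{object} = 0.5\,|z|\,NA$ (in object units; the linear small-defocus
model), optional RGGB Bayer sampling, Poisson shot noise (20 000 full-scale
photons by default, i.e. ~0.7% shot noise at typical levels — a
well-exposed CMOS operating point), Gaussian read noise (0.3%), and 8-bit
quantization. All randomness derives from one integer seed; identical seeds
give bit-identical framesets.

Organisms are parametric: fish (tapered body around an articulated
midline, oriented dark eyes, and a per-individual melanophore-like pattern
of near-black blotches generated from an identity-specific noise seed),
worms (thin articulated tubes), blobs, and textured point beads (the stereo
targets). `simulate_session()` moves organisms by a smooth random walk —
gamma-distributed per-step speeds (mean 5 mm/s by default, matching slow
larval cruising), heading diffusion, wall reflection, optional bounded z
walk within ±2.5 mm (the usable depth range).

What the simulator does *not* emulate — and what passing tests therefore do
not show about real data: photorealistic appearance, refraction at the
water surface, illumination flicker, rolling-shutter or synchronization
artifacts, camera rotations/tilts (stitching is translation-only by
design), and inter-camera parallax *within* an organism (organisms are
rendered at a single depth each). In particular the two members of a
simulated stereo pair differ only by translation plus independent noise, so
the simulated depth RMS (a few µm) is a best case; the printed ~100 µm
figure for hardware includes optical and calibration effects the simulator
deliberately omits, which is why the acceptance check is an upper bound.

For scale, full-sensor rendering is reserved for small arrays; stereo
experiments render per-camera sensor *windows* (`render_camera_roi()`)
around the objects of interest, so the full 4320×2432 geometry is exercised
without allocating gigapixels.

## Flat-field correction and demosaicing

The reference is the per-pixel mean of (by default) five out-of-focus
diffuser framesets, divided by its own global mean — a unit-mean gain image
per camera that captures vignetting and pixel sensitivity. Correction is
division only (no dark-frame subtraction; the hook is a no-op extension
point) and per-pixel rather than per-camera-scalar, because only the
per-pixel form actually removes vignetting. Near-zero gains (dead pixels)
are floored at $10^{-3}$ of the mean and counted in the report.
Demosaicing is plain bilinear interpolation of the RGGB mosaic (mask-
normalized convolution, so edges are exact); fancier methods add nothing
for downstream geometry.

## Stitching

`register_pair()` crops the predicted overlap of two neighbouring images
and estimates the residual translation by normalized cross-power-spectrum
(phase) correlation under a Hann window. Sub-pixel refinement uses the
side-lobe ratio $\delta = r_{+1}/(r_{+1}+r_0)$, which is exact for the
Dirichlet-shaped peak of an ideal sub-pixel translation (a quadratic fit
systematically underestimates it). Confidence is the ratio of the main
peak to the second peak outside a 5×5 exclusion zone; pairs below 1.5 are
flagged, weighted down (weight = confidence, floored at 0.05), but never
dropped unless a camera becomes disconnected — that is an error naming the
camera.

`calibrate_template()` registers all rook-adjacent pairs and solves the
per-camera translations by weighted least squares with camera (0,0)
anchored, then stores per-pair residuals. The camera model is
translation-only: rigidly mounted sensors have no relative rotation to
first order, and any residual rotation shows up in the pair residuals
(flagged above 2 px). Templates are estimated once from a feature-rich
calibration scene and reused for every subsequent frame — biological scenes
are too sparse to register reliably, which is why the calibration scene
generator exists. Blending is linear feathering with renormalization (the
weights form a partition of unity wherever any camera contributes);
fractional offsets are honoured by bilinear resampling at placement time.
Mosaic pixels no camera covers carry no data and are filled with the mean
covered intensity rather than zero, so they cannot masquerade as dark
objects. Out-of-plane objects can ghost in overlaps (translation-only
stitching is calibrated at the focal plane); this is a documented
limitation, not a defect.

## Tiled detection

Mosaics are larger than any detector wants to see, so `detect_tiled()`
runs a plug-in detector (contract: tile image in, boxes/scores/labels out)
over an overlapped tile plan, lifts boxes to mosaic coordinates, and
de-duplicates with greedy per-label non-maximum suppression (IoU threshold
0.5 by default; exact duplicates are suppressed at any threshold). Boxes
hugging a tile's interior border defer to a neighbouring tile that contains
them fully — a truncated view of an object the neighbour sees whole — which
makes the output stride-invariant provided the stride leaves at least one
object-diameter of overlap. The default tile is 1024 px with a 300 px
overlap margin (twice a 150 px maximum object extent). Failures of the
detector on individual tiles are recorded and the remaining tiles proceed;
only total failure is an error.

The shipped `reference_blob_detector()` is a classical
difference-of-Gaussians band-pass with polarity-aware *absolute*
thresholding (a per-tile relative threshold would hallucinate objects in
empty tiles), morphological closing to keep elongated bodies single, and
connected-component boxes. It is a desk-scale stand-in satisfying the same
contract as a learned detector; scores are normalized per tile to [0, 1].
`occluder_augment()` pastes masked organism crops with a controlled
pairwise box-IoU range and returns exact ground-truth boxes, for building
occlusion-robust training sets.

## Stereo depth measurement

Following detection, `extract_features()` finds Harris corners (with
sub-pixel quadratic localization — integer corners would quantize all
displacements identically and bias the mean disparity by up to half a
pixel) and attaches 256-bit binary descriptors built from pairwise
intensity comparisons on a fixed smoothed sampling pattern.
`match_features()` pairs descriptors by minimum Hamming distance with a
distinctiveness ratio (0.85) and a mutual-best check. `object_disparity()`
takes the displacement component along the baseline axis, rejects outliers
beyond 3 MADs on both components (the orthogonal component carries no
signal and is pure noise), and returns the mean over at least 3 survivors.
`estimate_depth()` converts through the thin-lens relation; in `track_3d()`
the calibrated stitching template supplies the focal-plane base disparity
(a one-point calibration of $B\,f$), and detections outside any two-camera
zone keep their lateral position with z flagged unavailable.

`depth_accuracy_sim()` is the package's depth-accuracy experiment: textured
1.2 mm beads uniformly placed over z ∈ [−2.5, 2.5] mm in the overlap zone
of an adjacent pair at the full printed geometry, rendered as 256 px sensor
windows with default noise, measured by the full pipeline. The acceptance
script runs 5 seeds × 20 beads (~100 measurements, about half a minute on
one CPU).

## Tracking and identity

Frame-to-frame linking is optimal gated assignment: pairs beyond the
displacement gate are inadmissible, dummy rows/columns price starting or
skipping a track at the gate cost, and the square problem is solved by an
$O(n^3)$ shortest-augmenting-path solver (property-tested against
exhaustive permutation). Tracks close after `max_gap` missed frames;
re-appearances start new tracks (re-identification is the embedder's job).

The identity embedder follows the triplet-loss recipe: three blocks of two
3×3 convolutions with ReLU and a 2×2 max pool, two fully connected layers,
64-dimensional output, trained with Adam on
$L = \max(0, \lVert a-p\rVert - \lVert a-n\rVert + m)$ with un-squared
Euclidean distances (a squared variant is available by flag). Outputs are
L2-normalized — the standard stabilization for triplet training — and the
margin defaults to 0.2 on the unit sphere. The forward/backward passes are
implemented directly (im2col convolution, explicit gradients, verified
against numerical differentiation); no deep-learning runtime is required.
Defaults mirror the full-scale recipe (62 epochs, batch 32); the desk-scale
experiments in the tests use 32 px inputs, 8 identities and 20 epochs,
which train in about two minutes on one CPU. Datasets are split
*temporally* — augmented training images come only from the earliest 80% of
frames, test images from the later 20% — never randomly across time, and
the 9-identity × 250-image configuration yields the 1800/450 split by
construction. Augmentation (small rotations, a midline flip, brightness
jitter, sub-crops) is a stand-in for an unspecified full-scale pipeline.
Identity crops are assumed orientation-normalized (as a tracker provides);
embedding collapse (all-identical training images) is detected and flagged
rather than silently accepted.

## Behaviour metrics

Occupancy maps are 2-D histograms normalized to total mass 1. Tail and eye
kinematics operate on single-organism crops: Otsu binarization, largest
component, Zhang–Suen thinning, longest-geodesic path (which prunes short
spurs), orientation by putting the wider end — located by the distance-
transform — first, then a running-mean smoothing and a sub-pixel
re-centring of each midline point onto the distance-transform ridge along
the local normal. The re-centring matters: a raw thinning skeleton hugs one
side of the rasterized boundary and biases segment angles by several
degrees. Segment angles are chord angles of equal-arc-length segments
(ends trimmed 5%) relative to the head-region (5–30% arc) body axis. Eyes
are the two darkest elliptical components in the head region; each eye's
angle is its second-moment major-axis orientation relative to the body
axis, with left/right assigned by the sign of the cross product with the
heading in image coordinates. All accuracy claims for these estimators are
made against rendered ground truth only — recovery within about ±3° at
40 µm/px sampling — never against real-animal figures.

Optical-flow activity is dense block matching (best-SSD integer offset per
16 px block within a ±4 px window), averaged over blocks whose intensity
variance exceeds a texture threshold; epoch labels give per-epoch means.
Counting uses connected-component labelling (4- or 8-connectivity, default
8) of a segmenter mask — any mask producer satisfies the contract; the
reference is adaptive local-mean thresholding plus a small opening —
with components below 50 px discarded and an area rule separating
individuals from swarms (default threshold 5× the median component area).
Densities divide by arena area from the mosaic's µm/px scale, with a SEM
computed across a caller-chosen grid of arena blocks (the partition is a
free parameter).

## Numerical and testing choices

* Boxes are half-open `[x0,x1)×[y0,y1)` in 0-based pixel coordinates;
  images are `[row, col]` matrices in [0, 1]; the world origin is the array
  centre with z toward the cameras. Camera images are inverted by the
  optics, so mosaics are 180°-rotated renditions of the world;
  `world_to_mosaic()` / `mosaic_to_world()` convert.
* Ties everywhere break toward the lower index (NMS order, mutual-best
  matching, assignment), making every pipeline stage deterministic.
* Degenerate inputs fail loudly: virtual images (u ≤ f), non-positive
  disparities, fewer than 3 surviving matches, skeletons too small to
  orient, empty reference sets.
* Every stochastic test fixes its seed. Brute-force oracles (exhaustive
  NMS, exhaustive Hamming scan, permutation assignment, BFS flood fill)
  are implemented independently in the test helpers and never share code
  with the package.
* Problem sizes in the test-suite were chosen to exercise every code path
  at desk scale: 2×3-camera stitching, 50-fish detection on a ~0.1 MP
  mosaic, 100-bead depth simulations, an 8-identity embedder — the full
  suite runs in roughly ten minutes on one CPU.

## Known limitations

Translation-only stitching ghosts out-of-plane structure in overlaps; the
depth model assumes parallel optical axes and a common focus distance;
the embedder is desk-scale (64 px default inputs versus 224 px at full
scale) and its accuracy on real melanophore patterns is untested by
construction; block-matching flow reports integer displacements only; and
the simulator's noise and illumination parameters are plausible operating
points, not calibrated to any specific sensor.
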