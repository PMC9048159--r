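---
title: "Methods: phantom-based QA analysis for radiotherapy PET-MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based QA analysis for radiotherapy PET-MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmrqa)
```

# Scope

`petmrqa` implements the analysis side of a six-test quality-assurance
programme for simultaneous PET-MR scanners used in radiotherapy planning:

1. **MR image quality** — ACR-style metrics (slice thickness, slice
   position, percent integral uniformity, ghosting, high-contrast
   resolution, manual low-contrast scores).
2. **MR geometric accuracy** — large field-of-view marker-grid distortion.
3. **Mechanical accuracy** — cross-plane phantom offsets/rotations against
   the image centre, plus ruler-based manual laser/couch readings.
4. **PET-MR alignment** — sphere phantom detection and rigid point-set
   registration of MR pair midpoints onto PET centroids.
5. **DW-MR ADC accuracy** — two-b-value apparent diffusion coefficient
   against temperature-interpolated literature references.
6. **PET SUV accuracy** — decay-corrected uniform-phantom standard uptake
   value.

Each analysis consumes DICOM series (or in-memory `image_volume` objects)
and emits `measurement` objects that feed a repeatability/stability
statistics and reporting layer. Synthetic phantom generators with exact
ground truth accompany every test so that the entire chain — DICOM
ingestion included — can be validated at desk scale.

# Coordinate and rotation conventions

All geometry lives in the DICOM patient frame (LPS), in millimetres, with
the scanner isocentre at the world origin. Voxel indices are 0-based and
map to voxel centres. Axis naming: RL = x, AP = y, SI = z.

There is no community-standard convention for QA rotation angles, so the
package fixes one and surfaces it in every report: pitch rotates about RL,
roll about SI, yaw about AP, composed extrinsically as
`R = Ry(yaw) Rz(roll) Rx(pitch)`, transforms acting as `p -> R p + t`. All
angles the package reports are only comparable with other systems after
mapping conventions. The alignment transform direction is MR midpoints
onto PET centroids.

# DICOM layer

The package carries a deliberately small DICOM reader/writer (Explicit VR
Little Endian, uncompressed, single-frame grayscale) covering the tags the
analyses require: geometry (position, orientation, pixel spacing), rescale
slope/intercept, modality and activity-concentration units, acquisition
time, and the diffusion b-value. The loader rejects mixed series UIDs,
slice-spacing variation above 1%, and missing geometry tags rather than
guessing. The writer is also the fixture writer for the synthetic
generators, so tests exercise the same ingestion path as scanner exports.
It is not a general DICOM implementation: compressed transfer syntaxes,
sequences and multi-frame objects are out of scope.

# Synthetic phantoms: what they emulate, and what not

Generators produce geometry and first-order noise only:

* **Grid phantom** (`gen_grid_phantom`): ~1,200 spherical markers
  (default 11 x 11 x 10 = 1,210, 30 mm pitch, 1 mm voxels) as isotropic
  Gaussian blobs (sigma = radius/2) over a low background, displaced by an
  arbitrary user displacement field plus optional per-marker jitter.
  Gaussian blobs rather than hard spheres keep sub-voxel centroid
  detection well posed and the partial-volume behaviour controlled; real
  marker/optics effects of a commercial phantom are not modelled.
* **Sphere phantom** (`gen_vqc_phantom`): five PET spheres, each flanked
  superior/inferior by an MR sphere at +-18 mm, so pair midpoints coincide
  with PET centres by construction; a known rigid misalignment is applied
  to the PET frame. The commercial layout is proprietary, so the nominal
  sphere positions are configurable and the defaults are an approximation.
* **Diffusion vials** (`gen_dw_vials`): three cylinders with
  mono-exponential signal `S(b) = S0 exp(-b ADC)` and Rician noise (the
  channel noise SD is set from the SNR at the lowest b-value and applied
  to every b image). No relaxation, eddy-current or EPI-distortion
  physics.
* **Uniform PET cylinder** (`gen_uniform_pet`): constant concentration
  with either Gaussian or scaled-Poisson (variance proportional to mean)
  voxel noise. Reconstructed PET noise is neither white nor Poisson, so
  this is a first-order stand-in; no sinogram/reconstruction simulation.
* **ACR-like phantom** (`gen_acr_like`): a disk with ramp bars, wedge
  bars, a uniform compartment, ghost patches and hole arrays at
  analytically known positions. Bar edges are rendered with a 2 mm linear
  partial-volume ramp, a stand-in for the in-plane point-spread function
  that also makes half-maximum interpolation exact at any edge phase.
* **Cross-plane phantom** (`gen_cross_phantom`): three orthogonal 10 cm
  Gaussian rods under a known rigid transform.

All generators are bit-deterministic given their spec (including seed),
and ground truth is returned beside the image; no analysis function reads
it. Passing tests on these phantoms demonstrates the correctness of the
analysis chain under controlled geometry and noise — not the behaviour of
any physical scanner, coil loading, B0/B1 effects, or vendor
reconstruction.

# Analysis methods and numerical choices

## ACR image quality

*Slice thickness*: the full-width-half-maximum length `L` of each ramp bar
profile (profile = per-column maximum over the configured box; half
maximum relative to the local plateau and baseline, sub-pixel via linear
interpolation), combined as `thickness = f (L_top L_bottom)/(L_top +
L_bottom)` with `f = 0.2` for 1:10 ramps. The harmonic mean cancels a
through-plane offset between opposed ramps.

*Slice position*: half the signed length difference of the two wedge bars
(crossed 45-degree wedges convert a through-plane offset into an in-plane
length difference at factor two).

*Uniformity*: `PIU = 100 (1 - (high - low)/(high + low))` with high/low
the extreme means of ~1 cm^2 windows (box means via an integral image)
fully inside the compartment ROI.

*Ghosting*: `100 |(top + bottom) - (left + right)| / (2 m_phantom)` over
four elliptical background ROIs and a large central ROI; background ROIs
must clear the phantom support (checked with the ellipse support
function).

*Resolution*: a hole row/column is resolved when every inter-hole trough
drops below a configurable fraction (default 0.7) of the smaller adjacent
peak; the result is the smallest diameter with a resolved line. This
replaces visual scoring with an explicit modulation criterion.

*Low contrast* is a recorded manual observation by design (0-40 spokes,
stored verbatim with observer metadata); no automated spoke detector is
provided. The ACR geometric sub-test is intentionally absent: the
dedicated grid-phantom test covers geometry.

## Geometric accuracy

Marker detection thresholds the image (default background + 0.25 of the
background-to-peak range), takes 26-neighbourhood local maxima, merges
maxima closer than a third of the grid pitch, and refines each to a
background-subtracted intensity-weighted centroid over a window of +-1.5
marker radii (3 sigma: truncation bias of the centroid < 0.02 mm, against
~0.2 mm at 2 sigma). Candidates are matched to nominal IDs after a coarse
two-pass rigid alignment; conflicts keep the brighter candidate, and
missing/spurious markers are reported. Fewer than 50% of expected markers
is a hard failure.

Phantom setup error is removed by a 6-DOF rigid fit of nominal onto
measured positions using markers within 10 cm of the isocentre, where true
gradient distortion is smallest; the residual per-marker displacement norm
is reported as distortion. This makes the metric invariant to phantom
placement (exactly so when the fit uses all markers) and is stated in
reports, since vendors do not document their separation of setup from
distortion. Distance from the isocentre uses the *measured* position;
shells are lower-edge inclusive at 10/15/20/25 cm, with shells under 25 cm
compared against the 2.0 mm limit recommended for MR-only radiotherapy
and the outer shell reported without tolerance.

Longitudinal statistics restrict to markers common to all sessions
(excluded IDs are reported with presence counts), then compute per-marker
mean, sample SD and range across sessions; the headline numbers are the
arithmetic mean of per-marker SDs and the mean range.

## Mechanical accuracy

Rotations are two-point secant angles from the +-5 cm marks — exactly what
manual marking supports — averaged over the two pairs that see each axis;
translations are the RL/AP components of the cross centre against the
image centre (the SI offset is an operator-entered internal-laser reading,
because it is measured against couch motion). Axis-pair separations below
50 mm are rejected as implausible, and each pair must be collinear with
the centre within a 5 mm sagitta. The automatic locator uses the global
bright-voxel centroid (the three arms are symmetric about the centre) and
short arm-end slabs; it defers to manual marking when ridges are not
found. Ruler/laser procedures themselves are not simulated: the package
stores and differences operator entries, extracts hysteresis from the
return-to-zero reading, and applies the +-2 mm tolerance.

## PET-MR alignment

Sphere detection reuses the blob detector with a top-candidate cut at half
the brightest blob; any count other than expected is an error. MR spheres
pair by mutual nearest neighbour, required to be SI-dominated and within a
40 mm window. Registration of the five midpoints onto the five PET
centroids is the closed-form least-squares (Kabsch) solution with the
determinant constrained to +1, so reflections are never returned;
spheres are equally weighted (intensity weighting was rejected for
robustness). Correspondence is nearest-neighbour, valid because
misalignments are tiny against the sphere pitch.

## ADC accuracy

Vials are segmented on the lowest-b image by Otsu threshold, 3-D connected
components (the three largest plausible components), and one-voxel erosion
against edge partial volume. The estimator is the per-voxel two-point
inversion `ADC = ln(S_low/S_high)/(b_high - b_low)` averaged over the
vial — the mean of the per-voxel ADC map, not the ADC of mean signals; the
two differ under noise, and the per-voxel convention matches common
analysis toolkits. Voxels with non-positive signal are excluded and
counted. A multi-b log-linear least-squares fit is provided for validation
acquisitions. The reference is piecewise-linear in temperature, evaluated
at the mean of the pre/post readings (a drift above 1 degree C warns);
extrapolation outside the table is refused unless explicitly enabled. The
shipped reference table is a synthetic stand-in with representative alkane
self-diffusion magnitudes and must be replaced with site-validated
literature values for real use. The water surround is not analysed.

## SUV accuracy

Activities decay as `A(t) = A0 2^(-dt/T_half)` (18F default 109.77 min),
with assayed and residual activities decayed separately to the *scan
start* (the chosen decay reference point, stated here because acquisitions
are short compared with the half-life ambiguity). With voxel values in
Bq/ml, `SUV = value x fill mass / net activity`, so a uniform, correctly
calibrated phantom reads SUV = 1 exactly — the reference is therefore 1 by
construction (density 1 g/ml default) and the result is the ROI-mean
percent difference. The ROI is an 18 cm diameter x 18 cm SI-aligned
cylinder centred on the support centroid, required to sit at least 99%
on support. Scanner-side corrections (reconstruction, attenuation maps for
couch/coils, scatter) are treated as already applied to the input.

## Statistics layer

Sample SD (n - 1) is used everywhere; with n = 3 repeats the denominator
choice is material, so it is fixed and documented rather than left
implicit. Tolerance bounds are inclusive. The trend screen (OLS slope vs
session index, flagged at |slope| > 2 SE) is an explicit numeric extension
of the traditional visual judgement of monthly plots, off the default
report path and labelled as a screening aid: at n = 12 its false-positive
rate is above the nominal 5% (t rather than normal tails), which is
acceptable for screening.

# Validation studies and problem sizes

The test-suite and acceptance studies run entirely on the synthetic
phantoms, at sizes chosen so that the whole chain (including the 1,210
marker grid at 1 mm voxels, ~31M voxels per session) completes in minutes:

* geometric recovery of a smooth radial 0-8 mm displacement field on the
  full 1,210-marker grid, and three-session repeatability with 0.2 mm
  per-axis marker jitter;
* three-session ADC repeatability with Rician noise at SNR 50 on vials at
  0.7/1.2/1.7 x 10^-3 mm^2/s and b = 50/800 s/mm^2;
* three-session alignment repeatability under a fixed
  (0.5, 0.3, 0.2) mm / 0.1 degree misalignment with 0.05 mm centroid
  noise;
* three-session cross-plane yaw repeatability at 0.5 degrees with 0.1 mm
  marking noise.

Oracle-style checks back the statistics (brute-force per-marker SD
averages, numeric least-squares registration, analytic Rician means,
closed-form decay).

# Known limitations

* No physics simulation: passing synthetic tests bounds algorithmic error,
  not scanner behaviour (coil profiles, B0 inhomogeneity, reconstruction
  bias are invisible here).
* The DICOM layer reads only uncompressed Explicit VR Little Endian.
* The rotation convention is package-defined; cross-system comparisons
  require mapping.
* The shipped ADC reference table is synthetic and site-replaceable.
* Distortion analysis measures; it does not correct, and no
  spherical-harmonic gradient model is fitted.
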