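---
title: "faquant: methods and design notes"
author: "faquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{faquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

faquant quantifies integrin-based cell–matrix adhesions (focal adhesions,
FAs) in single-channel fluorescence images and analyzes fluorescence
recovery after photobleaching (FRAP) of adhesion components. The analysis
region is a user-supplied binary cell mask — typically drawn on the F-actin
channel — so every measurement refers to exactly one cell. The package
deliberately does *not* attempt multi-channel handling, machine-learned
segmentation, adhesion-type classification, time-lapse adhesion tracking,
or diffusion–reaction FRAP models.

# The segmentation pipeline

`segmentAdhesions()` turns an intensity image plus cell mask into a label
map in four deterministic steps.

**1. Rolling-ball background subtraction.** The background is estimated by
grayscale opening with a flat disc structuring element (radius
`rollingBallRadiusPx`, default 50 px) and subtracted, clipping at zero.
The radius must be large relative to adhesion size — at the recommended
0.15–0.3 µm/px sampling, a 10 µm adhesion spans at most ~67 px, so 50 px
leaves adhesions intact while removing smooth cytoplasmic background. The
operation removes any constant offset entirely and is invariant to adding
one, which the test suite verifies. Internally intensities are rescaled to
[0, 1] for the morphology and back afterwards; a flat structuring element
commutes with linear rescaling, so this is exact, and the result is rounded
back to the integer raster (the opening only ever selects existing pixel
values).

**2. Automatic thresholding.** Default is Otsu's method: exhaustive
maximization of the between-class variance over all gray levels, computed
from the histogram of the background-subtracted pixels *inside the mask's
bounding box* (restricting to the bounding box keeps large empty fields
from biasing the histogram). Ties are broken toward the lower threshold,
and foreground is *strictly above* the threshold — ties at the threshold
value are background. A consequence of the tie rule worth knowing: for a
perfectly bimodal histogram with an empty gap between the populations the
criterion is constant across the gap, and the chosen threshold is the
gap's lower edge. This changes nothing about which pixels are foreground.
The triangle method and a fixed threshold are available via
`segmentationConfig()`. A constant image has no separable classes;
`autoThreshold()` then returns an empty foreground with a warning rather
than failing, so a blank field in a batch does not abort the run.

**3. Distance-transform watershed.** Adhesions frequently touch; the
binary foreground is split by flooding the negated Euclidean distance map.
Concretely: the distance map is smoothed with a Gaussian
(`smoothingSigmaPx`, default 1 px), maxima shallower than `hMaxima`
(default 1) are suppressed — realized as the flooding merge tolerance —
and the surviving maxima seed the flood. These two knobs trade
under-segmentation against the over-segmentation artefacts watershed can
introduce; raising `hMaxima` merges more, lowering it splits more. Pixels
where two basins meet are assigned to background, so split objects are
disjoint with a one-pixel watershed line between them; the label count
never drops below the plain connected-component count, and labeled pixels
are always a subset of the input foreground. The flood itself explores the
full 3×3 neighborhood; the 4/8 `connectivity` setting governs component
labeling and line removal.

**4. Mask intersection.** Labels are intersected with the cell mask after
labeling; a label the mask's concavity cuts into pieces keeps a single
identity (pieces are not relabeled), and labels left empty are dropped
before consecutive renumbering. Objects entirely outside the mask
therefore contribute nothing.

# Morphometric parameters

`measureAdhesions()` computes, per adhesion: pixel area; perimeter;
centroid; orientation; aspect ratio; shape factor `sf = perimeter²/area`;
centroid distance to the cell border; the angle of the centroid relative
to the cell centroid; and the acute relative orientation between adhesion
axis and that angle (0° = radially aligned, 90° = perpendicular). Area and
perimeter are always reported in pixels; `convertToPhysical()` *adds*
µm-converted columns without touching the pixel columns, so tables from
different magnifications remain comparable in pixels.

Conventions, chosen once and used everywhere: coordinates are 0-based with
x = column and y = row (y increases downward); angles are degrees in that
frame; orientation is the major axis of the moment-equivalent ellipse
(eigen-decomposition of the second central moment matrix of the pixel
centers), mapped to [−90, 90). Isotropic shapes (equal eigenvalues within
1e-9) get orientation 0 and aspect ratio 1 as a deterministic tie-break.

**Perimeter estimator.** The perimeter is the length of the 0.5-level
marching-squares contour of the pixel-set indicator *after* smoothing the
indicator with a Gaussian of σ = 1 px. Contouring the raw indicator
follows the pixelated staircase and overestimates curved boundaries by
~8% (a rasterized disc of radius 20 yields sf ≈ 14.4 instead of 4π ≈
12.57); the band-limited indicator places the contour at sub-pixel
positions and recovers the disc's sf to within 1%. For objects so small
that smoothing pulls the peak below 0.5, the raw indicator is contoured
instead. Shape factors are therefore comparable within faquant but not
necessarily with other tools, whose perimeter estimators differ.

**Border distance and the peripheral rule.** `dist_px` samples the mask's
Euclidean distance map at the nearest-integer centroid pixel. If a concave
mask leaves that pixel outside the foreground, the distance is reported as
0 and the row flagged `centroid_outside_mask` rather than silently
guessed. An adhesion is *peripheral* when `dist_px` is strictly less than
`periphFrac` (default 0.1) of the mask's maximum interior distance — an
adhesion exactly at the cutoff is not peripheral. The fraction is
configurable but should be held constant across images that are compared.

`summarizeImage()` reports per cell: mask area, adhesion count, adhesive
area fraction (exactly Σ area / mask area), peripheral fraction, and the
mean and sample standard deviation (n − 1) of every numeric parameter.
With zero adhesions the area fraction is 0 and the peripheral fraction is
written as NA. `filterByArea()` implements the size-exclusion step (drop
unrealistically small detections, or under-segmented clusters that appear
as one large object); the default keeps everything, and exclusion is an
explicit choice, mirroring the post-hoc spreadsheet workflow.

# File conventions

Images are single-channel 8- or 16-bit TIFF (or PNG); multi-channel input
is rejected with a message to split channels first. The mask is an 8-bit
binary image whose pixels are all 0 or 255 (foreground white), named
`<stem>_mask.<ext>` next to `<stem>.<ext>`. Outputs per image go to
`<outRoot>/<stem>/`: `FA data.csv` (one row per adhesion), `image
data.csv` (one row per cell), and a color-coded label overlay
`<stem>_labels.png` (colors assigned by a deterministic golden-angle hue
walk over label indices). Combined tables across all images, prefixed with
the source stem, land in the output root together with a run log
(package version, configuration echo, per-image threshold and counts).
CSVs are comma-separated, UTF-8, "." decimal, 6 significant digits —
enough that writing and re-reading reproduces values at the written
precision, and two runs over the same inputs are byte-identical.

# FRAP analysis

`normalizeFrap()` implements the standard three-step normalization:
subtract the background ROI; optionally divide by the
background-subtracted *reference* ROI relative to its own pre-bleach mean
(correcting fluorescence lost to imaging itself — omit the reference when
no such loss is observed); and divide by the mean of the bleached ROI's
pre-bleach frames so the pre-bleach level is exactly 1. Curves on
different grids are linearly interpolated onto the bleached grid. The
normalization is idempotent and invariant to rescaling the raw
intensities, and a noiseless unbleached control under exponential
acquisition decay comes out flat at 1 to machine precision — all verified
in the tests.

`fitOnePhase()` fits the one-phase association model

$$F(t) = f_0 + (plateau - f_0)\,(1 - e^{-kt})$$

by unweighted least squares (Levenberg–Marquardt) over the post-bleach
points, with t re-zeroed at the first post-bleach frame — the first
post-bleach point is included in the fit at t = 0. Starting values are
f0 = first post-bleach value, plateau = mean of the last three points, and
k = ln 2 over the observed time to half recovery. Derived quantities:
half-time ln(2)/k and mobile fraction (plateau − f0)/(1 − f0) on the
normalized scale. A flat curve is reported as `NoRecovery` instead of a
spurious rate (the plateau guess must exceed f0 by a noise floor taken
from the tail scatter); mobile fractions above 1 are flagged with a
warning, never clipped. The bleach frame can be auto-detected as the
first >50% drop relative to the running pre-bleach mean, or fixed
explicitly (two pre-bleach frames is the usual protocol).
`averageAndFit()` fits the pointwise mean of ≥2 normalized curves —
combining ROIs from independent experiments before fitting is the
recommended practice — and returns the per-curve fits alongside for
dispersion reporting.

# The synthetic-scene generator

`generateScene()` provides ground truth for every stage without any
microscopy data. It emulates: a disc or Fourier-perturbed blob cell mask;
elliptical adhesions with lognormal areas and uniform aspect ratios,
placed fully inside the mask by rejection sampling with non-overlapping
bounding circles (minimum gap 6 px so PSF tails do not bridge neighbors);
uniform or radially aligned orientations; Gaussian PSF blur; a smooth
background (offset plus horizontal ramp); Poisson shot noise on signal +
background plus Gaussian read noise — the standard fluorescence camera
model; and quantization to the configured bit depth. The truth table
carries each ellipse's analytic center, area (πab), aspect ratio,
orientation, border distance and peripheral flag, computed before
rasterization. The same seed yields bit-identical scenes.

Defaults are chosen to represent a routine confocal acquisition: 400×400
px at 0.2 µm/px, cell radius 160 px (32 µm), 30 adhesions with areas
lognormal(log 150, 0.3) and aspect ratios uniform on [2, 5] (adhesions
~1.6–5 µm long — within the 1–10 µm range typical of most cell types —
and elongated enough that orientation is well defined), signal 1000
counts over a 100-count background, PSF σ = 1 px, read noise sd 10. The
resulting signal-to-noise ratio, amplitude over total noise sd at an
adhesion pixel, is ~26.

What the generator does *not* emulate — and hence what passing its tests
does not show about real data: spatially varying adhesion brightness and
internal structure, clustered or merging adhesions, cytoplasmic
autofluorescence texture, optical aberrations beyond a Gaussian PSF, and
imperfect user-drawn masks. Validation on synthetic scenes demonstrates
that the measurement chain is correct, not that segmentation of any
particular stained sample is.

`generateFrapCurves()` renders the matching three-ROI FRAP set (bleached,
reference, background) from the closed-form recovery with optional
acquisition bleaching `e^{-λt}`, background offset, and Gaussian noise,
at the standard sampling of one frame per 15 s for 5 min with two
pre-bleach frames.

# Validation problem sizes

The shipped validation suite exercises: Otsu against an exhaustive
between-class-variance search on 50 random 8-bit images; area/centroid
against brute-force per-pixel accumulation on 100 random blobs (exact
agreement); a radius-20 disc (ar ≤ 1.02, sf within 5% of 4π) and a 10×40
rectangle (orientation 0° ± 1°, ar 4.00 ± 0.05 — the discrete-moment
value for a 10×40 pixel grid is 4.019); watershed on disc pairs and 50
random binary compositions; end-to-end recovery of a 30-ellipse scene
(all 30 detected; orientation within 5° and area within 15% for ≥90% of
objects; adhesive area fraction within 15% of truth); exact summary
conservation; FRAP parameter recovery to 1e-6 relative on the noiseless
standard sampling and a 100-seed Monte Carlo at noise sd 0.02 (median
half-time error ≤ 10%, observed ~5%); flatness of the bleach-corrected
control to 1e-9; and byte-identical batch re-runs. These sizes were
chosen so the entire suite completes in well under a minute per module on
a laptop while leaving the statistical checks comfortably powered.

# Known limitations

* The original adhesion-analysis macro this workflow mirrors does not
  document its exact auto-threshold algorithm, background radius, or
  perimeter estimator; faquant's choices are declared here and held
  fixed, so absolute sf or threshold values are comparable within faquant
  runs, not across tools.
* Orientation of near-circular adhesions (ar → 1) is intrinsically
  ill-defined; the deterministic tie-break reports 0°.
* Watershed over-segmentation on long, narrow or dumbbell-shaped
  adhesions is controlled but not eliminated by `hMaxima`; the area
  fraction is the more robust readout when adhesions form continuous
  plaques.
* `dist_px` is the border distance of the *centroid*, per the stated
  definition, not the minimal distance of the adhesion's nearest pixel.
* FRAP fitting assumes a single exponential; reaction-dominant multi-state
  or diffusion-coupled recoveries need models outside this package's
  scope.
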