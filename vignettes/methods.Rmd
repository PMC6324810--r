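---
title: "Quantifying microvessel alignment and groove containment on patterned substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvessel alignment and groove containment on patterned substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovealign)
```

## The problem

Endothelial cells co-cultured with osteoblasts on patterned bioceramic
substrates self-assemble into microcapillary-like structures, and substrate
architecture at the scale of hundreds of micrometres steers where those
structures form and how they orient. groovealign quantifies that steering
from confocal fluorescence Z-stacks of CD31-immunostained cultures with two
scalar statistics per sample:

* **DOA (Degree of Alignment)** — the ratio of orientation-histogram signal
  along the groove axis (0°) to the signal perpendicular to it (90°).
  DOA = 1 means random alignment.
* **DOC (Degree of Containment)** — the ratio of average segmented signal per
  unit cross-sectional length inside groove regions to that outside.
  DOC = 1 means a spatially uniform distribution.

Because confocal images of such cultures are rarely public, the package ships
a synthetic stack generator whose outputs exercise every pipeline stage with
known ground truth. All empirical statements below are reproduced by the
test suite or by `scripts/acceptance.R`.

## Substrate geometry

Seven architectures are modelled with their measured post-sintering
dimensions: three concave/convex pairs (widths 660 or 330 um, periodicities
1240 or 630 um, depths/heights 150–585 um) and a flat control. The
cross-section of a feature is an elliptical dip (or bump) of half-width
`width/2` reaching the measured depth; this reduces to a semicircle when the
depth equals half the width, and the "deep" variants are modelled as that
semicircle beneath vertical walls making up the measured total depth
(585 = 330 + 255 for the large deep design). The elliptical generalisation is
needed because sintering shrinkage left the shallow designs slightly
shallower than a true semicircle (for example 300 um deep at 660 um wide).

Depth is measured downward from the uppermost surface plane, so grooves are
the `z > 0` regions of concave designs; for convex designs "grooves" are the
regions between bumps (containment between ridges is the quantity of interest there). Intervals are
half-open in micrometres and partial intervals clipped at the crop boundary
are kept, matching how real samples are cropped mid-pattern.

## Synthetic stacks

`generate_coculture_stack()` renders vessel-like filaments as smooth random
curves with a Gaussian cross-profile (default FWHM 20 um), at a default
half-scale analysis frame of 1200 x 1050 px at 2.3917 um/px. Key choices:

* **Orientation.** The doubled angle is wrapped-normal with standard
  deviation `1/sqrt(kappa)` radians; `kappa = 0` is exactly uniform on
  [-90°, 90°).
* **Tortuosity.** Filament centrelines meander at two scales — ~120 um
  wavelength at 25–50 um amplitude plus a cell-scale ~40 um wavelength at
  ~9 um amplitude — spreading each filament's local tangents over roughly
  ±25°. Real CD31⁺ networks are tortuous at both scales, and this spread is
  what makes a 40-filament isotropic image measurably isotropic under a
  2°-bin DOA: near-straight filaments leave single orientation bins
  Poisson-limited in filament count, and even so, individual 40-filament
  draws carry genuine sample anisotropy (an image can simply contain more
  long filaments near 0° than near 90°), which is the dominant residual
  variance of per-image DOA.
* **Containment.** A filament flagged as contained is placed inside a groove
  interval, its lateral excursion capped by the groove half-width and its
  straight component capped so every centreline vertex stays inside.
  Containment therefore induces alignment, as it does physically.
* **Depth.** Structure depth follows the substrate profile at each x: the
  full amplitude goes to the nearest Z slice with a one-slice Gaussian
  bleed. Ten slices span `[0, depth + 50 um]`. A faint substrate surface
  signal (bioceramic autofluorescence, amplitude 0.25 of the filament peak)
  follows the same profile, so depth is recoverable from the stack even
  where no filament lies.
* **Noise.** A smooth random low-order polynomial background (amplitude
  0.08) plus per-voxel Gaussian noise; `snr` is the peak filament amplitude
  over the noise standard deviation (default 8). Poisson noise is omitted:
  the local thresholding stage is insensitive to the distinction at these
  SNRs.
* Filament lengths are uniform in 500–3000 um and brightness uniform in
  0.75–1.

What the generator does **not** emulate: branching and anastomosis, the
point-spread function, tile-stitching seams, uneven staining, or any
biophysics of self-assembly. Passing tests therefore show that the pipeline
measures what it claims on controlled tubular signal, not that it is robust
to every real-image artefact.

## Image preparation

Both analysis paths start the same way: maximum projection, rotation so the
grooves run vertically, a centred crop (2400 x 2100 px at full scale), and
rolling-ball background subtraction with a 50 px radius. The rolling ball
is the classical morphological construction (grayscale erosion then dilation
with a spherical structuring element; intensities on the 8-bit convention of
255 gray levels per intensity unit; mirror-padded borders), with two choices
mirroring the de-facto reference implementation of the operation: the
background is estimated on a 3x3 mean pre-smoothed copy, and for radii of
16 px and above the image is block-minimum shrunk 4x, the ball rolled at
reduced scale, and the background bilinearly re-enlarged. The exact
full-resolution construction is available (`shrink = 1`) and agrees on the
fixtures; the shrunk default makes the cost tractable at the analysis frame
sizes.

The localisation path continues: auto-contrast (0.7% total saturation, a
display-autoscale convention; the tails map to 0 and 255), 8-bit conversion,
Phansalkar local thresholding (radius 5 px, k = 0.25, r = 0.5, p = 2,
q = 10 — the constants the method is conventionally distributed with, on
unit-normalised intensities; disc window, mirror padding), and removal of
8-connected components below 400 um² (at 2.3917 um/px that keeps components
of 70 px and larger; the tie at exactly 400 um² is kept). Local means and
variances for the threshold are computed by exact integer-preserving
convolution, and the test suite verifies bit-identical agreement with a
literal per-pixel oracle.

A degenerate case worth knowing: on a stack with **no** signal at all,
auto-contrast stretches pure noise to full range and the local threshold
then marks a large, percolating fraction of it, which the particle filter
cannot remove. Empty images are therefore reported through their statistics
(DOA ≈ 1, DOC ≈ 1 — both at their null references), not through a
near-empty mask.

## Orientation analysis and DOA

The orientation histogram is computed from the 2-D power spectrum of the
Hann-apodised image: each spectral sample's power is accumulated (with
linear soft binning) into the orientation bin of the structure it
represents, 90 bins of 2° over [-90°, 90°). Three spectral exclusions are
applied: the DC bin and the annulus below 3 cycles per image (background
residual), everything outside the inscribed Nyquist disc (so the pixel grid
does not bias the angular distribution), and the low-frequency portions
(below 32 cycles per image) of the two exact zero-frequency axis lines.
The last exclusion matters: those samples carry frame-coherent row/column
structure — illumination trends and filament-coverage fluctuations — which
lands entirely in the 0° and 90° bins and would bias the DOA ratio upward
by a factor of ~2 on isotropic images.

DOA is the mean bin weight within ±2° of 0° divided by the mean weight
within ±2° of ±90° (window configurable). A zero perpendicular signal
returns an explicit infinite-alignment sentinel. DOA is invariant to
intensity scaling, approximately reciprocal under 90° rotation, and its
mean over isotropic synthetic images is ~1.

## Groove detection and DOC

Depth profiles are measured from the stack by averaging a 300 um-wide band
per column and slice, subtracting each column's minimum slice intensity
(background is flat in Z), suppressing the residual noise floor below 25%
of the column maximum, and taking the intensity-weighted Z centroid
(`argmax` available). Columns with less than 1% of the median column total
are interpolated; more than 50% missing is an error.

The groove detector maps its six parameters onto a concrete
algorithm (the original plugin's internals are unpublished, so the mapping
is this package's specification; it is validated against analytic ground
truth, not against the plugin's bitwise output):

1. smooth the profile with a moving mean of span
   `curvature x rolling_z_window` (0.4 x 100 = 40 um);
2. estimate the ridge level and depth range robustly as the extremes of a
   `rolling_z_window` (100 um) moving mean;
3. candidate groove points are deeper than `z_threshold` (0.5) times the
   depth range below the ridge level;
4. each candidate-run edge snaps to the steepest-slope point within
   `rolling_z_window / 2`, provided that slope reaches `slope_factor`
   (0.35) of the profile's maximum absolute slope — this lands on groove
   walls and bump rims for concave and convex designs alike;
5. intervals are scored as normalised depth plus `depth_weighting` (0.01)
   times normalised mean absolute curvature; intervals scoring below
   `depth_weighting` are discarded;
6. intervals closer than half the rolling window are merged.

A profile whose depth range is below 1% of the rolling window is flat: an
empty groove set, not an error. On noiseless analytic profiles of all six
patterned designs the detector reproduces the ground-truth interval counts,
centres within 30 um, and widths within 15%.

DOC divides the mean segmented-mask column average inside detected grooves
by that outside; in-groove and outside lengths are the summed sample
spacings of the classified profile points, which makes DOC exactly 1 for a
constant profile. Empty groove sets flag DOC as undefined; all-contained
signal returns an infinite-containment sentinel. Whether "signal" means the
binary mask (default) or the grayscale image is configurable; the mask is
the default because the averaging stage follows the binarisation
step.

## Group statistics

`summarize_groups()` reports per-architecture means and standard errors
(n = 3 replicates in the default experiment design). `kruskal_dunn()` runs the
Kruskal-Wallis omnibus test with tie correction and Dunn's mean-rank
pairwise z tests, flagged at 0.05 and 0.005. Two choices:

* Dunn p values are unadjusted by default (Holm available), matching how
  raw cutoffs are conventionally reported for this design.
* For 12 or fewer observations without ties, the omnibus p value is exact,
  from full enumeration of rank assignments. With triplicate groups the
  chi-squared approximation rejects at ~0.9% for a nominal 5% — far too
  conservative for any small-sample use — while the exact test achieves the
  nominal level (rejecting at p ≤ α; the null distribution is discrete with
  an atom exactly at 0.05).

Infinite/undefined DOA and DOC sentinels are excluded from testing with a
logged count.

## Problem sizes and determinism

The default synthetic frame is the half-scale preset (1200 x 1050 px);
tests use frames from 256 px up to the half-scale preset and the
simulation-study tests use reduced frames and replicate counts, keeping the
whole suite within a desktop-scale run. Identical configuration and seed
reproduce bit-identical stacks, reports, and CSV files; every source of
randomness is derived from the configured seed, and `write_report()` writes
a manifest (config echo, package version, output checksum) for
reproduction.

## Known limitations

* The groove-detector parameter mapping is a reconstruction; only its
  recovery behaviour on analytic profiles is testable.
* The DOA of a single image with few, weakly tortuous filaments is
  high-variance by construction (a ratio of two narrow angular windows);
  means over replicates are the meaningful quantity, as in the study
  design.
* Perfectly straight, frame-spanning periodic structures below 32 cycles
  per image fall on the excluded axis lines and are seen only through
  their spectral leakage.
* The empty-image degenerate case is reported through null-reference
  statistics, not a clean empty mask (see above).
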