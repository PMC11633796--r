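---
title: "Automated scoring of the ACR DM phantom: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated scoring of the ACR DM phantom: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mammoqc)
```

## The problem

Weekly image-quality QC of a full-field digital mammography unit is done by
imaging an accreditation phantom and scoring how many of its embedded test
objects a reader can see. The ACR Digital Mammography phantom (Model 086) is
a 31 x 19 cm, 4.1 cm thick PMMA slab whose wax insert carries six fibers
(0.33-0.80 mm diameter, alternating 45/135 degrees), six groups of six
microcalcification specks (0.14-0.33 mm) and six low-contrast masses
(thickness proxy 0.20-1.00 mm), each ladder decreasing in visibility.
Human scoring assigns 0 / 0.5 / 1 per object (not / partially / completely
visible), counts from the largest object down until the first zero, and
compares the three group totals against guideline minima: fibers >= 4,
speck groups >= 3, masses >= 3 (RANZCR) or fibers >= 2, specks >= 3,
masses >= 2 (ACR). `mammoqc` automates that assessment for "for
presentation" DICOM phantom images and ships a synthetic phantom simulator
so the entire pipeline can be exercised, with known ground truth, without
any clinical data.

## Pipeline

1. **Ingest** (`read_phantom_image`). Pixels are normalized to an
   objects-bright convention (`MONOCHROME1` is inverted as
   `(2^BitsStored - 1) - stored`), the pixel pitch is taken from
   `PixelSpacing`/`ImagerPixelSpacing` (a missing pitch is a hard error:
   every geometric decision depends on it), and the chest-wall side is
   inferred from `ImageLaterality` + `FieldOfViewHorizontalFlip`, with a
   deterministic default of the left image edge when the tags are absent.
   Because vendor post-processing places images on arbitrary value scales,
   nothing downstream uses absolute intensities: all detection is
   correlation-based or background-relative.

2. **Wax-block localization** (`segment_wax_block`). Otsu threshold over
   the image -> largest connected component = phantom body; Otsu again
   within the body -> wax-insert candidates; morphological closing and
   opening with a disc scaled to 2 mm; components are filtered by the
   insert's known physical area (+/-25%), the principal-axis angle gives
   the rotation estimate, and a minimum-area rectangle is fitted in the
   de-rotated frame. If the fitted rectangle misses the expected
   60 x 90 mm footprint by more than 10% in either dimension the function
   raises a classed `mammoqc_localization_failure` — this is exactly what
   a 25 mm chest-wall overhang produces (the insert is partially cut off),
   and the report/CLI translate it into a clean "Fail".

3. **ROI extraction and smoothing** (`extract_rois`, `smooth_roi`). The
   insert is partitioned into a 3-column (fibers | speck groups | masses)
   by 6-row grid of 18 cells, resampled into the de-rotated block frame by
   bilinear interpolation, so the analyzers always see upright ROIs
   regardless of how the phantom was laid on the support. Only these ROIs
   are Gaussian-smoothed (default sigma 0.1 mm, i.e. 1 px at the 0.1 mm
   simulator pitch); the source image is never altered.

4. **Detection** (`normxcorr2`, `analyze_*`). For every object a binary
   template of its nominal shape, size and orientation is generated at the
   image's pixel pitch (80 x 80 px for masses and fibers and 15 x 15 px
   for a single speck at the 50 um reference pitch; other pitches scale by
   `0.05/spacing`, rounded to odd). The windowed zero-mean normalized
   cross-correlation
   \[
   \gamma(u,v)=\frac{\sum_{x,y}[f(x,y)-\bar f_{u,v}][t(x-u,y-v)-\bar t]}
   {\{\sum_{x,y}[f(x,y)-\bar f_{u,v}]^2\sum_{x,y}[t(x-u,y-v)-\bar t]^2\}^{0.5}}
   \]
   is evaluated at every valid offset (FFT cross-correlation plus integral
   images; an exhaustive double-loop oracle pins the implementation in the
   test suite). A peak below `gamma_zero` scores 0 outright; otherwise a
   per-kind supplementary validator must also pass:

   * **masses** — an isotropic 2D Gaussian
     `A exp(-((x-x0)^2+(y-y0)^2)/(2 sigma0^2)) + Bkg` is least-squares
     fitted (Levenberg-Marquardt, multiple per-size initial widths); the
     mass is accepted when the fitted centroid agrees with the correlation
     peak (5 px at 50 um, scaled by pitch) and the FWHM
     (`2 sqrt(2 ln 2) sigma0`) lies within 0.5-1.8 x the nominal disc
     diameter;
   * **speck groups** — candidate specks are local maxima of the
     correlation surface; the candidate nearest the ROI centre anchors the
     group and every other candidate is validated by its Euclidean
     distance to the anchor against the nominal 2 mm within-group spacing
     (+/-30%); the validated count n (centre included) maps to the score:
     n >= 4 -> 1, 2 <= n <= 3 -> 0.5, n < 2 -> 0;
   * **fibers** — the correlation surface is binarized at 0.6 x its peak,
     and the largest blob's principal-axis orientation (second central
     moments) must lie within +/-4 degrees of the nominal 45 degrees
     (indices 1, 3, 5) or 135 degrees (2, 4, 6), compared modulo 180.

5. **Scoring** (`score_group`, `evaluate_pass`, `analyze_image`).
   Validated objects score 1 when the peak correlation reaches
   `gamma_full` and 0.5 in `[gamma_partial, gamma_full)`; groups apply the
   count-until-zero rule; totals are compared against both guideline
   criteria. All six objects are always scored (subject to the stop rule)
   rather than stopping at the pass threshold, so totals remain useful for
   longitudinal trending.

## Interpretations where the scoring rules are under-specified

* The 0.5 ("partially visible") band is only defined operationally for
  speck groups. For fibers and masses we award 0.5 when the correlation
  peak falls in `[gamma_partial, gamma_full)` *and* the supplementary
  validator passes; a failed validator is always 0.
* Only a raw score of 0 triggers the stop rule — a 0.5 does not. Objects
  below the first zero are not analyzed at all (their results carry
  `stopped = TRUE`), which also skips their validators.
* The speck count n includes the centre speck: a lone anchored centre
  gives n = 1, which stays consistent with "fewer than 2 means not
  detected".
* Correlation acceptance ranges are observer-anchored in routine use. The
  shipped defaults (`gamma_zero`/`gamma_full`: fibers 0.50/0.65, masses
  0.50/0.78; speck candidate threshold 0.30) were calibrated once on the
  simulator by comparing object-present renders across the contrast ladder
  with object-free regions; `calibrate_thresholds()` refits them from a
  user-supplied table of observer scores, reproducing that anchoring loop
  for real systems.
* Normalized correlation is amplitude-blind, so on smooth low-noise ROIs a
  faint background undulation can match a small disc template as well as a
  real speck does. The speck detector therefore also requires each
  candidate to carry at least 35% of the strongest candidate's fitted
  template amplitude (the least-squares regression slope of the template
  onto the window, a by-product of the correlation sums). The mask is
  applied before non-maximum suppression so a faint sidelobe cannot shadow
  a genuine speck.

## The simulator: what it emulates, and what it does not

`generate_phantom()` renders the phantom analytically in the transformed
frame: a PMMA body and wax-insert rectangle with half-pixel soft edges,
fibers as anti-aliased oriented bars, speck groups as six Gaussian dots
(FWHM = speck diameter) arranged as a regular pentagon plus centre at the
nominal 2 mm spacing, and masses as radially smooth 3 mm discs. Per-index
amplitudes follow a geometric contrast ladder
(`wax_level x base x decay^(index-1)`, defaults: base 0.09 / 0.20 / 0.07
for fibers / specks / masses, decay 0.75), giving the strictly decreasing
visibility the physical insert is built to have. Noise is
Poisson-Gaussian: variance `gain x intensity / dose + read_sd^2` with dose
factors 0.4 / 1.0 / 2.5 for the low / normal / high AEC surrogates — so
low dose is the noisiest image, and with the default ladder the smallest
one or two objects per kind drop out of detection there while a noise-free
render scores a full 6/6/6. Positioning controls mirror how a technologist
can misplace the phantom: lateral shift along the chest wall, rotation
about the insert centre, and signed chest-wall overhang (positive values
truncate the scene at the image edge). Exact sizes and positions of the
commercial insert are not public, so the layout (size ladders pinned at
the published endpoints and at 0.61 mm for fiber 3, 3 x 6 grid, 60 x 90 mm
insert 17 mm from the chest-wall edge of the body) is a documented default
in one editable config; a user with the vendor datasheet can override
every value and analyzer and simulator always share the same spec.

The simulator is deliberately not a physics model: no x-ray transport,
scatter, detector MTF, heel effect or vendor post-processing. Passing
tests on synthetic images therefore demonstrate that the geometry, rule
logic and detectors behave as specified under controlled contrast and
noise — not that the shipped thresholds are correct for any particular
clinical system. On real equipment the thresholds should be re-anchored
with `calibrate_thresholds()` against local observer scores.

## Numerical choices

* Constant correlation windows are an undefined 0/0 in the correlation
  formula; they are defined as gamma = 0, with the constant-window test at
  a roundoff-scaled floor (`(1e-5 x max|f|)^2 x n`). A constant template
  is an error.
* The Gaussian mass fit tries initial widths of 0.25 / 0.42 / 0.6 x the
  nominal disc diameter and keeps the lowest-residual converged fit;
  non-convergence from every start scores 0 with diagnostics.
* ROI resampling is bilinear; rotation estimates on the suite's renders
  are accurate to ~0.1 degree, and de-rotated ROI content matches the
  unperturbed phantom to a mean absolute difference below 5 intensity
  units (~0.1% of the wax level) at 5 degrees.
* Angles compare on the 180-degree circle
  (`|((a - b + 90) mod 180) - 90|`), so 178 and 2 degrees differ by 4.
* ICC(3,1) uses the two-way ANOVA mean squares of `score ~ subject +
  rater` (consistency form, single rater); Bland-Altman uses the n-1
  standard deviation. The software-vs-observers comparison treats the
  observers' average as one measurement per image.

## Problem sizes used by the test suite

The suite renders full-size phantoms (230 x 370 mm at 0.1 mm pitch,
2300 x 3700 px). The heavier properties use deliberately modest but
informative batch sizes: the correlation oracle checks 200 random
template/image pairs up to 16 x 16 / 64 x 64; Gaussian-fit recovery uses
100 noisy replicates; dose monotonicity compares median group scores over
10 seeds per AEC mode; positioning robustness runs the full 12-image
suite once at fixed seed.

## Known limitations

* The insert geometry defaults are plausible but not the vendor's; scoring
  real images with the defaults will localize the insert (only its overall
  size matters) but per-object ROIs require the true layout.
* The 180-degree ambiguity of a rectangle is not resolved: images are
  assumed not to be upside down relative to the laterality tags.
* The DICOM codec reads uncompressed little-endian transfer syntaxes only
  (Explicit and Implicit VR); compressed or multi-frame objects are
  rejected with a clear error.
* Rotations are supported to +/-10 degrees; beyond that localization
  fails rather than guessing.
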