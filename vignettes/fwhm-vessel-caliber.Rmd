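---
title: "Measuring retinal vessel calibers on OCT B-scans with FWHM edge localization"
author: "octvessel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vessel calibers on OCT B-scans with FWHM edge localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octvessel)
```

## The measurement problem

Retinal vessels are the one vascular bed that can be observed directly and
non-invasively, and their calibers track systemic vascular disease: carotid
stenosis narrows retinal arterioles and dilates venules, and revascularization
partially reverses both. On a spectral-domain OCT (SD-OCT) B-scan taken
perpendicular to a vessel in zone B, the vessel cross section shows the two
walls as bands flanking the lumen. A grayscale density profile drawn through
the vessel centre therefore shows, for dark-walled display polarity, two
valleys (the walls) around a bright plateau (the lumen). The measurement task
is to place the four wall boundaries — outer-upper, inner-upper, inner-lower,
outer-lower — with sub-pixel precision, and from them derive seven parameters
per eye:

* `RALD` / `RVLD` — arteriolar / venular lumen diameter (µm),
* `RAOD` / `RVOD` — arteriolar / venular outer diameter (µm),
* `AWT = (RAOD − RALD)/2`, `VWT = (RVOD − RVLD)/2` — wall thickness (µm),
* `AVR = RAOD/RVOD` — arteriovenous ratio (dimensionless).

Each vessel is measured on three replicate lines and the arithmetic means are
carried forward.

## The FWHM edge model

Because the imaging blurs the walls, an edge has no single-pixel location;
it lies between the extreme gray levels on either side of the transition.
The full-width-at-half-maximum (FWHM) rule makes that operational. For each
of the four flanks (outer and inner side of each wall):

1. **Levels.** Extreme levels are read from the 3-point moving-mean curve
   (`smooth3()`); the flank's *half level* is the arithmetic midpoint of its
   smoothed maximum and minimum. Using the smoothed curve makes the levels
   robust to single-pixel speckle excursions.
2. **Chord.** A line is fitted through the pair of *consecutive* samples with
   the largest absolute difference inside the flank — the steepest chord —
   on the raw profile by default (`chordOn = "raw"`); the 3-point averaging
   is applied to the extreme values only. Ties are broken toward the pair
   nearest the wall extremum, keeping the edge adjacent to the wall.
3. **Crossing.** The edge is where the chord crosses the half level, solved
   analytically; no magnified resampling of the raster is needed. The
   crossing must fall inside the flank, otherwise the profile is rejected
   (`edgeLocalizationError`).

The wall bands themselves are found on the smoothed curve (`locateBands()`):
the two most prominent wall-polarity extrema with an opposite-polarity lumen
extremum between them. Topographic prominence below the `prominence`
threshold (default 5 grayscale) disqualifies a wall candidate, which keeps
speckle dips from being taken for walls. Each flank then runs from the wall
extremum to the *nearest* opposite-polarity extremum on that side (lumen
inward, background shoulder outward; profile boundaries qualify). The
nearest-extremum rule matters under speckle: it keeps flanks short, so the
steepest-chord search cannot wander onto a noise jump on a distant plateau.
Profiles without two qualifying walls separated by a lumen extremum raise
`bandDetectionError` — the image does not clearly show the vessel wall and
is rejected, which mirrors how such images are excluded in practice.

The whole construction is invariant to affine intensity maps `a·v + b`
(`a > 0`): the half level and the chord transform together, so the crossing
is unchanged. It is likewise symmetric: mirroring a profile mirrors every
edge.

```{r example}
spec <- SyntheticVesselSpec(outerDiameter = 147, lumenDiameter = 114,
                            psfSigma = 2)
r <- renderProfile(spec)
es <- detectEdges(r$profile)
round(edgePositions(es) - edgePositions(r$truth), 3)
diametersFromEdges(es)
```

## The synthetic generator

No raw scans are distributed with this package, so every stage is exercised
against a synthetic model with exact ground truth. A vessel cross section is
a piecewise-constant template — background | wall | lumen | wall |
background — with the four discontinuities as the true edges. The render:

1. convolves the template with a Gaussian point-spread function of standard
   deviation `psfSigma` (µm), evaluated in closed form through the Gaussian
   CDF;
2. integrates over each pixel's aperture (a box of one pixel pitch, also in
   closed form). Detector pixels integrate rather than point-sample, and the
   aperture is what carries sub-pixel information at low blur: a
   point-sampled hard step can only ever be localized to the midpoint of its
   bracketing samples, whereas the pixel containing the step takes a
   proportionally intermediate value;
3. multiplies by unit-mean gamma speckle with shape `speckleShape`
   (`sd = 1/sqrt(shape)`; `Inf` disables noise), the standard surrogate for
   the multiplicative interference noise of coherent imaging. Nothing in the
   source text of the study this emulates quantifies image noise, so the
   default is noiseless and the shape is a free simulation parameter.

For 2-D B-scans (`renderBscan()`) the vessel is a lumen disk inside a wall
annulus and the PSF is applied along the axial (column) direction of each
A-scan. Axial-only blur mirrors the physics — OCT axial resolution is
coherence-gated and independent of the beam optics — and makes the vertical
centre-column of the image *exactly* the 1-D profile, which pins the
image-to-profile extraction path in tests. The model deliberately omits
retinal layers, vessel shadowing, motion artifacts and pulsation; passing
tests therefore certify the edge mathematics and plumbing, not robustness
to those confounders.

Default geometry (outer 147 µm, lumen 114 µm) and the cohort caliber scale
used in tests (outer 130–190 µm, wall 12–20 µm) follow the arm means of the
carotid-stenosis cohort the package is calibrated to; intensities default to
60/200/140 (wall/lumen/background — dark walls on mid-gray tissue with a
brighter lumen), which is arbitrary and immaterial since every edge estimate
is affine-invariant. `psfSigma` defaults to 5 µm, the device-class axial
resolution figure; pitch defaults to 5 µm/px after 1:1 aspect
normalization.

## The cohort simulator

`simulateCohort()` draws per-eye records for a control group (left/right
eyes) and a stenosis group (ipsilateral/contralateral, before/after carotid
stenting). Each arm is defined by the normal mean and SD of the four
*measured* diameters; the derived columns AWT, VWT and AVR are recomputed
row-wise, so the defining identities hold exactly in every record (and AVR
is a ratio of diameters, not an independently drawn quantity — its simulated
mean is a ratio-distribution mean).

Two correlations shape the joint draw:

* `subjectCorrelation` (default 0.9): exchangeable correlation between arms
  of the same subject. Same-subject eyes and repeat visits are strongly
  correlated, which is why paired contrasts in such cohorts reach |t| ≈ 15
  on mean differences that an independent test would call |t| ≈ 2.
* `vesselCorrelation` (default 0.95): correlation between a vessel's lumen
  and outer diameter. Fully independent draws at clinical SDs would make
  wall thickness `(outer − lumen)/2` negative in a few percent of records
  and inflate its SD to ~8 µm; 0.95 is the value implied by lumen caliber
  and wall thickness varying independently, and keeps wall-thickness SDs at
  the clinical 2–4 µm scale.

Arteries and veins are drawn independently of each other; the one visible
consequence is a somewhat larger simulated AVR spread than clinical tables
show (real arteriolar and venular calibers co-vary). Default arm moments and
sizes (59 control, 50 stenosis subjects) are the package's calibration to
the cohort it reproduces; see `defaultCohortArms()`.

## The statistics battery

`buildTables()` reproduces the eight standard comparisons of such a cohort
(control left vs right; stenosis-ipsilateral pre/post vs each control eye;
ipsilateral vs contralateral at both timepoints; ipsilateral pre vs post),
for all seven parameters. Conventions, chosen to match how published
summary tables of this kind recompute:

* **Student pooled-variance t** is the default for independent comparisons
  (`independentT()`, `pooledTFromSummary()`); Welch is available but it is
  the pooled form whose statistics agree with summary-row recomputation.
* **Paired t** on within-subject differences wherever both arms come from
  the same subjects, joined on `subject_id`. Paired statistics cannot be
  recovered from printed summary rows (they need the within-subject
  correlation), so no such recomputation is attempted.
* **Pearson chi-square without continuity correction** for 2×2 tables
  (`chiSquare2x2()`); Yates behind a flag; a Fisher exact p is attached
  whenever an expected count falls below 5.
* **Shapiro–Wilk gate** at alpha 0.05 routes each comparison to the t branch
  or to Mann–Whitney / Wilcoxon signed-rank (`rankTests()`: exact for n ≤ 25
  without ties, tie-corrected normal approximation otherwise).
* All tests are two-tailed at alpha 0.05 and no multiple-testing correction
  is applied. Statistics are always *first arm minus second arm*; published
  tables of this kind are not internally consistent about sign, so only
  magnitudes should be compared across sources.

## Numerical choices and degenerate inputs

* `smooth3` leaves the two boundary samples raw rather than truncating the
  window; edges never sit at profile termini.
* Plateaus (runs of equal smoothed values) count as one extremum at the run
  centre.
* Zero pooled variance with equal means yields t = 0, with unequal means an
  `infiniteStatisticError`; all-zero paired differences leave the
  signed-rank statistic undefined.
* `zoneBAnnulus()` offers two conventions, `"literal"` (radii 0.5 D/0.75 D,
  circles drawn at 1 and 1.5 disc diameters) and `"conventional"` (0.75
  D/1.0 D); protocols differ and intent is not guessed.
* Coordinates are continuous µm with the origin at the top-left pixel
  centre; aspect normalization resamples to the finer of the two pitches by
  bilinear interpolation.

## Known limitations

The FWHM caliber is biased once a wall band is under-resolved. At 5 µm
sampling a 12–20 µm wall trough spans only 2–4 samples; as blur grows the
measured (3-point-averaged) trough minimum rises, the half level rises with
it, and the outer crossing moves outward — the classic band-broadening bias
of half-maximum widths. At device-realistic blur (axial resolution ~5 µm
FWHM, Gaussian sigma ~2 µm) the bias is a fraction of a pixel, and the
replicate-averaged calibers are accurate to well under a micron of random
error; at several times that blur the bias reaches pixels. The magnified
(800 %) display resampling used in interactive workflows reduces the
smoothing footprint but not the underlying physics. Consequently synthetic
benchmarks in this package's tests distinguish the resolved regime (sigma
up to ~3 µm, where recovery is asserted tightly) from stress conditions at
larger blur.

Under strong speckle the steepest-chord rule — two consecutive raw samples —
occasionally latches onto a noise jump or pushes the crossing marginally
outside its flank; such profiles are rejected rather than silently
mis-measured, matching the protocol's "only images clearly showing the wall"
rule.

## Problem sizes used in the checks

The shipped test suite renders profiles of ~40–60 samples; recovery sweeps
use 200 random vessels per condition; cohort-level calibration uses 2,000
null cohorts (type-I rate of the pooled t) and 800 cohorts at published
effect sizes (mean t), with two-arm cohorts of 59 + 50 subjects. These sizes
keep the full suite under a minute of compute while leaving Monte-Carlo
standard errors well inside the asserted bands.
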