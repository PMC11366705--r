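Package: octvessel
Title: Retinal Vessel Caliber from OCT B-Scans by Full-Width-at-Half-Maximum
    Edge Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures retinal arteriolar and venular calibers on spectral-domain
    optical coherence tomography (SD-OCT) cross sections. A grayscale density
    profile drawn across a vessel is segmented by sub-pixel full-width-at-half-
    maximum (FWHM) edge localization: per-flank extrema are smoothed by a
    three-point moving mean, the half level is the midpoint of the flank's
    extreme values, and the edge is the crossing of that level with the line
    through the steepest pair of consecutive samples. Four wall edges per
    vessel yield lumen and outer diameters, wall thicknesses and the
    arteriovenous ratio. The package also ships a synthetic OCT vessel
    generator (analytic Gaussian point-spread blur, gamma speckle, known
    ground-truth edges), a cohort simulator, and the summary-statistics
    battery (Shapiro-Wilk gating, pooled and paired t tests, rank tests,
    Pearson chi-square) used to analyse such cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'show-methods.R'
    'synthetic.R'
    'image_profile.R'
    'fwhm.R'
    'metrics.R'
    'stats.R'
    'io.R'
    'pipeline.R'
    'octvessel-package.R'
RoxygenNote: 7.3.3
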