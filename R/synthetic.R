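# Synthetic OCT vessel generator. Every downstream stage of the pipeline is
# benchmarked against these renders, whose edge positions are known exactly.
#
# The imaging model: a piecewise-constant template
#   background | wall | lumen | wall | background
# convolved with a Gaussian point-spread function of standard deviation
# psfSigma, then integrated over each pixel's aperture (a box of one pixel
# pitch - detector pixels integrate, they do not point-sample), then
# multiplied by unit-mean gamma speckle. Both convolutions are evaluated
# analytically, so rendered values carry no discretization error and the
# ground-truth edges are exactly the template discontinuities. The pixel
# aperture is what carries sub-pixel edge information at low blur: a
# point-sampled hard step is localizable only to the midpoint of its
# bracketing samples, whereas the pixel containing the step takes a
# proportional intermediate value.

## Unit step at e, blurred with N(0, sigma^2) and averaged over a pixel
## aperture of width h centred on x. Uses int Phi(t/s) dt = t Phi(t/s)
## + s phi(t/s); for sigma = 0 the edge response is the exact linear ramp
## of width h.
.edgeResponse <- function(x, e, sigma, h) {
  if (h <= 0) {
    if (sigma > 0) return(stats::pnorm((x - e) / sigma))
    return(ifelse(x > e, 1, ifelse(x < e, 0, 0.5)))
  }
  G <- if (sigma > 0) {
    function(u) u * stats::pnorm(u / sigma) + sigma * stats::dnorm(u / sigma)
  } else {
    function(u) pmax(u, 0)
  }
  (G(x - e + h / 2) - G(x - e - h / 2)) / h
}

## The 4-edge template (or 2-edge: wall band without lumen, used for
## off-centre B-scan columns) through the blurred, pixel-integrated edge
## response. edges: increasing (outer-upper, inner-upper, inner-lower,
## outer-lower).
.blurTemplate <- function(x, edges, bg, wall, lum, sigma, aperture = 0) {
  stepAt <- function(e) .edgeResponse(x, e, sigma, aperture)
  if (length(edges) == 4L) {
    bg + (wall - bg) * (stepAt(edges[1]) - stepAt(edges[4])) +
      (lum - wall) * (stepAt(edges[2]) - stepAt(edges[3]))
  } else {
    bg + (wall - bg) * (stepAt(edges[1]) - stepAt(edges[2]))
  }
}

.applySpeckle <- function(values, shape, seed) {
  if (!is.finite(shape)) return(values)
  .withSeed(seed, function()
    values * stats::rgamma(length(values), shape = shape, rate = shape))
}

#' Render a synthetic vessel density profile with known edge positions
#'
#' Renders the 1-D grayscale density curve a measurement line through the
#' centre of the vessel of `spec` would produce, together with the true edge
#' positions. The vessel is centred on the profile; samples are `pixelPitch`
#' um apart starting at 0.
#'
#' @param spec a [SyntheticVesselSpec-class].
#' @param length profile length in um; must exceed
#'   `outerDiameter + 6 * psfSigma`. Default adds a 6-pixel background margin
#'   on each side.
#' @return list with elements `profile` ([DensityProfile-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' r <- renderProfile(SyntheticVesselSpec(psfSigma = 0))
#' edgePositions(r$truth)
#' @seealso [renderBscan()], [detectEdges()]
#' @export
renderProfile <- function(spec, length = NULL) {
  stopifnot(is(spec, "SyntheticVesselSpec"))
  validObject(spec)
  if (is.null(length))
    length <- spec@outerDiameter + 6 * spec@psfSigma + 12 * spec@pixelPitch
  .assertScalarNumber(length, "length", positive = TRUE)
  if (length <= spec@outerDiameter + 6 * spec@psfSigma)
    stopWithClass("invalidSpecError",
                  "profile length %.3g um cannot contain the vessel plus a 3-sigma margin per side",
                  length)
  n <- floor(length / spec@pixelPitch) + 1
  x <- (seq_len(n) - 1) * spec@pixelPitch
  centre <- x[n] / 2
  edges <- centre + c(-spec@outerDiameter, -spec@lumenDiameter,
                      spec@lumenDiameter, spec@outerDiameter) / 2
  vals <- .blurTemplate(x, edges, spec@backgroundIntensity,
                        spec@wallIntensity, spec@lumenIntensity,
                        spec@psfSigma, aperture = spec@pixelPitch)
  vals <- .applySpeckle(vals, spec@speckleShape, spec@seed)
  list(profile = DensityProfile(vals, step = spec@pixelPitch),
       truth = GroundTruth(edges))
}

#' Render a synthetic OCT B-scan of a vessel cross section
#'
#' Draws the vessel of `spec` as concentric disks (lumen inside a wall
#' annulus) centred on a `height` x `width` pixel canvas, applies the
#' Gaussian PSF analytically along the axial (column) direction of each
#' A-scan, and multiplies by per-pixel gamma speckle. Applying the PSF
#' axially mirrors the coherence-gated axial resolution of OCT and makes the
#' vertical centre-column profile exactly the 1-D profile of
#' [renderProfile()].
#'
#' @param spec a [SyntheticVesselSpec-class].
#' @param height,width canvas size in pixels; the canvas must contain the
#'   vessel plus a 3-sigma margin per side. Use odd sizes to land a pixel
#'   column exactly on the vessel centre.
#' @return list with elements `image` ([OCTImage-class], isotropic pitch)
#'   and `truth` ([GroundTruth-class] for the vertical line through the
#'   vessel centre, positions um from the top pixel centre).
#' @export
renderBscan <- function(spec, height = 61L, width = 61L) {
  stopifnot(is(spec, "SyntheticVesselSpec"))
  validObject(spec)
  p <- spec@pixelPitch
  H <- (height - 1) * p
  W <- (width - 1) * p
  need <- spec@outerDiameter + 6 * spec@psfSigma
  if (H <= need || W <= need)
    stopWithClass("invalidSpecError",
                  "canvas %.3g x %.3g um cannot contain the %.3g um annulus plus margins",
                  H, W, spec@outerDiameter)
  cy <- H / 2
  cx <- W / 2
  rOut <- spec@outerDiameter / 2
  rLum <- spec@lumenDiameter / 2
  y <- (seq_len(height) - 1) * p
  img <- matrix(spec@backgroundIntensity, nrow = height, ncol = width)
  for (j in seq_len(width)) {
    dx <- (j - 1) * p - cx
    if (abs(dx) >= rOut) next
    hOut <- sqrt(rOut^2 - dx^2)
    if (abs(dx) < rLum) {
      hLum <- sqrt(rLum^2 - dx^2)
      e <- cy + c(-hOut, -hLum, hLum, hOut)
    } else {
      e <- cy + c(-hOut, hOut)
    }
    img[, j] <- .blurTemplate(y, e, spec@backgroundIntensity,
                              spec@wallIntensity, spec@lumenIntensity,
                              spec@psfSigma, aperture = p)
  }
  img <- .applySpeckle(img, spec@speckleShape, spec@seed)
  truth <- GroundTruth(cy + c(-rOut, -rLum, rLum, rOut))
  list(image = OCTImage(img, axialPitch = p, transversePitch = p),
       truth = truth)
}

#' Default study arms for the cohort simulator
#'
#' The simulator's default calibration: one control group (group 0, left and
#' right eyes at a single timepoint) and one carotid-stenosis group (group 1,
#' ipsilateral and contralateral eyes before and after carotid artery
#' stenting), each arm given by the mean and SD (um) of the four measured
#' diameters. Values are representative zone-B calibers of such a cohort.
#'
#' @return data.frame with one row per arm.
#' @export
defaultCohortArms <- function() {
  arm <- function(group, eye, timepoint, rald, raod, rvld, rvod)
    data.frame(group = group, eye = eye, timepoint = timepoint,
               mean_RALD = rald[1], sd_RALD = rald[2],
               mean_RAOD = raod[1], sd_RAOD = raod[2],
               mean_RVLD = rvld[1], sd_RVLD = rvld[2],
               mean_RVOD = rvod[1], sd_RVOD = rvod[2],
               stringsAsFactors = FALSE)
  rbind(
    arm(0, "left", "single", c(114.46, 9.79), c(147.33, 10.81),
        c(150.21, 16.52), c(178.01, 16.60)),
    arm(0, "right", "single", c(114.67, 11.86), c(146.91, 12.36),
        c(149.91, 17.33), c(177.49, 18.35)),
    arm(1, "ipsilateral", "pre_CAS", c(103.96, 11.56), c(135.42, 12.17),
        c(155.25, 16.51), c(186.84, 18.65)),
    arm(1, "contralateral", "pre_CAS", c(111.18, 10.23), c(143.40, 9.03),
        c(152.67, 17.92), c(183.45, 18.41)),
    arm(1, "ipsilateral", "post_CAS", c(108.02, 11.48), c(139.56, 12.26),
        c(150.82, 15.68), c(182.23, 17.87)),
    arm(1, "contralateral", "post_CAS", c(110.47, 10.69), c(143.60, 9.09),
        c(147.34, 18.65), c(179.48, 18.17))
  )
}

#' Construct a CohortSpec
#'
#' @param arms data.frame of arm definitions (see [defaultCohortArms()] for
#'   the required columns and the default calibration).
#' @param n0,n1 subjects in group 0 / group 1.
#' @param subjectCorrelation exchangeable correlation between arms of the
#'   same subject, in `[0, 1)`. Default 0.9 (same-subject eyes and repeat
#'   visits are strongly correlated; paired contrasts are far more powerful
#'   than independent ones at this value).
#' @param vesselCorrelation correlation between the lumen and outer diameter
#'   of one vessel, in `[0, 1)`. Default 0.95, the value implied by lumen
#'   caliber and wall thickness varying independently at the calibrated SDs;
#'   it keeps simulated wall-thickness SDs at the clinical 2-4 um scale.
#' @param seed integer RNG seed, or NA.
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(arms = defaultCohortArms(), n0 = 59L, n1 = 50L,
                       subjectCorrelation = 0.9, vesselCorrelation = 0.95,
                       seed = NA_real_) {
  new("CohortSpec", arms = arms, n0 = as.integer(n0), n1 = as.integer(n1),
      subjectCorrelation = as.numeric(subjectCorrelation),
      vesselCorrelation = as.numeric(vesselCorrelation),
      seed = as.numeric(seed))
}

## Draw the lumen/outer pair of one vessel type for all arms of one group.
## Variables are ordered (arm1 lumen, arm1 outer, arm2 lumen, ...) with
## correlation R_arms (exchangeable rhoS) %x% R_vessel (2x2 rhoV).
.drawGroup <- function(ga, n, lumenCol, outerCol, rhoS, rhoV) {
  k <- nrow(ga)
  mu <- as.vector(rbind(ga[[paste0("mean_", lumenCol)]],
                        ga[[paste0("mean_", outerCol)]]))
  sds <- as.vector(rbind(ga[[paste0("sd_", lumenCol)]],
                         ga[[paste0("sd_", outerCol)]]))
  Rarm <- matrix(rhoS, k, k)
  diag(Rarm) <- 1
  Rves <- matrix(c(1, rhoV, rhoV, 1), 2, 2)
  R <- Rarm %x% Rves
  Sigma <- diag(sds, 2 * k) %*% R %*% diag(sds, 2 * k)
  out <- tryCatch(MASS::mvrnorm(n, mu = mu, Sigma = Sigma),
                  error = function(e)
                    stopWithClass("invalidSpecError",
                                  "degenerate cohort covariance: %s",
                                  conditionMessage(e)))
  matrix(out, nrow = n)
}

#' Simulate a per-eye cohort with exact derived-parameter identities
#'
#' Draws the four measured diameters of every (subject, arm) cell from the
#' multivariate normal model of the [CohortSpec-class] and recomputes the
#' derived columns AWT = (RAOD - RALD)/2, VWT = (RVOD - RVLD)/2 and
#' AVR = RAOD/RVOD row-wise, so those identities hold exactly in every
#' simulated record. Arteries and veins are drawn independently of each
#' other.
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame with columns subject_id, group, eye, timepoint, RALD,
#'   RAOD, AWT, RVLD, RVOD, VWT, AVR (diameters um, AVR dimensionless).
#' @examples
#' cohort <- simulateCohort(cohortSpec(seed = 1))
#' aggregate(RAOD ~ group + eye + timepoint, cohort, mean)
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  .withSeed(spec@seed, function() {
    rows <- list()
    for (g in c(0, 1)) {
      ga <- spec@arms[spec@arms$group == g, , drop = FALSE]
      if (!nrow(ga)) next
      n <- if (g == 0) spec@n0 else spec@n1
      ids <- sprintf("%s%03d", if (g == 0) "C" else "S", seq_len(n))
      art <- .drawGroup(ga, n, "RALD", "RAOD",
                        spec@subjectCorrelation, spec@vesselCorrelation)
      ven <- .drawGroup(ga, n, "RVLD", "RVOD",
                        spec@subjectCorrelation, spec@vesselCorrelation)
      for (a in seq_len(nrow(ga))) {
        pars <- vesselParameters(rald = art[, 2 * a - 1], raod = art[, 2 * a],
                                 rvld = ven[, 2 * a - 1], rvod = ven[, 2 * a])
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(subject_id = ids, group = g, eye = ga$eye[a],
                     timepoint = ga$timepoint[a], stringsAsFactors = FALSE),
          pars)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
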