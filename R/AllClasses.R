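# S4 containers. Conventions used throughout the package:
#  * intensities are 8-bit grayscale values stored as doubles (0-255 nominal;
#    synthetic speckle may exceed 255 and is only clamped on image export);
#  * every physical position, pitch and diameter is in micrometres (um);
#  * continuous image coordinates are (x, y) um with the origin at the centre
#    of the top-left pixel, x increasing along columns (transverse) and y
#    along rows (axial).

#' OCTImage: a grayscale OCT B-scan raster with physical pixel pitch
#'
#' Wraps a numeric matrix of grayscale values together with the axial
#' (row-direction) and transverse (column-direction) pixel pitches in um/px.
#'
#' @slot pixels numeric matrix, rows = axial samples, columns = transverse.
#' @slot axialPitch um per pixel along columns of a single A-scan (rows).
#' @slot transversePitch um per pixel across A-scans (columns).
#' @export
setClass("OCTImage",
  representation(pixels = "matrix", axialPitch = "numeric",
                 transversePitch = "numeric"))

setValidity("OCTImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels) || length(object@pixels) == 0L)
    msg <- c(msg, "'pixels' must be a non-empty numeric matrix")
  for (sl in c("axialPitch", "transversePitch")) {
    v <- slot(object, sl)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number (um/px)", sl))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OCTImage
#'
#' @param pixels numeric matrix of grayscale values (rows = axial direction).
#' @param axialPitch,transversePitch pixel pitch in um/px.
#' @return An [OCTImage-class] object.
#' @examples
#' img <- OCTImage(matrix(runif(200, 0, 255), 10, 20), axialPitch = 5,
#'                 transversePitch = 6)
#' @export
OCTImage <- function(pixels, axialPitch, transversePitch = axialPitch) {
  new("OCTImage", pixels = pixels, axialPitch = as.numeric(axialPitch),
      transversePitch = as.numeric(transversePitch))
}

#' DensityProfile: grayscale samples along a measurement line
#'
#' Uniformly spaced grayscale samples along a line drawn across a vessel.
#' Positions are um from the start of the line; at least 7 samples are
#' required (the minimum on which two 3-point-averaged extrema separated by a
#' lumen extremum can exist).
#'
#' @slot values numeric vector of grayscale samples.
#' @slot step sample spacing in um.
#' @slot origin position (um) of the first sample.
#' @export
setClass("DensityProfile",
  representation(values = "numeric", step = "numeric", origin = "numeric"))

setValidity("DensityProfile", function(object) {
  msg <- character()
  if (length(object@values) < 7L)
    msg <- c(msg, "a density profile needs at least 7 samples")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must all be finite")
  if (length(object@step) != 1L || !is.finite(object@step) || object@step <= 0)
    msg <- c(msg, "'step' must be a single positive number (um)")
  if (length(object@origin) != 1L || !is.finite(object@origin))
    msg <- c(msg, "'origin' must be a single finite number (um)")
  if (length(msg)) msg else TRUE
})

#' Construct a DensityProfile
#'
#' @param values numeric grayscale samples.
#' @param step sample spacing, um.
#' @param origin position of the first sample, um (default 0).
#' @return A [DensityProfile-class] object.
#' @export
DensityProfile <- function(values, step, origin = 0) {
  new("DensityProfile", values = as.numeric(values), step = as.numeric(step),
      origin = as.numeric(origin))
}

.EDGE_NAMES <- c("outer_upper", "inner_upper", "inner_lower", "outer_lower")

#' GroundTruth: true wall-edge positions of a synthetic vessel
#'
#' Positions (um, along the profile axis) of the four wall boundaries of a
#' rendered vessel, strictly increasing in the order outer-upper, inner-upper,
#' inner-lower, outer-lower.
#'
#' @slot positions named numeric vector of length 4.
#' @export
setClass("GroundTruth", representation(positions = "numeric"))

setValidity("GroundTruth", function(object) {
  p <- object@positions
  if (length(p) != 4L || !all(is.finite(p)))
    return("'positions' must be 4 finite edge positions")
  if (!identical(names(p), .EDGE_NAMES))
    return(sprintf("'positions' must be named %s", paste(.EDGE_NAMES, collapse = ", ")))
  if (any(diff(p) <= 0))
    return("edge positions must be strictly increasing")
  TRUE
})

#' Construct a GroundTruth
#' @param positions numeric length 4, um, in order outer-upper, inner-upper,
#'   inner-lower, outer-lower.
#' @return A [GroundTruth-class] object.
#' @export
GroundTruth <- function(positions) {
  positions <- as.numeric(positions)
  names(positions) <- .EDGE_NAMES
  new("GroundTruth", positions = positions)
}

#' EdgeSet: the four sub-pixel wall-edge estimates of one vessel
#'
#' One row per edge (outer-upper, inner-upper, inner-lower, outer-lower) with
#' the estimated sub-pixel position, the half level used, the slope of the
#' fitted chord (grayscale/um) and the indices of the consecutive sample pair
#' the chord passes through.
#'
#' @slot edges data.frame with columns wall, side, position, half_level,
#'   slope, chord_i0, chord_i1.
#' @export
setClass("EdgeSet", representation(edges = "data.frame"))

setValidity("EdgeSet", function(object) {
  e <- object@edges
  need <- c("wall", "side", "position", "half_level", "slope",
            "chord_i0", "chord_i1")
  if (!all(need %in% names(e)))
    return(sprintf("edge table must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e) != 4L) return("an EdgeSet has exactly 4 edges")
  key <- paste(e$side, e$wall, sep = "_")
  if (!identical(key, .EDGE_NAMES))
    return("edges must be ordered outer-upper, inner-upper, inner-lower, outer-lower")
  if (any(diff(e$position) <= 0))
    return("edge positions must be strictly increasing")
  if (any(e$slope == 0)) return("chord slopes must be non-zero")
  TRUE
})

#' SyntheticVesselSpec: geometry and imaging model of a synthetic vessel
#'
#' Describes a vessel cross section as a lumen of diameter `lumenDiameter`
#' inside a wall ring of outer diameter `outerDiameter` over a uniform
#' background, imaged with a Gaussian axial point-spread function of standard
#' deviation `psfSigma` and unit-mean multiplicative gamma speckle with shape
#' `speckleShape` (`Inf` = noiseless). `polarity` records whether walls are
#' darker (`"dark_walls"`, the default: walls appear as valleys on the
#' density curve) or brighter than their surroundings.
#'
#' @export
setClass("SyntheticVesselSpec",
  representation(outerDiameter = "numeric", lumenDiameter = "numeric",
                 wallIntensity = "numeric", lumenIntensity = "numeric",
                 backgroundIntensity = "numeric", psfSigma = "numeric",
                 speckleShape = "numeric", pixelPitch = "numeric",
                 polarity = "character", seed = "numeric"))

setValidity("SyntheticVesselSpec", function(object) {
  msg <- character()
  if (!(object@outerDiameter > object@lumenDiameter && object@lumenDiameter > 0))
    msg <- c(msg, "need outerDiameter > lumenDiameter > 0")
  if (object@psfSigma < 0) msg <- c(msg, "'psfSigma' must be >= 0")
  if (object@pixelPitch <= 0) msg <- c(msg, "'pixelPitch' must be > 0")
  if (object@speckleShape <= 0) msg <- c(msg, "'speckleShape' must be > 0 (Inf = noiseless)")
  ints <- c(object@wallIntensity, object@lumenIntensity, object@backgroundIntensity)
  if (any(ints < 0 | ints > 255))
    msg <- c(msg, "intensities must lie in [0, 255]")
  if (!object@polarity %in% c("dark_walls", "bright_walls"))
    msg <- c(msg, "'polarity' must be \"dark_walls\" or \"bright_walls\"")
  if (object@polarity == "dark_walls" &&
      !(object@wallIntensity < object@lumenIntensity &&
        object@wallIntensity < object@backgroundIntensity))
    msg <- c(msg, "dark_walls requires the wall darker than lumen and background")
  if (object@polarity == "bright_walls" &&
      !(object@wallIntensity > object@lumenIntensity &&
        object@wallIntensity > object@backgroundIntensity))
    msg <- c(msg, "bright_walls requires the wall brighter than lumen and background")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticVesselSpec
#'
#' Defaults describe a retinal arteriole of a healthy adult as it appears in a
#' superotemporal zone-B SD-OCT cross section: outer diameter 147 um, lumen
#' 114 um (wall thickness 16.5 um), dark walls (intensity 60) between a
#' mid-gray background (140) and a brighter lumen interior (200), Gaussian
#' axial PSF sigma of 5 um (the device-class axial resolution), 5 um/px
#' isotropic sampling and no speckle. All downstream edge estimates are
#' invariant to affine rescaling of the three intensities.
#'
#' @param outerDiameter,lumenDiameter vessel outer/lumen diameter, um.
#' @param wallIntensity,lumenIntensity,backgroundIntensity grayscale 0-255;
#'   when `polarity = "bright_walls"` and intensities are left at their
#'   defaults, wall and lumen intensities are swapped.
#' @param psfSigma Gaussian PSF standard deviation, um.
#' @param speckleShape gamma shape of unit-mean multiplicative speckle;
#'   `Inf` disables noise. Smaller shape = noisier (sd = 1/sqrt(shape)).
#' @param pixelPitch sample spacing, um/px (isotropic).
#' @param polarity `"dark_walls"` (valleys on the density curve) or
#'   `"bright_walls"`.
#' @param seed integer RNG seed for speckle, or NA to use the current stream.
#' @return A [SyntheticVesselSpec-class] object.
#' @examples
#' spec <- SyntheticVesselSpec(outerDiameter = 147, lumenDiameter = 114,
#'                             psfSigma = 5, speckleShape = Inf)
#' @export
SyntheticVesselSpec <- function(outerDiameter = 147, lumenDiameter = 114,
                                wallIntensity = NULL, lumenIntensity = NULL,
                                backgroundIntensity = 140, psfSigma = 5,
                                speckleShape = Inf, pixelPitch = 5,
                                polarity = c("dark_walls", "bright_walls"),
                                seed = NA_real_) {
  polarity <- match.arg(polarity)
  if (is.null(wallIntensity))
    wallIntensity <- if (polarity == "dark_walls") 60 else 200
  if (is.null(lumenIntensity))
    lumenIntensity <- if (polarity == "dark_walls") 200 else 60
  new("SyntheticVesselSpec",
      outerDiameter = as.numeric(outerDiameter),
      lumenDiameter = as.numeric(lumenDiameter),
      wallIntensity = as.numeric(wallIntensity),
      lumenIntensity = as.numeric(lumenIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      psfSigma = as.numeric(psfSigma), speckleShape = as.numeric(speckleShape),
      pixelPitch = as.numeric(pixelPitch), polarity = polarity,
      seed = as.numeric(seed))
}

.COHORT_PARAMS <- c("RALD", "RAOD", "AWT", "RVLD", "RVOD", "VWT", "AVR")
.ARM_MOMENTS <- as.vector(outer(c("mean", "sd"),
                                c("RALD", "RAOD", "RVLD", "RVOD"),
                                function(a, b) paste(a, b, sep = "_")))

#' CohortSpec: sampling model for a simulated per-eye cohort
#'
#' Each row of `arms` defines one study arm (a group/eye/timepoint cell) by
#' the normal mean and SD of the four measured diameters (RALD, RAOD, RVLD,
#' RVOD, um). Within a subject, arms are drawn from a multivariate normal
#' with exchangeable correlation `subjectCorrelation`; within a vessel, lumen
#' and outer diameter are correlated at `vesselCorrelation`. The derived
#' columns AWT, VWT and AVR are always recomputed row-wise from the drawn
#' diameters, so the wall-thickness and ratio identities hold exactly for
#' every simulated record.
#'
#' @export
setClass("CohortSpec",
  representation(arms = "data.frame", n0 = "integer", n1 = "integer",
                 subjectCorrelation = "numeric", vesselCorrelation = "numeric",
                 seed = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  a <- object@arms
  need <- c("group", "eye", "timepoint", .ARM_MOMENTS)
  if (!all(need %in% names(a)))
    msg <- c(msg, sprintf("'arms' must have columns %s", paste(need, collapse = ", ")))
  else {
    if (!all(a$group %in% c(0, 1))) msg <- c(msg, "'group' must be 0 or 1")
    sds <- as.matrix(a[, grep("^sd_", names(a))])
    if (any(!is.finite(sds)) || any(sds < 0)) msg <- c(msg, "SDs must be >= 0")
    mns <- as.matrix(a[, grep("^mean_", names(a))])
    if (any(!is.finite(mns))) msg <- c(msg, "means must be finite")
    if (anyDuplicated(a[c("group", "eye", "timepoint")]))
      msg <- c(msg, "duplicate arm (group, eye, timepoint)")
  }
  if (object@n0 < 2L || object@n1 < 2L) msg <- c(msg, "arm sizes must be >= 2")
  for (sl in c("subjectCorrelation", "vesselCorrelation")) {
    r <- slot(object, sl)
    if (length(r) != 1L || !is.finite(r) || r < 0 || r >= 1)
      msg <- c(msg, sprintf("'%s' must be in [0, 1)", sl))
  }
  if (length(msg)) msg else TRUE
})

#' VesselMeasurement: replicate diameters of one vessel and their means
#'
#' Holds the replicate lumen/outer diameters (um) of a single artery or vein
#' (three replicates expected) and their arithmetic means.
#'
#' @export
setClass("VesselMeasurement",
  representation(vessel = "character", lumenReplicates = "numeric",
                 outerReplicates = "numeric", lumenMean = "numeric",
                 outerMean = "numeric"))

setValidity("VesselMeasurement", function(object) {
  msg <- character()
  nl <- length(object@lumenReplicates)
  if (nl < 1L || nl != length(object@outerReplicates))
    msg <- c(msg, "need >= 1 replicate (lumen, outer) pairs of equal length")
  else if (any(object@outerReplicates < object@lumenReplicates))
    msg <- c(msg, "every replicate outer diameter must be >= its lumen diameter")
  if (any(object@lumenReplicates < 0)) msg <- c(msg, "diameters must be >= 0")
  if (!object@vessel %in% c("artery", "vein"))
    msg <- c(msg, "'vessel' must be \"artery\" or \"vein\"")
  if (!isTRUE(all.equal(object@lumenMean, mean(object@lumenReplicates))) ||
      !isTRUE(all.equal(object@outerMean, mean(object@outerReplicates))))
    msg <- c(msg, "means must be the arithmetic means of the replicates")
  if (length(msg)) msg else TRUE
})

#' StatResult: one test statistic of the comparison battery
#'
#' @slot test test name.
#' @slot statistic the test statistic.
#' @slot df degrees of freedom (NA for exact tests).
#' @slot p two-tailed p-value.
#' @slot alpha significance level (0.05 throughout).
#' @slot twoTailed logical, always TRUE here.
#' @slot note list of auxiliary values (e.g. a Fisher exact p when expected
#'   counts fall below 5).
#' @export
setClass("StatResult",
  representation(test = "character", statistic = "numeric", df = "numeric",
                 p = "numeric", alpha = "numeric", twoTailed = "logical",
                 note = "list"))

setValidity("StatResult", function(object) {
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    return("'p' must lie in [0, 1]")
  TRUE
})

.statResult <- function(test, statistic, df = NA_real_, p, note = list()) {
  new("StatResult", test = test, statistic = as.numeric(statistic),
      df = as.numeric(df), p = as.numeric(p), alpha = 0.05, twoTailed = TRUE,
      note = note)
}

## Internal: wall-band decomposition of a profile (sample indices).
setClass("WallBands",
  representation(upper = "integer", lower = "integer", lumen = "integer",
                 upperOuter = "integer", upperInner = "integer",
                 lowerInner = "integer", lowerOuter = "integer"))

setValidity("WallBands", function(object) {
  if (!(object@upper < object@lumen && object@lumen < object@lower))
    return("need upper wall extremum < lumen extremum < lower wall extremum")
  for (sl in c("upperOuter", "upperInner", "lowerInner", "lowerOuter")) {
    r <- slot(object, sl)
    if (length(r) != 2L || r[1] >= r[2])
      return(sprintf("flank '%s' must be a non-empty index range", sl))
  }
  TRUE
})
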