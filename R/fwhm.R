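# FWHM sub-pixel edge localization.
#
# On the density curve a vessel appears as two wall bands (valleys for dark
# walls) flanking the lumen. For each of the four flanks (outer and inner
# side of each wall):
#   1. extreme levels are read from the 3-point moving-mean curve within the
#      flank; the half level is the arithmetic midpoint of the flank's
#      maximum and minimum;
#   2. a line ("chord") is fitted through the pair of consecutive samples
#      with the largest absolute difference, by default on the RAW profile;
#   3. the edge is where the chord crosses the half level.
# The construction is invariant to affine intensity transforms a*v + b
# (a > 0): the half level and the chord transform together.

#' Three-point moving mean with untouched endpoints
#'
#' Centred moving average of window 3. The two boundary samples keep their
#' raw values (edges never sit at profile termini, and truncating the window
#' there would bias the boundary levels).
#'
#' @param values numeric vector, length >= 3.
#' @return numeric vector of the same length.
#' @examples
#' smooth3(c(0, 0, 100, 0, 0))
#' @export
smooth3 <- function(values) {
  n <- length(values)
  if (n < 3L || !is.numeric(values))
    stopWithClass("invalidInputError", "smooth3 needs a numeric vector of >= 3 samples")
  out <- values
  out[2:(n - 1)] <- (values[1:(n - 2)] + values[2:(n - 1)] + values[3:n]) / 3
  out
}

## Plateau-aware local extrema of type "max"/"min". Runs of equal values are
## reduced to their centre index. Interior runs need both neighbouring runs
## strictly on the opposite side; boundary runs qualify only when
## includeBoundary is TRUE and their single neighbour is on the opposite side.
.runExtrema <- function(s, type = c("max", "min"), includeBoundary = FALSE) {
  type <- match.arg(type)
  r <- rle(s)
  k <- length(r$values)
  if (k == 1L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (j in seq_len(k)) {
    v <- r$values[j]
    lOK <- if (j > 1L) {
      if (type == "max") r$values[j - 1] < v else r$values[j - 1] > v
    } else includeBoundary
    rOK <- if (j < k) {
      if (type == "max") r$values[j + 1] < v else r$values[j + 1] > v
    } else includeBoundary
    if (lOK && rOK)
      out <- c(out, starts[j] + (r$lengths[j] - 1L) %/% 2L)
  }
  out
}

## Topographic prominence of a local maximum of w at index i: walk out on
## each side until a strictly higher point (or the boundary), take the lowest
## point passed; prominence = height - max(left base, right base).
.prominence <- function(w, i) {
  n <- length(w)
  h <- w[i]
  lmin <- h
  j <- i - 1L
  while (j >= 1L && w[j] <= h) {
    if (w[j] < lmin) lmin <- w[j]
    j <- j - 1L
  }
  rmin <- h
  j <- i + 1L
  while (j <= n && w[j] <= h) {
    if (w[j] < rmin) rmin <- w[j]
    j <- j + 1L
  }
  h - max(lmin, rmin)
}

#' Locate the two wall bands and their flank ranges on a density profile
#'
#' Works on the 3-point-averaged curve. The two most prominent wall-polarity
#' extrema (valleys for `"dark_walls"`) with an opposite-polarity lumen
#' extremum between them become the upper and lower wall bands; wall
#' candidates with topographic prominence below `prominence` (default 5
#' grayscale) are ignored, which keeps speckle-induced dips from being taken
#' for walls. Each wall's flanks then run from the wall extremum to the
#' nearest opposite-polarity extremum on each side (lumen side inward,
#' background shoulder outward; profile boundaries qualify), which under
#' speckle keeps the steepest-chord search close to the wall.
#'
#' Profiles without two qualifying wall extrema separated by a lumen
#' extremum raise a `bandDetectionError` - such an image does not clearly
#' show the vessel wall and is rejected.
#'
#' @param profile a [DensityProfile-class].
#' @param polarity `"dark_walls"` (default) or `"bright_walls"`.
#' @param prominence minimum prominence (grayscale) for wall and shoulder
#'   extrema on the smoothed curve.
#' @return A `WallBands` object (sample indices of the wall, lumen and flank
#'   ranges).
#' @export
locateBands <- function(profile, polarity = c("dark_walls", "bright_walls"),
                        prominence = 5) {
  stopifnot(is(profile, "DensityProfile"))
  polarity <- match.arg(polarity)
  s <- smooth3(profile@values)
  w <- if (polarity == "dark_walls") -s else s  # walls become maxima of w

  cand <- .runExtrema(w, "max", includeBoundary = FALSE)
  if (length(cand)) {
    prom <- vapply(cand, function(i) .prominence(w, i), numeric(1))
    cand <- cand[prom >= prominence]
    prom <- prom[prom >= prominence]
  }
  if (length(cand) < 2L)
    stopWithClass("bandDetectionError",
                  "found %d wall extremum(a) with prominence >= %g; need 2 (image rejected)",
                  length(cand), prominence)
  top <- cand[order(-prom)][1:2]
  upper <- min(top)
  lower <- max(top)

  oppo <- .runExtrema(w, "min", includeBoundary = TRUE)
  between <- oppo[oppo > upper & oppo < lower]
  if (!length(between))
    stopWithClass("bandDetectionError",
                  "no lumen extremum between the two wall bands (image rejected)")
  lumen <- between[which.min(w[between])]

  ## Each flank runs from the wall extremum to the NEAREST opposite-polarity
  ## extremum on that side (lumen side inward, background shoulder outward).
  ## Under speckle this keeps flanks short, so the steepest-chord search
  ## cannot wander onto noise jumps far from the wall.
  left <- oppo[oppo < upper]
  right <- oppo[oppo > lower]
  innerU <- min(between)
  innerL <- max(between)
  shoulderU <- if (length(left)) max(left) else 1L
  shoulderL <- if (length(right)) min(right) else length(w)
  if (shoulderU >= upper || shoulderL <= lower)
    stopWithClass("bandDetectionError",
                  "wall band lacks an outward background shoulder (image rejected)")

  new("WallBands", upper = as.integer(upper), lower = as.integer(lower),
      lumen = as.integer(lumen),
      upperOuter = as.integer(c(shoulderU, upper)),
      upperInner = as.integer(c(upper, innerU)),
      lowerInner = as.integer(c(innerL, lower)),
      lowerOuter = as.integer(c(lower, shoulderL)))
}

#' Half level of one flank
#'
#' The midpoint `(max + min) / 2` of the 3-point-averaged curve within the
#' flank: the "half maximum" the method is named after.
#'
#' @param smoothed the smoothed profile values (from [smooth3()]).
#' @param flank integer `c(first, last)` sample index range of the flank.
#' @return the half level (grayscale).
#' @export
flankHalfLevel <- function(smoothed, flank) {
  idx <- flank[1]:flank[2]
  seg <- smoothed[idx]
  mx <- max(seg)
  mn <- min(seg)
  if (mx == mn)
    stopWithClass("degenerateFlankError",
                  "flank [%d, %d] is flat; no half level exists", flank[1], flank[2])
  (mx + mn) / 2
}

#' Steepest chord of one flank
#'
#' Finds the pair of consecutive samples within the flank with the largest
#' absolute value difference - by default on the raw, unsmoothed profile -
#' and returns the line through those two points. Ties are broken toward the
#' pair nearest the wall extremum, keeping the edge adjacent to the wall.
#'
#' @param values profile values the chord is fitted on (raw by default in
#'   [detectEdges()]).
#' @param flank integer `c(first, last)` index range.
#' @param positions sample positions, um.
#' @param extremum index of the wall extremum (for the tie-break).
#' @return list with `slope` (grayscale/um), `intercept`, and the sample pair
#'   indices `i0`, `i1`.
#' @export
steepestChord <- function(values, flank, positions, extremum = flank[1]) {
  i0 <- flank[1]
  i1 <- flank[2]
  if (i1 - i0 < 1L)
    stopWithClass("degenerateFlankError", "flank needs >= 2 samples")
  lo <- i0:(i1 - 1L)
  d <- abs(values[lo + 1L] - values[lo])
  dmax <- max(d)
  if (dmax == 0)
    stopWithClass("degenerateFlankError",
                  "all consecutive differences in flank [%d, %d] are zero", i0, i1)
  ties <- lo[d == dmax]
  dist <- pmin(abs(ties - extremum), abs(ties + 1L - extremum))
  a <- ties[order(dist, abs(ties - extremum))][1]
  b <- a + 1L
  slope <- (values[b] - values[a]) / (positions[b] - positions[a])
  intercept <- values[a] - slope * positions[a]
  list(slope = slope, intercept = intercept, i0 = a, i1 = b)
}

#' Edge position: chord meets half level
#'
#' Solves `chord(x) = halfLevel` for the sub-pixel position x. The crossing
#' must fall inside the flank's position range, otherwise an
#' `edgeLocalizationError` is raised.
#'
#' @param chord result of [steepestChord()].
#' @param halfLevel from [flankHalfLevel()].
#' @param flankRange `c(lo, hi)` positions (um) of the flank.
#' @return edge position, um.
#' @export
edgePosition <- function(chord, halfLevel, flankRange) {
  if (chord$slope == 0)
    stopWithClass("degenerateFlankError", "chord slope is zero")
  x <- (halfLevel - chord$intercept) / chord$slope
  tol <- 1e-9 * max(abs(flankRange), 1)
  if (x < flankRange[1] - tol || x > flankRange[2] + tol)
    stopWithClass("edgeLocalizationError",
                  "half-level crossing %.4g um falls outside the flank [%.4g, %.4g] um",
                  x, flankRange[1], flankRange[2])
  x
}

#' Detect the four vessel-wall edges of a density profile
#'
#' Full FWHM edge localization: wall bands and flanks from [locateBands()],
#' then per flank the half level on the smoothed curve, the steepest chord
#' (on the raw curve by default) and the half-level crossing. The four edges
#' must come out in strictly increasing order outer-upper < inner-upper <
#' inner-lower < outer-lower.
#'
#' @param profile a [DensityProfile-class].
#' @param polarity `"dark_walls"` (default) or `"bright_walls"`.
#' @param prominence minimum extremum prominence, grayscale (see
#'   [locateBands()]).
#' @param chordOn `"raw"` (default) fits the steepest chord on the raw
#'   profile; `"smoothed"` fits it on the 3-point-averaged curve. The
#'   half level is always read from the smoothed curve.
#' @return An [EdgeSet-class].
#' @examples
#' r <- renderProfile(SyntheticVesselSpec(psfSigma = 5))
#' es <- detectEdges(r$profile)
#' edgePositions(es) - edgePositions(r$truth)
#' @export
detectEdges <- function(profile, polarity = c("dark_walls", "bright_walls"),
                        prominence = 5, chordOn = c("raw", "smoothed")) {
  polarity <- match.arg(polarity)
  chordOn <- match.arg(chordOn)
  bands <- locateBands(profile, polarity, prominence)
  raw <- profile@values
  s <- smooth3(raw)
  chordVals <- if (chordOn == "raw") raw else s
  pos <- profilePositions(profile)

  flanks <- list(
    list(range = bands@upperOuter, extremum = bands@upper,
         wall = "upper", side = "outer"),
    list(range = bands@upperInner, extremum = bands@upper,
         wall = "upper", side = "inner"),
    list(range = bands@lowerInner, extremum = bands@lower,
         wall = "lower", side = "inner"),
    list(range = bands@lowerOuter, extremum = bands@lower,
         wall = "lower", side = "outer"))

  rows <- lapply(flanks, function(f) {
    half <- flankHalfLevel(s, f$range)
    chord <- steepestChord(chordVals, f$range, pos, f$extremum)
    x <- edgePosition(chord, half, pos[f$range])
    data.frame(wall = f$wall, side = f$side, position = x, half_level = half,
               slope = chord$slope, chord_i0 = chord$i0, chord_i1 = chord$i1,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  if (any(diff(edges$position) <= 0))
    stopWithClass("edgeOrderingError",
                  "detected edges are not in increasing outer/inner/inner/outer order")
  new("EdgeSet", edges = edges)
}
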