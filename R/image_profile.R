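# From raster B-scan to physical-units density profile.
#
# Coordinates are continuous um with the origin at the centre of the top-left
# pixel; a raster of n pixels at pitch p therefore spans [0, (n-1)*p] on that
# axis. Both resampling and profile sampling use bilinear interpolation; the
# FWHM crossing downstream is computed analytically, so no magnified
# resampling of the raster is ever needed.

.bilinearAt <- function(px, ap, tp, xUm, yUm) {
  nr <- nrow(px)
  nc <- ncol(px)
  r <- pmin(pmax(yUm / ap, 0), nr - 1) + 1
  cc <- pmin(pmax(xUm / tp, 0), nc - 1) + 1
  r0 <- pmin(floor(r), nr - 1)
  c0 <- pmin(floor(cc), nc - 1)
  fr <- r - r0
  fc <- cc - c0
  v00 <- px[cbind(r0, c0)]
  v01 <- px[cbind(r0, c0 + 1)]
  v10 <- px[cbind(r0 + 1, c0)]
  v11 <- px[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

#' Resample an OCT image to an isotropic 1:1 um aspect
#'
#' Resamples the raster so both axes share the same um/px pitch (the smaller
#' of the two input pitches, so no axis loses resolution), using bilinear
#' interpolation. The physical extent of the image is preserved to within one
#' pixel pitch per axis. Already-isotropic images are returned unchanged.
#'
#' @param img an [OCTImage-class].
#' @return An [OCTImage-class] with equal pitches.
#' @examples
#' img <- OCTImage(matrix(runif(10000, 0, 255), 100, 100),
#'                 axialPitch = 5, transversePitch = 6)
#' dim(aspectNormalize(img))  # 100 x 120
#' @export
aspectNormalize <- function(img) {
  stopifnot(is(img, "OCTImage"))
  validObject(img)
  ap <- img@axialPitch
  tp <- img@transversePitch
  if (ap == tp) return(img)
  target <- min(ap, tp)
  nr <- nrow(img@pixels)
  nc <- ncol(img@pixels)
  nr2 <- as.integer(round((nr - 1) * ap / target)) + 1L
  nc2 <- as.integer(round((nc - 1) * tp / target)) + 1L
  y <- (seq_len(nr2) - 1) * target
  x <- (seq_len(nc2) - 1) * target
  grid <- expand.grid(y = y, x = x)
  vals <- .bilinearAt(img@pixels, ap, tp, grid$x, grid$y)
  OCTImage(matrix(vals, nrow = nr2, ncol = nc2), axialPitch = target,
           transversePitch = target)
}

#' Sample a density profile along a measurement line
#'
#' Samples the image by bilinear interpolation at uniform spacing along the
#' segment from `p0` to `p1` (both `c(x, y)` in um). Positions are measured
#' from `p0`. This is the "line tool" step: the operator draws a line
#' perpendicular through the middle of the vessel and reads off the grayscale
#' density curve.
#'
#' @param img an [OCTImage-class] (normally aspect-normalized first).
#' @param p0,p1 segment endpoints, `c(x, y)` um.
#' @param step sample spacing um; default = the finer pixel pitch.
#' @return A [DensityProfile-class].
#' @export
extractProfile <- function(img, p0, p1, step = NULL) {
  stopifnot(is(img, "OCTImage"))
  validObject(img)
  if (length(p0) != 2L || length(p1) != 2L || !all(is.finite(c(p0, p1))))
    stopWithClass("invalidInputError", "'p0' and 'p1' must be finite (x, y) um")
  if (is.null(step)) step <- min(img@axialPitch, img@transversePitch)
  .assertScalarNumber(step, "step", positive = TRUE)
  xmax <- (ncol(img@pixels) - 1) * img@transversePitch
  ymax <- (nrow(img@pixels) - 1) * img@axialPitch
  eps <- 1e-9 * max(xmax, ymax, 1)
  for (p in list(p0, p1))
    if (p[1] < -eps || p[1] > xmax + eps || p[2] < -eps || p[2] > ymax + eps)
      stopWithClass("outOfBoundsError",
                    "segment endpoint (%.3g, %.3g) um lies outside the %.3g x %.3g um raster",
                    p[1], p[2], xmax, ymax)
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0)
    stopWithClass("invalidInputError", "'p0' and 'p1' must differ")
  n <- floor(len / step + eps) + 1
  t <- (seq_len(n) - 1) * step
  u <- (p1 - p0) / len
  xs <- p0[1] + t * u[1]
  ys <- p0[2] + t * u[2]
  vals <- .bilinearAt(img@pixels, img@axialPitch, img@transversePitch, xs, ys)
  DensityProfile(vals, step = step)
}

#' Zone-B measurement annulus around the optic disc
#'
#' Returns the annulus within which vessel measurement lines are placed.
#' Two conventions are provided and neither is guessed for the other:
#' \describe{
#'   \item{`"literal"`}{concentric circles of 1.0 and 1.5 optic-disc
#'     diameters, i.e. radii `(0.5 D, 0.75 D)` - a protocol that draws the
#'     positioning circles at those literal diameters;}
#'   \item{`"conventional"`}{the standard zone B at radii `(0.75 D, 1.0 D)`.}
#' }
#'
#' @param discCenter optic-disc centre, `c(x, y)` um.
#' @param discDiameter optic-disc diameter D, um.
#' @param mode `"literal"` or `"conventional"`.
#' @return list with `center`, `innerRadius`, `outerRadius` (um) and `mode`.
#' @examples
#' zoneBAnnulus(c(0, 0), 1500, "literal")$innerRadius       # 750
#' zoneBAnnulus(c(0, 0), 1500, "conventional")$innerRadius  # 1125
#' @export
zoneBAnnulus <- function(discCenter, discDiameter,
                         mode = c("literal", "conventional")) {
  mode <- match.arg(mode)
  .assertScalarNumber(discDiameter, "discDiameter", positive = TRUE)
  if (length(discCenter) != 2L || !all(is.finite(discCenter)))
    stopWithClass("invalidInputError", "'discCenter' must be finite (x, y) um")
  radii <- switch(mode,
                  literal = c(0.5, 0.75) * discDiameter,
                  conventional = c(0.75, 1.0) * discDiameter)
  structure(list(center = as.numeric(discCenter), innerRadius = radii[1],
                 outerRadius = radii[2], mode = mode),
            class = "zoneBAnnulus")
}

#' Is a point inside a zone-B annulus?
#'
#' @param annulus result of [zoneBAnnulus()].
#' @param point `c(x, y)` um.
#' @return logical.
#' @export
zoneBContains <- function(annulus, point) {
  stopifnot(inherits(annulus, "zoneBAnnulus"))
  r <- sqrt(sum((point - annulus$center)^2))
  r >= annulus$innerRadius && r <= annulus$outerRadius
}
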