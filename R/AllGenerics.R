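# Accessor generics. Slots are never reached into from user code.

#' @rdname OCTImage-class
#' @param x an object.
#' @export
setGeneric("pixelMatrix", function(x) standardGeneric("pixelMatrix"))
#' @rdname OCTImage-class
#' @export
setGeneric("axialPitch", function(x) standardGeneric("axialPitch"))
#' @rdname OCTImage-class
#' @export
setGeneric("transversePitch", function(x) standardGeneric("transversePitch"))

#' @rdname DensityProfile-class
#' @param x an object.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname DensityProfile-class
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))
#' @rdname DensityProfile-class
#' @export
setGeneric("profileStep", function(x) standardGeneric("profileStep"))

#' @rdname EdgeSet-class
#' @param x an object.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' Edge (or ground-truth) positions in um
#' @param x an [EdgeSet-class] or [GroundTruth-class] object.
#' @return named numeric vector (outer_upper, inner_upper, inner_lower,
#'   outer_lower), um.
#' @export
setGeneric("edgePositions", function(x) standardGeneric("edgePositions"))

#' @rdname StatResult-class
#' @param x an object.
#' @export
setGeneric("testName", function(x) standardGeneric("testName"))
#' @rdname StatResult-class
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))
#' @rdname StatResult-class
#' @export
setGeneric("degreesOfFreedom", function(x) standardGeneric("degreesOfFreedom"))
#' @rdname StatResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

setMethod("pixelMatrix", "OCTImage", function(x) x@pixels)
setMethod("axialPitch", "OCTImage", function(x) x@axialPitch)
setMethod("transversePitch", "OCTImage", function(x) x@transversePitch)
#' @export
setMethod("dim", "OCTImage", function(x) dim(x@pixels))

setMethod("profileValues", "DensityProfile", function(x) x@values)
setMethod("profileStep", "DensityProfile", function(x) x@step)
setMethod("profilePositions", "DensityProfile", function(x)
  x@origin + (seq_along(x@values) - 1) * x@step)
#' @export
setMethod("length", "DensityProfile", function(x) length(x@values))

setMethod("edgeTable", "EdgeSet", function(x) x@edges)
setMethod("edgePositions", "EdgeSet", function(x) {
  p <- x@edges$position
  names(p) <- .EDGE_NAMES
  p
})
setMethod("edgePositions", "GroundTruth", function(x) x@positions)
#' @export
setMethod("as.data.frame", "EdgeSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@edges)

setMethod("testName", "StatResult", function(x) x@test)
setMethod("testStatistic", "StatResult", function(x) x@statistic)
setMethod("degreesOfFreedom", "StatResult", function(x) x@df)
setMethod("pValue", "StatResult", function(x) x@p)
#' @export
setMethod("as.data.frame", "StatResult",
          function(x, row.names = NULL, optional = FALSE, ...)
            data.frame(test = x@test, statistic = x@statistic, df = x@df,
                       p = x@p, stringsAsFactors = FALSE))

#' @rdname VesselMeasurement-class
#' @param x an object.
#' @export
setGeneric("lumenDiameter", function(x) standardGeneric("lumenDiameter"))
#' @rdname VesselMeasurement-class
#' @export
setGeneric("outerDiameter", function(x) standardGeneric("outerDiameter"))
setMethod("lumenDiameter", "VesselMeasurement", function(x) x@lumenMean)
setMethod("outerDiameter", "VesselMeasurement", function(x) x@outerMean)
setMethod("lumenDiameter", "SyntheticVesselSpec", function(x) x@lumenDiameter)
setMethod("outerDiameter", "SyntheticVesselSpec", function(x) x@outerDiameter)
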