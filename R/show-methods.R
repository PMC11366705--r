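setMethod("show", "OCTImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("OCTImage: %d x %d px (%.4g um axial x %.4g um transverse pitch)\n",
              d[1], d[2], object@axialPitch, object@transversePitch))
  cat(sprintf("  extent %.4g x %.4g um, grayscale range [%.4g, %.4g]\n",
              (d[1] - 1) * object@axialPitch, (d[2] - 1) * object@transversePitch,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "DensityProfile", function(object) {
  n <- length(object@values)
  cat(sprintf("DensityProfile: %d samples, step %.4g um, span [%.4g, %.4g] um\n",
              n, object@step, object@origin,
              object@origin + (n - 1) * object@step))
  cat(sprintf("  grayscale range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth edge positions (um):\n")
  print(round(object@positions, 3))
})

setMethod("show", "EdgeSet", function(object) {
  cat("EdgeSet (FWHM sub-pixel wall edges):\n")
  e <- object@edges
  cat(sprintf("  %-11s %9.3f um  (half level %.2f, slope %.2f gs/um)\n",
              paste(e$side, e$wall, sep = "-"), e$position, e$half_level,
              e$slope), sep = "")
  d <- c(outer = e$position[4] - e$position[1],
         lumen = e$position[3] - e$position[2])
  cat(sprintf("  outer diameter %.3f um, lumen diameter %.3f um\n",
              d["outer"], d["lumen"]))
})

setMethod("show", "SyntheticVesselSpec", function(object) {
  cat(sprintf(paste0("SyntheticVesselSpec: outer %.4g um, lumen %.4g um ",
                     "(wall %.4g um), %s\n"),
              object@outerDiameter, object@lumenDiameter,
              (object@outerDiameter - object@lumenDiameter) / 2,
              object@polarity))
  cat(sprintf("  intensities wall/lumen/background %g/%g/%g, PSF sigma %g um\n",
              object@wallIntensity, object@lumenIntensity,
              object@backgroundIntensity, object@psfSigma))
  cat(sprintf("  speckle shape %s, pitch %g um/px, seed %s\n",
              format(object@speckleShape), object@pixelPitch,
              format(object@seed)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d arms; n0 = %d, n1 = %d subjects\n",
              nrow(object@arms), object@n0, object@n1))
  cat(sprintf("  subject correlation %.3g, lumen-outer correlation %.3g\n",
              object@subjectCorrelation, object@vesselCorrelation))
  print(object@arms[, c("group", "eye", "timepoint")])
})

setMethod("show", "VesselMeasurement", function(object) {
  cat(sprintf("VesselMeasurement (%s): %d replicate(s)\n", object@vessel,
              length(object@lumenReplicates)))
  cat(sprintf("  mean lumen %.3f um, mean outer %.3f um\n",
              object@lumenMean, object@outerMean))
})

setMethod("show", "StatResult", function(object) {
  df <- if (is.na(object@df)) "" else sprintf(", df = %g", object@df)
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (two-tailed, alpha = %g)\n",
              object@test, object@statistic, df, object@p, object@alpha))
  if (length(object@note))
    cat("  note:", paste(names(object@note), unlist(lapply(object@note, format)),
                         sep = " = ", collapse = "; "), "\n")
})
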