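# Pipeline front end: run configuration, the three batch commands
# (simulate / measure / stats) and JSON run manifests. A thin command-line
# wrapper over these functions ships in inst/scripts/octvessel.R.

#' Run configuration
#'
#' Collects every tunable of the pipeline with its default. A YAML config
#' file may override any subset (see [readRunConfig()]). The seed and an md5
#' hash of the configuration are recorded in every output manifest, so
#' identical config + inputs reproduce identical outputs.
#'
#' @param polarity wall polarity on the density curve.
#' @param chordOn fit the steepest chord on the `"raw"` or `"smoothed"`
#'   profile.
#' @param prominence minimum extremum prominence, grayscale.
#' @param axialPitch,transversePitch image pixel pitch, um/px.
#' @param replicates expected replicate measurements per vessel.
#' @param zoneMode zone-B convention, see [zoneBAnnulus()].
#' @param gate apply the Shapiro-Wilk normality gate in [buildTables()].
#' @param tVariant `"pooled"` or `"welch"`.
#' @param seed integer RNG seed.
#' @param outDir output directory.
#' @return a `runConfig` list.
#' @export
runConfig <- function(polarity = "dark_walls", chordOn = "raw",
                      prominence = 5, axialPitch = 5, transversePitch = 6,
                      replicates = 3, zoneMode = "literal", gate = TRUE,
                      tVariant = "pooled", seed = 1L, outDir = ".") {
  cfg <- list(polarity = match.arg(polarity, c("dark_walls", "bright_walls")),
              chordOn = match.arg(chordOn, c("raw", "smoothed")),
              prominence = prominence, axialPitch = axialPitch,
              transversePitch = transversePitch, replicates = replicates,
              zoneMode = match.arg(zoneMode, c("literal", "conventional")),
              gate = isTRUE(gate),
              tVariant = match.arg(tVariant, c("pooled", "welch")),
              seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "runConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return a `runConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stopWithClass("invalidInputError", "unknown config key(s): %s",
                  paste(bad, collapse = ", "))
  do.call(runConfig, y)
}

.writeManifest <- function(outDir, command, config, extra = list()) {
  hashable <- unclass(config)
  hashable$outDir <- NULL  # where results land does not change what they are
  manifest <- c(list(command = command,
                     package = "octvessel",
                     version = as.character(utils::packageVersion("octvessel")),
                     seed = config$seed,
                     config = unclass(config),
                     config_hash = .configHash(hashable)),
                extra)
  path <- file.path(outDir, sprintf("%s_manifest.json", command))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate: write a synthetic profile, B-scan and cohort to disk
#'
#' Renders the vessel of `spec` as a profile CSV and a B-scan image (PNG by
#' default) with its ground-truth edge CSV, simulates the cohort of
#' `cohort`, and writes a JSON manifest capturing config, seed and package
#' version. Seeds are taken from the config when the specs carry none.
#'
#' @param config a [runConfig()].
#' @param spec a [SyntheticVesselSpec-class].
#' @param cohort a [CohortSpec-class], or NULL to skip.
#' @param imageFormat bmp, png or tiff.
#' @return named character vector of the files written, invisibly.
#' @export
cmdSimulate <- function(config = runConfig(), spec = SyntheticVesselSpec(),
                        cohort = cohortSpec(), imageFormat = "png") {
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.na(spec@seed)) spec@seed <- config$seed
  files <- c()
  r <- renderProfile(spec)
  files["profile"] <- writeProfile(r$profile, file.path(outDir, "profile.csv"))
  b <- renderBscan(spec)
  files["image"] <- writeOCTImage(b$image,
                                  file.path(outDir, paste0("bscan.", imageFormat)))
  truth <- data.frame(edge = .EDGE_NAMES,
                      profile_um = unname(edgePositions(r$truth)),
                      bscan_um = unname(edgePositions(b$truth)))
  files["truth"] <- file.path(outDir, "truth.csv")
  utils::write.csv(truth, files["truth"], row.names = FALSE)
  if (!is.null(cohort)) {
    if (is.na(cohort@seed)) cohort@seed <- config$seed
    files["cohort"] <- writeCohort(simulateCohort(cohort),
                                   file.path(outDir, "cohort.csv"))
  }
  files["manifest"] <- .writeManifest(outDir, "simulate", config,
                                      list(files = as.list(files)))
  invisible(files)
}

#' Measure: vessels on an image via ROI measurement lines
#'
#' Reads the image and the ROI lines, aspect-normalizes, extracts a density
#' profile per line, runs FWHM edge detection, and averages replicate lines
#' per vessel. Band-detection failures are reported per ROI and the run
#' continues; the returned status is 0 (all ROIs measured), 2 (some failed)
#' or 1 (nothing measured).
#'
#' @param config a [runConfig()] (pitches, polarity, chord and prominence
#'   settings are taken from it).
#' @param imagePath grayscale BMP/PNG/TIFF.
#' @param roiPath ROI CSV, see [readROILines()].
#' @return list with `measurements` (per-vessel data.frame), `edges` (per-ROI
#'   edge table), `failures` (per-ROI error messages) and `status`.
#' @export
cmdMeasure <- function(config, imagePath, roiPath) {
  img <- readOCTImage(imagePath, config$axialPitch, config$transversePitch)
  img <- aspectNormalize(img)
  roi <- readROILines(roiPath, img)
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  edges <- list()
  fails <- character()
  diam <- list()
  for (i in seq_len(nrow(roi))) {
    res <- tryCatch({
      pr <- extractProfile(img, c(roi$x0[i], roi$y0[i]),
                           c(roi$x1[i], roi$y1[i]))
      es <- detectEdges(pr, polarity = config$polarity,
                        prominence = config$prominence,
                        chordOn = config$chordOn)
      list(es = es, d = diametersFromEdges(es))
    }, octvesselError = function(e) e)
    if (inherits(res, "error")) {
      fails[as.character(i)] <- conditionMessage(res)
      warning(sprintf("ROI %d rejected: %s", i, conditionMessage(res)))
      next
    }
    edges[[length(edges) + 1L]] <- cbind(roi = i, vessel = roi$vessel[i],
                                         edgeTable(res$es))
    diam[[length(diam) + 1L]] <- data.frame(roi = i, vessel = roi$vessel[i],
                                            lumen = res$d["lumen"],
                                            outer = res$d["outer"])
  }
  measurements <- NULL
  if (length(diam)) {
    dd <- do.call(rbind, diam)
    measurements <- do.call(rbind, lapply(split(dd, dd$vessel), function(g) {
      if (nrow(g) != config$replicates)
        warning(sprintf("vessel '%s': %d replicate(s), %d expected",
                        g$vessel[1], nrow(g), config$replicates))
      m <- suppressWarnings(
        averageReplicates(g$lumen, g$outer,
                          vessel = if (g$vessel[1] %in% c("artery", "vein"))
                            g$vessel[1] else "artery"))
      data.frame(vessel = g$vessel[1], n_replicates = nrow(g),
                 lumen_um = lumenDiameter(m), outer_um = outerDiameter(m))
    }))
    rownames(measurements) <- NULL
    utils::write.csv(measurements,
                     file.path(outDir, "measurements.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, edges), file.path(outDir, "edges.csv"),
                     row.names = FALSE)
  }
  status <- if (!length(diam)) 1L else if (length(fails)) 2L else 0L
  .writeManifest(outDir, "measure", config,
                 list(image = imagePath, roi = roiPath,
                      failures = as.list(fails), status = status))
  list(measurements = measurements,
       edges = if (length(edges)) do.call(rbind, edges) else NULL,
       failures = fails, status = status)
}

#' Stats: run the comparison battery on a cohort CSV
#'
#' Validates the cohort schema, builds every comparison table the labels
#' allow (see [buildTables()]), writes one CSV per table plus a JSON report
#' of skipped comparisons and the run manifest.
#'
#' @param config a [runConfig()].
#' @param cohortPath cohort CSV.
#' @return the [buildTables()] result, invisibly.
#' @export
cmdStats <- function(config, cohortPath) {
  cohort <- readCohort(cohortPath)
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  battery <- buildTables(cohort, gate = config$gate, variant = config$tVariant)
  for (nm in names(battery$tables))
    utils::write.csv(battery$tables[[nm]],
                     file.path(outDir, sprintf("table_%s.csv", nm)),
                     row.names = FALSE)
  jsonlite::write_json(as.list(battery$skipped),
                       file.path(outDir, "skipped.json"), auto_unbox = TRUE)
  .writeManifest(outDir, "stats", config,
                 list(cohort = cohortPath,
                      tables = as.list(names(battery$tables)),
                      skipped = as.list(battery$skipped)))
  invisible(battery)
}
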