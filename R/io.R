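# File formats: 8-bit grayscale BMP/PNG/TIFF images, CSV tables for ROI
# lines, profiles, edge sets and cohorts. PNG and TIFF go through the png
# and tiff packages; BMP (the device export format) has no reader on CRAN's
# imaging stack, so a minimal uncompressed BMP codec lives here.

.toGray <- function(arr) {
  if (length(dim(arr)) == 3L) {
    warning("multi-channel image: averaging channels to grayscale")
    arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  arr * 255
}

## Minimal BMP reader: uncompressed (BI_RGB) 8-bit palette or 24-bit files.
.readBMP <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 2)
  if (!identical(rawToChar(sig), "BM"))
    stopWithClass("invalidInputError", "'%s' is not a BMP file", path)
  readBin(con, "integer", 2, size = 4, endian = "little")  # file size, reserved
  dataOffset <- readBin(con, "integer", 1, size = 4, endian = "little")
  headerSize <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (headerSize < 40)
    stopWithClass("invalidInputError", "unsupported BMP header (size %d)", headerSize)
  w <- readBin(con, "integer", 1, size = 4, endian = "little")
  h <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")  # planes
  bpp <- readBin(con, "integer", 1, size = 2, endian = "little")
  compression <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (compression != 0)
    stopWithClass("invalidInputError", "compressed BMP (type %d) not supported",
                  compression)
  if (!bpp %in% c(8L, 24L))
    stopWithClass("invalidInputError", "only 8-bit and 24-bit BMP supported, got %d",
                  bpp)
  topDown <- h < 0
  h <- abs(h)
  pal <- NULL
  if (bpp == 8L) {
    seek(con, 14 + headerSize)
    nPal <- (dataOffset - 14 - headerSize) / 4
    palRaw <- readBin(con, "raw", nPal * 4)
    pm <- matrix(as.integer(palRaw), ncol = 4, byrow = TRUE)  # B, G, R, 0
    pal <- (pm[, 1] + pm[, 2] + pm[, 3]) / 3
  }
  seek(con, dataOffset)
  rowBytes <- ((w * bpp / 8 + 3) %/% 4) * 4
  raw <- readBin(con, "raw", rowBytes * h)
  px <- matrix(0, nrow = h, ncol = w)
  for (i in seq_len(h)) {
    row <- as.integer(raw[((i - 1) * rowBytes + 1):((i - 1) * rowBytes + w * bpp / 8)])
    vals <- if (bpp == 8L) pal[row + 1L]
    else colMeans(matrix(row, nrow = 3))  # B, G, R per pixel
    r <- if (topDown) i else h - i + 1L
    px[r, ] <- vals
  }
  px
}

## Minimal BMP writer: 8-bit grayscale palette, bottom-up, uncompressed.
.writeBMP <- function(px, path) {
  px <- round(pmin(pmax(px, 0), 255))
  h <- nrow(px)
  w <- ncol(px)
  rowBytes <- ((w + 3) %/% 4) * 4
  dataOffset <- 14 + 40 + 256 * 4
  fileSize <- dataOffset + rowBytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(c(fileSize, 0, dataOffset)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(40, w, h)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 8)), con, size = 2, endian = "little")
  writeBin(as.integer(c(0, rowBytes * h, 2835, 2835, 256, 0)), con, size = 4,
           endian = "little")
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0, 256)))
  writeBin(pal, con)
  pad <- as.raw(rep(0, rowBytes - w))
  for (i in h:1) writeBin(c(as.raw(px[i, ]), pad), con)
  invisible(path)
}

#' Read a grayscale OCT image (BMP, PNG or TIFF)
#'
#' @param path image file; format from the extension.
#' @param axialPitch,transversePitch pixel pitch, um/px (device metadata is
#'   not stored in these formats, so the caller supplies it).
#' @return An [OCTImage-class] with grayscale values 0-255.
#' @export
readOCTImage <- function(path, axialPitch, transversePitch = axialPitch) {
  if (!file.exists(path))
    stopWithClass("invalidInputError", "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = .toGray(png::readPNG(path)),
               tif = , tiff = .toGray(tiff::readTIFF(path)),
               bmp = .readBMP(path),
               stopWithClass("invalidInputError",
                             "unsupported image format '.%s' (use bmp/png/tiff)",
                             ext))
  OCTImage(px, axialPitch, transversePitch)
}

#' Write a grayscale OCT image (BMP, PNG or TIFF)
#'
#' Values are clamped to [0, 255] and written as 8-bit grayscale.
#'
#' @param img an [OCTImage-class].
#' @param path output path; format from the extension.
#' @return the path, invisibly.
#' @export
writeOCTImage <- function(img, path) {
  stopifnot(is(img, "OCTImage"))
  px <- pmin(pmax(img@pixels, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(px, path),
         tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
         bmp = .writeBMP(img@pixels, path),
         stopWithClass("invalidInputError",
                       "unsupported image format '.%s' (use bmp/png/tiff)", ext))
  invisible(path)
}

#' Read measurement-line ROIs
#'
#' A ROI file is a CSV with columns `x0, y0, x1, y1` (one measurement line
#' per row) and optionally `vessel` (artery/vein) and `units` ("um" or
#' "px"); rows in px are converted using the image pitches.
#'
#' @param path CSV file.
#' @param img an [OCTImage-class], required when any row is in px.
#' @return data.frame with x0, y0, x1, y1 in um and a vessel column.
#' @export
readROILines <- function(path, img = NULL) {
  roi <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x0", "y0", "x1", "y1")
  miss <- setdiff(need, names(roi))
  if (length(miss))
    stopWithClass("invalidInputError", "ROI file lacks column(s): %s",
                  paste(miss, collapse = ", "))
  if (is.null(roi$units)) roi$units <- "um"
  if (is.null(roi$vessel)) roi$vessel <- "artery"
  px <- roi$units == "px"
  if (any(px)) {
    if (is.null(img))
      stopWithClass("invalidInputError",
                    "ROI rows in px need the image for pitch conversion")
    roi$x0[px] <- roi$x0[px] * transversePitch(img)
    roi$x1[px] <- roi$x1[px] * transversePitch(img)
    roi$y0[px] <- roi$y0[px] * axialPitch(img)
    roi$y1[px] <- roi$y1[px] * axialPitch(img)
  }
  roi[c("x0", "y0", "x1", "y1", "vessel")]
}

#' Write a density profile as two-column CSV
#' @param profile a [DensityProfile-class].
#' @param path output CSV (columns position_um, value).
#' @return the path, invisibly.
#' @export
writeProfile <- function(profile, path) {
  utils::write.csv(data.frame(position_um = profilePositions(profile),
                              value = profileValues(profile)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an edge set as CSV
#' @param es an [EdgeSet-class].
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
writeEdgeSet <- function(es, path) {
  utils::write.csv(edgeTable(es), path, row.names = FALSE)
  invisible(path)
}

.COHORT_COLUMNS <- c("subject_id", "group", "eye", "timepoint", .COHORT_PARAMS)

#' Write / read a per-eye cohort table
#'
#' The cohort CSV schema is the column set of [simulateCohort()]:
#' subject_id, group, eye, timepoint, RALD, RAOD, AWT, RVLD, RVOD, VWT, AVR.
#' `readCohort()` validates the schema and reports offending columns and
#' rows.
#'
#' @param cohort data.frame in cohort schema.
#' @param path CSV path.
#' @return `writeCohort`: the path invisibly; `readCohort`: the validated
#'   data.frame.
#' @export
writeCohort <- function(cohort, path) {
  miss <- setdiff(.COHORT_COLUMNS, names(cohort))
  if (length(miss))
    stopWithClass("invalidInputError", "cohort lacks column(s): %s",
                  paste(miss, collapse = ", "))
  utils::write.csv(cohort[.COHORT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.COHORT_COLUMNS, names(cohort))
  if (length(miss))
    stopWithClass("invalidInputError", "cohort file lacks column(s): %s",
                  paste(miss, collapse = ", "))
  for (p in .COHORT_PARAMS) {
    bad <- which(!is.finite(cohort[[p]]))
    if (length(bad))
      stopWithClass("invalidInputError",
                    "non-numeric %s in row(s) %s", p,
                    paste(utils::head(bad, 5), collapse = ", "))
  }
  cohort
}
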