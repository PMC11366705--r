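# Internal helpers shared across modules.

## Signal a classed error so callers (and cmdMeasure's per-ROI loop) can
## distinguish rejection modes: invalidSpecError, bandDetectionError,
## degenerateFlankError, edgeLocalizationError, edgeOrderingError,
## outOfBoundsError, invalidInputError, infiniteStatisticError,
## undefinedStatisticError.
stopWithClass <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "octvesselError", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  )
  stop(cond)
}

.assertScalarNumber <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stopWithClass("invalidInputError", "'%s' must be a single finite number", name)
  if (positive && x <= 0)
    stopWithClass("invalidInputError", "'%s' must be > 0", name)
  if (nonneg && x < 0)
    stopWithClass("invalidInputError", "'%s' must be >= 0", name)
  invisible(x)
}

## Run `fun()` under a fixed RNG seed without disturbing the caller's RNG
## stream; seed = NA means "use the current stream".
.withSeed <- function(seed, fun) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed)) return(fun())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  fun()
}

## Canonical md5 of an R object via its serialized JSON; used for run manifests.
.configHash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}
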