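# From edge sets to the seven vessel parameters.
#
# Parameter definitions (all diameters um):
#   RALD / RVLD  lumen diameter  = inner-lower - inner-upper edge
#   RAOD / RVOD  outer diameter  = outer-lower - outer-upper edge
#   AWT = (RAOD - RALD) / 2,  VWT = (RVOD - RVLD) / 2   (wall thickness)
#   AVR = RAOD / RVOD                                    (arteriovenous ratio)

#' Lumen and outer diameter from an edge set
#'
#' @param es an [EdgeSet-class].
#' @return named numeric `c(lumen, outer)`, um.
#' @export
diametersFromEdges <- function(es) {
  stopifnot(is(es, "EdgeSet"))
  p <- edgePositions(es)
  c(lumen = unname(p["inner_lower"] - p["inner_upper"]),
    outer = unname(p["outer_lower"] - p["outer_upper"]))
}

#' Average replicate diameter measurements of one vessel
#'
#' Every vessel is measured several times (three replicates expected) and
#' the arithmetic means are carried forward. A replicate count other than
#' three is allowed but triggers a warning so protocol deviations are
#' logged.
#'
#' @param lumen,outer numeric vectors of replicate diameters, um (equal
#'   length, >= 1).
#' @param vessel `"artery"` or `"vein"`.
#' @return A [VesselMeasurement-class].
#' @examples
#' m <- averageReplicates(c(103, 104, 104.88), c(135, 136, 135.26))
#' lumenDiameter(m); outerDiameter(m)  # 103.96, 135.42
#' @export
averageReplicates <- function(lumen, outer, vessel = c("artery", "vein")) {
  vessel <- match.arg(vessel)
  if (length(lumen) < 1L || length(lumen) != length(outer))
    stopWithClass("invalidInputError",
                  "need >= 1 replicate (lumen, outer) pairs of equal length")
  if (length(lumen) != 3L)
    warning(sprintf("%d replicate(s) supplied where 3 are expected", length(lumen)))
  new("VesselMeasurement", vessel = vessel,
      lumenReplicates = as.numeric(lumen), outerReplicates = as.numeric(outer),
      lumenMean = mean(lumen), outerMean = mean(outer))
}

#' The seven vessel parameters from four diameters
#'
#' Vectorized formula layer: given arteriolar and venular lumen/outer
#' diameters it derives wall thicknesses and the arteriovenous ratio,
#'   AWT = (RAOD - RALD)/2, VWT = (RVOD - RVLD)/2, AVR = RAOD/RVOD.
#'
#' @param rald,raod,rvld,rvod diameters, um (recycled to a common length).
#' @return data.frame with columns RALD, RAOD, AWT, RVLD, RVOD, VWT, AVR.
#' @examples
#' vesselParameters(103.96, 135.42, 149.91, 177.49)
#' @export
vesselParameters <- function(rald, raod, rvld, rvod) {
  if (any(rvod == 0))
    stopWithClass("invalidInputError", "RVOD = 0: arteriovenous ratio undefined")
  data.frame(RALD = rald, RAOD = raod, AWT = (raod - rald) / 2,
             RVLD = rvld, RVOD = rvod, VWT = (rvod - rvld) / 2,
             AVR = raod / rvod)
}

#' Assemble one per-eye record from averaged artery and vein measurements
#'
#' Populates all seven vessel parameters from the replicate-averaged
#' diameters. By default AVR is the ratio of the mean diameters
#' (`avr = "ratio_of_means"`); `"mean_of_ratios"` instead averages the
#' per-replicate RAOD/RVOD ratios (requires equal replicate counts). The two
#' differ in general - a ratio of means is not a mean of ratios.
#'
#' @param artery,vein [VesselMeasurement-class] objects.
#' @param subjectId subject identifier.
#' @param group 0 (control) or 1 (stenosis).
#' @param eye `"left"`, `"right"`, `"ipsilateral"` or `"contralateral"`.
#' @param timepoint `"single"`, `"pre_CAS"` or `"post_CAS"`.
#' @param avr AVR convention, see above.
#' @return one-row data.frame with columns subject_id, group, eye,
#'   timepoint, RALD, RAOD, AWT, RVLD, RVOD, VWT, AVR.
#' @examples
#' a <- averageReplicates(rep(103.96, 3), rep(135.42, 3), "artery")
#' v <- averageReplicates(rep(149.91, 3), rep(177.49, 3), "vein")
#' deriveRecord(a, v, "S001", 1, "ipsilateral", "pre_CAS")$AWT  # 15.73
#' @export
deriveRecord <- function(artery, vein, subjectId = "S001", group = 0,
                         eye = c("left", "right", "ipsilateral", "contralateral"),
                         timepoint = c("single", "pre_CAS", "post_CAS"),
                         avr = c("ratio_of_means", "mean_of_ratios")) {
  stopifnot(is(artery, "VesselMeasurement"), is(vein, "VesselMeasurement"))
  eye <- match.arg(eye)
  timepoint <- match.arg(timepoint)
  avr <- match.arg(avr)
  if (vein@outerMean == 0)
    stopWithClass("invalidInputError", "mean RVOD is zero; AVR undefined")
  pars <- vesselParameters(artery@lumenMean, artery@outerMean,
                           vein@lumenMean, vein@outerMean)
  if (avr == "mean_of_ratios") {
    if (length(artery@outerReplicates) != length(vein@outerReplicates))
      stopWithClass("invalidInputError",
                    "mean_of_ratios needs equal artery and vein replicate counts")
    pars$AVR <- mean(artery@outerReplicates / vein@outerReplicates)
  }
  cbind(data.frame(subject_id = subjectId, group = group, eye = eye,
                   timepoint = timepoint, stringsAsFactors = FALSE),
        pars)
}

#' Measure a vessel on an image: replicate profiles to averaged diameters
#'
#' Convenience wrapper used by the measurement pipeline: runs
#' [detectEdges()] on each replicate profile, converts edge sets to
#' diameters and averages the replicates.
#'
#' @param profiles list of [DensityProfile-class] replicates of one vessel.
#' @param vessel `"artery"` or `"vein"`.
#' @param ... passed to [detectEdges()].
#' @return A [VesselMeasurement-class].
#' @export
measureVessel <- function(profiles, vessel = c("artery", "vein"), ...) {
  vessel <- match.arg(vessel)
  d <- vapply(profiles, function(p) diametersFromEdges(detectEdges(p, ...)),
              numeric(2))
  averageReplicates(lumen = d["lumen", ], outer = d["outer", ], vessel = vessel)
}
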