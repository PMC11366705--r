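# Independent oracles and fixture builders used across the suite.

## Brute-force half-level crossing: evaluate the piecewise-linear
## interpolant of (positions, values) on a dense grid over the flank and
## return every crossing of `half`, located by linear interpolation between
## grid points (grid resolution 1e-3 um gives crossings far below 1e-3
## error on linear data).
denseCrossings <- function(values, positions, flank, half, res = 1e-3) {
  xs <- seq(positions[flank[1]], positions[flank[2]], by = res)
  fs <- approx(positions, values, xs)$y
  d <- fs - half
  out <- xs[d == 0]
  sw <- which(d[-1] * d[-length(d)] < 0)
  for (i in sw) {
    out <- c(out, xs[i] + res * d[i] / (d[i] - d[i + 1]))
  }
  sort(out)
}

## Exact Mann-Whitney two-sided p by full enumeration of all C(n+m, n)
## group assignments of the pooled sample (no ties assumed). The doubling
## convention matches the standard exact two-sided definition.
enumMannWhitneyP <- function(x, y) {
  n <- length(x)
  m <- length(y)
  pool <- c(x, y)
  rk <- rank(pool)
  uObs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  us <- apply(idx, 2, function(s) sum(rk[s]) - n * (n + 1) / 2)
  pLo <- mean(us <= uObs)
  pHi <- mean(us >= uObs)
  min(1, 2 * min(pLo, pHi))
}

## EdgeSet straight from positions (for metrics tests).
makeEdgeSet <- function(positions) {
  new("EdgeSet", edges = data.frame(
    wall = c("upper", "upper", "lower", "lower"),
    side = c("outer", "inner", "inner", "outer"),
    position = as.numeric(positions),
    half_level = 100, slope = c(-16, 28, -28, 16),
    chord_i0 = 1L, chord_i1 = 2L, stringsAsFactors = FALSE))
}

## A piecewise-LINEAR vessel-like profile (plateaus joined by straight
## ramps), on which the steepest-chord crossing and the dense interpolant
## crossing must agree to machine precision.
trapezoidProfile <- function(bg = 140, wall = 60, lum = 200, plateau = 6,
                             ramp = 2, step = 5) {
  lev <- function(from, to, k) {
    if (k == 0) return(numeric(0))
    from + (to - from) * seq_len(k) / (k + 1)
  }
  v <- c(rep(bg, plateau), lev(bg, wall, ramp), rep(wall, plateau),
         lev(wall, lum, ramp), rep(lum, 2 * plateau), lev(lum, wall, ramp),
         rep(wall, plateau), lev(wall, bg, ramp), rep(bg, plateau))
  DensityProfile(v, step = step)
}

## Random vessel spec at the cohort's caliber scale.
randomVesselSpec <- function(psfSigma, ...) {
  out <- runif(1, 130, 190)
  wt <- runif(1, 12, 20)
  SyntheticVesselSpec(outerDiameter = out, lumenDiameter = out - 2 * wt,
                      psfSigma = psfSigma, ...)
}
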