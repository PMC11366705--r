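# Synthetic generator: exact plateaus, blur symmetry, speckle statistics,
# ground-truth geometry, B-scan construction, cohort simulation.

test_that("unblurred noiseless render has exact plateaus and centred truth edges", {
  spec <- SyntheticVesselSpec(outerDiameter = 147, lumenDiameter = 114,
                              psfSigma = 0, speckleShape = Inf, pixelPitch = 5)
  r <- renderProfile(spec)
  x <- profilePositions(r$profile)
  v <- profileValues(r$profile)
  centre <- max(x) / 2
  expect_equal(unname(edgePositions(r$truth)),
               centre + c(-73.5, -57, 57, 73.5))
  e <- edgePositions(r$truth)
  # samples clear of every edge by more than half an aperture sit exactly on
  # the template plateaus
  clear <- sapply(x, function(p) min(abs(p - e)) > 2.5)
  lumen <- clear & x > e[2] & x < e[3]
  wallU <- clear & x > e[1] & x < e[2]
  bgL <- clear & x < e[1]
  expect_true(all(v[lumen] == 200))
  expect_true(all(v[wallU] == 60))
  expect_true(all(v[bgL] == 140))
})

test_that("blurred render crosses the plateau midpoint exactly at well-separated edges", {
  # wide wall (50 um = 10 sigma) so each edge is an isolated symmetric
  # transition; pitch 1 um puts samples exactly on the truth edges
  spec <- SyntheticVesselSpec(outerDiameter = 200, lumenDiameter = 100,
                              psfSigma = 5, speckleShape = Inf, pixelPitch = 1)
  r <- renderProfile(spec)
  x <- profilePositions(r$profile)
  v <- profileValues(r$profile)
  e <- edgePositions(r$truth)
  expect_true(all(e %in% x))
  expect_equal(v[match(e[["outer_upper"]], x)], (140 + 60) / 2, tolerance = 1e-8)
  expect_equal(v[match(e[["inner_upper"]], x)], (60 + 200) / 2, tolerance = 1e-8)
  expect_equal(v[match(e[["inner_lower"]], x)], (200 + 60) / 2, tolerance = 1e-8)
  expect_equal(v[match(e[["outer_lower"]], x)], (60 + 140) / 2, tolerance = 1e-8)
})

test_that("speckle is seeded-deterministic and leaves the caller's RNG alone", {
  spec <- SyntheticVesselSpec(speckleShape = 50, seed = 7)
  a <- renderProfile(spec)
  set.seed(123)
  before <- runif(1)
  b <- renderProfile(spec)
  set.seed(123)
  expect_identical(runif(1), before)  # render did not consume the stream
  expect_identical(profileValues(a$profile), profileValues(b$profile))
  c <- renderProfile(SyntheticVesselSpec(speckleShape = 50, seed = 8))
  expect_false(identical(profileValues(a$profile), profileValues(c$profile)))
})

test_that("speckle factors have unit mean within Monte-Carlo error", {
  spec <- SyntheticVesselSpec(speckleShape = 50, seed = 11)
  clean <- renderProfile(SyntheticVesselSpec(speckleShape = Inf),
                         length = 20000)
  noisy <- renderProfile(spec, length = 20000)
  factors <- profileValues(noisy$profile) / profileValues(clean$profile)
  n <- length(factors)
  se <- (1 / sqrt(50)) / sqrt(n)
  expect_lt(abs(mean(factors) - 1), 3 * se)
})

test_that("ground truth is ordered and reproduces the spec diameters for random specs", {
  set.seed(5)
  for (i in 1:50) {
    spec <- randomVesselSpec(psfSigma = runif(1, 0, 8),
                             speckleShape = sample(c(Inf, 100, 30), 1),
                             seed = i)
    r <- renderProfile(spec)
    p <- edgePositions(r$truth)
    expect_true(all(diff(p) > 0))
    expect_equal(unname(p[["outer_lower"]] - p[["outer_upper"]]),
                 outerDiameter(spec))
    expect_equal(unname(p[["inner_lower"]] - p[["inner_upper"]]),
                 lumenDiameter(spec))
  }
})

test_that("profile render rejects invalid geometry", {
  expect_error(SyntheticVesselSpec(outerDiameter = 100, lumenDiameter = 120),
               "outerDiameter > lumenDiameter")
  expect_error(SyntheticVesselSpec(pixelPitch = -1), "pixelPitch")
  expect_error(renderProfile(SyntheticVesselSpec(psfSigma = 5), length = 150),
               class = "invalidSpecError")
})

test_that("B-scan centre column equals the 1-D profile and mirrors under rotation", {
  spec <- SyntheticVesselSpec(psfSigma = 4, speckleShape = Inf)
  b <- renderBscan(spec, height = 61L, width = 61L)
  px <- pixelMatrix(b$image)
  r <- renderProfile(spec, length = 60 * 5)
  expect_equal(px[, 31], profileValues(r$profile), tolerance = 1e-12)
  expect_equal(unname(edgePositions(b$truth)), unname(edgePositions(r$truth)))
  # 180 degree rotation leaves the noiseless raster invariant, so the
  # ground-truth edges mirror about the canvas centre
  expect_equal(px, px[nrow(px):1, ncol(px):1], tolerance = 1e-12)
  H <- (nrow(px) - 1) * 5
  expect_equal(unname(H - rev(edgePositions(b$truth))),
               unname(edgePositions(b$truth)))
})

test_that("speckled B-scan is bit-identical under the same seed; canvas too small errors", {
  spec <- SyntheticVesselSpec(speckleShape = 80, seed = 3)
  b1 <- renderBscan(spec)
  b2 <- renderBscan(spec)
  expect_identical(pixelMatrix(b1$image), pixelMatrix(b2$image))
  expect_error(renderBscan(SyntheticVesselSpec(), height = 20L, width = 61L),
               class = "invalidSpecError")
})

test_that("cohort simulation: derived identities hold exactly and seeds reproduce", {
  cs <- cohortSpec(seed = 42)
  cohort <- simulateCohort(cs)
  expect_equal(nrow(cohort), 2 * 59 + 4 * 50)
  expect_identical(cohort$AWT, (cohort$RAOD - cohort$RALD) / 2)
  expect_identical(cohort$VWT, (cohort$RVOD - cohort$RVLD) / 2)
  expect_identical(cohort$AVR, cohort$RAOD / cohort$RVOD)
  expect_identical(cohort, simulateCohort(cs))
  expect_false(identical(cohort, simulateCohort(cohortSpec(seed = 43))))
})

test_that("zero-SD cohort degenerates to the arm means", {
  arms <- defaultCohortArms()
  arms[grep("^sd_", names(arms))] <- 0
  cohort <- simulateCohort(cohortSpec(arms = arms, seed = 1))
  g0r <- cohort[cohort$group == 0 & cohort$eye == "right", ]
  expect_equal(unique(round(g0r$RAOD, 10)), 146.91)
  expect_equal(unique(round(g0r$RALD, 10)), 114.67)
  expect_equal(unique(round(g0r$VWT, 10)), (177.49 - 149.91) / 2)
})

test_that("cohort spec validation rejects bad correlations and arm sizes", {
  expect_error(cohortSpec(subjectCorrelation = 1), "\\[0, 1\\)")
  expect_error(cohortSpec(vesselCorrelation = -0.1), "\\[0, 1\\)")
  expect_error(cohortSpec(n0 = 1), ">= 2")
})
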