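# The statistics battery: summary-row t, sample t tests, chi-square, rank
# tests, the normality gate and the table builder.

test_that("pooled t from summary rows reproduces published statistics", {
  # Group 0 right eye vs stenosis-group ipsilateral eye, pre stenting
  raod <- pooledTFromSummary(146.91, 12.36, 59, 135.42, 12.17, 50)
  expect_lt(abs(testStatistic(raod) - 4.870), 0.005)
  expect_equal(degreesOfFreedom(raod), 107)
  expect_lt(pValue(raod), 0.001)
  rald <- pooledTFromSummary(114.67, 11.86, 59, 103.96, 11.56, 50)
  expect_lt(abs(testStatistic(rald) - 4.753), 0.005)
  # identical arms: t = 0, p = 1
  same <- pooledTFromSummary(10, 2, 20, 10, 2, 20)
  expect_equal(testStatistic(same), 0)
  expect_equal(pValue(same), 1)
  expect_error(pooledTFromSummary(10, 0, 20, 11, 0, 20),
               class = "infiniteStatisticError")
})

test_that("sample-based pooled t agrees with the summary formula to 1e-12", {
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(17, 100, 12)
    b <- rnorm(23, 104, 9)
    ts <- independentT(a, b, "pooled")
    tf <- pooledTFromSummary(mean(a), sd(a), length(a),
                             mean(b), sd(b), length(b))
    expect_equal(testStatistic(ts), testStatistic(tf), tolerance = 1e-12)
    expect_equal(pValue(ts), pValue(tf), tolerance = 1e-12)
  }
})

test_that("independent t: antisymmetry, identity, Welch option", {
  set.seed(15)
  a <- rnorm(20, 5, 1)
  b <- rnorm(25, 6, 3)
  ab <- independentT(a, b)
  ba <- independentT(b, a)
  expect_equal(testStatistic(ab), -testStatistic(ba))
  expect_equal(pValue(ab), pValue(ba))
  expect_equal(testStatistic(independentT(a, a)), 0)
  w <- independentT(a, b, "welch")
  expect_false(isTRUE(all.equal(degreesOfFreedom(w), degreesOfFreedom(ab))))
})

test_that("paired t handles identity, constant shift, and beats pooled on correlated pairs", {
  x <- rnorm(15, 100, 10)
  expect_equal(testStatistic(pairedT(x, x)), 0)
  expect_equal(pValue(pairedT(x, x)), 1)
  expect_error(pairedT(x, x + 3), class = "infiniteStatisticError")
  expect_error(pairedT(x, x[-1]), class = "invalidInputError")
  # strongly correlated before/after: the paired statistic dwarfs the
  # independent one computed on the same data (why same-subject tables show
  # |t| near 15 where the between-group contrast of similar size gives ~2)
  set.seed(16)
  S <- matrix(c(11.56^2, 0.986 * 11.56 * 11.48,
                0.986 * 11.56 * 11.48, 11.48^2), 2, 2)
  d <- MASS::mvrnorm(50, mu = c(103.96, 108.02), Sigma = S)
  tp <- abs(testStatistic(pairedT(d[, 1], d[, 2])))
  ti <- abs(testStatistic(independentT(d[, 1], d[, 2])))
  expect_gt(tp, 3 * ti)
})

test_that("2x2 chi-square without continuity correction matches published values", {
  expect_lt(abs(testStatistic(chiSquare2x2(23, 14, 36, 36)) - 1.456), 0.001)
  expect_lt(abs(testStatistic(chiSquare2x2(23, 13, 36, 37)) - 2.062), 0.001)
  expect_lt(abs(testStatistic(chiSquare2x2(33, 37, 26, 13)) - 3.845), 0.001)
  expect_equal(degreesOfFreedom(chiSquare2x2(23, 14, 36, 36)), 1)
})

test_that("chi-square is invariant to transposition and row/column swaps", {
  s <- function(...) testStatistic(chiSquare2x2(...))
  expect_equal(s(23, 14, 36, 36), s(23, 36, 14, 36))  # transpose
  expect_equal(s(23, 14, 36, 36), s(36, 36, 23, 14))  # row swap
  expect_equal(s(23, 14, 36, 36), s(14, 23, 36, 36))  # column swap
  expect_equal(s(7, 7, 7, 7), 0)
  expect_error(chiSquare2x2(0, 0, 5, 9), class = "undefinedStatisticError")
  expect_error(chiSquare2x2(1.5, 2, 3, 4), class = "invalidInputError")
})

test_that("chi-square flags small expected counts with a Fisher exact p", {
  res <- chiSquare2x2(1, 9, 8, 3)
  expect_true(isTRUE(res@note$low_expected))
  expect_equal(res@note$fisher_p,
               fisher.test(rbind(c(1, 9), c(8, 3)))$p.value)
  yates <- chiSquare2x2(23, 14, 36, 36, correct = TRUE)
  expect_lt(testStatistic(yates), testStatistic(chiSquare2x2(23, 14, 36, 36)))
})

test_that("Mann-Whitney: complete separation, null behaviour, enumeration oracle", {
  a <- rnorm(10)
  b <- a + 1000
  res <- rankTests(a, b)
  expect_equal(testStatistic(res), 0)  # no pair with a > b
  expect_equal(pValue(res), 2 / choose(20, 10))  # minimal two-sided exact p
  # permuted single distribution: mostly non-significant over seeds
  set.seed(17)
  ps <- replicate(20, {
    x <- rnorm(12)
    y <- sample(rnorm(12))
    pValue(rankTests(x, y))
  })
  expect_gte(sum(ps > 0.05), 17)
  # small-n exact p equals full enumeration
  set.seed(18)
  for (i in 1:6) {
    n <- sample(4:8, 1)
    m <- sample(4:8, 1)
    x <- rnorm(n)
    y <- rnorm(m, 0.5)
    expect_equal(pValue(rankTests(x, y)), enumMannWhitneyP(x, y),
                 tolerance = 1e-12)
  }
})

test_that("paired rank test rejects all-zero differences and handles shifts", {
  x <- rnorm(12)
  expect_error(rankTests(x, x, paired = TRUE),
               class = "undefinedStatisticError")
  res <- rankTests(x, x + 100, paired = TRUE)
  expect_equal(testStatistic(res), 0)
  expect_lt(pValue(res), 0.01)
})

test_that("the Shapiro-Wilk gate routes normal and skewed data correctly", {
  expect_error(shapiroWilkGate(c(1, 2)), class = "invalidInputError")
  expect_error(shapiroWilkGate(rep(3, 10)), class = "invalidInputError")
  set.seed(19)
  routes <- replicate(100, shapiroWilkGate(rnorm(500)))
  # type-I rate of the gate is 5%: ~95 of 100 normal samples route normal
  expect_gte(sum(routes == "normal"), 85)
  skew <- replicate(20, shapiroWilkGate(rexp(200)))
  expect_true(all(skew == "skewed"))
})

test_that("the table builder emits all eight comparisons with sane structure", {
  cohort <- simulateCohort(cohortSpec(seed = 77))
  bat <- buildTables(cohort)
  expect_length(bat$skipped, 0)
  expect_setequal(names(bat$tables),
                  c("control_left_vs_right", "pre_vs_control_right",
                    "pre_vs_control_left", "post_vs_control_right",
                    "post_vs_control_left", "ipsi_vs_contra_pre",
                    "ipsi_vs_contra_post", "pre_vs_post_ipsilateral"))
  for (tab in bat$tables) {
    expect_equal(tab$parameter,
                 c("RALD", "RAOD", "AWT", "RVLD", "RVOD", "VWT", "AVR"))
    expect_true(all(tab$p >= 0 & tab$p <= 1))
  }
  # paired comparisons use paired tests, independent ones do not
  expect_true(all(grepl("paired|signed rank",
                        bat$tables$pre_vs_post_ipsilateral$test)))
  expect_false(any(grepl("paired|signed rank",
                         bat$tables$pre_vs_control_right$test)))
  # the stenosis group's pre-stenting arteries are narrower than control:
  # first-minus-second statistic is strongly negative for RAOD
  expect_lt(bat$tables$pre_vs_control_right$statistic[2], -2)
})

test_that("missing arms are skipped with a structured report", {
  cohort <- simulateCohort(cohortSpec(seed = 78))
  noG1 <- cohort[cohort$group == 0, ]
  bat <- buildTables(noG1)
  expect_setequal(names(bat$tables), "control_left_vs_right")
  expect_length(bat$skipped, 7)
  expect_match(bat$skipped[["pre_vs_control_right"]], "arm sizes")
  noPost <- cohort[cohort$timepoint != "post_CAS", ]
  batPost <- buildTables(noPost)
  expect_true(all(c("post_vs_control_right", "ipsi_vs_contra_post",
                    "pre_vs_post_ipsilateral") %in% names(batPost$skipped)))
  expect_error(buildTables(cohort[, -5]), class = "invalidInputError")
})
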