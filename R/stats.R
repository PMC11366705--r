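# The comparison battery: Shapiro-Wilk gating, pooled/paired t tests, rank
# tests and the Pearson chi-square, plus recomputation of test statistics
# from printed summary rows (mean +/- SD, n). Everything is two-tailed at
# alpha 0.05 and no multiple-testing correction is applied, matching how
# such cohort tables are conventionally analysed. The t statistic is always
# the FIRST arm minus the SECOND.

#' Shapiro-Wilk normality gate
#'
#' Routes a sample to the parametric (`"normal"`) or rank-based (`"skewed"`)
#' branch of the battery at alpha 0.05.
#'
#' @param x numeric sample, n >= 3, non-constant.
#' @param alpha gate level.
#' @return `"normal"` or `"skewed"`, with attributes `p` and `statistic`
#'   (the Shapiro-Wilk W).
#' @export
shapiroWilkGate <- function(x, alpha = 0.05) {
  if (length(x) < 3L)
    stopWithClass("invalidInputError", "normality gate needs n >= 3")
  if (stats::sd(x) == 0)
    stopWithClass("invalidInputError",
                  "constant sample: Shapiro-Wilk W is undefined")
  sw <- stats::shapiro.test(x)
  structure(if (sw$p.value < alpha) "skewed" else "normal",
            p = sw$p.value, statistic = unname(sw$statistic))
}

#' Student pooled-variance t test from a printed summary row
#'
#' Recomputes the independent-samples t statistic from the two arms'
#' mean, SD and n:
#' \deqn{t = (m_A - m_B) / (s_p \sqrt{1/n_A + 1/n_B}), \quad
#'   s_p^2 = \frac{(n_A-1)s_A^2 + (n_B-1)s_B^2}{n_A+n_B-2}}
#' with df = nA + nB - 2 and a two-tailed p. This is the form that
#' reproduces published table statistics from their own summary cells.
#'
#' @param meanA,sdA,nA first arm moments.
#' @param meanB,sdB,nB second arm moments.
#' @return A [StatResult-class].
#' @examples
#' ## arms (146.91 +/- 12.36, n 59) vs (135.42 +/- 12.17, n 50): t = 4.870
#' testStatistic(pooledTFromSummary(146.91, 12.36, 59, 135.42, 12.17, 50))
#' @export
pooledTFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB) {
  for (v in list(sdA, sdB)) .assertScalarNumber(v, "sd", nonneg = TRUE)
  if (nA < 2 || nB < 2)
    stopWithClass("invalidInputError", "both arms need n >= 2")
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
  if (sp2 == 0) {
    if (meanA == meanB)
      return(.statResult("Student pooled t (summary)", 0, df, 1))
    stopWithClass("infiniteStatisticError",
                  "zero pooled variance with unequal means: t is infinite")
  }
  t <- (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
  .statResult("Student pooled t (summary)", t, df, 2 * stats::pt(-abs(t), df))
}

#' Independent two-sample t test
#'
#' Sample-based counterpart of [pooledTFromSummary()]; the pooled variant
#' agrees with the summary formula fed the samples' own moments. Welch is
#' available as an option but the pooled form is the default: it is the one
#' whose statistics match published summary-row recomputation.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param variant `"pooled"` (Student) or `"welch"`.
#' @return A [StatResult-class]; statistic is mean(a) - mean(b) scaled.
#' @export
independentT <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stopWithClass("invalidInputError", "both arms need n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(.statResult(sprintf("independent t (%s)", variant), 0,
                         length(a) + length(b) - 2, 1))
    stopWithClass("infiniteStatisticError",
                  "zero variance in both arms with unequal means: t is infinite")
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  .statResult(sprintf("independent t (%s)", variant),
              unname(tt$statistic), unname(tt$parameter), tt$p.value)
}

#' Paired t test
#'
#' One-sample t on the within-subject differences `before - after`,
#' df = n - 1, two-tailed.
#'
#' @param before,after equal-length numeric samples, n >= 2.
#' @return A [StatResult-class].
#' @export
pairedT <- function(before, after) {
  if (length(before) != length(after))
    stopWithClass("invalidInputError", "paired samples must have equal length")
  if (length(before) < 2L)
    stopWithClass("invalidInputError", "paired t needs n >= 2")
  d <- before - after
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(.statResult("paired t", 0, length(d) - 1, 1))
    stopWithClass("infiniteStatisticError",
                  "constant non-zero paired differences: t is infinite")
  }
  tt <- stats::t.test(before, after, paired = TRUE)
  .statResult("paired t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value)
}

#' Pearson chi-square for a 2x2 table
#'
#' Pearson's chi-square WITHOUT continuity correction (the form that
#' reproduces published 2x2 statistics from their printed counts),
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1. Yates'
#' correction is available behind `correct`. When any expected count is
#' below 5 the Fisher exact p is computed as well and attached to the
#' result's note.
#'
#' @param a,b,c,d cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @param correct apply Yates' continuity correction (default FALSE).
#' @return A [StatResult-class]; note holds `fisher_p` and
#'   `low_expected = TRUE` when the small-count flag fires.
#' @examples
#' testStatistic(chiSquare2x2(23, 14, 36, 36))  # 1.456
#' @export
chiSquare2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stopWithClass("invalidInputError", "counts must be non-negative integers")
  m <- rbind(c(a, b), c(c, d))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stopWithClass("undefinedStatisticError",
                  "a zero margin leaves the chi-square statistic undefined")
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  note <- list()
  if (any(ct$expected < 5))
    note <- list(low_expected = TRUE,
                 fisher_p = stats::fisher.test(m)$p.value)
  .statResult(if (correct) "Pearson chi-square (Yates)" else "Pearson chi-square",
              unname(ct$statistic), unname(ct$parameter), ct$p.value,
              note = note)
}

#' Rank-based comparisons: Mann-Whitney U and Wilcoxon signed rank
#'
#' The non-parametric branch of the battery. Unpaired samples get the
#' Mann-Whitney U (two-tailed; exact when both arms have n <= 25 and no
#' ties, else the tie-corrected normal approximation); paired samples get
#' the Wilcoxon signed-rank test under the same exactness rule.
#'
#' @param a,b numeric samples.
#' @param paired logical.
#' @return A [StatResult-class] (statistic is U resp. V).
#' @export
rankTests <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b))
      stopWithClass("invalidInputError", "paired samples must have equal length")
    d <- a - b
    if (all(d == 0))
      stopWithClass("undefinedStatisticError",
                    "all paired differences are zero: signed-rank test undefined")
    exact <- length(d[d != 0]) <= 25 && !anyDuplicated(abs(d[d != 0]))
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = exact, correct = FALSE))
    return(.statResult("Wilcoxon signed rank", unname(wt$statistic),
                       NA_real_, wt$p.value))
  }
  exact <- length(a) <= 25 && length(b) <= 25 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  .statResult("Mann-Whitney U", unname(wt$statistic), NA_real_, wt$p.value)
}

## The eight cohort comparisons: which arms, and whether subjects pair.
.COMPARISONS <- list(
  control_left_vs_right =
    list(a = c(0, "left", "single"), b = c(0, "right", "single"), paired = TRUE),
  pre_vs_control_right =
    list(a = c(1, "ipsilateral", "pre_CAS"), b = c(0, "right", "single"),
         paired = FALSE),
  pre_vs_control_left =
    list(a = c(1, "ipsilateral", "pre_CAS"), b = c(0, "left", "single"),
         paired = FALSE),
  post_vs_control_right =
    list(a = c(1, "ipsilateral", "post_CAS"), b = c(0, "right", "single"),
         paired = FALSE),
  post_vs_control_left =
    list(a = c(1, "ipsilateral", "post_CAS"), b = c(0, "left", "single"),
         paired = FALSE),
  ipsi_vs_contra_pre =
    list(a = c(1, "ipsilateral", "pre_CAS"), b = c(1, "contralateral", "pre_CAS"),
         paired = TRUE),
  ipsi_vs_contra_post =
    list(a = c(1, "ipsilateral", "post_CAS"),
         b = c(1, "contralateral", "post_CAS"), paired = TRUE),
  pre_vs_post_ipsilateral =
    list(a = c(1, "ipsilateral", "pre_CAS"), b = c(1, "ipsilateral", "post_CAS"),
         paired = TRUE))

.selectArm <- function(cohort, key) {
  cohort[cohort$group == as.numeric(key[1]) & cohort$eye == key[2] &
           cohort$timepoint == key[3], , drop = FALSE]
}

#' Build the full comparison battery from a per-eye cohort
#'
#' Runs the eight standard comparisons of such a cohort - control left vs
#' right eye; stenosis ipsilateral (pre and post stenting) vs each control
#' eye; ipsilateral vs contralateral before and after stenting; and
#' ipsilateral before vs after - for all seven vessel parameters. Paired
#' tests are used exactly where both arms come from the same subjects
#' (joined on `subject_id`), independent tests elsewhere. When `gate` is
#' TRUE each comparison is routed through the Shapiro-Wilk gate (per arm for
#' independent comparisons, on the differences for paired ones) and falls
#' back to the matching rank test when normality is rejected.
#'
#' @param cohort data.frame as produced by [simulateCohort()] or
#'   [readCohort()].
#' @param gate apply the normality gate (default TRUE).
#' @param variant t-test variant for independent comparisons.
#' @return list with `tables` (named list of data.frames: parameter, per-arm
#'   mean/sd/n, statistic, df, p, test) and `skipped` (named character:
#'   reasons for any comparison whose arms are missing). Statistics are
#'   first arm minus second arm.
#' @export
buildTables <- function(cohort, gate = TRUE, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  need <- c("subject_id", "group", "eye", "timepoint", .COHORT_PARAMS)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stopWithClass("invalidInputError", "cohort lacks column(s): %s",
                  paste(miss, collapse = ", "))
  tables <- list()
  skipped <- character()
  for (nm in names(.COMPARISONS)) {
    cmp <- .COMPARISONS[[nm]]
    A <- .selectArm(cohort, cmp$a)
    B <- .selectArm(cohort, cmp$b)
    if (nrow(A) < 2L || nrow(B) < 2L) {
      skipped[nm] <- sprintf("arm sizes %d vs %d (need >= 2 each)",
                             nrow(A), nrow(B))
      next
    }
    if (cmp$paired) {
      ids <- intersect(A$subject_id, B$subject_id)
      if (length(ids) < 2L) {
        skipped[nm] <- sprintf("only %d matched subject(s)", length(ids))
        next
      }
      A <- A[match(ids, A$subject_id), ]
      B <- B[match(ids, B$subject_id), ]
    }
    rows <- lapply(.COHORT_PARAMS, function(p) {
      x <- A[[p]]
      y <- B[[p]]
      useRank <- FALSE
      if (gate) {
        useRank <- if (cmp$paired) {
          shapiroWilkGate(x - y) == "skewed"
        } else {
          shapiroWilkGate(x) == "skewed" || shapiroWilkGate(y) == "skewed"
        }
      }
      res <- if (useRank) rankTests(x, y, paired = cmp$paired)
      else if (cmp$paired) pairedT(x, y)
      else independentT(x, y, variant)
      data.frame(parameter = p,
                 meanA = mean(x), sdA = stats::sd(x), nA = length(x),
                 meanB = mean(y), sdB = stats::sd(y), nB = length(y),
                 statistic = res@statistic, df = res@df, p = res@p,
                 test = res@test, stringsAsFactors = FALSE)
    })
    tables[[nm]] <- do.call(rbind, rows)
  }
  list(tables = tables, skipped = skipped)
}
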