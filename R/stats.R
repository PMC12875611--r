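#' @include AllClasses.R
NULL

newTestResult <- function(statistic, df, p, nA, nB, method,
                          degenerate = FALSE) {
  new("TestResult", statistic = statistic, df = df, pValue = p,
      nA = as.integer(nA), nB = as.integer(nB), method = method,
      degenerate = degenerate)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance two-sample location test:
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. When
#' both samples have zero variance the test is degenerate: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0` with the degenerate flag set.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return a [TestResult-class].
#' @export
#' @examples
#' welchT(c(1, 2, 3, 4), c(2, 3, 4, 5))
welchT <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (dm == 0)
      return(newTestResult(0, NA_real_, 1, na, nb, "Welch two-sample t-test",
                           degenerate = TRUE))
    return(newTestResult(sign(dm) * Inf, NA_real_, 0, na, nb,
                         "Welch two-sample t-test", degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  t <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  newTestResult(t, df, p, na, nb, "Welch two-sample t-test")
}

#' Paired two-sample t-test
#'
#' One-sample t-test on the paired differences, two-sided. All-zero
#' differences give `t = 0, p = 1`; constant non-zero differences are the
#' degenerate zero-variance branch with `p = 0`.
#'
#' @param a,b equal-length paired numeric samples (length >= 2).
#' @return a [TestResult-class].
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  d <- a - b
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::var(d) == 0) {
    if (mean(d) == 0)
      return(newTestResult(0, NA_real_, 1, n, n, "paired t-test",
                           degenerate = TRUE))
    return(newTestResult(sign(mean(d)) * Inf, NA_real_, 0, n, n,
                         "paired t-test", degenerate = TRUE))
  }
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  df <- n - 1
  newTestResult(t, df, 2 * stats::pt(-abs(t), df), n, n, "paired t-test")
}

#' Compare every group's symmetry scores to the intact-limb group
#'
#' For every non-intact group and every score column (per-class and
#' combined), runs a Welch two-sided t-test against the intact group — the
#' intact limb being the reference "typical asymmetric structure". No
#' multiple-testing correction is applied by default; set `bh = TRUE` for
#' Benjamini-Hochberg adjusted p-values in an extra column.
#'
#' @param scores a score table (see [scoreTable()]): columns `group`,
#'   `sample`, `window`, `class_1`..`class_5`, `combined`.
#' @param intactGroup name of the reference group.
#' @param bh apply Benjamini-Hochberg adjustment across all reported tests.
#' @return tidy data.frame: `group`, `metric`, `statistic`, `df`, `p`,
#'   `n_intact`, `n_group` (and `p_bh` when requested).
#' @export
compareToIntact <- function(scores, intactGroup, bh = FALSE) {
  if (!intactGroup %in% scores$group)
    stop("intact group '", intactGroup, "' not present in the score table",
         call. = FALSE)
  metrics <- intersect(c(paste0("class_", 1:5), "combined"),
                       colnames(scores))
  others <- setdiff(unique(scores$group), intactGroup)
  rows <- list()
  for (g in others) {
    for (m in metrics) {
      a <- scores[scores$group == g, m]
      b <- scores[scores$group == intactGroup, m]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) next
      res <- welchT(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, statistic = res@statistic, df = res@df,
        p = res@pValue, n_intact = length(b), n_group = length(a),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Outcome rates of an accessory-limb-model table
#'
#' Converts per-condition regress/bump/limb counts into percentages of N.
#' Percentages are exact (`100 * count / N`); round to one decimal for the
#' conventional printed style.
#'
#' @param tbl data.frame with columns `condition`, `N`, `regress`, `bump`,
#'   `limb`; counts must be non-negative and sum to `N` per row.
#' @return data.frame with the counts plus `regress_pct`, `bump_pct`,
#'   `limb_pct`.
#' @export
#' @examples
#' outcomeRates(table1Outcomes())
outcomeRates <- function(tbl) {
  need <- c("condition", "N", "regress", "bump", "limb")
  if (!all(need %in% colnames(tbl)))
    stop("outcome table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(tbl$N == 0)) stop("N must be positive for every condition",
                            call. = FALSE)
  cnt <- as.matrix(tbl[, c("regress", "bump", "limb")])
  if (any(cnt < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(cnt) != tbl$N))
    stop("regress + bump + limb must equal N in every row", call. = FALSE)
  out <- tbl[, need]
  out$regress_pct <- 100 * tbl$regress / tbl$N
  out$bump_pct <- 100 * tbl$bump / tbl$N
  out$limb_pct <- 100 * tbl$limb / tbl$N
  out
}

#' Packaged ALM outcome counts
#'
#' The published induction-rate table of the accessory limb model: number
#' of experiments per condition and how many regressed, formed a bump, or
#' formed a multi-digit limb. Conditions are named by wound orientation
#' (Ant/Post/Dor/VentBL) with "+P/+A/+V/+D" marking an opposite-side skin
#' graft.
#'
#' @return data.frame with columns `condition`, `N`, `regress`, `bump`,
#'   `limb`.
#' @export
table1Outcomes <- function() {
  path <- system.file("extdata", "table1_outcomes.csv",
                      package = "SectionSymmetry", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test on a 2 x 2 table
#'
#' Sums, over the hypergeometric distribution with the observed margins,
#' the probabilities of all tables no more probable than the observed one.
#'
#' @param m 2 x 2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher2x2(matrix(c(5, 0, 0, 5), 2))
fisher2x2 <- function(m) {
  m <- as.matrix(m)
  stopifnot(identical(dim(m), c(2L, 2L)))
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  r1 <- sum(m[1L, ]); n <- sum(m)
  c1 <- sum(m[, 1L])
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  pObs <- stats::dhyper(m[1L, 1L], c1, n - c1, r1)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}
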