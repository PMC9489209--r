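# Population-level comparisons of per-cell mobility statistics.

# Significance coding used throughout: n.s. (p >= 0.05), * (p < 0.05),
# ** (p < 0.001), *** (p < 0.0001).
.significanceCode <- function(p) {
  if (p < 1e-4) "***"
  else if (p < 1e-3) "**"
  else if (p < 0.05) "*"
  else "n.s."
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Compares two groups of per-cell statistics (typically MSD at 10 s)
#' with midrank handling of ties: the exact null distribution when
#' n_a + n_b <= 20 and there are no ties, otherwise the normal
#' approximation with tie and continuity correction. "Wilcoxon rank-sum"
#' and "Mann-Whitney" are the same test; both names are accepted via
#' \code{statisticName}.
#'
#' @param a,b numeric vectors (both non-empty)
#' @param labels group labels, character(2)
#' @param statisticName "wilcoxon_rank_sum" (default) or "mann_whitney_u"
#' @return a [PopulationComparison-class]
#' @examples
#' pValue(rankSumTest(c(1, 2), c(3, 4)))  # exact: 2/6
#' @export
rankSumTest <- function(a, b, labels = c("a", "b"),
                        statisticName = c("wilcoxon_rank_sum", "mann_whitney_u")) {
  statisticName <- match.arg(statisticName)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("NA values in input")
  pooled <- c(a, b)
  degenerate <- length(unique(pooled)) == 1L
  if (degenerate) {
    p <- 1
    U <- length(a) * length(b) / 2
  } else {
    ties <- anyDuplicated(pooled) > 0L
    exact <- (length(a) + length(b) <= 20L) && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    p <- wt$p.value
    U <- unname(wt$statistic)
  }
  methods::new("PopulationComparison",
    groupLabels = labels, nPerGroup = c(length(a), length(b)),
    statisticName = statisticName, statisticValue = U,
    pValue = p, significanceCode = .significanceCode(p),
    degenerate = degenerate)
}

#' Box-plot summary
#'
#' Quartiles by linear interpolation between order statistics
#' (\code{stats::quantile} type 7). Outliers are values below
#' q1 - 1.5 IQR or above q3 + 1.5 IQR; whiskers span the full range of
#' the remaining values.
#'
#' @param values numeric vector with at least one value
#' @return a [BoxSummary-class]
#' @export
boxSummary <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) stop("need at least one non-NA value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  inl <- values[values >= lo & values <= hi]
  methods::new("BoxSummary", median = q[2], q1 = q[1], q3 = q[3],
               whiskerLow = min(inl), whiskerHigh = max(inl),
               outliers = sort(out))
}

#' Mixed-population analysis of per-cell MSD values
#'
#' Emulates contamination of a damaged population with a fraction of
#' undamaged cells and asks whether the mixture is still distinguishable
#' from the pure damaged population. Two things are computed: (i) the
#' reference rank-sum test damaged vs undamaged, and (ii) over
#' \code{nReplicates} bootstrap replicates, a mixed sample of
#' \code{length(damaged)} values -- floor(fraction * n) drawn with
#' replacement from the undamaged pool, the rest from the damaged pool --
#' is tested against the damaged-only sample; the fraction of replicates
#' significant at 0.05 is reported alongside the group means. A single
#' deterministic stratified mix (evenly spaced order statistics of each
#' pool, no resampling) is also computed.
#'
#' @param damaged,undamaged per-cell MSD values of the two reference
#'   populations
#' @param fractionUndamaged fraction of undamaged cells in the mixture
#'   (default 0.2)
#' @param nReplicates bootstrap replicates (default 1000)
#' @param seed RNG seed for the resampling
#' @return a list with elements \code{baseComparison}
#'   (a [PopulationComparison-class]), \code{significantFraction},
#'   \code{replicatePValues}, \code{deterministicComparison},
#'   \code{meanDamaged}, \code{meanUndamaged}, \code{meanMixed},
#'   \code{fractionUndamaged}, \code{nReplicates}
#' @export
mixtureAnalysis <- function(damaged, undamaged, fractionUndamaged = 0.2,
                            nReplicates = 1000L, seed = 1L) {
  if (fractionUndamaged < 0 || fractionUndamaged > 1)
    stop("'fractionUndamaged' must be in [0, 1]")
  damaged <- as.numeric(damaged); undamaged <- as.numeric(undamaged)
  base <- rankSumTest(damaged, undamaged, labels = c("damaged", "undamaged"))
  n <- length(damaged)
  nU <- as.integer(floor(fractionUndamaged * n))
  nD <- n - nU
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(seed)
  pv <- numeric(nReplicates)
  mixMeans <- numeric(nReplicates)
  for (r in seq_len(nReplicates)) {
    mixed <- c(if (nU > 0L) sample(undamaged, nU, replace = TRUE),
               if (nD > 0L) sample(damaged, nD, replace = TRUE))
    pv[r] <- pValue(rankSumTest(mixed, damaged, labels = c("mixed", "damaged")))
    mixMeans[r] <- mean(mixed)
  }
  # deterministic stratified mix: evenly spaced order statistics
  pick <- function(v, k) {
    if (k == 0L) return(numeric())
    sort(v)[round(seq(1L, length(v), length.out = k))]
  }
  detMix <- c(pick(undamaged, nU), pick(damaged, nD))
  detCmp <- rankSumTest(detMix, damaged, labels = c("mixed", "damaged"))
  list(baseComparison = base,
       significantFraction = mean(pv < 0.05),
       replicatePValues = pv,
       deterministicComparison = detCmp,
       meanDamaged = mean(damaged),
       meanUndamaged = mean(undamaged),
       meanMixed = mean(mixMeans),
       fractionUndamaged = fractionUndamaged,
       nReplicates = as.integer(nReplicates))
}
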