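# Two-group uniqueness of peaks from presence/absence patterns: either
# simple proportion thresholds, or a likelihood-ratio (G) test of
# independence on the per-peak 2x2 table (group x observed/missing) with
# the Williams small-sample correction.

.checkTwoGroups <- function(ds, groups, minPerGroup = 1L) {
  if (is.null(groups)) groups <- groups(ds)
  groups <- groups[!is.na(groups)]
  if (is.null(names(groups)) || !length(groups))
    stop("groups must be a named sample -> label vector ",
         "(see detectGroups)")
  unknown <- setdiff(names(groups), colnames(ds))
  if (length(unknown))
    stop("group assignment refers to unknown sample(s): ",
         paste(head(unknown, 5), collapse = ", "))
  labs <- unique(groups)
  if (length(labs) != 2L)
    stop("exactly two groups are required; got: ",
         paste(labs, collapse = ", "))
  sizes <- table(factor(groups, levels = labs))
  if (any(sizes < minPerGroup))
    stop(if (minPerGroup >= 3L)
      "the G-test requires that groups consist of at least three samples each"
      else "each group needs at least one sample")
  list(samples = split(names(groups), factor(groups, levels = labs)),
       labels = labs, sizes = as.integer(sizes))
}

.presenceCounts <- function(ds, grp) {
  if (!isMissingEncoded(ds))
    stop("encode missing values first (encodeMissing)")
  obs <- !is.na(peakTable(ds))
  a <- rowSums(obs[, grp$samples[[1L]], drop = FALSE])
  b <- rowSums(obs[, grp$samples[[2L]], drop = FALSE])
  list(a = a, b = b, n1 = grp$sizes[1L], n2 = grp$sizes[2L])
}

.uniqLabels <- c("unique_to_group1", "unique_to_group2",
                 "observed_in_both", "insufficient")

.comparisonResult <- function(ds, df, grp, method, config) {
  res <- DataFrame(df, row.names = rownames(ds))
  metadata(res) <- list(method = method, config = config,
                        groupLabels = grp$labels, groupSizes = grp$sizes)
  res
}

#' Peaks unique to a group by presence/absence thresholds
#'
#' A peak is unique to a group when its observed proportion there is at
#' least `presThreshold` while the other group's proportion is at most
#' `absnThreshold`; observed in both when both proportions reach
#' `presThreshold`; otherwise the evidence is insufficient.
#'
#' @param ds an [FTMSExperiment-class] with missing encoded.
#' @param groups named sample -> label vector with exactly two labels;
#'   defaults to `groups(ds)`.
#' @param presThreshold minimum proportion for "observed" (default 0.5).
#' @param absnThreshold maximum proportion for "absent" (default 0).
#' @return a `DataFrame` (one row per peak) with per-group observed counts
#'   and proportions and a `uniqueness` factor over
#'   `unique_to_group1`, `unique_to_group2`, `observed_in_both`,
#'   `insufficient`; group labels/sizes and the configuration are in
#'   `metadata()`.
#' @seealso [gtestUniqueness()]
#' @export
thresholdUniqueness <- function(ds, groups = NULL, presThreshold = 0.5,
                                absnThreshold = 0) {
  stopifnot(absnThreshold >= 0, presThreshold <= 1,
            absnThreshold < presThreshold)
  grp <- .checkTwoGroups(ds, groups, minPerGroup = 1L)
  pc <- .presenceCounts(ds, grp)
  p1 <- pc$a / pc$n1; p2 <- pc$b / pc$n2
  lab <- rep("insufficient", nrow(ds))
  lab[p1 >= presThreshold & p2 >= presThreshold] <- "observed_in_both"
  lab[p1 >= presThreshold & p2 <= absnThreshold] <- "unique_to_group1"
  lab[p2 >= presThreshold & p1 <= absnThreshold] <- "unique_to_group2"
  df <- data.frame(nObsGroup1 = pc$a, nGroup1 = pc$n1, pGroup1 = p1,
                   nObsGroup2 = pc$b, nGroup2 = pc$n2, pGroup2 = p2,
                   uniqueness = factor(lab, levels = .uniqLabels))
  .comparisonResult(ds, df, grp, "threshold",
                    list(presThreshold = presThreshold,
                         absnThreshold = absnThreshold))
}

#' G statistic, Williams correction and p-value for 2x2 presence tables
#'
#' Vectorized over peaks: for observed counts `a` (of `n1`) and `b` (of
#' `n2`), builds the 2x2 table rows = groups, columns = (observed, missing),
#' computes `G = 2 * sum(O * log(O/E))` over cells with `O > 0`, the
#' Williams factor
#' `q = 1 + (n/n1 + n/n2 - 1) * (n/c1 + n/c2 - 1) / (6n)` from the table
#' margins, the corrected `G/q`, and the chi-square (df = 1) upper-tail
#' p-value.  A degenerate margin (peak observed in no or every sample)
#' yields `G = 0`, `q = 1`, `p = 1`.
#'
#' @param a,b observed-sample counts per peak in groups 1 and 2.
#' @param n1,n2 group sizes.
#' @return data.frame with columns `G`, `q`, `Gcorrected`, `pValue`.
#' @export
gStatistic <- function(a, b, n1, n2) {
  n <- n1 + n2
  c1 <- a + b
  c2 <- n - c1
  O <- cbind(a, n1 - a, b, n2 - b)
  E <- cbind(n1 * c1, n1 * c2, n2 * c1, n2 * c2) / n
  term <- O * log(O / E)
  term[O == 0] <- 0
  G <- 2 * rowSums(term)
  q <- 1 + ((n / n1 + n / n2 - 1) * (n / c1 + n / c2 - 1)) / (6 * n)
  degenerate <- c1 == 0 | c2 == 0
  G[degenerate] <- 0
  q[degenerate] <- 1
  p <- pchisq(G / q, df = 1, lower.tail = FALSE)
  p[degenerate] <- 1
  data.frame(G = G, q = q, Gcorrected = G / q, pValue = p)
}

#' Peaks unique to a group by the Williams-corrected G-test
#'
#' Tests, per peak, whether the probability of observing the peak is
#' independent of group membership (likelihood-ratio test on the 2x2
#' group x observed/missing table, Williams-corrected, chi-square with one
#' degree of freedom).  Requires at least three samples per group.  A peak
#' is unique to the group with the larger observed proportion when the
#' p-value is at most `alpha` and that proportion reaches `presThreshold`;
#' it is observed in both when the p-value exceeds `alpha` and both
#' proportions are positive; otherwise insufficient.
#'
#' @inheritParams thresholdUniqueness
#' @param alpha significance level (default 0.05).
#' @param pAdjust apply a Benjamini-Hochberg correction and use the
#'   adjusted p-values for labeling (off by default; an `pAdjusted` column
#'   is emitted when on).
#' @return a `DataFrame` as in [thresholdUniqueness()] plus columns `G`,
#'   `q`, `Gcorrected`, `pValue` (and `pAdjusted` when requested).
#' @export
gtestUniqueness <- function(ds, groups = NULL, presThreshold = 0.5,
                            absnThreshold = 0, alpha = 0.05,
                            pAdjust = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  grp <- .checkTwoGroups(ds, groups, minPerGroup = 3L)
  pc <- .presenceCounts(ds, grp)
  p1 <- pc$a / pc$n1; p2 <- pc$b / pc$n2
  g <- gStatistic(pc$a, pc$b, pc$n1, pc$n2)
  pUse <- g$pValue
  if (pAdjust) {
    g$pAdjusted <- p.adjust(g$pValue, method = "BH")
    pUse <- g$pAdjusted
  }
  lab <- rep("insufficient", nrow(ds))
  sig <- pUse <= alpha
  lab[!sig & p1 > 0 & p2 > 0] <- "observed_in_both"
  lab[sig & p1 >= p2 & p1 >= presThreshold] <- "unique_to_group1"
  lab[sig & p2 > p1 & p2 >= presThreshold] <- "unique_to_group2"
  df <- data.frame(nObsGroup1 = pc$a, nGroup1 = pc$n1, pGroup1 = p1,
                   nObsGroup2 = pc$b, nGroup2 = pc$n2, pGroup2 = p2,
                   g, uniqueness = factor(lab, levels = .uniqLabels))
  .comparisonResult(ds, df, grp, "gtest",
                    list(presThreshold = presThreshold,
                         absnThreshold = absnThreshold, alpha = alpha,
                         pAdjust = pAdjust))
}
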