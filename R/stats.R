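# Nonparametric comparisons across strategies and observers: joint-rank
# Kruskal-Wallis tests applied pairwise, Benjamini-Hochberg correction at
# a 10% false discovery rate, and Wilcoxon signed-rank tests for paired
# observer comparisons.  The test engines are the base-R implementations;
# the wrappers fix the degenerate cases and the reporting surface.

#' Kruskal-Wallis rank test
#'
#' Ranks all values of all groups together (midranks for ties) and
#' compares rank sums across groups; the tie-corrected H statistic is
#' referred to a chi-square with (number of groups - 1) degrees of
#' freedom.  If every pooled value is identical the test is degenerate:
#' H = 0, p = 1.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("'groups' must be a list of >= 2 numeric vectors")
  if (any(vapply(groups, length, 0L) == 0)) stop("groups must be non-empty")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Benjamini-Hochberg step-up decisions
#'
#' Sorts the p-values ascending, finds the largest k with
#' p(k) <= k q / m, and rejects hypotheses 1..k.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param q Target false discovery rate in (0, 1).
#' @return Logical vector of rejection decisions, in input order.
#' @export
benjamini_hochberg <- function(pvalues, q = 0.10) {
  if (length(pvalues) == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must be in [0, 1]")
  if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  p.adjust(pvalues, method = "BH") <= q
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's original treatment); the
#' statistic uses midranks, with an exact p-value for up to 25 non-zero
#' pairs and a continuity-corrected normal approximation beyond.  If every
#' difference is zero the test is degenerate: W = 0, p = 1.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `statistic` (W, the positive-rank sum), `p_value`,
#'   `n` (non-zero pairs used).
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = "two.sided") {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  d <- a - b
  nz <- d != 0
  if (!any(nz)) return(list(statistic = 0, p_value = 1, n = 0L))
  n <- sum(nz)
  wt <- suppressWarnings(
    wilcox.test(a[nz], b[nz], paired = TRUE, alternative = alternative,
                exact = n <= 25, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n)
}

strategy_order <- c("SELECT_BEST", "GRADIENT", "THRESHOLD", "MANUAL")

#' Pairwise strategy comparisons with FDR correction
#'
#' For one metric of the long-format table, runs the two-group
#' Kruskal-Wallis test (joint ranking of both strategies' values) for
#' every pair of strategies and applies the Benjamini-Hochberg step-up
#' rule to the family of pairwise p-values.
#'
#' @param table Metrics table from [build_metrics_table].
#' @param metric Metric name, e.g. `"jaccard"` or `"pct_matv"`.
#' @param kind `"pairwise"` (inter-observer rows) or `"vs_mv"`.
#' @param q False discovery rate (default 0.10).
#' @return Data frame with one row per strategy pair: `metric`,
#'   `group_a`, `group_b`, `statistic`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
compare_strategies <- function(table, metric = "jaccard",
                               kind = "pairwise", q = 0.10) {
  sub <- table[table$metric == metric & table$kind == kind, ]
  strategies <- intersect(strategy_order, unique(sub$strategy))
  if (length(strategies) < 2)
    stop("need >= 2 strategies with metric '", metric, "'")
  pairs <- combn(strategies, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    kw <- kruskal_wallis(list(sub$value[sub$strategy == pr[1]],
                              sub$value[sub$strategy == pr[2]]))
    data.frame(metric = metric, group_a = pr[1], group_b = pr[2],
               statistic = kw$statistic, p_value = kw$p_value,
               stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$significant <- benjamini_hochberg(out$p_value, q)
  out
}

#' Paired observer comparisons within each strategy
#'
#' Compares the absolute reference-based percentage MATV differences of
#' every observer pair with the Wilcoxon signed-rank test, paired by
#' lesion, with Benjamini-Hochberg correction per strategy family —
#' the experience-effect analysis.
#'
#' @inheritParams compare_strategies
#' @return Data frame with `strategy`, `obs_a`, `obs_b`, `statistic`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
compare_observers <- function(table, metric = "pct_matv", q = 0.10) {
  sub <- table[table$metric == metric & table$kind == "vs_mv", ]
  if (nrow(sub) == 0) stop("no vs-MV rows for metric '", metric, "'")
  out <- do.call(rbind, lapply(split(sub, sub$strategy), function(ss) {
    obs <- sort(unique(ss$obs_a))
    wide <- tapply(abs(ss$value), list(ss$lesion, ss$obs_a), mean)
    res <- do.call(rbind, lapply(combn(obs, 2, simplify = FALSE), function(pr) {
      wt <- wilcoxon_signed_rank(wide[, pr[1]], wide[, pr[2]])
      data.frame(strategy = ss$strategy[1], obs_a = pr[1], obs_b = pr[2],
                 statistic = wt$statistic, p_value = wt$p_value,
                 stringsAsFactors = FALSE)
    }))
    res$p_adjusted <- p.adjust(res$p_value, method = "BH")
    res$significant <- benjamini_hochberg(res$p_value, q)
    res
  }))
  rownames(out) <- NULL
  out
}

#' Tally of select-the-best preferences
#'
#' Counts how often each of the four automatic algorithms was chosen as
#' the best segmentation, with percentages of all decisions rounded to
#' one decimal.
#'
#' @param records Either a list of `segmentation_record`s (the
#'   `SELECT_BEST` ones are used) or a character vector of chosen labels.
#' @return Data frame with `label`, `count`, `pct`, ordered by count.
#' @export
select_best_tally <- function(records) {
  labels <- if (is.character(records)) records
  else {
    sel <- Filter(function(r) inherits(r, "segmentation_record") &&
                    r$strategy == "SELECT_BEST", records)
    if (length(sel) == 0) stop("no SELECT_BEST records")
    vapply(sel, function(r) r$provenance$chosen_label, "")
  }
  panel_labels <- c("41MAX", "SUV4", "SUV2.5", "AUTO")
  counts <- table(factor(labels, levels = union(panel_labels, unique(labels))))
  out <- data.frame(label = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$pct <- round(100 * out$count / sum(out$count), 1)
  out[order(-out$count), , drop = FALSE]
}
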