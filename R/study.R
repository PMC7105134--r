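# End-to-end orchestration: phantom suite -> simulated observers ->
# metrics table -> statistics, wrapped in a single classed object.

#' Run a complete simulated inter-observer segmentation study
#'
#' Generates (or accepts) a suite of synthetic PET lesions, has every
#' simulated observer delineate every lesion with the four strategies,
#' builds the long-format metrics table against per-strategy majority-vote
#' references, and runs the strategy and observer comparisons: pairwise
#' two-group Kruskal-Wallis tests on inter-observer Jaccard and percentage
#' MATV differences with Benjamini-Hochberg correction, a global
#' Kruskal-Wallis across all four strategies for context, paired Wilcoxon
#' observer comparisons, per-strategy quartile summaries, and the
#' select-the-best preference tally.
#'
#' @param n_lesions Number of synthetic lesions (ignored when `suite` is
#'   given).
#' @param observers Observer panel; default [default_observer_panel()].
#' @param seed Integer seed driving the suite and every observer draw.
#' @param q False discovery rate for the Benjamini-Hochberg correction.
#' @param mv_policy Majority-vote reference policy,
#'   `"EXPERIENCED_ONLY"` (default) or `"ALL"`.
#' @param suite Optional pre-built list of `phantom_case`s.
#' @return A `pet_study` object with fields `records`, `metrics`,
#'   `comparisons` (one data frame per metric family), `global_tests`,
#'   `summaries`, `observer_comparisons`, `tally`, `lesions`, and the
#'   call parameters; it has `print`, `summary` and `plot` methods.
#' @export
run_interobserver_study <- function(n_lesions = 20,
                                    observers = default_observer_panel(),
                                    seed = 1L, q = 0.10,
                                    mv_policy = "EXPERIENCED_ONLY",
                                    suite = NULL) {
  suite <- suite %||% make_scenario_suite(n_lesions, seed)
  records <- run_study(suite, observers, seed)
  metrics <- build_metrics_table(records, suite, observers, mv_policy)

  comparisons <- list(
    jaccard = compare_strategies(metrics, "jaccard", "pairwise", q),
    pct_matv = compare_strategies(metrics, "pct_matv", "pairwise", q))
  global_tests <- lapply(c(jaccard = "jaccard", pct_matv = "pct_matv"),
    function(m) {
      sub <- metrics[metrics$metric == m & metrics$kind == "pairwise", ]
      kruskal_wallis(split(sub$value, sub$strategy))
    })

  summaries <- rbind(
    strategy_summary(metrics, "jaccard", "pairwise"),
    strategy_summary(metrics, "pct_matv", "pairwise"),
    strategy_summary(metrics, "ppv_se", "vs_mv"),
    strategy_summary(metrics, "pct_matv", "vs_mv"),
    strategy_summary(metrics, "pct_suv_max", "vs_mv"),
    strategy_summary(metrics, "pct_suv_mean", "vs_mv"),
    strategy_summary(metrics, "pct_tlg", "vs_mv"))

  lesions <- data.frame(
    lesion = vapply(suite, `[[`, "", "lesion_id"),
    matv_ml = vapply(suite, function(cs) mask_volume_ml(cs$ground_truth), 0),
    confounder = vapply(suite, function(cs) !is.null(cs$confounder_mask), TRUE),
    stringsAsFactors = FALSE)

  structure(list(records = records, metrics = metrics,
                 comparisons = comparisons, global_tests = global_tests,
                 summaries = summaries,
                 observer_comparisons = compare_observers(metrics, q = q),
                 tally = select_best_tally(records),
                 lesions = lesions,
                 n_lesions = length(suite),
                 n_observers = length(observers),
                 seed = seed, q = q, mv_policy = mv_policy),
            class = "pet_study")
}

# Quartile summary (median, Q1, Q3, IQR) of one metric per strategy.
strategy_summary <- function(table, metric, kind) {
  sub <- table[table$metric == metric & table$kind == kind, ]
  strategies <- intersect(strategy_order, unique(sub$strategy))
  do.call(rbind, lapply(strategies, function(s) {
    v <- sub$value[sub$strategy == s]
    qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(metric = metric, kind = kind, strategy = s, n = length(v),
               q1 = qs[1], median = qs[2], q3 = qs[3], iqr = qs[3] - qs[1],
               stringsAsFactors = FALSE)
  }))
}

#' Median of one metric per strategy
#'
#' Convenience accessor, e.g. the median pairwise Jaccard per strategy in
#' decreasing-user-interaction order.
#'
#' @param x A `pet_study`.
#' @param metric Metric name (default `"jaccard"`).
#' @param kind Row kind (default `"pairwise"`).
#' @return Named numeric vector ordered SELECT_BEST, GRADIENT, THRESHOLD,
#'   MANUAL.
#' @export
study_medians <- function(x, metric = "jaccard", kind = "pairwise") {
  s <- x$summaries
  s <- s[s$metric == metric & s$kind == kind, ]
  setNames(s$median, s$strategy)[intersect(strategy_order, s$strategy)]
}

#' @export
print.pet_study <- function(x, ...) {
  cat(sprintf("Simulated PET inter-observer segmentation study\n"))
  cat(sprintf("  %d lesions x %d observers x 4 strategies (seed %d, MV: %s)\n",
              x$n_lesions, x$n_observers, x$seed, x$mv_policy))
  med <- study_medians(x, "jaccard")
  cat("  median pairwise Jaccard: ",
      paste(sprintf("%s %.3f", names(med), med), collapse = ", "), "\n", sep = "")
  nsig <- vapply(x$comparisons, function(cc) sum(cc$significant), 0L)
  cat(sprintf("  significant strategy comparisons (BH, q = %.2f): JC %d/6, %%MATV %d/6\n",
              x$q, nsig[["jaccard"]], nsig[["pct_matv"]]))
  cat("  select-the-best preferences: ",
      paste(sprintf("%s %d (%.1f%%)", x$tally$label, x$tally$count,
                    x$tally$pct), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.pet_study <- function(object, ...) {
  structure(list(study = object), class = "summary.pet_study")
}

#' @export
print.summary.pet_study <- function(x, ...) {
  s <- x$study
  print(s)
  cat("\nPer-strategy quartile summaries:\n")
  print(s$summaries, row.names = FALSE, digits = 4)
  cat("\nPairwise strategy comparisons (two-group Kruskal-Wallis, BH-corrected):\n")
  for (nm in names(s$comparisons)) {
    cat(" ", nm, "\n")
    cc <- s$comparisons[[nm]]
    cc$mark <- ifelse(cc$significant, sprintf("p=%.3g", cc$p_value), "n.s.")
    print(cc[, c("group_a", "group_b", "statistic", "p_adjusted", "mark")],
          row.names = FALSE, digits = 3)
  }
  sig_obs <- s$observer_comparisons[s$observer_comparisons$significant, ]
  cat("\nSignificant paired observer differences (|%MATV| vs MV):",
      if (nrow(sig_obs) == 0) " none\n" else "\n")
  if (nrow(sig_obs) > 0)
    print(sig_obs[, c("strategy", "obs_a", "obs_b", "p_value")],
          row.names = FALSE, digits = 3)
  invisible(x)
}

#' Boxplots of inter-observer agreement by strategy
#'
#' @param x A `pet_study`.
#' @param metric Metric to plot (default `"jaccard"`).
#' @param kind Row kind (default `"pairwise"`).
#' @param ... Passed to [graphics::boxplot].
#' @return Invisibly, the boxplot stats.
#' @export
plot.pet_study <- function(x, metric = "jaccard", kind = "pairwise", ...) {
  sub <- x$metrics[x$metrics$metric == metric & x$metrics$kind == kind, ]
  sub$strategy <- factor(sub$strategy,
                         levels = intersect(strategy_order, sub$strategy))
  invisible(boxplot(value ~ strategy, data = sub,
                    ylab = metric,
                    xlab = "strategy (user-interaction increases ->)",
                    main = sprintf("%s (%s)", metric, kind), ...))
}
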