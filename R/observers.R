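# Parameterised stochastic stand-ins for the six human observers.  A
# simulated observer is a biased, noisy threshold selector plus a boundary
# editor: the "satisfactory" percent threshold is anchored at the
# objectively overlap-optimal value for the lesion and perturbed by a
# per-strategy Gaussian, experience controls bias, noise and edit rate,
# and the select-the-best observer picks the overlap-optimal panel member
# with a given accuracy.  This generative model is entirely synthetic (the
# study it emulates used human raters); its knobs map one-to-one onto the
# reported effects: experience -> bias/edit rate, strategy -> variance,
# with user interaction decreasing from manual to select-the-best.

#' Observer profile
#'
#' @param id Observer identifier.
#' @param experience `"EXPERIENCED"` or `"NOVICE"`.
#' @param threshold_bias_pct Systematic offset (percent points of SUVmax)
#'   added to the chosen threshold; positive values shrink the VOI, the
#'   tendency reported for less experienced raters.
#' @param sd_manual,sd_threshold,sd_gradient Standard deviations (percent
#'   points) of the threshold choice under the manual starting shrink, the
#'   interactive threshold and the gradient-assisted workflow; the
#'   gradient display anchors the boundary, so `sd_gradient <=
#'   sd_threshold <= sd_manual`.
#' @param manual_edit_rate Probability that each voxel of the boundary
#'   shell is toggled during manual editing, in \[0, 1).
#' @param select_accuracy_p Probability of picking the overlap-optimal
#'   panel member in the select-the-best workflow.
#' @param annex_rate Probability that, in a confounder-adjacent case, the
#'   manual edit annexes nearby confounder-organ voxels (the
#'   kidney/heart failure mode).
#' @return An `observer_profile`.
#' @export
observer_profile <- function(id, experience = c("EXPERIENCED", "NOVICE"),
                             threshold_bias_pct = 0,
                             sd_manual = 4, sd_threshold = 3,
                             sd_gradient = 0.8,
                             manual_edit_rate = 0.05,
                             select_accuracy_p = 0.85,
                             annex_rate = 0) {
  experience <- match.arg(experience)
  stopifnot(sd_manual >= 0, sd_threshold >= 0, sd_gradient >= 0,
            manual_edit_rate >= 0, manual_edit_rate < 1,
            select_accuracy_p >= 0, select_accuracy_p <= 1,
            annex_rate >= 0, annex_rate <= 1)
  structure(list(id = id, experience = experience,
                 threshold_bias_pct = threshold_bias_pct,
                 sd_manual = sd_manual, sd_threshold = sd_threshold,
                 sd_gradient = sd_gradient,
                 manual_edit_rate = manual_edit_rate,
                 select_accuracy_p = select_accuracy_p,
                 annex_rate = annex_rate),
            class = "observer_profile")
}

#' Default six-observer panel
#'
#' Three experienced observers (o1-o3: unbiased, low threshold noise, few
#' manual edits, high select accuracy) and three with less experience
#' (o4a, o4b, o5: positive threshold bias, higher noise and edit rates,
#' lower select accuracy; o4a and o4b may annex adjacent confounder
#' organs during manual editing).
#'
#' @return Named list of six [observer_profile]s.
#' @export
default_observer_panel <- function() {
  exp_prof <- function(id)
    observer_profile(id, "EXPERIENCED", threshold_bias_pct = 0,
                     sd_manual = 4, sd_threshold = 3, sd_gradient = 0.8,
                     manual_edit_rate = 0.05, select_accuracy_p = 0.85)
  nov_prof <- function(id, annex = 0)
    observer_profile(id, "NOVICE", threshold_bias_pct = 3,
                     sd_manual = 7, sd_threshold = 5, sd_gradient = 1.2,
                     manual_edit_rate = 0.15, select_accuracy_p = 0.65,
                     annex_rate = annex)
  panel <- list(exp_prof("o1"), exp_prof("o2"), exp_prof("o3"),
                nov_prof("o4a", annex = 0.5), nov_prof("o4b", annex = 0.5),
                nov_prof("o5"))
  names(panel) <- vapply(panel, `[[`, "", "id")
  panel
}

new_segmentation_record <- function(lesion_id, observer_id, strategy, mask,
                                    provenance) {
  structure(list(lesion_id = lesion_id, observer_id = observer_id,
                 strategy = strategy, mask = mask, provenance = provenance),
            class = "segmentation_record")
}

#' @export
print.segmentation_record <- function(x, ...) {
  cat(sprintf("<segmentation_record> %s / %s / %s: %.2f mL\n",
              x$lesion_id, x$observer_id, x$strategy,
              mask_volume_ml(x$mask)))
  invisible(x)
}

# Overlap-optimal percent threshold: argmax over the integer slider grid
# of the Jaccard between the thresholded mask and the ground truth.
# Evaluated by sorting the in-rough-mask values once (strict > cut at each
# grid point).
ideal_pct <- function(case, grid = 0:100) {
  v <- case$image$values[case$rough_mask$values]
  truth_in <- case$ground_truth$values[case$rough_mask$values]
  n_truth <- sum(case$ground_truth$values)
  suv_max <- max(v)
  ord <- order(v, decreasing = TRUE)
  cum_tp <- cumsum(truth_in[ord])
  vs <- sort(v)
  m <- length(v)
  jc <- vapply(grid, function(p) {
    thr <- p / 100 * suv_max
    n_above <- m - findInterval(thr, vs)  # voxels strictly > thr
    if (n_above == 0) return(0)
    tp <- cum_tp[n_above]
    tp / (n_above + n_truth - tp)
  }, 0)
  grid[which.max(jc)]
}

# The interactive slider works in integer percent steps, so the chosen
# threshold is rounded; low-noise observers therefore coincide exactly on
# well-defined boundaries.  The experience bias models the window-driven
# tendency to shrink the VOI; the gradient display shows the boundary
# independently of the intensity window, which is exactly what it is for,
# so the bias does not apply there.
choose_pct <- function(profile, case, sd_pct, biased = TRUE) {
  ideal <- ideal_pct(case)
  bias <- if (biased) profile$threshold_bias_pct else 0
  round(min(100, max(0, ideal + bias + rnorm(1, 0, sd_pct))))
}

#' Simulate an interactive (threshold or gradient-assisted) delineation
#'
#' The observer's chosen percent threshold is the overlap-optimal value
#' for the case plus the profile bias plus Gaussian noise with the
#' strategy's standard deviation, clamped to \[0, 100\] and rounded to the
#' integer slider step; the record holds the percent-of-maximum
#' segmentation at that threshold.  Under the gradient workflow the
#' experience bias is dropped (the gradient display anchors the boundary
#' independently of the intensity window) and only the smaller
#' `sd_gradient` noise remains.  Draws from the current RNG state; seed
#' upstream for reproducibility.
#'
#' @param profile An [observer_profile].
#' @param case A `phantom_case`.
#' @param strategy `"THRESHOLD"` or `"GRADIENT"`.
#' @return A `segmentation_record`.
#' @export
simulate_interactive <- function(profile, case,
                                 strategy = c("THRESHOLD", "GRADIENT")) {
  strategy <- match.arg(strategy)
  sd_pct <- if (strategy == "GRADIENT") profile$sd_gradient else profile$sd_threshold
  pct <- choose_pct(profile, case, sd_pct, biased = strategy != "GRADIENT")
  res <- threshold_pct_max(case$image, case$rough_mask, pct)
  new_segmentation_record(case$lesion_id, profile$id, strategy, res$mask,
                          list(chosen_pct = pct,
                               threshold_suv = res$threshold_suv))
}

#' Simulate a manual delineation
#'
#' Starts from an interactive threshold choice with the (larger) manual
#' standard deviation, then edits the boundary: every voxel of the mask's
#' morphological boundary shell (one voxel pitch in mm, clipped to the
#' rough mask) is independently toggled with the profile's edit rate.  In
#' confounder-adjacent cases, with probability `annex_rate` the edit also
#' annexes the confounder-organ voxels lying within `annex_reach_mm` of
#' the segmentation — the only way a simulated mask escapes the rough
#' mask, mirroring the reported kidney annexation.
#'
#' @inheritParams simulate_interactive
#' @param annex_reach_mm Reach of confounder annexation, mm.
#' @return A `segmentation_record`.
#' @export
simulate_manual <- function(profile, case, annex_reach_mm = 15) {
  pct <- choose_pct(profile, case, profile$sd_manual)
  res <- threshold_pct_max(case$image, case$rough_mask, pct)
  mask_vals <- res$mask$values
  sp <- case$image$spacing
  pitch <- max(sp)
  grown <- dilate_mask(res$mask, pitch)
  shrunk <- erode_mask(res$mask, pitch)
  shell <- grown$values & !shrunk$values & case$rough_mask$values
  shell_idx <- which(shell)
  toggled <- 0L
  if (length(shell_idx) > 0 && profile$manual_edit_rate > 0) {
    flip <- runif(length(shell_idx)) < profile$manual_edit_rate
    mask_vals[shell_idx[flip]] <- !mask_vals[shell_idx[flip]]
    toggled <- sum(flip)
  }
  annexed <- FALSE
  if (!is.null(case$confounder_mask) && profile$annex_rate > 0 &&
      runif(1) < profile$annex_rate) {
    reach <- dilate_mask(binary_mask(mask_vals, sp), annex_reach_mm)
    grab <- case$confounder_mask$values & reach$values
    if (any(grab)) {
      mask_vals <- mask_vals | grab
      annexed <- TRUE
    }
  }
  new_segmentation_record(case$lesion_id, profile$id, "MANUAL",
                          binary_mask(mask_vals, sp),
                          list(chosen_pct = pct, n_toggled = toggled,
                               annexed_confounder = annexed,
                               shell_size = length(shell_idx)))
}

#' Simulate a select-the-best decision
#'
#' Runs (or reuses) the four-algorithm panel, then with probability
#' `select_accuracy_p` picks the member with the highest Jaccard against
#' the ground truth, otherwise one of the other three uniformly.
#'
#' @inheritParams simulate_interactive
#' @param panel Optional precomputed [run_auto_panel] result for the case
#'   (it is deterministic, so it can be shared across observers).
#' @return A `segmentation_record`; provenance records the chosen label.
#' @export
simulate_select_best <- function(profile, case, panel = NULL) {
  panel <- panel %||% run_auto_panel(case$image, case$rough_mask)
  jcs <- vapply(panel, function(r) {
    if (!any(r$mask$values) && !any(case$ground_truth$values)) return(NA_real_)
    if (!any(r$mask$values | case$ground_truth$values)) return(NA_real_)
    jaccard(r$mask, case$ground_truth)
  }, 0)
  best <- which.max(jcs)
  pick <- if (runif(1) < profile$select_accuracy_p) best
          else sample(setdiff(seq_along(panel), best), 1L)
  label <- names(panel)[pick]
  new_segmentation_record(case$lesion_id, profile$id, "SELECT_BEST",
                          panel[[pick]]$mask,
                          list(chosen_label = label,
                               best_label = names(panel)[best],
                               panel_jaccard = jcs))
}

#' Run the full lesion x observer x strategy factorial
#'
#' Every observer delineates every lesion with all four strategies.  Each
#' cell is seeded from a stable hash of (lesion, observer, strategy) XOR
#' the global seed, so a single cell can be reproduced in isolation and
#' adding observers never perturbs existing cells.  The deterministic
#' four-algorithm panel is computed once per lesion and shared.
#'
#' @param suite List of `phantom_case`s (e.g. [make_scenario_suite]).
#' @param observers List of [observer_profile]s (>= 2).
#' @param seed Integer global seed.
#' @param strategies Character subset of
#'   `c("MANUAL", "THRESHOLD", "GRADIENT", "SELECT_BEST")`.
#' @return List of `segmentation_record`s, one per cell.
#' @export
run_study <- function(suite, observers, seed = 1L,
                      strategies = c("MANUAL", "THRESHOLD", "GRADIENT",
                                     "SELECT_BEST")) {
  if (length(suite) < 1) stop("'suite' must be non-empty")
  if (length(observers) < 2) stop("need at least 2 observers")
  strategies <- match.arg(strategies, several.ok = TRUE)
  records <- list()
  for (case in suite) {
    panel <- if ("SELECT_BEST" %in% strategies)
      run_auto_panel(case$image, case$rough_mask) else NULL
    for (profile in observers) {
      for (strategy in strategies) {
        set.seed(cell_seed(seed, case$lesion_id, profile$id, strategy))
        rec <- switch(strategy,
          MANUAL = simulate_manual(profile, case),
          THRESHOLD = simulate_interactive(profile, case, "THRESHOLD"),
          GRADIENT = simulate_interactive(profile, case, "GRADIENT"),
          SELECT_BEST = simulate_select_best(profile, case, panel = panel))
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  records
}
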