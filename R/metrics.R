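# Majority-vote reference construction and the agreement / feature
# metrics: Jaccard for observer pairs, sensitivity and positive predictive
# value against the majority-vote reference, and percentage differences of
# MATV, SUVmax, SUVmean and TLG.
#
# The combined PPV/SE uses the TP/FP/FN forms SE = TP/(TP+FN),
# PPV = TP/(TP+FP), with the segmentation / reference roles labelled
# explicitly (seg, ref) throughout.

#' Voxel overlap tallies between a segmentation and a reference
#'
#' @param seg,ref [binary_mask]s sharing geometry.
#' @return An `overlap_counts` list with `tp`, `fp`, `fn`, `n_seg`,
#'   `n_ref`.
#' @export
overlap_counts <- function(seg, ref) {
  stop_if_geometry_mismatch(seg, ref)
  s <- seg$values; r <- ref$values
  tp <- sum(s & r)
  structure(list(tp = tp, fp = sum(s) - tp, fn = sum(r) - tp,
                 n_seg = sum(s), n_ref = sum(r)),
            class = "overlap_counts")
}

#' Jaccard coefficient of two masks
#'
#' Intersection over union; 1 is perfect agreement.  Undefined (an error)
#' when both masks are empty.
#'
#' @param a,b [binary_mask]s sharing geometry.
#' @return Value in \[0, 1\]; symmetric in its arguments.
#' @export
jaccard <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  uni <- sum(a$values | b$values)
  if (uni == 0) stop("Jaccard undefined: both masks are empty")
  sum(a$values & b$values) / uni
}

#' Sensitivity (recall) against a reference mask
#'
#' TP / (TP + FN): the fraction of the reference recovered by the
#' segmentation.
#'
#' @inheritParams overlap_counts
#' @return Value in \[0, 1\].
#' @export
sensitivity <- function(seg, ref) {
  oc <- overlap_counts(seg, ref)
  if (oc$n_ref == 0) stop("sensitivity undefined: empty reference")
  oc$tp / (oc$tp + oc$fn)
}

#' Positive predictive value (precision) against a reference mask
#'
#' TP / (TP + FP): the fraction of the segmentation that is reference.
#'
#' @inheritParams overlap_counts
#' @return Value in \[0, 1\].
#' @export
ppv <- function(seg, ref) {
  oc <- overlap_counts(seg, ref)
  if (oc$n_seg == 0) stop("PPV undefined: empty segmentation")
  oc$tp / (oc$tp + oc$fp)
}

#' Combined PPV/SE score
#'
#' The arithmetic mean of sensitivity and positive predictive value.
#'
#' @inheritParams overlap_counts
#' @return Value in \[0, 1\].
#' @export
ppv_se <- function(seg, ref) {
  (sensitivity(seg, ref) + ppv(seg, ref)) / 2
}

#' Majority-vote consensus mask
#'
#' A voxel belongs to the consensus iff strictly more than half of the
#' input segmentations include it (3 masks need >= 2 votes, 6 masks >= 4;
#' even-split ties are excluded).
#'
#' @param masks List of >= 2 [binary_mask]s sharing geometry.
#' @return A [binary_mask]; always contains the intersection of the
#'   inputs and is contained in their union.
#' @export
majority_vote <- function(masks) {
  if (length(masks) < 2) stop("need at least 2 masks")
  for (m in masks[-1]) stop_if_geometry_mismatch(masks[[1]], m)
  votes <- Reduce(`+`, lapply(masks, function(m) m$values * 1L))
  binary_mask(votes > length(masks) / 2, masks[[1]]$spacing)
}

#' SUV and volume features of a VOI
#'
#' SUVmax and SUVmean of the in-mask voxels, metabolically active tumor
#' volume (MATV, mL), and total lesion glycolysis TLG = MATV x SUVmean.
#'
#' @param image A [suv_image] in SUV.
#' @param mask Non-empty [binary_mask] sharing geometry.
#' @return A `feature_set` list with `suv_max`, `suv_mean`, `matv_ml`,
#'   `tlg`.
#' @export
extract_features <- function(image, mask) {
  stop_if_geometry_mismatch(image, mask)
  if (!any(mask$values)) stop("cannot extract features from an empty mask")
  v <- image$values[mask$values]
  matv <- mask_volume_ml(mask)
  structure(list(suv_max = max(v), suv_mean = mean(v), matv_ml = matv,
                 tlg = matv * mean(v)),
            class = "feature_set")
}

#' Percentage difference against a reference value
#'
#' 100 (reference - observed) / reference.  The sign convention makes an
#' observed value far above the reference strongly negative (an observed
#' SUVmax 3.925x the reference scores -292.5%), matching how
#' reference-based feature differences are reported.
#'
#' @param observed,reference Scalars; `reference` non-zero.
#' @return Percentage difference.
#' @export
percent_diff <- function(observed, reference) {
  if (reference == 0) stop("percentage difference undefined for zero reference")
  100 * (reference - observed) / reference
}

#' Symmetric percentage volume difference of an observer pair
#'
#' 100 |v1 - v2| / mean(v1, v2); symmetric because observer pairs have no
#' natural ordering.
#'
#' @param v1,v2 Positive volumes.
#' @return Percentage difference, >= 0.
#' @export
pairwise_percent_matv_diff <- function(v1, v2) {
  if (v1 <= 0 || v2 <= 0) stop("volumes must be positive")
  100 * abs(v1 - v2) / mean(c(v1, v2))
}

#' Long-format metrics table for a set of segmentation records
#'
#' Per lesion x strategy this emits (i) every observer pair's Jaccard and
#' symmetric percentage MATV difference, and (ii) against the per-strategy
#' majority-vote reference (built from the experienced observers only or
#' from all observers), every observer's PPV, SE, combined PPV/SE, and
#' reference-based percentage differences of MATV, SUVmax, SUVmean and
#' TLG.  SUVmax is taken inside the delivered mask, which is what makes
#' annexed-confounder outliers visible.
#'
#' @param records List of `segmentation_record`s (from [run_study]).
#' @param suite The list of `phantom_case`s the records refer to.
#' @param observers The observer panel (for experience labels).
#' @param mv_policy `"EXPERIENCED_ONLY"` or `"ALL"`.
#' @return A data.frame with columns `lesion`, `strategy`, `kind`
#'   (`"pairwise"` or `"vs_mv"`), `obs_a`, `obs_b`, `metric`, `value`.
#' @export
build_metrics_table <- function(records, suite, observers,
                                mv_policy = c("EXPERIENCED_ONLY", "ALL")) {
  mv_policy <- match.arg(mv_policy)
  cases <- setNames(suite, vapply(suite, `[[`, "", "lesion_id"))
  exp_ids <- names(observers)[vapply(observers, function(o)
    o$experience == "EXPERIENCED", TRUE)]
  keys <- vapply(records, function(r) paste(r$lesion_id, r$strategy, sep = "\r"), "")
  rows <- list()
  add <- function(lesion, strategy, kind, a, b, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      lesion = lesion, strategy = strategy, kind = kind,
      obs_a = a, obs_b = b, metric = metric, value = value,
      stringsAsFactors = FALSE)

  for (key in unique(keys)) {
    grp <- records[keys == key]
    lesion <- grp[[1]]$lesion_id
    strategy <- grp[[1]]$strategy
    ids <- vapply(grp, `[[`, "", "observer_id")
    if (length(unique(ids)) < 2)
      stop("need >= 2 observers per lesion x strategy")
    masks <- setNames(lapply(grp, `[[`, "mask"), ids)
    vols <- vapply(masks, mask_volume_ml, 0)

    for (pair in combn(ids, 2, simplify = FALSE)) {
      add(lesion, strategy, "pairwise", pair[1], pair[2], "jaccard",
          jaccard(masks[[pair[1]]], masks[[pair[2]]]))
      add(lesion, strategy, "pairwise", pair[1], pair[2], "pct_matv",
          pairwise_percent_matv_diff(vols[pair[1]], vols[pair[2]]))
    }

    mv_ids <- if (mv_policy == "EXPERIENCED_ONLY")
      intersect(ids, exp_ids) else ids
    if (length(mv_ids) < 2)
      stop("majority vote needs >= 2 observers under policy ", mv_policy)
    mv <- majority_vote(masks[mv_ids])
    if (!any(mv$values)) next  # degenerate consensus: no reference rows
    img <- cases[[lesion]]$image
    mv_feat <- extract_features(img, mv)
    for (id in ids) {
      add(lesion, strategy, "vs_mv", id, "MV", "ppv", ppv(masks[[id]], mv))
      add(lesion, strategy, "vs_mv", id, "MV", "se",
          sensitivity(masks[[id]], mv))
      add(lesion, strategy, "vs_mv", id, "MV", "ppv_se",
          ppv_se(masks[[id]], mv))
      feat <- extract_features(img, masks[[id]])
      add(lesion, strategy, "vs_mv", id, "MV", "pct_matv",
          percent_diff(feat$matv_ml, mv_feat$matv_ml))
      add(lesion, strategy, "vs_mv", id, "MV", "pct_suv_max",
          percent_diff(feat$suv_max, mv_feat$suv_max))
      add(lesion, strategy, "vs_mv", id, "MV", "pct_suv_mean",
          percent_diff(feat$suv_mean, mv_feat$suv_mean))
      add(lesion, strategy, "vs_mv", id, "MV", "pct_tlg",
          percent_diff(feat$tlg, mv_feat$tlg))
    }
  }
  do.call(rbind, rows)
}
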