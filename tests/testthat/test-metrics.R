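mask_from_idx <- function(idx, dim3 = c(3, 3, 3), spacing = c(1, 1, 1)) {
  a <- array(FALSE, dim3); a[idx] <- TRUE
  binary_mask(a, spacing)
}

test_that("overlap counts tally TP/FP/FN voxelwise", {
  seg <- mask_from_idx(1:3); ref <- mask_from_idx(1:3)
  oc <- overlap_counts(seg, ref)
  expect_equal(c(oc$tp, oc$fp, oc$fn), c(3, 0, 0))

  oc2 <- overlap_counts(mask_from_idx(c(1, 2)), mask_from_idx(c(2, 3)))
  expect_equal(c(oc2$tp, oc2$fp, oc2$fn), c(1, 1, 1))

  oc3 <- overlap_counts(mask_from_idx(integer(0)), mask_from_idx(1:4))
  expect_equal(c(oc3$tp, oc3$fp, oc3$fn), c(0, 0, 4))
  expect_error(overlap_counts(seg, mask_from_idx(1, dim3 = c(2, 2, 2))),
               "geometry|grid")
})

test_that("Jaccard handles identity, disjointness and the worked 2/4 case", {
  expect_equal(jaccard(mask_from_idx(c(2, 5)), mask_from_idx(c(2, 5))), 1)
  expect_equal(jaccard(mask_from_idx(1:2), mask_from_idx(3:4)), 0)
  expect_equal(jaccard(mask_from_idx(1:3), mask_from_idx(2:4)), 0.5)
  expect_error(jaccard(mask_from_idx(integer(0)), mask_from_idx(integer(0))),
               "empty")
})

test_that("sensitivity, PPV and their mean follow the TP/FP/FN forms", {
  seg <- mask_from_idx(c(1, 2)); ref <- mask_from_idx(c(2, 3))
  expect_equal(sensitivity(seg, ref), 0.5)
  expect_equal(ppv(seg, ref), 0.5)
  expect_equal(ppv_se(seg, ref), 0.5)

  expect_equal(ppv_se(mask_from_idx(1:4), mask_from_idx(1:4)), 1)

  big <- mask_from_idx(1:8); small <- mask_from_idx(1:4)  # seg = 2x ref
  expect_equal(sensitivity(big, small), 1)
  expect_equal(ppv(big, small), 0.5)
  expect_equal(ppv_se(big, small), 0.75)
  expect_error(sensitivity(seg, mask_from_idx(integer(0))), "empty")
  expect_error(ppv(mask_from_idx(integer(0)), ref), "empty")
})

test_that("overlap metrics equal brute-force set computations on random masks", {
  set.seed(17)
  for (i in 1:200) {
    s <- rand_mask(c(3, 4, 2), p = runif(1, 0.2, 0.8), nonempty = TRUE)
    r <- binary_mask(rand_mask_array(c(3, 4, 2), runif(1, 0.2, 0.8)) |
                       (runif(24) < 0.1), s$spacing)
    if (!any(r$values)) r$values[1] <- TRUE
    bf <- bf_overlap(s$values, r$values)
    oc <- overlap_counts(s, r)
    expect_equal(c(oc$tp, oc$fp, oc$fn), c(bf$tp, bf$fp, bf$fn))
    expect_equal(jaccard(s, r), bf_jaccard(s$values, r$values))
    expect_equal(sensitivity(s, r), bf$tp / (bf$tp + bf$fn))
    expect_equal(ppv(s, r), bf$tp / (bf$tp + bf$fp))
    # Jaccard is bounded by both asymmetric agreement measures
    expect_lte(jaccard(s, r), min(sensitivity(s, r), ppv(s, r)) + 1e-12)
  }
})

test_that("majority vote needs a strict majority and respects vote bounds", {
  mv <- majority_vote(list(mask_from_idx(c(1, 2)), mask_from_idx(c(2, 3)),
                           mask_from_idx(2)))
  expect_equal(which(mv$values), 2)

  same <- mask_from_idx(c(4, 7))
  expect_identical(majority_vote(list(same, same, same))$values, same$values)

  set.seed(19)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    masks <- lapply(1:n, function(j) rand_mask(c(3, 3, 3), p = 0.5))
    mv <- majority_vote(masks)$values
    expect_identical(mv, bf_majority_vote(lapply(masks, `[[`, "values")))
    inter <- Reduce(`&`, lapply(masks, `[[`, "values"))
    uni <- Reduce(`|`, lapply(masks, `[[`, "values"))
    expect_true(all(mv[inter]) && !any(mv & !uni))
    perm <- sample(n)
    expect_identical(majority_vote(masks[perm])$values, mv)
  }

  # an even panel: exactly half the votes is excluded
  a <- mask_from_idx(1); b <- mask_from_idx(2)
  expect_equal(sum(majority_vote(list(a, a, b, b))$values), 0)
})

test_that("feature extraction reports SUVmax, SUVmean, MATV and the TLG identity", {
  a <- array(5, c(5, 5, 4))
  img <- suv_image(a, c(5, 5, 5))  # 100 voxels of 0.125 mL
  mask <- binary_mask(array(TRUE, dim(a)), c(5, 5, 5))
  f <- extract_features(img, mask)
  expect_equal(f$suv_max, 5)
  expect_equal(f$suv_mean, 5)
  expect_equal(f$tlg, f$matv_ml * 5)

  two <- suv_image(array(c(10, 2), c(2, 1, 1)), c(10, 10, 10))
  f2 <- extract_features(two, binary_mask(array(TRUE, c(2, 1, 1)), c(10, 10, 10)))
  expect_equal(f2$suv_max, 10)
  expect_equal(f2$suv_mean, 6)

  set.seed(23)
  for (i in 1:20) {
    img <- suv_image(array(rexp(27, 1 / 3), c(3, 3, 3)), runif(3, 1, 5))
    m <- rand_mask(c(3, 3, 3), img$spacing, nonempty = TRUE)
    m$spacing <- img$spacing
    f <- extract_features(img, m)
    expect_equal(f$tlg, mask_volume_ml(m) * mean(img$values[m$values]))
    expect_lte(f$suv_mean, f$suv_max)
  }
})

test_that("percentage differences follow the reference-based and symmetric conventions", {
  expect_equal(percent_diff(50, 50), 0)
  expect_equal(percent_diff(3.925 * 8, 8), -292.5)
  expect_equal(percent_diff(0.8 * 8, 8), 20)
  expect_error(percent_diff(1, 0), "zero")

  expect_equal(pairwise_percent_matv_diff(120, 120), 0)
  expect_equal(pairwise_percent_matv_diff(150, 100), 40)
  set.seed(29)
  for (i in 1:20) {
    v <- runif(2, 1, 500)
    expect_equal(pairwise_percent_matv_diff(v[1], v[2]),
                 pairwise_percent_matv_diff(v[2], v[1]))
  }
  expect_error(pairwise_percent_matv_diff(0, 5), "positive")
})

test_that("the metrics table emits all pairwise and vs-MV rows", {
  cs <- make_test_case(seed = 12, id = "lesX")
  obs <- default_observer_panel()  # o1-o3 experienced
  recs <- run_study(list(cs), obs, seed = 21,
                    strategies = c("THRESHOLD", "GRADIENT"))
  tab <- build_metrics_table(recs, list(cs), obs, "EXPERIENCED_ONLY")

  for (strat in c("THRESHOLD", "GRADIENT")) {
    pw <- tab[tab$strategy == strat & tab$kind == "pairwise" &
                tab$metric == "jaccard", ]
    expect_equal(nrow(pw), choose(6, 2))
    vm <- tab[tab$strategy == strat & tab$kind == "vs_mv", ]
    expect_equal(nrow(vm), 6 * 7)  # 7 metrics per observer
  }
  expect_true(all(tab$value[tab$metric == "jaccard"] >= 0 &
                  tab$value[tab$metric == "jaccard"] <= 1))
  expect_false(any(duplicated(
    tab[, c("lesion", "strategy", "kind", "obs_a", "obs_b", "metric")])))

  # an observer identical to the MV scores perfectly
  masks <- lapply(Filter(function(r) r$strategy == "THRESHOLD" &&
                           r$observer_id %in% c("o1", "o2", "o3"), recs),
                  `[[`, "mask")
  mv <- majority_vote(masks)
  expect_equal(ppv_se(mv, mv), 1)
  expect_equal(percent_diff(mask_volume_ml(mv), mask_volume_ml(mv)), 0)
})
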