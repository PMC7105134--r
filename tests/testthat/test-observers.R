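noise_free <- function(id, experience = "EXPERIENCED")
  observer_profile(id, experience, threshold_bias_pct = 0, sd_manual = 0,
                   sd_threshold = 0, sd_gradient = 0, manual_edit_rate = 0,
                   select_accuracy_p = 1)

test_that("noise-free observers agree perfectly and manual reduces to interactive", {
  cs <- make_test_case(seed = 2)
  o1 <- noise_free("a"); o2 <- noise_free("b")
  set.seed(1); r1 <- simulate_interactive(o1, cs, "THRESHOLD")
  set.seed(2); r2 <- simulate_interactive(o2, cs, "THRESHOLD")
  expect_identical(r1$mask$values, r2$mask$values)
  expect_equal(jaccard(r1$mask, r2$mask), 1)

  set.seed(3); rm <- simulate_manual(o1, cs)
  expect_identical(rm$mask$values, r1$mask$values)
  set.seed(4); rg <- simulate_interactive(o1, cs, "GRADIENT")
  expect_identical(rg$mask$values, r1$mask$values)
})

test_that("interactive choices are reproducible under a fixed seed", {
  cs <- make_test_case(seed = 5)
  prof <- default_observer_panel()$o4a
  set.seed(99); ra <- simulate_interactive(prof, cs, "THRESHOLD")
  set.seed(99); rb <- simulate_interactive(prof, cs, "THRESHOLD")
  expect_identical(ra$provenance$chosen_pct, rb$provenance$chosen_pct)
  expect_identical(ra$mask$values, rb$mask$values)
})

test_that("the overlap-optimal threshold recovers a noiseless sphere", {
  cs <- make_test_case(seed = 8, noise = 0, texture = 0)
  o <- noise_free("a")
  set.seed(1); r <- simulate_interactive(o, cs, "THRESHOLD")
  expect_gt(jaccard(r$mask, cs$ground_truth), 0.9)
})

test_that("manual edits only touch the boundary shell, at the expected rate", {
  cs <- make_test_case(seed = 6)
  prof <- observer_profile("e", "NOVICE", threshold_bias_pct = 0,
                           sd_manual = 0, sd_threshold = 0, sd_gradient = 0,
                           manual_edit_rate = 0.2, select_accuracy_p = 1)
  base <- observer_profile("e0", "NOVICE", threshold_bias_pct = 0,
                           sd_manual = 0, sd_threshold = 0, sd_gradient = 0,
                           manual_edit_rate = 0, select_accuracy_p = 1)
  set.seed(1); pre <- simulate_manual(base, cs)
  pitch <- max(cs$image$spacing)
  shell <- dilate_mask(pre$mask, pitch)$values &
    !erode_mask(pre$mask, pitch)$values & cs$rough_mask$values
  interior <- pre$mask$values & !shell

  total_toggled <- 0; n_draws <- 40
  for (s in 1:n_draws) {
    set.seed(s)
    post <- simulate_manual(prof, cs)
    expect_identical(post$mask$values[interior], pre$mask$values[interior])
    expect_true(!any(post$mask$values & !cs$rough_mask$values))
    total_toggled <- total_toggled + post$provenance$n_toggled
  }
  n_shell <- sum(shell)
  expected <- n_draws * n_shell * 0.2
  sd3 <- 3 * sqrt(n_draws * n_shell * 0.2 * 0.8)
  expect_lt(abs(total_toggled - expected), sd3)
})

test_that("select-the-best picks the overlap-optimal member when accurate", {
  cs <- make_test_case(seed = 4)
  pan <- run_auto_panel(cs$image, cs$rough_mask)
  jcs <- vapply(pan, function(r) jaccard(r$mask, cs$ground_truth), 0)
  prof <- noise_free("a")
  set.seed(1)
  r <- simulate_select_best(prof, cs, panel = pan)
  expect_identical(r$provenance$chosen_label, names(which.max(jcs)))
  set.seed(77); c1 <- simulate_select_best(prof, cs, panel = pan)
  set.seed(77); c2 <- simulate_select_best(prof, cs, panel = pan)
  expect_identical(c1$provenance$chosen_label, c2$provenance$chosen_label)
})

test_that("select accuracy 0.25 makes the four labels asymptotically uniform", {
  cs <- make_test_case(seed = 4)
  pan <- run_auto_panel(cs$image, cs$rough_mask)
  prof <- observer_profile("u", select_accuracy_p = 0.25)
  set.seed(123)
  picks <- vapply(1:1200, function(i)
    simulate_select_best(prof, cs, panel = pan)$provenance$chosen_label, "")
  tab <- table(factor(picks, levels = names(pan)))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("the factorial study is complete, cell-reproducible and rough-mask-bounded", {
  suite <- list(make_test_case(seed = 1, id = "lesA"),
                make_test_case(seed = 2, id = "lesB"))
  panel <- default_observer_panel()
  recs <- run_study(suite, panel, seed = 11)
  expect_length(recs, 2 * 6 * 4)

  # re-running one cell in isolation reproduces that record
  target <- recs[[which(vapply(recs, function(r)
    r$lesion_id == "lesB" && r$observer_id == "o4b" &&
      r$strategy == "MANUAL", TRUE))[1]]]
  set.seed(petseg:::cell_seed(11, "lesB", "o4b", "MANUAL"))
  redo <- simulate_manual(panel$o4b, suite[[2]])
  expect_identical(redo$mask$values, target$mask$values)

  for (r in recs) {
    rough <- suite[[match(r$lesion_id, c("lesA", "lesB"))]]$rough_mask
    annexed <- isTRUE(r$provenance$annexed_confounder)
    if (!annexed) expect_true(!any(r$mask$values & !rough$values))
  }
})

test_that("noise-free panels agree across observers within every strategy", {
  suite <- list(make_test_case(seed = 3, id = "lesC"))
  panel <- list(noise_free("a"), noise_free("b"), noise_free("c"))
  names(panel) <- c("a", "b", "c")
  recs <- run_study(suite, panel, seed = 5)
  for (strat in c("MANUAL", "THRESHOLD", "GRADIENT", "SELECT_BEST")) {
    masks <- lapply(Filter(function(r) r$strategy == strat, recs), `[[`, "mask")
    for (m in masks[-1]) expect_equal(jaccard(masks[[1]], m), 1)
  }
})
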