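flat_image <- function(vals, spacing = c(4, 4, 4)) {
  n <- length(vals)
  a <- array(0, c(n, 1, 1))
  a[, 1, 1] <- vals
  suv_image(a, spacing)
}
full_mask <- function(image) binary_mask(array(TRUE, dim(image$values)),
                                         image$spacing)

test_that("percent-of-maximum threshold keeps voxels strictly above pct of in-mask max", {
  img <- flat_image(c(10, 5, 4, 2))
  rough <- full_mask(img)
  r <- threshold_pct_max(img, rough, 41)
  expect_equal(r$threshold_suv, 4.1)
  expect_equal(sum(r$mask$values), 2)
  expect_true(all(img$values[r$mask$values] %in% c(10, 5)))

  expect_equal(sum(threshold_pct_max(img, rough, 100)$mask$values), 0)
  expect_equal(sum(threshold_pct_max(img, rough, 0)$mask$values), 4)
  expect_error(threshold_pct_max(img, rough, 101), "0, 100")
  empty <- binary_mask(array(FALSE, dim(img$values)), img$spacing)
  expect_error(threshold_pct_max(img, empty, 41), "empty")
})

test_that("fixed-SUV threshold excludes the cut value itself", {
  img <- flat_image(c(10, 5, 4, 2))
  rough <- full_mask(img)
  expect_equal(sum(threshold_fixed(img, rough, 4)$mask$values), 2)
  expect_equal(sum(threshold_fixed(img, rough, 0)$mask$values), 4)
  expect_equal(sum(threshold_fixed(img, rough, 11)$mask$values), 0)
})

test_that("threshold masks nest with the cut value", {
  set.seed(7)
  img <- suv_image(array(rexp(512, 1 / 4), c(8, 8, 8)), c(4, 4, 4))
  rough <- binary_mask(rand_mask_array(c(8, 8, 8), 0.7), c(4, 4, 4))
  cuts <- sort(runif(6, 0, 12))
  masks <- lapply(cuts, function(ct) threshold_fixed(img, rough, ct)$mask$values)
  for (i in seq_len(length(cuts) - 1))
    expect_true(all(masks[[i]][masks[[i + 1]]])) # higher cut is a subset

  vols <- vapply(seq(0, 100, by = 10), function(p)
    sum(threshold_pct_max(img, rough, p)$mask$values), 0)
  expect_true(all(diff(vols) <= 0))
  for (m in masks) expect_true(!any(m & !rough$values))
})

test_that("SUVpeak is the spacing-aware 1 mL neighbourhood mean", {
  u <- suv_image(array(7, c(6, 6, 6)), c(4, 4, 4))
  expect_equal(suv_peak(u, full_mask(u))$value, 7)

  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 19
  img <- suv_image(a, c(4, 4, 4))
  pk <- suv_peak(img, full_mask(img))
  expect_equal(pk$n_kernel, 19)   # 1 + 6 at 4 mm + 12 at sqrt(32) mm
  expect_equal(pk$value, 1)       # 19 / 19
  # every neighbourhood containing the hot voxel ties at 1; the reported
  # centre must be one of them
  expect_lte(sqrt(sum(((pk$center - c(5, 5, 5)) * 4)^2)), 6)
})

test_that("SUVpeak never exceeds SUVmax and matches the brute-force kernel mean", {
  set.seed(13)
  for (i in 1:6) {
    sp <- list(c(4, 4, 4), c(3.1819, 3.1819, 2), c(2, 3, 5))[[(i %% 3) + 1]]
    vals <- array(rexp(216, 1 / 5), c(6, 6, 6))
    img <- suv_image(vals, sp)
    mask <- rand_mask(c(6, 6, 6), sp, p = 0.5, nonempty = TRUE)
    got <- suv_peak(img, mask)$value
    expect_lte(got, max(vals[mask$values]) + 1e-12)
    expect_equal(got, bf_suv_peak(vals, sp, mask$values), tolerance = 1e-12)
  }
})

test_that("AUTO converges to the contrast-adapted fixed point on two-level phantoms", {
  # uniform SUV-10 cube on SUV-2 background: T = 2 + 0.5 (10 - 2) = 6
  a <- array(2, c(24, 24, 24))
  a[8:17, 8:17, 8:17] <- 10
  img <- suv_image(a, c(4, 4, 4))
  tumor <- binary_mask(a > 2, c(4, 4, 4))
  rough <- dilate_mask(tumor, 8)
  r <- auto_segment(img, rough)
  expect_true(r$converged)
  expect_equal(r$suv_peak, 10)
  expect_equal(r$threshold_suv, 6, tolerance = 1e-3)
  expect_identical(r$mask$values, tumor$values)

  # zero background: T converges to half the peak
  b <- array(0, c(24, 24, 24)); b[8:17, 8:17, 8:17] <- 10
  img0 <- suv_image(b, c(4, 4, 4))
  r0 <- auto_segment(img0, dilate_mask(binary_mask(b > 0, c(4, 4, 4)), 8))
  expect_equal(r0$threshold_suv, 5, tolerance = 1e-3)

  # threshold bracketed by background and peak
  expect_true(r$background_suv <= r$threshold_suv &&
              r$threshold_suv <= r$suv_peak)
})

test_that("gradient magnitude is exact on constants and linear ramps, per mm", {
  flat <- suv_image(array(3, c(10, 10, 10)), c(4, 4, 4))
  expect_equal(max(abs(gradient_image(flat)$values)), 0)

  ramp_vals <- function(n, dx, slope) {
    x <- (seq_len(n) - 0.5) * dx
    array(rep(slope * x, times = n * n), c(n, n, n))
  }
  g4 <- gradient_image(suv_image(ramp_vals(12, 4, 2), c(4, 4, 4)))
  interior <- g4$values[5:8, 5:8, 5:8]
  expect_equal(max(abs(interior - 2)), 0, tolerance = 1e-10)

  g2 <- gradient_image(suv_image(ramp_vals(12, 2, 2), c(2, 2, 2)))
  expect_equal(g2$values[6, 6, 6], g4$values[6, 6, 6], tolerance = 1e-10)
})

test_that("the automatic panel is ordered, deterministic and internally nested", {
  cs <- make_test_case(seed = 3, noise = 0)
  pan <- run_auto_panel(cs$image, cs$rough_mask)
  expect_identical(names(pan), c("41MAX", "SUV4", "SUV2.5", "AUTO"))
  suv_max <- max(cs$image$values[cs$rough_mask$values])
  expect_equal(pan$`41MAX`$threshold_suv, 0.41 * suv_max)

  pan2 <- run_auto_panel(cs$image, cs$rough_mask)
  expect_identical(lapply(pan, `[[`, "mask"), lapply(pan2, `[[`, "mask"))

  # cut 4 < cut 0.41*10.x: the 41MAX mask nests inside SUV4 when SUVmax > 9.76
  if (pan$`41MAX`$threshold_suv > 4)
    expect_true(all(pan$SUV4$mask$values[pan$`41MAX`$mask$values]))
  for (r in pan)
    expect_true(!any(r$mask$values & !cs$rough_mask$values))
})

test_that("the 1 mL SUVpeak sphere has the conventional 1.2 cm diameter", {
  expect_equal(round(sphere_diameter_cm(1), 1), 1.2)
})
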