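# The delineation algorithms embedded in the four workflows: interactive
# percent-of-maximum thresholding, the fixed SUV 4 / SUV 2.5 cuts, the
# contrast-adapted method at 50% of SUVpeak with local background
# correction, and the gradient-magnitude image.  All masks are restricted
# to the inside of the rough pre-marking mask, and voxel inclusion is
# strictly greater-than the threshold throughout ("higher than" / "above"):
# ties are measure-zero on continuous data, and a 100% threshold is
# consequently empty.

new_threshold_result <- function(mask, threshold_suv, rule, pct = NULL,
                                 iterations = NULL, converged = NULL,
                                 background_suv = NULL, suv_peak = NULL) {
  structure(list(mask = mask, threshold_suv = threshold_suv, rule = rule,
                 pct = pct, iterations = iterations, converged = converged,
                 background_suv = background_suv, suv_peak = suv_peak),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> rule %s, threshold %.4g SUV, %d voxels (%.2f mL)\n",
              x$rule, x$threshold_suv, sum(x$mask$values),
              mask_volume_ml(x$mask)))
  if (!is.null(x$iterations))
    cat(sprintf("  converged: %s after %d iterations (background %.4g SUV)\n",
                x$converged, x$iterations, x$background_suv))
  invisible(x)
}

check_seg_inputs <- function(image, rough_mask, need_nonempty = TRUE) {
  if (!inherits(image, "suv_image")) stop("'image' must be a suv_image")
  if (!inherits(rough_mask, "binary_mask")) stop("'rough_mask' must be a binary_mask")
  stop_if_geometry_mismatch(image, rough_mask)
  if (need_nonempty && !any(rough_mask$values))
    stop("rough mask is empty")
  invisible(NULL)
}

#' Percent-of-maximum threshold segmentation
#'
#' Includes the voxels of the rough mask whose value is strictly above
#' `pct`% of the maximum value found inside the rough mask.
#'
#' @param image A [suv_image].
#' @param rough_mask Non-empty [binary_mask] restricting the search.
#' @param pct Percentage of the in-mask maximum, in \[0, 100\].
#' @return A `threshold_result` (fields `mask`, `threshold_suv`, `rule`,
#'   `pct`).
#' @export
threshold_pct_max <- function(image, rough_mask, pct) {
  check_seg_inputs(image, rough_mask)
  if (!is.numeric(pct) || length(pct) != 1L || pct < 0 || pct > 100)
    stop("'pct' must be in [0, 100]")
  suv_max <- max(image$values[rough_mask$values])
  thr <- pct / 100 * suv_max
  m <- binary_mask(rough_mask$values & image$values > thr, image$spacing)
  new_threshold_result(m, thr, "PCT_MAX", pct = pct)
}

#' Fixed-SUV threshold segmentation
#'
#' Includes the voxels of the rough mask with value strictly above
#' `suv_cut` (the conventional SUV 4 and SUV 2.5 cuts).
#'
#' @inheritParams threshold_pct_max
#' @param suv_cut Absolute threshold in SUV, >= 0.
#' @return A `threshold_result`.
#' @export
threshold_fixed <- function(image, rough_mask, suv_cut) {
  check_seg_inputs(image, rough_mask, need_nonempty = FALSE)
  if (!is.numeric(suv_cut) || length(suv_cut) != 1L || suv_cut < 0)
    stop("'suv_cut' must be >= 0")
  m <- binary_mask(rough_mask$values & image$values > suv_cut, image$spacing)
  new_threshold_result(m, suv_cut, "FIXED_SUV")
}

#' SUVpeak: highest mean over a 1 mL spherical neighbourhood
#'
#' For every voxel of the rough mask, averages the image over all voxels
#' whose centres lie within `radius_mm` (Euclidean, mm space) of that
#' voxel's centre — the 1 mL, 1.2 cm diameter spherical neighbourhood of
#' the EANM/UPICT definition — and returns the highest such mean together
#' with its centre voxel.  Sphere membership is spacing-aware; near the
#' grid boundary the neighbourhood is truncated to in-grid voxels.
#'
#' @inheritParams threshold_pct_max
#' @param radius_mm Neighbourhood radius in mm (default 6, i.e. the
#'   printed 1.2 cm diameter).
#' @return List with `value` (SUV), `center` (voxel index triple), and
#'   `n_kernel` (neighbourhood size away from boundaries).
#' @export
suv_peak <- function(image, rough_mask, radius_mm = 6) {
  check_seg_inputs(image, rough_mask)
  d <- dim(image$values)
  idx <- which(rough_mask$values)
  coords <- arrayInd(idx, d)
  offs <- ball_offsets(radius_mm, image$spacing)
  acc <- numeric(length(idx))
  cnt <- integer(length(idx))
  for (r in seq_len(nrow(offs))) {
    tg <- coords
    tg[, 1] <- tg[, 1] + offs[r, 1]
    tg[, 2] <- tg[, 2] + offs[r, 2]
    tg[, 3] <- tg[, 3] + offs[r, 3]
    lin <- coords_to_lin(tg, d)
    ok <- !is.na(lin)
    acc[ok] <- acc[ok] + image$values[lin[ok]]
    cnt[ok] <- cnt[ok] + 1L
  }
  means <- acc / cnt
  best <- which.max(means)
  list(value = means[best], center = as.integer(coords[best, ]),
       n_kernel = nrow(offs))
}

#' Parameters of the contrast-adapted (AUTO) segmentation
#'
#' @param peak_fraction Fraction of SUVpeak in the adaptive threshold
#'   (default 0.50).
#' @param shell_inner_mm,shell_outer_mm Local background shell: voxels
#'   whose mm-distance from the current VOI lies in
#'   (`shell_inner_mm`, `shell_outer_mm`\].
#' @param max_iter Iteration cap of the fixed-point update.
#' @param tol_suv Convergence tolerance on the threshold, SUV.
#' @return An `auto_params` list.
#' @export
auto_params <- function(peak_fraction = 0.5, shell_inner_mm = 2,
                        shell_outer_mm = 10, max_iter = 100, tol_suv = 1e-3) {
  stopifnot(peak_fraction > 0, peak_fraction < 1,
            shell_inner_mm >= 0, shell_outer_mm > shell_inner_mm,
            max_iter >= 1, tol_suv > 0)
  structure(list(peak_fraction = peak_fraction,
                 shell_inner_mm = shell_inner_mm,
                 shell_outer_mm = shell_outer_mm,
                 max_iter = max_iter, tol_suv = tol_suv),
            class = "auto_params")
}

#' Contrast-adapted threshold segmentation (AUTO)
#'
#' Includes voxels above 50% of SUVpeak with local background correction.
#' The threshold is the fixed point of T = B + f (P - B), where P is
#' SUVpeak inside the rough mask, f the peak fraction, and B the mean
#' image value over a shell of voxels at mm-distance in
#' (`shell_inner_mm`, `shell_outer_mm`\] from the current VOI.  Iteration
#' starts at T = f P and stops when the threshold moves less than
#' `tol_suv` (or the VOI repeats exactly, which pins the fixed point).
#'
#' @inheritParams threshold_pct_max
#' @param params An [auto_params].
#' @return A `threshold_result` with `iterations`, `converged`,
#'   `background_suv` and `suv_peak` filled in.
#' @export
auto_segment <- function(image, rough_mask, params = auto_params()) {
  check_seg_inputs(image, rough_mask)
  if (!inherits(params, "auto_params")) stop("'params' must be auto_params")
  v <- image$values
  sp <- image$spacing
  peak <- suv_peak(image, rough_mask)$value
  f <- params$peak_fraction
  offs_out <- ball_offsets(params$shell_outer_mm, sp)
  offs_in <- if (params$shell_inner_mm > 0)
    ball_offsets(params$shell_inner_mm, sp) else NULL

  thr <- f * peak
  bg <- 0
  converged <- FALSE
  iter <- 0L
  prev_voi <- NULL
  while (iter < params$max_iter) {
    iter <- iter + 1L
    voi <- rough_mask$values & v > thr
    if (any(voi)) {
      reach_out <- shift_or(voi, offs_out)
      reach_in <- if (is.null(offs_in)) voi else shift_or(voi, offs_in)
      shell <- reach_out & !reach_in & !voi
      if (any(shell)) {
        bg <- mean(v[shell])
      } else {
        warning("empty background shell; using B = 0")
        bg <- 0
      }
    } else {
      bg <- 0
    }
    thr_new <- bg + f * (peak - bg)
    same_voi <- !is.null(prev_voi) && identical(voi, prev_voi)
    if (abs(thr_new - thr) < params$tol_suv || same_voi) {
      thr <- thr_new
      converged <- TRUE
      break
    }
    thr <- thr_new
    prev_voi <- voi
  }
  if (!converged)
    warning("AUTO threshold did not converge within max_iter; returning last iterate")
  m <- binary_mask(rough_mask$values & v > thr, sp)
  new_threshold_result(m, thr, "AUTO", iterations = iter,
                       converged = converged, background_suv = bg,
                       suv_peak = peak)
}

#' Gradient-magnitude image
#'
#' Per-voxel magnitude of the 3-D spatial intensity gradient in SUV/mm,
#' computed with spacing-aware Gaussian-derivative filters (sigma of one
#' voxel pitch per axis, in mm).  The result emphasises the boundaries of
#' high-uptake regions independently of any display window.
#'
#' @param image A [suv_image].
#' @param sigma_vox Derivative-of-Gaussian scale in voxels per axis.
#' @return A [suv_image] holding the gradient magnitude (SUV/mm).
#' @export
gradient_image <- function(image, sigma_vox = 1) {
  if (!inherits(image, "suv_image")) stop("'image' must be a suv_image")
  sp <- image$spacing
  smooth_k <- gaussian_kernel_1d(sigma_vox)
  total <- array(0, dim(image$values))
  for (axis in 1:3) {
    g <- conv_axis(image$values,
                   gaussian_deriv_kernel_1d(sigma_vox, sp[axis]), axis)
    for (other in setdiff(1:3, axis))
      g <- conv_axis(g, smooth_k, other)
    total <- total + g^2
  }
  suv_image(sqrt(total), sp, unit = "SUV")
}

#' The four-algorithm automatic panel
#'
#' Runs, in a fixed order, the four established threshold-based
#' segmentations offered by the select-the-best workflow: 41% of SUVmax
#' (`41MAX`), fixed SUV 4 (`SUV4`), fixed SUV 2.5 (`SUV2.5`), and the
#' contrast-adapted method (`AUTO`).
#'
#' @inheritParams threshold_pct_max
#' @param params [auto_params] for the AUTO member.
#' @return Named list of four `threshold_result`s in the order
#'   `41MAX`, `SUV4`, `SUV2.5`, `AUTO`.
#' @export
run_auto_panel <- function(image, rough_mask, params = auto_params()) {
  list(`41MAX` = threshold_pct_max(image, rough_mask, 41),
       SUV4 = threshold_fixed(image, rough_mask, 4),
       `SUV2.5` = threshold_fixed(image, rough_mask, 2.5),
       AUTO = auto_segment(image, rough_mask, params))
}

#' Analytic diameter of a sphere of given volume
#'
#' Used to express the SUVpeak neighbourhood: a 1 mL sphere has diameter
#' (6 V / pi)^(1/3) ~ 12.4 mm, conventionally quoted as 1.2 cm.
#'
#' @param volume_ml Sphere volume in mL.
#' @return Diameter in cm.
#' @export
sphere_diameter_cm <- function(volume_ml = 1) {
  (6 * volume_ml * 1000 / pi)^(1 / 3) / 10
}
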