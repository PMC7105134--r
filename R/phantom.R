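# Synthetic FDG-PET phantoms with known ground truth.  The generator
# emulates EARL-like whole-body PET at summary level: a piecewise-constant
# uptake map (background near SUV 1, tumor components SUV 4-15, optional
# hot "organ" confounders), a multiplicative low-frequency heterogeneity
# texture inside the tumor, an isotropic Gaussian point-spread function
# (default 6.5 mm FWHM, matching post-reconstruction smoothing), and
# additive Gaussian noise in SUV units.  No projection-space simulation.

#' Phantom configuration
#'
#' @param shape Integer length-3 grid dimensions.
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @param background_suv Uniform background uptake (SUV).
#' @param tumor List of components, each `list(center=, radii=, uptake=)`
#'   with `center` in mm (voxel-centre coordinates, origin at the grid
#'   corner), `radii` one radius or three semi-axes in mm, and `uptake` in
#'   SUV (>= 0).  At least one component is required; the ground-truth mask
#'   is their union before blurring.
#' @param texture_amplitude Relative amplitude of the smooth multiplicative
#'   heterogeneity texture applied inside the tumor (0 = homogeneous).
#' @param texture_scale_mm Correlation length (Gaussian sigma, mm) of the
#'   texture field.
#' @param psf_fwhm_mm Full width at half maximum of the isotropic Gaussian
#'   point-spread function, mm (>= 0).
#' @param noise_sd_suv Standard deviation of additive Gaussian noise (SUV,
#'   >= 0), applied after blurring.
#' @param confounder Optional list of components (same form as `tumor`)
#'   modelling adjacent high-uptake organs (heart/kidney analogues); never
#'   part of the ground truth.
#' @param rough_mask_dilation_mm Dilation radius building the rough
#'   pre-marking mask from the ground truth.
#' @param rough_include_confounder If `FALSE` (default) confounder voxels
#'   are clipped out of the rough mask (the organ was close to, but not
#'   part of, the pre-marked region); if `TRUE` the rough mask may annex
#'   them, reproducing the adjacent-heart failure mode.
#' @param seed Integer seed making the case fully reproducible.
#' @param lesion_id Optional identifier.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(44L, 44L, 44L),
                           spacing = c(4, 4, 4),
                           background_suv = 1,
                           tumor = list(list(center = shape * spacing / 2,
                                             radii = 25, uptake = 8)),
                           texture_amplitude = 0.3,
                           texture_scale_mm = 15,
                           psf_fwhm_mm = 6.5,
                           noise_sd_suv = 0.08,
                           confounder = NULL,
                           rough_mask_dilation_mm = 10,
                           rough_include_confounder = FALSE,
                           seed = 1L,
                           lesion_id = NULL) {
  stopifnot(length(shape) == 3L, all(shape >= 1),
            length(spacing) == 3L, all(spacing > 0),
            background_suv >= 0, psf_fwhm_mm >= 0, noise_sd_suv >= 0,
            texture_amplitude >= 0, rough_mask_dilation_mm >= 0,
            length(tumor) >= 1L)
  for (comp in c(tumor, confounder)) {
    if (!all(c("center", "radii", "uptake") %in% names(comp)))
      stop("each component needs center, radii and uptake")
    if (comp$uptake < 0) stop("component uptake must be >= 0")
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 background_suv = background_suv, tumor = tumor,
                 texture_amplitude = texture_amplitude,
                 texture_scale_mm = texture_scale_mm,
                 psf_fwhm_mm = psf_fwhm_mm, noise_sd_suv = noise_sd_suv,
                 confounder = confounder,
                 rough_mask_dilation_mm = rough_mask_dilation_mm,
                 rough_include_confounder = rough_include_confounder,
                 seed = as.integer(seed), lesion_id = lesion_id),
            class = "phantom_config")
}

# Rasterise one ellipsoid component on the voxel-centre grid; errors if it
# pokes outside the physical grid extent.
rasterise_component <- function(comp, shape, spacing) {
  radii <- rep(as.numeric(comp$radii), length.out = 3)
  centre <- as.numeric(comp$center)
  extent <- shape * spacing
  if (any(centre - radii < 0) || any(centre + radii > extent))
    stop("component extends outside the grid (centre ",
         paste(signif(centre, 4), collapse = ", "), " mm, radii ",
         paste(signif(radii, 4), collapse = ", "), " mm)")
  ax <- lapply(1:3, function(k) {
    x <- (seq_len(shape[k]) - 0.5) * spacing[k]
    ((x - centre[k]) / radii[k])^2
  })
  outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+") <= 1
}

#' Generate one synthetic PET case
#'
#' Builds the uptake map, applies the intra-tumor heterogeneity texture,
#' convolves with the point-spread function (reflect boundary padding),
#' adds noise, and derives the ground-truth and rough pre-marking masks.
#' The ground truth is the pre-blur tumor support; the rough mask is its
#' spacing-aware dilation, optionally clipped to exclude confounder organs.
#'
#' @param config A [phantom_config].
#' @return A `phantom_case` with fields `image` ([suv_image], unit SUV),
#'   `ground_truth`, `rough_mask`, `confounder_mask` (or `NULL`),
#'   `lesion_id`, `config`, `seed`.
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) stop("'config' must be a phantom_config")
  shape <- config$shape; spacing <- config$spacing
  set.seed(config$seed)

  uptake <- array(config$background_suv, shape)
  truth <- array(FALSE, shape)
  for (comp in config$tumor) {
    m <- rasterise_component(comp, shape, spacing)
    uptake[m] <- pmax(uptake[m], comp$uptake)
    truth <- truth | m
  }
  conf <- NULL
  if (!is.null(config$confounder)) {
    conf <- array(FALSE, shape)
    for (comp in config$confounder) {
      m <- rasterise_component(comp, shape, spacing)
      uptake[m] <- pmax(uptake[m], comp$uptake)
      conf <- conf | m
    }
    if (any(conf & truth))
      stop("confounder overlaps the tumor ground truth")
  }

  if (config$texture_amplitude > 0 && any(truth)) {
    z <- array(rnorm(prod(shape)), shape)
    z <- gaussian_smooth(z, config$texture_scale_mm, spacing)
    z <- z / sd(z)
    tex <- pmax(1 + config$texture_amplitude * z, 0.1)
    uptake[truth] <- uptake[truth] * tex[truth]
  }

  img <- uptake
  if (config$psf_fwhm_mm > 0) {
    sigma_mm <- config$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
    img <- gaussian_smooth(img, sigma_mm, spacing)
  }
  if (config$noise_sd_suv > 0)
    img <- img + array(rnorm(prod(shape), 0, config$noise_sd_suv), shape)

  if (any(truth) && max(img[truth]) < config$background_suv)
    warning("point-spread blurring pushed the tumor below background level")

  truth_mask <- binary_mask(truth, spacing)
  rough <- dilate_mask(truth_mask, config$rough_mask_dilation_mm)
  conf_mask <- if (!is.null(conf)) binary_mask(conf, spacing) else NULL
  if (!is.null(conf) && !config$rough_include_confounder)
    rough <- binary_mask(rough$values & !conf, spacing)

  structure(list(image = suv_image(img, spacing, unit = "SUV"),
                 ground_truth = truth_mask,
                 rough_mask = rough,
                 confounder_mask = conf_mask,
                 lesion_id = config$lesion_id %||% "lesion01",
                 config = config, seed = config$seed),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s: grid %s @ %s mm, MATV %.1f mL%s\n",
              x$lesion_id, paste(dim(x$image$values), collapse = "x"),
              paste(signif(x$image$spacing, 5), collapse = "x"),
              mask_volume_ml(x$ground_truth),
              if (!is.null(x$confounder_mask)) ", confounder-adjacent" else ""))
  invisible(x)
}

#' Deterministic suite of synthetic lesions
#'
#' Mirrors the study design of twenty scans across four cancer types (five
#' each): lung-like mid-size spheres and bulky lymphoma-like two-lobe
#' lesions on the 4 x 4 x 4 mm grid (the latter with ground-truth MATV
#' above 300 mL), melanoma-like spheres and sarcoma-like elongated
#' ellipsoids on the 3.1819 x 3.1819 x 2 mm grid.  One melanoma-like case
#' sits next to a hot "heart" that the rough mask annexes, and one
#' lymphoma-like case next to a hot "kidney" excluded from the rough mask,
#' reproducing the two adjacent-organ failure modes.
#'
#' @param n_lesions Number of cases (>= 1); archetypes cycle.
#' @param seed Integer master seed; per-case seeds are derived from it so
#'   the suite is reproducible case by case.
#' @return List of `phantom_case` objects.
#' @export
make_scenario_suite <- function(n_lesions = 20, seed = 1L) {
  if (n_lesions < 1) stop("'n_lesions' must be >= 1")
  types <- c("lung", "lymphoma", "melanoma", "sarcoma")
  lapply(seq_len(n_lesions), function(i) {
    type <- types[(i - 1L) %% 4L + 1L]
    case_seed <- cell_seed(seed, "suite", i)
    set.seed(case_seed)
    cfg <- switch(type,
      lung = {
        shape <- c(44L, 44L, 44L); spacing <- c(4, 4, 4)
        ctr <- shape * spacing / 2
        phantom_config(shape, spacing,
          tumor = list(list(center = ctr, radii = runif(1, 18, 30),
                            uptake = runif(1, 6, 12))),
          texture_amplitude = 0.25, seed = case_seed)
      },
      lymphoma = {
        shape <- c(48L, 48L, 48L); spacing <- c(4, 4, 4)
        ctr <- shape * spacing / 2
        r_main <- runif(1, 42, 46)
        tumor <- list(
          list(center = ctr, radii = r_main, uptake = runif(1, 5, 9)),
          list(center = ctr + c(0.5, 0.3, -0.4) * r_main,
               radii = r_main * c(0.55, 0.5, 0.6), uptake = runif(1, 5, 9)))
        conf <- NULL
        if (i == 6L)  # kidney analogue, close to but outside the rough mask
          conf <- list(list(center = ctr + c(r_main + 20, 0, 0), radii = 13,
                            uptake = runif(1, 8, 12)))
        phantom_config(shape, spacing, tumor = tumor, confounder = conf,
          rough_include_confounder = FALSE,
          texture_amplitude = 0.35, seed = case_seed)
      },
      melanoma = {
        shape <- c(48L, 48L, 72L); spacing <- c(3.1819, 3.1819, 2)
        ctr <- shape * spacing / 2
        r <- runif(1, 14, 22)
        conf <- NULL; incl <- FALSE
        if (i == 3L) {  # heart analogue partially inside the rough mask
          conf <- list(list(center = ctr + c(r + 22, 0, 0), radii = 15,
                            uptake = runif(1, 7, 10)))
          incl <- TRUE
        }
        phantom_config(shape, spacing,
          tumor = list(list(center = ctr, radii = r,
                            uptake = runif(1, 8, 15))),
          confounder = conf, rough_include_confounder = incl,
          texture_amplitude = 0.3, seed = case_seed)
      },
      sarcoma = {
        shape <- c(48L, 48L, 72L); spacing <- c(3.1819, 3.1819, 2)
        ctr <- shape * spacing / 2
        phantom_config(shape, spacing,
          tumor = list(list(center = ctr,
                            radii = c(runif(1, 12, 18), runif(1, 12, 18),
                                      runif(1, 28, 40)),
                            uptake = runif(1, 4, 10))),
          texture_amplitude = 0.3, seed = case_seed)
      })
    cfg$lesion_id <- sprintf("lesion%02d_%s", i, type)
    generate_phantom(cfg)
  })
}
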