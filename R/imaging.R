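# Geometry-aware volume containers, NIfTI I/O, SUV conversion and basic
# VOI arithmetic.  All physical computation elsewhere in the package works
# in mm space derived from the voxel spacing, because the study mixes two
# anisotropic reconstruction grids (4 x 4 x 4 mm and 3.1819 x 3.1819 x 2 mm).

#' Construct a PET volume with voxel spacing and a unit tag
#'
#' A `suv_image` is a 3-D numeric array plus its voxel spacing in mm and a
#' unit tag, either activity concentration (`"BQ_PER_ML"`) as reconstructed,
#' or body-weight-normalised standardized uptake values (`"SUV"`).
#'
#' @param values 3-D numeric array of voxel values; all finite.
#' @param spacing Numeric length-3, voxel edge lengths (dx, dy, dz) in mm;
#'   strictly positive.
#' @param unit `"SUV"` or `"BQ_PER_ML"`.
#' @return An object of class `suv_image` with fields `values`, `spacing`,
#'   `unit`.
#' @export
suv_image <- function(values, spacing, unit = c("SUV", "BQ_PER_ML")) {
  unit <- match.arg(unit)
  values <- as.array(values)
  if (length(dim(values)) != 3L || length(values) == 0L)
    stop("'values' must be a non-empty 3-D array")
  if (!all(is.finite(values)))
    stop("all voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive voxel edge lengths in mm")
  structure(list(values = values, spacing = spacing, unit = unit),
            class = "suv_image")
}

#' Construct a binary volume-of-interest mask
#'
#' @param values 3-D logical (or 0/1 numeric) array.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return An object of class `binary_mask` with fields `values`, `spacing`.
#' @export
binary_mask <- function(values, spacing) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || length(values) == 0L)
    stop("'values' must be a non-empty 3-D array")
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1)))
      stop("numeric mask values must be 0/1")
    values <- array(values != 0, dim(values))
  }
  if (!is.logical(values)) stop("mask values must be logical or 0/1")
  if (anyNA(values)) stop("mask values must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive voxel edge lengths in mm")
  structure(list(values = values, spacing = spacing), class = "binary_mask")
}

#' @export
print.suv_image <- function(x, ...) {
  cat(sprintf("<suv_image> %s, %s mm, unit %s, range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"),
              x$unit, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s, %s mm, %d voxels on (%.2f mL)\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"),
              sum(x$values), mask_volume_ml(x)))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-5) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing)))
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b))
    stop("volumes do not share grid shape and voxel spacing")
  invisible(NULL)
}

#' Read a 3-D volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3-D volume with
#'   valid (positive) pixel dimensions.
#' @param unit Unit tag to attach (`"SUV"` or `"BQ_PER_ML"`); NIfTI has no
#'   standard slot for it.
#' @return A [suv_image].
#' @export
read_volume <- function(path, unit = c("SUV", "BQ_PER_ML")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(as.array(img)), dim(img))  # plain array, no NIfTI attrs
  if (length(dim(a)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(a)), " dimensions: ", path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("missing or degenerate voxel spacing in ", path)
  suv_image(a, sp[1:3], unit = unit)
}

#' Read a binary mask from a NIfTI file
#'
#' Any non-zero voxel is taken as inside the VOI.
#'
#' @inheritParams read_volume
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$values != 0, v$spacing)
}

#' Write a volume or mask to a NIfTI file
#'
#' Images are stored as float64 so that reading them back reproduces the
#' grid bit-exactly; masks are stored as uint8 0/1.  Spacing survives the
#' round trip to float32 precision (the NIfTI pixdim field).
#'
#' @param x A [suv_image] or [binary_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "suv_image")) {
    a <- x$values
    dt <- "double"
  } else if (inherits(x, "binary_mask")) {
    a <- array(as.integer(x$values), dim(x$values))
    dt <- "uint8"
  } else stop("'x' must be a suv_image or binary_mask")
  attr(a, "pixdim") <- x$spacing
  RNifti::writeNifti(a, path, datatype = dt)
  invisible(path)
}

#' Patient metadata for SUV conversion
#'
#' @param injected_activity Injected activity in Bq (> 0).
#' @param body_weight Body weight in g (> 0).
#' @param id Optional identifier.
#' @return An object of class `patient_meta`.
#' @export
patient_meta <- function(injected_activity, body_weight, id = NULL) {
  if (!is.numeric(injected_activity) || injected_activity <= 0)
    stop("'injected_activity' must be > 0 (Bq)")
  if (!is.numeric(body_weight) || body_weight <= 0)
    stop("'body_weight' must be > 0 (g)")
  structure(list(injected_activity = injected_activity,
                 body_weight = body_weight, id = id),
            class = "patient_meta")
}

#' Read patient metadata from CSV
#'
#' Expects columns `id`, `injected_activity_MBq`, `weight_kg` and converts
#' them to the Bq and g used internally.
#'
#' @param path CSV file path.
#' @return A list of [patient_meta] objects, named by `id`.
#' @export
read_patient_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "injected_activity_MBq", "weight_kg")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    patient_meta(df$injected_activity_MBq[i] * 1e6,
                 df$weight_kg[i] * 1000, id = df$id[i]))
  names(out) <- df$id
  out
}

#' Convert an activity-concentration image to SUV
#'
#' SUV is the ratio of the activity concentration in the image to the
#' injected activity divided by body weight.  With concentration in Bq/mL,
#' activity in Bq and weight in g, the ratio is dimensionless (1 mL of
#' tissue is taken as 1 g).  Decay correction is assumed to have been
#' applied upstream by the reconstruction.
#'
#' @param image A [suv_image] with unit `"BQ_PER_ML"`.
#' @param meta A [patient_meta].
#' @return A [suv_image] with unit `"SUV"`, same geometry.
#' @export
to_suv <- function(image, meta) {
  if (!inherits(image, "suv_image")) stop("'image' must be a suv_image")
  if (image$unit != "BQ_PER_ML")
    stop("image is already in SUV; refusing to convert twice")
  if (!inherits(meta, "patient_meta")) stop("'meta' must be a patient_meta")
  f <- meta$injected_activity / meta$body_weight
  suv_image(image$values / f, image$spacing, unit = "SUV")
}

#' Volume of a mask in mL
#'
#' Voxel count times voxel volume (dx * dy * dz mm^3) divided by 1000.
#' This is the metabolically active tumor volume (MATV) when the mask is a
#' tumor VOI.
#'
#' @param mask A [binary_mask].
#' @return Volume in mL (0 for an empty mask).
#' @export
mask_volume_ml <- function(mask) {
  if (!inherits(mask, "binary_mask")) stop("'mask' must be a binary_mask")
  sum(mask$values) * prod(mask$spacing) / 1000
}

#' Spacing-aware binary dilation
#'
#' Adds every voxel whose centre lies within `radius_mm` (Euclidean, in mm)
#' of the centre of an included voxel.  The output always contains the
#' input; radius 0 is the identity.
#'
#' @param mask A [binary_mask].
#' @param radius_mm Dilation radius in mm, >= 0.
#' @return A [binary_mask].
#' @export
dilate_mask <- function(mask, radius_mm) {
  if (!inherits(mask, "binary_mask")) stop("'mask' must be a binary_mask")
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm < 0)
    stop("'radius_mm' must be a single non-negative number")
  if (radius_mm == 0 || !any(mask$values)) return(mask)
  offs <- ball_offsets(radius_mm, mask$spacing)
  binary_mask(shift_or(mask$values, offs), mask$spacing)
}

#' Spacing-aware binary erosion
#'
#' Complement of the dilation of the complement; keeps voxels whose whole
#' mm-ball neighbourhood of voxel centres is inside the mask.
#'
#' @inheritParams dilate_mask
#' @return A [binary_mask].
#' @export
erode_mask <- function(mask, radius_mm) {
  if (!inherits(mask, "binary_mask")) stop("'mask' must be a binary_mask")
  if (radius_mm < 0) stop("'radius_mm' must be non-negative")
  if (radius_mm == 0) return(mask)
  offs <- ball_offsets(radius_mm, mask$spacing)
  binary_mask(!shift_or(!mask$values, offs), mask$spacing)
}
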