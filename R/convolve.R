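# Separable 1-D convolutions along array axes with symmetric (reflect)
# boundary padding.  Used for the reconstruction point-spread function,
# the heterogeneity texture and the Gaussian-derivative gradient operator.

conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dim(ap) <- c(n, prod(d[-axis]))
  idx <- (1 - r):(n + r)
  idx[idx < 1] <- 1 - idx[idx < 1]
  idx[idx > n] <- 2 * n + 1 - idx[idx > n]
  idx <- pmin(pmax(idx, 1L), n)  # guard for kernels longer than the axis
  pad <- ap[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(ap))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * pad[j:(j + n - 1), , drop = FALSE]
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Normalised so that a linear ramp of c per mm along the axis responds with
# exactly c in the interior, whatever the voxel spacing.
gaussian_deriv_kernel_1d <- function(sigma_vox, spacing_mm) {
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma_vox^2))
  raw <- x * g
  raw / (spacing_mm * sum(x^2 * g))
}

# Isotropic (mm-space) Gaussian smoothing of a 3-D array.
gaussian_smooth <- function(a, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(a)
  for (axis in 1:3) {
    sv <- sigma_mm / spacing[axis]
    a <- conv_axis(a, gaussian_kernel_1d(sv), axis)
  }
  a
}
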