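# Brute-force oracles and fixture builders, independent of the package's
# implementation paths.

rand_mask_array <- function(dim3, p = 0.4) {
  array(runif(prod(dim3)) < p, dim3)
}

rand_mask <- function(dim3 = c(4, 4, 4), spacing = c(1, 1, 1), p = 0.4,
                      nonempty = FALSE) {
  a <- rand_mask_array(dim3, p)
  if (nonempty && !any(a)) a[sample(length(a), 1)] <- TRUE
  binary_mask(a, spacing)
}

# Set-algebra overlap oracle on logical arrays.
bf_overlap <- function(s, r) {
  list(tp = sum(s & r), fp = sum(s & !r), fn = sum(!s & r))
}

bf_jaccard <- function(s, r) sum(s & r) / sum(s | r)

# Per-voxel vote loop.
bf_majority_vote <- function(arrs) {
  n <- length(arrs)
  out <- array(FALSE, dim(arrs[[1]]))
  for (i in seq_along(out)) {
    votes <- sum(vapply(arrs, function(a) a[i], TRUE))
    out[i] <- votes > n / 2
  }
  out
}

# Triple-loop SUVpeak: for every mask voxel, average over all voxels whose
# centre is within radius_mm in mm space.
bf_suv_peak <- function(vals, spacing, mask, radius_mm = 6) {
  d <- dim(vals)
  best <- -Inf
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!mask[i, j, k]) next
    acc <- 0; cnt <- 0
    for (a in 1:d[1]) for (b in 1:d[2]) for (cc in 1:d[3]) {
      dist2 <- ((a - i) * spacing[1])^2 + ((b - j) * spacing[2])^2 +
        ((cc - k) * spacing[3])^2
      if (dist2 <= radius_mm^2 + 1e-9) {
        acc <- acc + vals[a, b, cc]; cnt <- cnt + 1
      }
    }
    if (acc / cnt > best) best <- acc / cnt
  }
  best
}

# Tie-corrected Kruskal-Wallis H from the rank-sum formula, written out.
bf_kruskal_h <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  rk <- rank(pooled)
  start <- 0
  h <- 0
  for (g in groups) {
    rg <- sum(rk[start + seq_along(g)])
    h <- h + rg^2 / length(g)
    start <- start + length(g)
  }
  h <- 12 / (N * (N + 1)) * h - 3 * (N + 1)
  ties <- table(pooled)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / corr
}

# Exact signed-rank null distribution by enumerating all sign assignments.
bf_wilcoxon_exact <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% rk
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Small phantom cases used across observer/metrics tests.
make_test_case <- function(seed = 1, radius = 22, uptake = 10,
                           noise = 0.05, texture = 0.2, psf = 6.5,
                           id = sprintf("case%02d", seed)) {
  cfg <- phantom_config(shape = c(32L, 32L, 32L), spacing = c(4, 4, 4),
                        tumor = list(list(center = c(64, 64, 64),
                                          radii = radius, uptake = uptake)),
                        texture_amplitude = texture, psf_fwhm_mm = psf,
                        noise_sd_suv = noise, seed = seed, lesion_id = id)
  generate_phantom(cfg)
}
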