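# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer offsets (voxel units) whose centre-to-centre distance in mm is
# <= radius_mm on an anisotropic grid.  Row per offset, columns i/j/k.
ball_offsets <- function(radius_mm, spacing) {
  r <- pmax(0, floor(radius_mm / spacing + 1e-9))
  g <- as.matrix(expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 + (g[, 3] * spacing[3])^2
  g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

# OR-accumulate shifted copies of a logical 3-D array (binary dilation core).
shift_or <- function(x, offsets) {
  d <- dim(x)
  out <- array(FALSE, d)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    dst1 <- pmax(1, 1 + o)
    dst2 <- pmin(d, d + o)
    if (any(dst1 > dst2)) next
    src1 <- dst1 - o
    src2 <- dst2 - o
    out[dst1[1]:dst2[1], dst1[2]:dst2[2], dst1[3]:dst2[3]] <-
      out[dst1[1]:dst2[1], dst1[2]:dst2[2], dst1[3]:dst2[3]] |
      x[src1[1]:src2[1], src1[2]:src2[2], src1[3]:src2[3]]
  }
  out
}

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1);
# used to derive stable per-cell seeds that do not move when the design grows.
stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

cell_seed <- function(global_seed, ...) {
  h <- stable_hash(paste(..., sep = "\r"))
  as.integer(bitwXor(h, as.integer(global_seed) %% 2147483647L) %% 2147483647L)
}

# Linear indices of coordinate matrix rows (n x 3) inside dims d; NA outside.
coords_to_lin <- function(coords, d) {
  ok <- coords[, 1] >= 1 & coords[, 1] <= d[1] &
    coords[, 2] >= 1 & coords[, 2] <= d[2] &
    coords[, 3] >= 1 & coords[, 3] <= d[3]
  lin <- (coords[, 3] - 1) * d[1] * d[2] + (coords[, 2] - 1) * d[1] + coords[, 1]
  lin[!ok] <- NA_integer_
  lin
}
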