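# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own computation paths.

# Ray-casting point-in-polygon (even-odd rule); boundary hits are treated
# as inside by nudging the test point, so callers should avoid placing
# points exactly on edges when exactness matters.
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Exhaustive-sweep Otsu: maximize between-class variance over every
# candidate threshold midway between consecutive sorted unique values.
oracle_otsu <- function(values) {
  u <- sort(unique(values))
  cands <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cands, function(th) {
    lo <- values[values <= th]
    hi <- values[values > th]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cands[which.max(bcv)]
}

# Full-enumeration Mann-Whitney oracle for tie-free data: U1 by pairwise
# counting, two-sided p from the exact U distribution over all rank splits.
oracle_mwu <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  # U1 = n1*n2 + n1(n1+1)/2 - R1 counts pairs with a below b
  u1 <- sum(outer(a, b, "<"))
  N <- n1 + n2
  splits <- utils::combn(N, n1)
  ranks <- seq_len(N)
  us <- apply(splits, 2, function(idx) {
    n1 * n2 + n1 * (n1 + 1) / 2 - sum(ranks[idx])
  })
  p_lo <- mean(us <= u1)
  p_hi <- mean(us >= u1)
  list(u1 = u1, u2 = n1 * n2 - u1,
       p = min(1, 2 * min(p_lo, p_hi)))
}

# Classic rank-difference Spearman formula (tie-free only).
oracle_spearman_rho <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# All permutations of 1..n (recursive; for tiny n only).
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# Build a binary_mask object directly from a logical matrix.
make_mask <- function(grid, pixel_size_um = 1, channel_name = "test") {
  structure(list(grid = grid, pixel_size_um = pixel_size_um,
                 channel_name = channel_name, threshold_used = 0.5,
                 method = "fixed"),
            class = "binary_mask")
}

# Axis-aligned rectangular ROI in pixel coordinates.
rect_roi <- function(x0, y0, x1, y1, roi_id = "r", glomerulus_id = "g",
                     pixel_size_um = 1) {
  slit_roi(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)),
           roi_id = roi_id, glomerulus_id = glomerulus_id,
           pixel_size_um = pixel_size_um)
}

# Small, fast generator parameter set for tests that do not depend on the
# default field size; explicit arguments override the speed-ups.
small_params <- function(...) {
  args <- utils::modifyList(
    list(field_size_px = c(96L, 96L), n_z = 3L, roi_margin_um = 1,
         endothelial_clutter = FALSE),
    list(...))
  do.call(synth_params, args)
}

# Rasterize a circle outline as a ring mask (used by length-oracle tests).
circle_ring_mask <- function(radius_um, pixel_size_um, half_width_um = 0.13) {
  n <- ceiling(2 * radius_um / pixel_size_um) + 11
  ctr <- n / 2
  d <- sqrt(outer(((seq_len(n)) - ctr)^2, ((seq_len(n)) - ctr)^2, "+")) *
    pixel_size_um
  make_mask(abs(d - radius_um) < half_width_um, pixel_size_um)
}
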