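# Shared numerical helpers.
#
# Conventions used throughout: 3D arrays are indexed [z, y, x] (axis 1 is the
# axial/compression direction); coordinate and displacement *vectors* are in
# (x, y, z) component order; physical coordinates are micrometres with voxel
# centre i (0-based) at i * voxel_size along each axis.

# Trilinear sampling of a 3D array at fractional voxel coordinates.
# pz, py, px are 0-based voxel-centre coordinates; values outside the
# [0, n-1] box return NA.
sample_trilinear <- function(arr, pz, py, px) {
  d <- dim(arr)
  inside <- pz >= 0 & pz <= d[1] - 1 & py >= 0 & py <= d[2] - 1 &
    px >= 0 & px <= d[3] - 1
  out <- rep(NA_real_, length(pz))
  if (!any(inside)) return(out)
  pz <- pz[inside]; py <- py[inside]; px <- px[inside]
  fz <- pmin(pmax(floor(pz), 0), d[1] - 2); wz <- pz - fz
  fy <- pmin(pmax(floor(py), 0), d[2] - 2); wy <- py - fy
  fx <- pmin(pmax(floor(px), 0), d[3] - 2); wx <- px - fx
  # linear index of the low corner (1-based)
  base <- 1 + fz + d[1] * (fy + d[2] * fx)
  sz <- 1; sy <- d[1]; sx <- d[1] * d[2]
  v <- arr[base]           * (1 - wz) * (1 - wy) * (1 - wx) +
    arr[base + sz]         * wz       * (1 - wy) * (1 - wx) +
    arr[base + sy]         * (1 - wz) * wy       * (1 - wx) +
    arr[base + sz + sy]    * wz       * wy       * (1 - wx) +
    arr[base + sx]         * (1 - wz) * (1 - wy) * wx +
    arr[base + sz + sx]    * wz       * (1 - wy) * wx +
    arr[base + sy + sx]    * (1 - wz) * wy       * wx +
    arr[base + sz + sy + sx] * wz     * wy       * wx
  out[inside] <- v
  out
}

# Shift an array along one axis by k voxels with edge replication.
shift_clamped <- function(arr, axis, k) {
  d <- dim(arr)
  idx <- pmin(pmax(seq_len(d[axis]) + k, 1L), d[axis])
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Separable Gaussian blur, sigma in voxels, truncated at 3 sigma,
# edge-replicated. sigma = 0 returns the input.
gaussian_blur3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  for (axis in 1:3) {
    acc <- array(0, dim(arr))
    for (k in -r:r) acc <- acc + w[k + r + 1] * shift_clamped(arr, axis, k)
    arr <- acc
  }
  arr
}

# Box (Chebyshev ball) dilation of a 0/1 array, separable running maximum.
dilate_box3 <- function(arr, radius) {
  if (radius <= 0) return(arr)
  for (axis in 1:3) {
    acc <- arr
    for (k in seq_len(radius)) {
      acc <- pmax(acc, shift_clamped(arr, axis, k),
                  shift_clamped(arr, axis, -k))
    }
    arr <- acc
  }
  arr
}

# Run code with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sorted principal values of symmetric 3x3 tensors, vectorized.
# eps: n x 6 matrix with columns (exx, eyy, ezz, exy, eyz, exz) — tensor
# (not engineering) shear components. Returns n x 3, descending.
principal_values_sym3 <- function(eps) {
  exx <- eps[, 1]; eyy <- eps[, 2]; ezz <- eps[, 3]
  exy <- eps[, 4]; eyz <- eps[, 5]; exz <- eps[, 6]
  q <- (exx + eyy + ezz) / 3
  p2 <- (exx - q)^2 + (eyy - q)^2 + (ezz - q)^2 +
    2 * (exy^2 + eyz^2 + exz^2)
  p <- sqrt(p2 / 6)
  n <- length(q)
  out <- matrix(q, n, 3)
  nz <- p > 0
  if (any(nz)) {
    bxx <- (exx[nz] - q[nz]) / p[nz]; byy <- (eyy[nz] - q[nz]) / p[nz]
    bzz <- (ezz[nz] - q[nz]) / p[nz]
    bxy <- exy[nz] / p[nz]; byz <- eyz[nz] / p[nz]; bxz <- exz[nz] / p[nz]
    detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[nz] + 2 * p[nz] * cos(phi)
    e3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    out[nz, 1] <- e1
    out[nz, 3] <- e3
    out[nz, 2] <- 3 * q[nz] - e1 - e3
  }
  colnames(out) <- c("p1", "p2", "p3")
  out
}

# Trilinear interpolation weights of points on a regular node grid.
# axes: list of 3 strictly increasing node-position vectors (in the same
# units as the point coordinates), ordered (z, y, x) to match array axes.
# pts_zyx: n x 3 matrix of point coordinates in (z, y, x) order.
# Returns node ids (n x 8) into the z-fastest node ordering and weights
# (n x 8); errors if a point lies outside the grid coverage.
grid_weights <- function(axes, pts_zyx, what = "point") {
  nc <- vapply(axes, length, 1L)
  ids <- matrix(0L, nrow(pts_zyx), 8)
  wts <- matrix(0, nrow(pts_zyx), 8)
  cell <- matrix(0L, nrow(pts_zyx), 3)
  loc <- matrix(0, nrow(pts_zyx), 3)
  for (a in 1:3) {
    p <- pts_zyx[, a]
    lo <- axes[[a]][1]; hi <- axes[[a]][nc[a]]
    bad <- p < lo - 1e-9 | p > hi + 1e-9
    if (any(bad))
      stop(sprintf("%s outside the grid coverage along axis %d (value %.6g not in [%.6g, %.6g])",
                   what, a, p[which(bad)[1]], lo, hi), call. = FALSE)
    i <- findInterval(p, axes[[a]], rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), nc[a] - 1L)
    cell[, a] <- i
    loc[, a] <- (p - axes[[a]][i]) / (axes[[a]][i + 1] - axes[[a]][i])
  }
  corner <- 0L
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    corner <- corner + 1L
    iz <- cell[, 1] + oz; iy <- cell[, 2] + oy; ix <- cell[, 3] + ox
    ids[, corner] <- iz + nc[1] * ((iy - 1L) + nc[2] * (ix - 1L))
    wz <- if (oz == 1) loc[, 1] else 1 - loc[, 1]
    wy <- if (oy == 1) loc[, 2] else 1 - loc[, 2]
    wx <- if (ox == 1) loc[, 3] else 1 - loc[, 3]
    wts[, corner] <- wz * wy * wx
  }
  list(ids = ids, weights = wts)
}

# Tricubic (Catmull-Rom cubic convolution) sampling at fractional voxel
# coordinates; reproduces cubics' smoothness and linear ramps exactly and has
# far smaller sub-voxel bias than trilinear sampling at blurred edges.
# Same interface as sample_trilinear; out-of-box points return NA; border
# support is clamp-replicated.
sample_tricubic <- function(arr, pz, py, px) {
  d <- dim(arr)
  inside <- pz >= 0 & pz <= d[1] - 1 & py >= 0 & py <= d[2] - 1 &
    px >= 0 & px <= d[3] - 1
  out <- rep(NA_real_, length(pz))
  if (!any(inside)) return(out)
  pz <- pz[inside]; py <- py[inside]; px <- px[inside]
  cr_w <- function(t) {
    t2 <- t * t; t3 <- t2 * t
    list(0.5 * (-t3 + 2 * t2 - t),
         0.5 * (3 * t3 - 5 * t2 + 2),
         0.5 * (-3 * t3 + 4 * t2 + t),
         0.5 * (t3 - t2))
  }
  fz <- pmin(pmax(floor(pz), 0), d[1] - 2); tz <- pz - fz
  fy <- pmin(pmax(floor(py), 0), d[2] - 2); ty <- py - fy
  fx <- pmin(pmax(floor(px), 0), d[3] - 2); tx <- px - fx
  wz <- cr_w(tz); wy <- cr_w(ty); wx <- cr_w(tx)
  iz <- lapply(-1:2, function(k) pmin(pmax(fz + k, 0), d[1] - 1))
  iy <- lapply(-1:2, function(k) pmin(pmax(fy + k, 0), d[2] - 1))
  ix <- lapply(-1:2, function(k) pmin(pmax(fx + k, 0), d[3] - 1))
  acc <- numeric(length(pz))
  for (a in 1:4) for (b in 1:4) {
    wyx <- wy[[a]] * wx[[b]]
    base_yx <- d[1] * (iy[[a]] + d[2] * ix[[b]])
    for (cc in 1:4) {
      acc <- acc + arr[1 + iz[[cc]] + base_yx] * wz[[cc]] * wyx
    }
  }
  out[inside] <- acc
  out
}
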