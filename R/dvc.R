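#' DVC measurement grid
#'
#' Regular grid of measurement nodes overlaid on an image pair, with nodes
#' spaced `ns` voxels apart (the "nodal spacing", the resolution/precision
#' trade-off knob of grid-based DVC; 48 voxels, about 1.9 mm at 39 um
#' voxels, is the default used for whole vertebral bodies). The grid starts
#' at `origin` (voxel units, 0-based) and extends along each axis with
#' enough nodes for its cells to cover every voxel centre of the volume.
#'
#' @param vol A `vertfe_volume` the grid should cover.
#' @param ns Nodal spacing in voxels (>= 4).
#' @param origin Voxel coordinates (z, y, x) of node (0, 0, 0).
#' @return A `dvc_grid` with node axes in voxel and physical units.
#' @export
dvc_grid <- function(vol, ns = 48, origin = c(0, 0, 0)) {
  stopifnot(inherits(vol, "vertfe_volume"))
  if (ns < 4) stop("nodal spacing must be >= 4 voxels", call. = FALSE)
  d <- dim(vol$data)
  # cells must cover the voxel-corner lattice [0, dim] so that boundary
  # conditions can be interpolated at the extreme mesh node planes
  axes_vox <- lapply(1:3, function(a) {
    n_cells <- max(1L, ceiling((d[a] - origin[a]) / ns))
    origin[a] + ns * (0:n_cells)
  })
  node_counts <- vapply(axes_vox, length, 1L)
  structure(list(ns = ns, origin = origin, axes_vox = axes_vox,
                 node_counts = node_counts, dims = d,
                 voxel_size = vol$voxel_size),
            class = "dvc_grid")
}

# node positions: n x 3 (x, y, z) um, z-fastest node ordering
grid_node_coords <- function(grid) {
  ax <- grid$axes_vox; h <- grid$voxel_size
  nzc <- grid$node_counts[1]; nyc <- grid$node_counts[2]
  nxc <- grid$node_counts[3]
  cbind(rep(ax[[3]] * h, each = nzc * nyc),
        rep(rep(ax[[2]] * h, each = nzc), times = nxc),
        rep(ax[[1]] * h, times = nyc * nxc))
}

#' Registration settings for the DVC solver
#'
#' @param regularization_weight Dimensionless weight of the squared-Laplacian
#'   smoothness penalty on the nodal field, relative to the image term (the
#'   penalty is scaled by `trace(JtJ)/trace(LtL)` at the start of each
#'   pyramid level so the weight is resolution-independent). Default 0.05,
#'   chosen with the zero-strain repeatability protocol.
#' @param pyramid_levels Coarse-to-fine levels (>= 1); level l downsamples
#'   the images by `2^(l-1)` with block averaging.
#' @param max_iterations Gauss-Newton iterations per level.
#' @param tolerance Relative objective decrease below which a level stops.
#' @param interpolation Image interpolation when sampling the moved image:
#'   `"cubic"` (Catmull-Rom cubic convolution, the default; much smaller
#'   sub-voxel bias at blurred bone edges) or `"trilinear"`.
#' @param refine_factor Internal discretization refinement at the finest
#'   pyramid level: the nodal field is re-estimated on a grid with spacing
#'   `ns / refine_factor` and read out at the requested nodes. Refinement
#'   reduces the systematic overshoot a piecewise-trilinear representation
#'   shows near its resolving limit (fields varying over a few nodal
#'   spacings); 1 disables it. The output grid is unchanged.
#' @return A `registration_settings` list.
#' @export
registration_settings <- function(regularization_weight = 0.05,
                                  pyramid_levels = 3L,
                                  max_iterations = 30L,
                                  tolerance = 1e-6,
                                  interpolation = c("cubic", "trilinear"),
                                  refine_factor = 2L) {
  if (regularization_weight < 0) stop("weight must be >= 0", call. = FALSE)
  if (pyramid_levels < 1) stop("need >= 1 pyramid level", call. = FALSE)
  if (!refine_factor %in% c(1L, 2L))
    stop("`refine_factor` must be 1 or 2", call. = FALSE)
  structure(list(regularization_weight = regularization_weight,
                 pyramid_levels = as.integer(pyramid_levels),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 interpolation = match.arg(interpolation),
                 refine_factor = as.integer(refine_factor)),
            class = "registration_settings")
}

#' Register a preloaded/loaded volume pair (global DVC)
#'
#' Recovers the nodal displacement field `u` minimising the masked sum of
#' squared grey differences between `fixed` and the back-warped `moved`
#' image, `sum_mask [fixed(x) - moved(x + u(x))]^2`, plus a squared-Laplacian
#' smoothness penalty on the nodal field, where `u` is trilinearly
#' interpolated from the grid nodes. Minimisation is by Gauss-Newton
#' iterations with step halving (the objective never increases across
#' accepted steps) over a coarse-to-fine image pyramid. The solver is
#' deterministic: no randomness is involved.
#'
#' @param fixed,moved [grey_volume()]s of the preloaded and loaded states.
#' @param mask A [mask_volume()]; only voxels inside it contribute to the
#'   image term.
#' @param grid A [dvc_grid()] (defaults to nodal spacing 48 on `fixed`).
#' @param settings A [registration_settings()].
#' @return A `displacement_grid`: list with `grid`, `u` (n_nodes x 3
#'   displacements in um, components (x, y, z), z-fastest node order) and
#'   `convergence` (final objective, iterations per level, warning flag).
#' @export
register_volumes <- function(fixed, moved, mask, grid = dvc_grid(fixed),
                             settings = registration_settings()) {
  stopifnot(inherits(fixed, "grey_volume"), inherits(moved, "grey_volume"),
            inherits(mask, "mask_volume"))
  check_same_dims(fixed, moved)
  check_same_dims(fixed, mask)
  if (sum(mask$data) == 0) stop("empty mask", call. = FALSE)

  n_nodes <- prod(grid$node_counts)
  u <- matrix(0, n_nodes, 3)          # um, components (x, y, z)
  LtL <- grid_laplacian_gram(grid)
  iter_log <- integer(0)
  warn <- FALSE
  final_obj <- NA_real_

  for (lev in seq(settings$pyramid_levels, 1)) {
    f <- 2^(lev - 1)
    lf <- downsample_block(fixed$data, f)
    lm <- downsample_block(moved$data, f)
    lmask <- downsample_block(array(as.numeric(mask$data), dim(mask$data)),
                              f) >= 0.5
    if (!any(lmask)) lmask <- downsample_block(
      array(as.numeric(mask$data), dim(mask$data)), f) > 0
    res <- gn_level(lf, lm, lmask, grid, u, LtL, f, settings)
    u <- res$u
    iter_log <- c(iter_log, res$iterations)
    warn <- warn || res$warning
    final_obj <- res$objective
  }
  if (settings$refine_factor > 1L) {
    fine <- refine_grid(grid, settings$refine_factor)
    coarse_disp <- structure(list(grid = grid, u = u,
                                  convergence = list()),
                             class = "displacement_grid")
    pts <- grid_node_coords(fine)
    u_fine <- interpolate_displacement(coarse_disp, pts)
    LtLf <- grid_laplacian_gram(fine)
    ref_settings <- settings
    # the refined level starts from a converged coarse solution; a few
    # polishing iterations suffice. The dimensionless second difference of a
    # smooth field shrinks by refine_factor^2 on the half-spacing grid, so
    # the squared penalty needs refine_factor^4 more weight to keep the same
    # physical smoothness pressure (otherwise the finer basis fits noise).
    ref_settings$max_iterations <- min(settings$max_iterations, 6L)
    ref_settings$tolerance <- max(settings$tolerance, 1e-5)
    ref_settings$regularization_weight <-
      settings$regularization_weight * settings$refine_factor^4
    res <- gn_level(fixed$data, moved$data, mask$data == 1L, fine, u_fine,
                    LtLf, 1, ref_settings)
    iter_log <- c(iter_log, res$iterations)
    warn <- warn || res$warning
    final_obj <- res$objective
    # read out at the requested (coarse) nodes
    fine_disp <- structure(list(grid = fine, u = res$u,
                                convergence = list()),
                           class = "displacement_grid")
    u <- interpolate_displacement(fine_disp, grid_node_coords(grid))
  }
  structure(list(grid = grid, u = u,
                 convergence = list(objective = final_obj,
                                    iterations = iter_log,
                                    warning = warn)),
            class = "displacement_grid")
}

# half-spacing refinement of a grid (same origin and physical coverage)
refine_grid <- function(grid, factor) {
  axes <- lapply(grid$axes_vox, function(a) {
    n <- length(a)
    seq(a[1], a[n], by = (a[2] - a[1]) / factor)
  })
  structure(list(ns = grid$ns / factor, origin = grid$origin,
                 axes_vox = axes,
                 node_counts = vapply(axes, length, 1L),
                 dims = grid$dims, voxel_size = grid$voxel_size),
            class = "dvc_grid")
}

# Block-mean downsampling by integer factor f (edge blocks padded by
# replication so dims become multiples of f).
downsample_block <- function(arr, f) {
  if (f == 1) return(arr)
  d <- dim(arr)
  dn <- ceiling(d / f)
  for (a in 1:3) {
    pad <- dn[a] * f - d[a]
    if (pad > 0) {
      idx <- c(seq_len(d[a]), rep(d[a], pad))
      arr <- switch(a, arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE], arr[, , idx, drop = FALSE])
      d <- dim(arr)
    }
  }
  # average over f^3 blocks, one axis at a time
  for (a in 1:3) {
    d <- dim(arr)
    m <- d[a] / f
    perm <- c(a, setdiff(1:3, a))
    x <- aperm(arr, perm)
    dim(x) <- c(f, m * prod(d[-a]))
    x <- colMeans(x)
    dim(x) <- c(m, d[setdiff(1:3, a)])
    arr <- aperm(x, order(perm))
  }
  arr
}

# Gauss-Newton at one pyramid level. Voxel centre b (0-based, level units)
# sits at original-volume voxel coordinate b*f + (f-1)/2.
gn_level <- function(lf, lm, lmask, grid, u, LtL, f, settings) {
  d <- dim(lf)
  h_lvl <- grid$voxel_size * f
  midx <- which(lmask)
  nvox <- length(midx)
  # level voxel coords (z, y, x), 0-based
  vz <- (midx - 1) %% d[1]
  vy <- ((midx - 1) %/% d[1]) %% d[2]
  vx <- (midx - 1) %/% (d[1] * d[2])
  # original-volume voxel units for grid weights
  orig <- cbind(vz, vy, vx) * f + (f - 1) / 2
  gw <- grid_weights(grid$axes_vox, orig, what = "masked voxel")
  n_nodes <- prod(grid$node_counts)
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(nvox), 8), j = as.vector(gw$ids),
    x = as.vector(gw$weights), dims = c(nvox, n_nodes))
  fvals <- lf[midx]
  # image gradient of the moved image (grey per level-voxel)
  gx <- (shift_clamped(lm, 3, 1) - shift_clamped(lm, 3, -1)) / 2
  gy <- (shift_clamped(lm, 2, 1) - shift_clamped(lm, 2, -1)) / 2
  gz <- (shift_clamped(lm, 1, 1) - shift_clamped(lm, 1, -1)) / 2

  sampler <- if (identical(settings$interpolation, "trilinear"))
    sample_trilinear else sample_tricubic
  objective <- function(u) {
    disp <- (W %*% u) / h_lvl           # level-voxel units, n x 3 (x,y,z)
    wz <- vz + disp[, 3]; wy <- vy + disp[, 2]; wx <- vx + disp[, 1]
    mv <- sampler(lm, wz, wy, wx)
    r <- fvals - mv
    r[is.na(r)] <- 0
    list(r = r, wz = wz, wy = wy, wx = wx,
         ssd = sum(r^2))
  }

  lam_eff <- NULL
  cur <- objective(u)
  smooth_pen <- function(u) sum((LtL %*% u) * u)
  obj_val <- function(cur, u) cur$ssd +
    (if (is.null(lam_eff)) 0 else lam_eff * smooth_pen(u))
  iterations <- 0L
  warning_flag <- FALSE
  for (it in seq_len(settings$max_iterations)) {
    iterations <- it
    # gradient sampled at the warped positions
    sgx <- sampler(gx, cur$wz, cur$wy, cur$wx)
    sgy <- sampler(gy, cur$wz, cur$wy, cur$wx)
    sgz <- sampler(gz, cur$wz, cur$wy, cur$wx)
    sgx[is.na(sgx)] <- 0; sgy[is.na(sgy)] <- 0; sgz[is.na(sgz)] <- 0
    # d(warped)/d(u_node,comp) = g_comp / h_lvl * basis weight
    g <- cbind(sgx, sgy, sgz) / h_lvl
    blocks <- vector("list", 9)
    for (ci in 1:3) for (cj in ci:3) {
      blk <- Matrix::crossprod(W, (g[, ci] * g[, cj]) * W)
      blocks[[(ci - 1) * 3 + cj]] <- blk
      if (cj != ci) blocks[[(cj - 1) * 3 + ci]] <- blk
    }
    A <- rbind(
      cbind(blocks[[1]], blocks[[2]], blocks[[3]]),
      cbind(blocks[[4]], blocks[[5]], blocks[[6]]),
      cbind(blocks[[7]], blocks[[8]], blocks[[9]]))
    if (is.null(lam_eff)) {
      trL <- sum(Matrix::diag(LtL)) * 3
      trA <- sum(Matrix::diag(A))
      lam_eff <- if (trL > 0)
        settings$regularization_weight * trA / trL else 0
    }
    LtL3 <- Matrix::bdiag(LtL, LtL, LtL)
    rhs <- as.vector(vapply(1:3, function(ci)
      as.vector(Matrix::crossprod(W, g[, ci] * cur$r)), numeric(n_nodes))) -
      lam_eff * as.vector(LtL3 %*% as.vector(u))
    sys <- Matrix::forceSymmetric(
      A + lam_eff * LtL3 +
        Matrix::Diagonal(3 * n_nodes, 1e-12 * max(Matrix::diag(A), 1e-30)))
    delta <- tryCatch(as.vector(Matrix::solve(sys, rhs)),
                      error = function(e) rep(0, 3 * n_nodes))
    if (!all(is.finite(delta))) {
      warning_flag <- TRUE
      break
    }
    if (all(delta == 0)) break   # zero gradient: already at an optimum
    delta <- matrix(delta, n_nodes, 3)
    f0 <- obj_val(cur, u)
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:8) {
      u_try <- u + alpha * delta
      cand <- objective(u_try)
      if (obj_val(cand, u_try) < f0) {
        rel <- (f0 - obj_val(cand, u_try)) / max(f0, 1e-30)
        u <- u_try
        cur <- cand
        accepted <- TRUE
        if (rel < settings$tolerance) {
          return(list(u = u, iterations = it, warning = FALSE,
                      objective = obj_val(cur, u)))
        }
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      # no decreasing step: converged (or stuck) at this level
      break
    }
  }
  if (iterations == settings$max_iterations) warning_flag <- TRUE
  list(u = u, iterations = iterations, warning = warning_flag,
       objective = obj_val(cur, u))
}

# Gram matrix L^T L of the dimensionless axis-wise second-difference
# operator on the grid nodes, applied per displacement component. Rows
# exist only where both neighbours exist, so any affine nodal field has
# exactly zero penalty (no shrinkage of uniform strains at the grid edge).
grid_laplacian_gram <- function(grid) {
  nc <- grid$node_counts
  n <- prod(nc)
  idx <- function(iz, iy, ix) iz + nc[1] * ((iy - 1L) + nc[2] * (ix - 1L))
  all_iz <- rep(seq_len(nc[1]), times = nc[2] * nc[3])
  all_iy <- rep(rep(seq_len(nc[2]), each = nc[1]), times = nc[3])
  all_ix <- rep(seq_len(nc[3]), each = nc[1] * nc[2])
  nid <- idx(all_iz, all_iy, all_ix)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  row0 <- 0L
  for (a in 1:3) {
    coord <- switch(a, all_iz, all_iy, all_ix)
    ok <- which(coord > 1L & coord < nc[a])
    if (length(ok) == 0) next
    prev <- switch(a,
                   idx(all_iz - 1L, all_iy, all_ix),
                   idx(all_iz, all_iy - 1L, all_ix),
                   idx(all_iz, all_iy, all_ix - 1L))
    nxt <- switch(a,
                  idx(all_iz + 1L, all_iy, all_ix),
                  idx(all_iz, all_iy + 1L, all_ix),
                  idx(all_iz, all_iy, all_ix + 1L))
    rows <- row0 + seq_along(ok)
    ti <- c(ti, rows, rows, rows)
    tj <- c(tj, prev[ok], nid[ok], nxt[ok])
    tx <- c(tx, rep(1, length(ok)), rep(-2, length(ok)), rep(1, length(ok)))
    row0 <- row0 + length(ok)
  }
  if (row0 == 0L) return(Matrix::Diagonal(n, 0))
  L <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(row0, n))
  Matrix::crossprod(L)
}

#' Interpolate a DVC displacement field at arbitrary points
#'
#' Trilinear interpolation within the grid cell containing each point; nodal
#' fields sampled from an affine map are reproduced exactly. Points outside
#' the grid's cell coverage raise an error (no extrapolation).
#'
#' @param disp A `displacement_grid` from [register_volumes()] (or built
#'   synthetically with [displacement_grid_from_function()]).
#' @param points n x 3 matrix of physical coordinates, um, (x, y, z).
#' @return n x 3 matrix of displacements, um, (x, y, z).
#' @export
interpolate_displacement <- function(disp, points) {
  stopifnot(inherits(disp, "displacement_grid"))
  points <- as_points3(points)
  h <- disp$grid$voxel_size
  pts_zyx <- cbind(points[, 3], points[, 2], points[, 1]) / h
  gw <- grid_weights(disp$grid$axes_vox, pts_zyx, what = "point")
  out <- matrix(0, nrow(points), 3)
  for (cmp in 1:3) {
    vals <- matrix(disp$u[gw$ids, cmp], nrow(points), 8)
    out[, cmp] <- rowSums(vals * gw$weights)
  }
  colnames(out) <- c("x", "y", "z")
  out
}

as_points3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  points
}

#' Build a displacement grid from a field function
#'
#' Samples an analytic (or otherwise known) displacement function at the
#' grid nodes. Used to impose synthetic ground-truth boundary conditions and
#' in end-to-end recovery experiments with exact boundary sampling.
#'
#' @param grid A [dvc_grid()].
#' @param fun Function mapping an n x 3 matrix of (x, y, z) um coordinates
#'   to n x 3 displacements in um.
#' @return A `displacement_grid`.
#' @export
displacement_grid_from_function <- function(grid, fun) {
  stopifnot(inherits(grid, "dvc_grid"))
  u <- fun(grid_node_coords(grid))
  stopifnot(is.matrix(u), nrow(u) == prod(grid$node_counts), ncol(u) == 3)
  structure(list(grid = grid, u = u,
                 convergence = list(objective = 0, iterations = 0L,
                                    warning = FALSE)),
            class = "displacement_grid")
}

#' Strain field on the DVC grid
#'
#' Treats the grid as an 8-noded hexahedral mesh and evaluates the
#' small-strain tensor at each cell centre from the trilinear shape-function
#' derivatives, with principal strains from the symmetric eigendecomposition
#' (sorted descending).
#'
#' @param disp A `displacement_grid`.
#' @return A tibble with one row per grid cell: cell centre position (um),
#'   the six strain components (dimensionless; `exy` etc. are tensor shear
#'   components) and sorted principal strains `p1 >= p2 >= p3`.
#' @export
grid_strain <- function(disp) {
  stopifnot(inherits(disp, "displacement_grid"))
  grid <- disp$grid
  nc <- grid$node_counts
  if (any(nc < 2)) stop("grid needs >= 2 nodes per axis", call. = FALSE)
  ncell <- nc - 1L
  h <- grid$voxel_size
  sizes <- vapply(grid$axes_vox, function(a) (a[2] - a[1]) * h, 1)  # (z,y,x)
  cz <- rep(seq_len(ncell[1]), times = ncell[2] * ncell[3])
  cy <- rep(rep(seq_len(ncell[2]), each = ncell[1]), times = ncell[3])
  cx <- rep(seq_len(ncell[3]), each = ncell[1] * ncell[2])
  idx <- function(iz, iy, ix) iz + nc[1] * ((iy - 1L) + nc[2] * (ix - 1L))
  eps <- strain_from_corners(
    corner_u = function(oz, oy, ox)
      disp$u[idx(cz + oz, cy + oy, cx + ox), , drop = FALSE],
    hx = sizes[3], hy = sizes[2], hz = sizes[1])
  pv <- principal_values_sym3(eps)
  centre <- cbind(
    x = (grid$axes_vox[[3]][cx] + grid$axes_vox[[3]][cx + 1]) / 2 * h,
    y = (grid$axes_vox[[2]][cy] + grid$axes_vox[[2]][cy + 1]) / 2 * h,
    z = (grid$axes_vox[[1]][cz] + grid$axes_vox[[1]][cz + 1]) / 2 * h)
  tibble::tibble(cell = seq_along(cz),
                 x_um = centre[, 1], y_um = centre[, 2], z_um = centre[, 3],
                 exx = eps[, 1], eyy = eps[, 2], ezz = eps[, 3],
                 exy = eps[, 4], eyz = eps[, 5], exz = eps[, 6],
                 p1 = pv[, 1], p2 = pv[, 2], p3 = pv[, 3])
}

# Cell-centre small-strain tensor from the 8 corner displacements of
# axis-aligned hexahedra with edge lengths (hx, hy, hz) um.
# corner_u(oz, oy, ox) returns the n x 3 displacement (um) of the corner
# with offsets o in {0, 1}. Columns of the result:
# (exx, eyy, ezz, exy, eyz, exz), tensor shear components.
strain_from_corners <- function(corner_u, hx, hy, hz) {
  G <- vector("list", 9)  # d u_i / d x_j, i,j in (x,y,z)
  for (i in 1:9) G[[i]] <- 0
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    u <- corner_u(oz, oy, ox)
    sx <- 2 * ox - 1; sy <- 2 * oy - 1; sz <- 2 * oz - 1
    # dN/dx = sx/(4 hx) etc. at the centroid
    for (i in 1:3) {
      G[[(i - 1) * 3 + 1]] <- G[[(i - 1) * 3 + 1]] + u[, i] * sx / (4 * hx)
      G[[(i - 1) * 3 + 2]] <- G[[(i - 1) * 3 + 2]] + u[, i] * sy / (4 * hy)
      G[[(i - 1) * 3 + 3]] <- G[[(i - 1) * 3 + 3]] + u[, i] * sz / (4 * hz)
    }
  }
  cbind(exx = G[[1]], eyy = G[[5]], ezz = G[[9]],
        exy = (G[[2]] + G[[4]]) / 2,
        eyz = (G[[6]] + G[[8]]) / 2,
        exz = (G[[3]] + G[[7]]) / 2)
}

#' Zero-strain precision check
#'
#' Registers two independent acquisitions of the same (undeformed) geometry
#' and reports the random error of the measurement: standard deviation of
#' the nodal displacements (um) and of the cell strains (microstrain). For
#' identical images both are zero; with image noise they quantify the DVC
#' precision at the chosen nodal spacing.
#'
#' @inheritParams register_volumes
#' @param repeated A [grey_volume()]: second rendering of the same geometry.
#' @return A list with `displacement` (tibble: per-component and overall sd,
#'   um), `strain` (tibble: per-component sd, microstrain), the counts of
#'   supported nodes and fully supported cells used, and the underlying
#'   `displacement_grid`. Statistics cover only nodes (and cells) with real
#'   image support (see [dvc_node_support()]).
#' @export
zero_strain_check <- function(fixed, repeated, mask, grid = dvc_grid(fixed),
                              settings = registration_settings()) {
  disp <- register_volumes(fixed, repeated, mask, grid, settings)
  supp <- dvc_node_support(grid, mask)
  well <- supp >= 0.25 * grid$ns^3
  if (!any(well)) well <- supp > 0
  u <- disp$u[well, , drop = FALSE]
  comp_sd <- apply(u, 2, stats::sd)
  strains <- grid_strain(disp)
  # keep cells whose eight corner nodes are all supported
  nc <- grid$node_counts
  ncell <- nc - 1L
  cz <- rep(seq_len(ncell[1]), times = ncell[2] * ncell[3])
  cy <- rep(rep(seq_len(ncell[2]), each = ncell[1]), times = ncell[3])
  cx <- rep(seq_len(ncell[3]), each = ncell[1] * ncell[2])
  idx <- function(iz, iy, ix) iz + nc[1] * ((iy - 1L) + nc[2] * (ix - 1L))
  cell_ok <- rep(TRUE, length(cz))
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1)
    cell_ok <- cell_ok & well[idx(cz + oz, cy + oy, cx + ox)]
  sc <- strains[cell_ok, , drop = FALSE]
  scomp <- c("exx", "eyy", "ezz", "exy", "eyz", "exz")
  strain_sd <- if (nrow(sc) > 1)
    vapply(scomp, function(cn) stats::sd(sc[[cn]]), 1) * 1e6
  else rep(NA_real_, 6)
  list(
    displacement = tibble::tibble(
      component = c("x", "y", "z", "overall"),
      sd_um = c(comp_sd, stats::sd(as.vector(u)))),
    strain = tibble::tibble(component = scomp, sd_ue = strain_sd),
    n_nodes = sum(well), n_cells = sum(cell_ok),
    field = disp)
}

#' Masked support of each DVC grid node
#'
#' Sum of the trilinear basis weights of a node over the masked voxels: the
#' effective number of voxels informing that node's displacement estimate
#' (an interior node fully surrounded by mask has support `ns^3`). Nodes
#' with little support are determined mostly by the smoothness penalty and
#' should be excluded when scoring DVC accuracy, just as displacement
#' comparisons are restricted to grid nodes inside the specimen.
#'
#' @param grid A [dvc_grid()].
#' @param mask A [mask_volume()] on the gridded volume.
#' @return Numeric vector, one value per grid node (z-fastest order).
#' @export
dvc_node_support <- function(grid, mask) {
  stopifnot(inherits(grid, "dvc_grid"), inherits(mask, "mask_volume"))
  d <- dim(mask$data)
  midx <- which(mask$data == 1L)
  vz <- (midx - 1) %% d[1]
  vy <- ((midx - 1) %/% d[1]) %% d[2]
  vx <- (midx - 1) %/% (d[1] * d[2])
  gw <- grid_weights(grid$axes_vox, cbind(vz, vy, vx), what = "masked voxel")
  as.vector(Matrix::sparseMatrix(
    i = as.vector(gw$ids), j = rep(1L, length(gw$ids)),
    x = as.vector(gw$weights), dims = c(prod(grid$node_counts), 1L)))
}
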