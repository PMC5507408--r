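full_cube_mesh <- function(n = 4, voxel = 1000) {
  build_mesh(binary_volume(array(1L, c(n, n, n)), voxel))
}

test_that("mesh construction shares nodes between face-adjacent voxels", {
  one <- build_mesh(binary_volume(array(1L, c(1, 1, 1)), 39))
  expect_equal(one$n_elem, 1)
  expect_equal(one$n_node, 8)

  two <- array(0L, c(1, 1, 2)); two[] <- 1L
  m2 <- build_mesh(binary_volume(two, 39))
  expect_equal(m2$n_elem, 2)
  expect_equal(m2$n_node, 12)   # 4 shared corners

  expect_error(build_mesh(binary_volume(array(0L, c(2, 2, 2)) + 0L, 39)),
               "binary|empty|mesh")
})

test_that("node count equals the brute-force corner enumeration", {
  blob <- random_connected_blob(c(10, 10, 10), fill = 0.35, seed = 8)
  mesh <- build_mesh(binary_volume(blob, 39))
  # oracle: enumerate corner coordinate triples of every bone voxel
  vox <- which(blob == 1L, arr.ind = TRUE)
  corners <- character(0)
  for (i in seq_len(nrow(vox)))
    for (oz in 0:1) for (oy in 0:1) for (ox in 0:1)
      corners <- c(corners, paste(vox[i, 1] + oz, vox[i, 2] + oy,
                                  vox[i, 3] + ox))
  expect_equal(mesh$n_node, length(unique(corners)))
  expect_equal(mesh$n_elem, nrow(vox))
})

test_that("element stiffness has the structure elasticity theory demands", {
  K <- element_stiffness(elastic_params(12, 0.3), 39)
  expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6)   # rigid modes
  expect_equal(sum(ev > 1e-9 * max(ev)), 18)
  # rigid translation in each direction maps to zero force
  for (c in 1:3) {
    u <- rep(0, 24); u[seq(c, 24, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-12 * max(abs(K)))
  }
  # linear in the modulus
  expect_equal(element_stiffness(elastic_params(24, 0.3), 39), 2 * K,
               tolerance = 1e-12)
  expect_error(elastic_params(12, 0.5), "incompressible")
})

test_that("patch test: affine boundary displacements reproduce affine fields", {
  A <- matrix(c(0.01, 0.003, 0, 0.002, -0.004, 0.001, 0, 0.005, -0.008),
              3, 3, byrow = TRUE)
  b <- c(3, -2, 7)
  affine <- function(pts) pts %*% t(A) + matrix(b, nrow(pts), 3, byrow = TRUE)
  for (seed in c(2, 5)) {
    blob <- random_connected_blob(c(7, 7, 7), fill = 0.75, seed = seed)
    mesh <- build_mesh(binary_volume(blob, 50))
    bc <- bc_from_function(mesh, affine, nodes = "surface")
    expect_lt(length(bc$nodes), mesh$n_node)   # interior nodes are free
    sol <- solve_microfe(mesh, elastic_params(10, 0.3), bc, tolerance = 1e-10)
    expected <- affine(mesh$node_coords)
    rel <- max(abs(sol$u - expected)) / max(abs(expected))
    expect_lt(rel, 1e-8)
    # and the element strains are uniformly sym(A)
    st <- element_strains(mesh, sol)
    sym <- (A + t(A)) / 2
    expect_lt(max(abs(st$exx - sym[1, 1])), 1e-10)
    expect_lt(max(abs(st$exz - sym[1, 3])), 1e-10)
  }
})

test_that("iterative and assembled solves match a dense direct oracle", {
  blob <- random_connected_blob(c(5, 5, 5), fill = 0.5, seed = 12)
  expect_lte(sum(blob), 200)
  mesh <- build_mesh(binary_volume(blob, 100))
  fun <- function(pts) cbind(1e-3 * pts[, 3], -2e-3 * pts[, 1],
                             -5e-3 * pts[, 3])
  bc <- bc_from_function(mesh, fun, nodes = "axial")
  params <- elastic_params(8, 0.3)
  oracle <- dense_fe_solve(mesh, params, bc)
  scale <- max(abs(oracle))
  sparse <- solve_microfe(mesh, params, bc, tolerance = 1e-10,
                          sparse_threshold = 1e6)
  pcg <- solve_microfe(mesh, params, bc, tolerance = 1e-10,
                       sparse_threshold = 0)
  expect_lt(max(abs(sparse$u - oracle)) / scale, 1e-8)
  expect_lt(max(abs(pcg$u - oracle)) / scale, 1e-8)
  expect_equal(pcg$method, "pcg")
  expect_equal(sparse$method, "sparse-direct")
})

test_that("boundary conditions come from the grid at the extreme planes only", {
  mesh <- full_cube_mesh(4, 39)
  bin <- binary_volume(array(1L, c(4, 4, 4)), 39)
  grid <- dvc_grid(bin, ns = 4)
  A <- matrix(c(0, 0, 0.001, 0, 0, 0, 0, 0, -0.002), 3, 3, byrow = TRUE)
  disp <- displacement_grid_from_function(grid, function(pts) pts %*% t(A))
  bc <- apply_boundary_conditions(mesh, disp)
  z <- mesh$node_coords[bc$nodes, 3]
  expect_true(all(z %in% c(0, 4 * 39)))
  expect_equal(length(bc$nodes), 2 * 5 * 5)
  expect_equal(bc$u, mesh$node_coords[bc$nodes, ] %*% t(A),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a grid not covering the mesh raises an out-of-domain error
  small_grid <- structure(grid, class = "dvc_grid")
  small_grid$axes_vox[[1]] <- c(0, 2)
  small_grid$node_counts[1] <- 2L
  small_disp <- displacement_grid_from_function(
    small_grid, function(pts) 0 * pts)
  expect_error(apply_boundary_conditions(mesh, small_disp), "outside")
})

test_that("confined compression of a cube matches the closed form", {
  mesh <- full_cube_mesh(4, 1000)          # 4 mm cube of 1 mm voxels
  fun <- function(pts) cbind(0 * pts[, 1], 0 * pts[, 2], -0.01 * pts[, 3])
  bc <- bc_from_function(mesh, fun, nodes = "surface")
  params <- elastic_params(1, 0.3)
  sol <- solve_microfe(mesh, params, bc, tolerance = 1e-10)
  fr <- reaction_forces(mesh, params, bc, sol)
  # sigma_zz = E (1 - nu) / ((1 + nu)(1 - 2 nu)) * 0.01 over 16 mm^2
  analytic <- 1e-3 * 0.7 / (1.3 * 0.4) * 0.01 * (4000^2)
  expect_equal(fr$af, analytic, tolerance = 1e-8)
  expect_lt(fr$equilibrium, 1e-8 * fr$af)
  # uniform strain state
  st <- element_strains(mesh, sol)
  expect_equal(unique(round(st$ezz, 10)), -0.01)
  expect_equal(unique(round(st$p3, 10)), -0.01)
})

test_that("axial force is exactly proportional to the tissue modulus", {
  blob <- random_connected_blob(c(6, 6, 6), fill = 0.6, seed = 3)
  mesh <- build_mesh(binary_volume(blob, 80))
  fun <- function(pts) cbind(0 * pts[, 1], 0 * pts[, 2], -0.005 * pts[, 3])
  bc <- bc_from_function(mesh, fun, nodes = "axial")
  af_at <- function(e) {
    params <- elastic_params(e, 0.3)
    sol <- solve_microfe(mesh, params, bc, tolerance = 1e-10)
    reaction_forces(mesh, params, bc, sol)$af
  }
  af12 <- af_at(12.0); af46 <- af_at(4.6)
  expect_equal(af46 / af12, 4.6 / 12.0, tolerance = 1e-8)
})

test_that("rigid boundary motion produces no strain and no reactions", {
  blob <- random_connected_blob(c(6, 6, 6), fill = 0.5, seed = 6)
  mesh <- build_mesh(binary_volume(blob, 60))
  shift <- function(pts) matrix(c(12, -7, 4), nrow(pts), 3, byrow = TRUE)
  bc <- bc_from_function(mesh, shift, nodes = "axial")
  params <- elastic_params(12, 0.3)
  sol <- solve_microfe(mesh, params, bc, tolerance = 1e-10)
  fr <- reaction_forces(mesh, params, bc, sol)
  st <- element_strains(mesh, sol)
  expect_lt(fr$af, 1e-6)
  expect_lt(max(abs(st$p1)), 1e-9)
  # a small linearised rotation also gives (numerically) zero strain
  theta <- 1e-4
  W <- matrix(c(0, -theta, 0, theta, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  bcr <- bc_from_function(mesh, function(pts) pts %*% t(W), nodes = "surface")
  solr <- solve_microfe(mesh, params, bcr, tolerance = 1e-10)
  str <- element_strains(mesh, solr)
  expect_lt(max(abs(str$p1)) * 1e6, 1)   # below 1 microstrain
})

test_that("centroid strains match a numerical derivative of the interpolant", {
  blob <- random_connected_blob(c(4, 4, 4), fill = 0.7, seed = 10)
  mesh <- build_mesh(binary_volume(blob, 50))
  u <- vertfe:::with_seed(2, matrix(stats::rnorm(mesh$n_node * 3, 0, 5),
                                    ncol = 3))
  sol <- structure(list(u = u), class = "fe_solution")
  st <- element_strains(mesh, sol)
  # oracle: central differences of the trilinear interpolant at the centroid
  offs <- vertfe:::hex_local_offsets()
  h <- mesh$voxel_size
  interp_at <- function(e, local) {   # local in [0,1]^3 (x,y,z)
    w <- apply(offs, 1, function(o)
      prod(ifelse(o == 1, local, 1 - local)))
    colSums(w * u[mesh$elem_nodes[e, ], ])
  }
  delta <- 1e-5
  for (e in c(1, nrow(mesh$elem_nodes))) {
    G <- matrix(0, 3, 3)
    for (j in 1:3) {
      lp <- lm <- c(0.5, 0.5, 0.5)
      lp[j] <- lp[j] + delta; lm[j] <- lm[j] - delta
      G[, j] <- (interp_at(e, lp) - interp_at(e, lm)) / (2 * delta * h)
    }
    sym <- (G + t(G)) / 2
    expect_equal(c(st$exx[e], st$eyy[e], st$ezz[e]),
                 c(sym[1, 1], sym[2, 2], sym[3, 3]), tolerance = 1e-6)
    expect_equal(c(st$exy[e], st$eyz[e], st$exz[e]),
                 c(sym[1, 2], sym[2, 3], sym[1, 3]), tolerance = 1e-6)
  }
  # principal values agree with a dense eigendecomposition
  for (e in c(1, 2)) {
    M <- matrix(c(st$exx[e], st$exy[e], st$exz[e],
                  st$exy[e], st$eyy[e], st$eyz[e],
                  st$exz[e], st$eyz[e], st$ezz[e]), 3, 3)
    expect_equal(c(st$p1[e], st$p2[e], st$p3[e]),
                 sort(eigen(M, symmetric = TRUE)$values, decreasing = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("yield fractions count elements beyond the strain limits", {
  mk <- function(p1, p3) {
    out <- tibble::tibble(element = seq_along(p1), p1 = p1, p3 = p3)
    class(out) <- c("strain_field", class(out))
    out
  }
  crit <- yield_criteria()    # +7200 / -8000 microstrain
  expect_equal(yield_fractions(mk(rep(0, 10), rep(-0.005, 10)),
                               crit)$compressive_fraction, 0)
  expect_equal(yield_fractions(mk(rep(0, 10), rep(-0.01, 10)),
                               crit)$compressive_fraction, 1)
  half <- yield_fractions(mk(rep(0, 10), rep(c(-0.01, -0.005), 5)), crit)
  expect_equal(half$compressive_fraction, 0.5)
  expect_equal(half$tensile_fraction, 0)
  expect_error(yield_criteria(-1, -2), "microstrain")
})
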