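test_that("registering identical images returns a zero field", {
  fx <- dvc_fixture()
  disp <- register_volumes(fx$phantom$grey, fx$phantom$grey, fx$mask,
                           fx$grid)
  expect_lt(max(abs(disp$u)), 1e-9)
  expect_false(disp$convergence$warning)
})

test_that("an integer translation is recovered almost exactly", {
  fx <- dvc_fixture()
  h <- fx$spec$voxel_size
  fld <- make_field(field_spec("translation", list(shift = c(3 * h, 0, 0))),
                    fx$spec$dims, h)
  loaded <- warp_volume(fx$phantom$grey, fld,
                        background = fx$spec$grey_background,
                        interpolation = "cubic")
  disp <- register_volumes(fx$phantom$grey, loaded, fx$mask, fx$grid)
  err <- sweep(disp$u[fx$well, , drop = FALSE], 2, c(3 * h, 0, 0)) / h
  expect_lt(sqrt(mean(err^2)), 0.1)
  expect_lt(max(abs(colMeans(err))), 0.1)
})

test_that("a smooth sinusoidal field with image noise is recovered", {
  fx <- dvc_fixture()
  h <- fx$spec$voxel_size
  ns <- fx$grid$ns
  fld <- make_field(field_spec("sinusoidal",
                               list(amplitude = 2 * h, period = 4 * ns * h)),
                    fx$spec$dims, h)
  loaded <- warp_volume(fx$phantom$grey, fld,
                        background = fx$spec$grey_background,
                        interpolation = "cubic")
  sigma <- 0.02 * fx$spec$grey_bone
  noisy <- function(vol, seed) grey_volume(
    vol$data + vertfe:::with_seed(seed,
      array(stats::rnorm(length(vol$data), 0, sigma), dim(vol$data))),
    h)
  disp <- register_volumes(noisy(fx$phantom$grey, 31), noisy(loaded, 32),
                           fx$mask, fx$grid)
  truth <- vertfe:::fixed_frame_truth(fld, fx$nodes[fx$well, , drop = FALSE])
  err <- (disp$u[fx$well, , drop = FALSE] - truth) / h
  expect_lt(sqrt(mean(err^2)), 0.3)
})

test_that("displacement interpolation is exact at nodes and for affine fields", {
  fx <- dvc_fixture()
  A <- matrix(c(0.01, 0.002, 0, 0, -0.005, 0.001, 0, 0, -0.02), 3, 3,
              byrow = TRUE)
  b <- c(5, -3, 10)
  fun <- function(pts) pts %*% t(A) + matrix(b, nrow(pts), 3, byrow = TRUE)
  disp <- displacement_grid_from_function(fx$grid, fun)
  # at a node: that node's value exactly
  i <- 7
  expect_equal(interpolate_displacement(disp, fx$nodes[i, , drop = FALSE]),
               disp$u[i, , drop = FALSE], ignore_attr = TRUE)
  # arbitrary interior points: trilinear reproduces the affine map exactly
  set.seed(1)
  pts <- cbind(runif(20, 50, 1300), runif(20, 50, 1300), runif(20, 50, 1300))
  expect_equal(interpolate_displacement(disp, pts), fun(pts),
               tolerance = 1e-12, ignore_attr = TRUE)
  # outside the grid coverage: error, no extrapolation
  expect_error(interpolate_displacement(disp, matrix(c(-500, 0, 0), 1)),
               "outside")
})

test_that("grid strain reproduces constant, affine and smooth fields", {
  fx <- dvc_fixture()
  # rigid translation: identically zero strain
  tr <- displacement_grid_from_function(
    fx$grid, function(pts) matrix(c(7, -3, 2), nrow(pts), 3, byrow = TRUE))
  st <- grid_strain(tr)
  expect_lt(max(abs(as.matrix(st[, c("exx", "eyy", "ezz",
                                     "exy", "eyz", "exz")]))), 1e-12)

  # affine field: uniform strain sym(A) in every cell
  A <- matrix(c(0.01, 0.004, 0, 0, -0.005, 0.002, 0.006, 0, -0.02), 3, 3,
              byrow = TRUE)
  af <- displacement_grid_from_function(fx$grid, function(pts) pts %*% t(A))
  sa <- grid_strain(af)
  sym <- (A + t(A)) / 2
  expect_equal(unique(round(sa$exx, 12)), sym[1, 1])
  expect_equal(unique(round(sa$ezz, 12)), sym[3, 3])
  expect_equal(unique(round(sa$exy, 12)), sym[1, 2])
  expect_equal(unique(round(sa$eyz, 12)), sym[2, 3])
  # trace equals the sum of principal strains
  expect_equal(sa$p1 + sa$p2 + sa$p3, sa$exx + sa$eyy + sa$ezz,
               tolerance = 1e-9)

  # smooth sinusoid: cell-centre strain converges at second order in the
  # nodal spacing (error drops ~4x when the spacing halves)
  h <- fx$spec$voxel_size
  per <- 14 * 8 * h
  fun <- function(pts) cbind(30 * sin(2 * pi * pts[, 3] / per), 0 * pts[, 1],
                             0 * pts[, 1])
  err_for <- function(ns) {
    g <- dvc_grid(fx$phantom$grey, ns = ns)
    s <- grid_strain(displacement_grid_from_function(g, fun))
    truth <- 30 * (2 * pi / per) * cos(2 * pi * s$z_um / per) / 2  # exz
    max(abs(s$exz - truth))
  }
  e8 <- err_for(8); e4 <- err_for(4)
  expect_lt(e4, e8 / 2)
})

test_that("zero-strain repeat scans quantify precision", {
  fx <- dvc_fixture()
  # identical images: zero displacement and strain random error
  zs0 <- zero_strain_check(fx$phantom$grey, fx$phantom$grey, fx$mask,
                           fx$grid)
  expect_lt(max(zs0$displacement$sd_um), 1e-9)
  expect_lt(max(zs0$strain$sd_ue), 1e-3)

  # two noise realisations of one geometry: sub-voxel displacement error
  h <- fx$spec$voxel_size
  sigma <- 0.02 * fx$spec$grey_bone
  noisy <- function(seed) grey_volume(
    fx$phantom$grey$data + vertfe:::with_seed(seed,
      array(stats::rnorm(length(fx$phantom$grey$data), 0, sigma),
            dim(fx$phantom$grey$data))), h)
  zs <- zero_strain_check(noisy(41), noisy(42), fx$mask, fx$grid)
  expect_lt(max(zs$displacement$sd_um) / h, 0.1)
})

test_that("precision improves monotonically with nodal spacing", {
  spec <- phantom_spec(dims = c(48, 48, 48), noise_sigma = 0,
                       blur_sigma = 1.0, seed = 7)
  p <- generate_phantom(spec)
  mask <- trim_mask_border(
    build_mask(p$grey, vertfe:::default_low_threshold(p$grey), 2), 3)
  sigma <- 0.02 * spec$grey_bone
  noisy <- function(seed) grey_volume(
    p$grey$data + vertfe:::with_seed(seed,
      array(stats::rnorm(length(p$grey$data), 0, sigma),
            dim(p$grey$data))), spec$voxel_size)
  g1 <- noisy(41); g2 <- noisy(42)
  sds <- vapply(c(8, 16, 32), function(ns) {
    zs <- zero_strain_check(g1, g2, mask, dvc_grid(p$grey, ns = ns))
    max(zs$displacement$sd_um)
  }, 1)
  expect_true(all(diff(sds) < 0))
})
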