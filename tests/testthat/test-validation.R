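test_that("comparison points respect bone membership and the middle slab", {
  # 10-voxel tall full cube mesh with a carved-out pore voxel that
  # contains the grid node at (400, 400, 400) um
  arr <- array(1L, c(10, 6, 6))
  arr[5, 5, 5] <- 0L
  bin <- binary_volume(arr, 100)
  mesh <- build_mesh(bin)
  grid <- dvc_grid(bin, ns = 4)
  disp <- displacement_grid_from_function(
    grid, function(pts) cbind(0 * pts[, 1], 0 * pts[, 2], -0.01 * pts[, 3]))
  bc <- apply_boundary_conditions(mesh, disp)
  sol <- solve_microfe(mesh, elastic_params(10, 0.3), bc, tolerance = 1e-9)

  cmp <- select_comparison_points(disp, mesh, sol, height_fraction = 0.7)
  # slab: mesh height 1000 um, middle 70% = [150, 850]
  expect_true(all(cmp$z_um >= 150 & cmp$z_um <= 850))
  # the node in the pore voxel is excluded
  expect_false(any(cmp$z_um == 400 & cmp$y_um == 400 & cmp$x_um == 400))
  # a mid-height node inside bone is included
  expect_true(any(cmp$z_um == 400 & cmp$y_um == 0 & cmp$x_um == 0))
  # nodes in the bottom 15% are excluded by construction
  expect_false(any(cmp$z_um < 150))
  # predictions track the imposed axial compression (the interior deviates
  # slightly from the nodal field because only the end planes are driven)
  expect_equal(cmp$u_fe_z, -0.01 * cmp$z_um, tolerance = 0.05)
  # measured values are the grid nodal values themselves
  expect_equal(cmp$u_dvc_z, -0.01 * cmp$z_um, tolerance = 1e-12)
})

test_that("Cook's screen removes a gross outlier and spares collinear data", {
  # perfectly collinear data: degenerate distances, nothing removed
  x <- 1:10
  y <- 2 * x + 1
  flt <- cooks_filter(x, y)
  expect_equal(flt$removed, integer(0))

  # 10 collinear points plus one planted gross outlier
  set.seed(7)
  x2 <- c(1:10, 5.5)
  y2 <- c(2 * (1:10) + rnorm(10, 0, 0.05), 40)   # ~10 sigma off the line
  flt2 <- cooks_filter(x2, y2, k = 5)
  expect_equal(flt2$removed, 11L)
  # agreement with the leave-one-out refit definition
  d_loo <- cooks_loo(x2, y2)
  expect_equal(which(d_loo >= 5 * mean(d_loo)), 11L)
  d_pkg <- stats::cooks.distance(stats::lm(y2 ~ x2))
  expect_equal(unname(d_pkg), d_loo, tolerance = 1e-8)

  expect_error(cooks_filter(1:3, 1:3), "4 points")
})

test_that("regression statistics at and around the identity", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.4, 0.7)
  id <- regression_stats(x, x)
  expect_equal(id$slope, 1)
  expect_equal(id$intercept, 0)
  expect_equal(id$r2, 1)
  expect_equal(id$rmse, 0)
  expect_equal(id$max_error, 0)
  expect_equal(id$cc, 1)

  xc <- c(-3, -1.4, 0, 0.6, 1.4, 2.4)   # centred: mean zero
  neg <- regression_stats(xc, -xc)
  expect_equal(neg$cc, -1, tolerance = 1e-12)

  expect_error(regression_stats(rep(1, 5), 1:5), "variance")
  expect_error(regression_stats(1:3, 1:3), "4 points")
})

test_that("Lin's concordance uses population moments", {
  # frozen from direct evaluation of the formula with 1/n moments:
  # s_xy = 2/3, s_x2 = s_y2 = 2/3, (mx - my)^2 = 1 -> 4/3 / (7/3) = 4/7
  expect_equal(lins_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-15)
})

test_that("concordance never exceeds Pearson correlation in magnitude", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(30)
    y <- 0.5 * x + rnorm(30, sd = runif(1, 0.1, 2)) + runif(1, -2, 2)
    expect_lte(abs(lins_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

test_that("force differences reproduce the reference table rows", {
  f <- vertebra_forces()
  d12 <- force_diff(f$af_exp_N, f$af_fe_12gpa_N, f$specimen_id)
  expect_equal(d12$pct_diff_rounded[d12$specimen_id == "S#1"], 133)
  expect_equal(d12$pct_diff_rounded[d12$specimen_id == "S#2"], 80)
  d46 <- force_diff(f$af_exp_N, f$af_fe_4p6gpa_N, f$specimen_id)
  expect_equal(d46$pct_diff_rounded[d46$specimen_id == "S#3"], 80)
  expect_equal(force_diff(100, 100)$pct_diff, 0)
  expect_error(force_diff(-5, 10), "positive")
})

test_that("back-calculation has the closed-form properties", {
  f <- vertebra_forces()
  bc <- back_calculate_modulus(f$af_fe_12gpa_N, f$af_exp_N, e_ref = 12.0)
  expect_equal(round(bc$e_backcalc, 1), 4.6)

  expect_equal(back_calculate_modulus(c(10, 20), c(10, 20), 7)$e_backcalc, 7)
  expect_equal(back_calculate_modulus(2 * c(10, 20), c(10, 20),
                                      12)$e_backcalc, 6)
  # scale equivariance: scaling the predictions by c divides the scale by c
  b1 <- back_calculate_modulus(f$af_fe_12gpa_N, f$af_exp_N, 12)
  b2 <- back_calculate_modulus(3 * f$af_fe_12gpa_N, f$af_exp_N, 12)
  expect_equal(b2$scale, b1$scale / 3, tolerance = 1e-12)
  expect_error(back_calculate_modulus(c(0, 0), c(1, 2), 12), "zero")

  td <- tidy(bc)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$n, 4)
})

test_that("per-direction validation applies the screen then regresses", {
  set.seed(3)
  n <- 40
  base <- tibble::tibble(
    node = 1:n,
    x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000),
    z_um = runif(n, 0, 1000),
    u_dvc_x = rnorm(n), u_dvc_y = rnorm(n), u_dvc_z = rnorm(n, 0, 10))
  base$u_fe_x <- base$u_dvc_x + rnorm(n, 0, 0.05)
  base$u_fe_y <- base$u_dvc_y + rnorm(n, 0, 0.05)
  base$u_fe_z <- base$u_dvc_z + rnorm(n, 0, 0.05)
  class(base) <- c("comparison_table", class(base))
  out <- validate_displacements(base)
  expect_equal(nrow(out), 3)
  expect_true(all(out$cc > 0.99))
  expect_true(all(out$slope > 0.9 & out$slope < 1.1))
})
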