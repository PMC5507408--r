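make_cube_volume <- function(dims = c(11, 11, 11), lo = 4, hi = 8,
                             bright = 200, dark = 10) {
  arr <- array(dark, dims)
  arr[lo:hi, lo:hi, lo:hi] <- bright
  grey_volume(arr, 39)
}

test_that("build_mask dilates, fills holes and rejects empty masks", {
  vol <- make_cube_volume()
  m <- build_mask(vol, low_threshold = 100, dilation_radius = 1)
  expect_true(all(m$data[4:8, 4:8, 4:8] == 1))      # covers the cube
  expect_true(all(m$data[3:9, 3:9, 3:9] == 1))      # expanded by 1 voxel
  expect_equal(m$data[1, 1, 1], 0L)

  # hollow bright shell: dark core must be filled
  arr <- array(10, c(11, 11, 11))
  arr[3:9, 3:9, 3:9] <- 200
  arr[5:7, 5:7, 5:7] <- 10
  hm <- build_mask(grey_volume(arr, 39), 100, 0)
  expect_true(all(hm$data[5:7, 5:7, 5:7] == 1))

  expect_error(build_mask(grey_volume(array(0, c(5, 5, 5)), 39), 10), "empty")
})

test_that("masked Otsu threshold matches an exhaustive scan and the midpoint", {
  set.seed(42)
  v <- c(rnorm(4000, 80, 10), rnorm(4000, 180, 10))
  dims <- c(20, 20, 20)
  vol <- grey_volume(array(v, dims), 39)
  mask <- mask_volume(array(1L, dims), 39)
  thr <- suggest_threshold(vol, mask)

  # oracle: exhaustive scan over all 256 candidate bin edges, computing the
  # between-class variance directly from the data; the criterion plateaus
  # across the near-empty gap between modes, so the plateau midpoint is the
  # deterministic optimum
  edges <- seq(min(v), max(v), length.out = 257)[2:256]
  bcv <- vapply(edges, function(t) {
    a <- v[v < t]; b <- v[v >= t]
    if (length(a) == 0 || length(b) == 0) return(-Inf)
    length(a) * length(b) * (mean(a) - mean(b))^2
  }, 1)
  plateau <- which(bcv >= max(bcv) * (1 - 1e-12))
  expect_equal(thr, edges[plateau[ceiling(length(plateau) / 2)]],
               tolerance = 1e-12)
  # equal-weight equal-variance modes: threshold near the analytic midpoint
  expect_lt(abs(thr - 130), 3)

  expect_error(suggest_threshold(grey_volume(array(5, dims), 39), mask),
               "degenerate")
})

test_that("segment applies threshold within the mask and records it", {
  vol <- make_cube_volume()
  mask <- build_mask(vol, 100, 1)
  b <- segment(vol, mask, 100)
  expect_s3_class(b, "binary_volume")
  expect_equal(sum(b$data), 5^3)
  expect_equal(b$threshold_used, 100)
  expect_equal(sum(segment(vol, mask, min(vol$data))$data), sum(mask$data))
  expect_error(segment(vol, mask, max(vol$data) + 1), "no bone")
})

test_that("connectivity filter keeps the largest face-connected component", {
  # two cubes touching only along an edge: edge contact is not face contact
  arr <- array(0L, c(10, 10, 10))
  arr[2:4, 2:4, 2:4] <- 1L   # 27 voxels
  arr[5:6, 5:6, 2:4] <- 1L   # 12 voxels, shares only the edge at (4/5,4/5,.)
  b <- connectivity_filter(binary_volume(arr, 39))
  expect_equal(sum(b$data), 27)
  expect_true(all(b$data[5:6, 5:6, 2:4] == 0))

  single <- binary_volume(array(c(1L, rep(0L, 7)), c(2, 2, 2)), 39)
  expect_identical(connectivity_filter(single)$data, single$data)
})

test_that("connectivity filter agrees with a brute-force flood fill", {
  arr <- vertfe:::with_seed(99,
    array(as.integer(runif(20^3) < 0.3), c(20, 20, 20)))
  got <- connectivity_filter(binary_volume(arr, 39))
  expect_identical(got$data, flood_fill_largest(arr))
  # idempotence
  expect_identical(connectivity_filter(got)$data, got$data)
})

test_that("crop_fraction keeps the centred rounded slab", {
  vol <- grey_volume(array(rep(1:10, each = 1, times = 4 * 4),
                           c(10, 4, 4)) * 0 +
                       array(rep(1:10, times = 16), c(10, 4, 4)), 39)
  # N = 10, fraction 0.5: slices 3..7 (1-based), i.e. 0-based [2, 7)
  c5 <- crop_fraction(vol, 0.5)
  expect_equal(dim(c5$data), c(5, 4, 4))
  expect_equal(c5$data[, 1, 1], 3:7)
  # fraction 1 is the identity for every volume type
  expect_identical(crop_fraction(vol, 1)$data, vol$data)
  m <- mask_volume(array(1L, c(10, 4, 4)), 39)
  expect_identical(crop_fraction(m, 1)$data, m$data)
  # N = 11, fraction 0.7: round(7.7) = 8 slices, offset floor(3/2) = 1
  v11 <- grey_volume(array(rep(1:11, times = 16), c(11, 4, 4)), 39)
  c7 <- crop_fraction(v11, 0.7)
  expect_equal(dim(c7$data)[1], 8)
  expect_equal(c7$data[, 1, 1], 2:9)
  expect_error(crop_fraction(vol, 0), "fraction")
})

test_that("BV/TV counts bone over mask and is monotone in the threshold", {
  vol <- make_cube_volume()
  mask <- build_mask(vol, 100, 1)
  bin <- segment(vol, mask, 100)
  expect_equal(bone_volume_fraction(bin, mask), sum(bin$data) / sum(mask$data))
  full <- segment(vol, mask, min(vol$data))
  expect_equal(bone_volume_fraction(full, mask), 1.0)

  # raising the threshold never increases BV/TV
  p <- generate_phantom(phantom_spec(dims = c(24, 24, 24),
                                     shell_thickness = 39, seed = 5))
  m <- mask_volume(array(1L, c(24, 24, 24)), p$grey$voxel_size)
  thr <- seq(min(p$grey$data) + 1, max(p$grey$data) - 1, length.out = 8)
  bv <- vapply(thr, function(t)
    bone_volume_fraction(segment(p$grey, m, t), m), 1)
  expect_true(all(diff(bv) <= 0))

  small <- binary_volume(array(c(1L, rep(0L, 124)), c(5, 5, 5)), 39)
  wrong <- mask_volume(array(c(0L, 1L, rep(0L, 123)), c(5, 5, 5)), 39)
  expect_error(bone_volume_fraction(small, wrong), "outside the mask")
})

test_that("cortical/trabecular split matches phantom construction labels", {
  spec <- phantom_spec(dims = c(40, 40, 40), shell_thickness = 3 * 39,
                       noise_sigma = 0, seed = 21)
  p <- generate_phantom(spec)
  lab <- split_cortical_trabecular(p$bone, shell_depth = 3)
  bone_idx <- p$bone$data == 1L
  # labels partition the bone voxels exactly
  expect_identical(lab$data > 0L, bone_idx)
  agreement <- mean(lab$data[bone_idx] == p$labels$data[bone_idx])
  expect_gte(agreement, 0.95)

  # purely trabecular phantom: no voxel labelled cortical
  p0 <- generate_phantom(phantom_spec(dims = c(32, 32, 32),
                                      shell_thickness = 0, seed = 3))
  lab0 <- split_cortical_trabecular(p0$bone, shell_depth = 3)
  expect_equal(sum(p0$labels$data == 2L), 0)
  expect_error(split_cortical_trabecular(p0$bone, shell_depth = 0),
               "shell_depth")
})

test_that("trim_mask_border clears exactly the requested layers", {
  m <- mask_volume(array(1L, c(10, 10, 10)), 39)
  t2 <- trim_mask_border(m, 2)
  expect_equal(sum(t2$data), 6^3)
  expect_true(all(t2$data[3:8, 3:8, 3:8] == 1))
})
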