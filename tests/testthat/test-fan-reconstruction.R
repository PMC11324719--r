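# Fan geometry and parallel-plane reconstruction.

test_that("frame_pixel_to_world follows the rotation-with-offset geometry", {
  fr <- fan_frame(matrix(0, 40, 30), angle_deg = 0,
                  in_plane_spacing = c(0.5, 0.5), offset_mm = 2)
  # theta = 0, u = 0: 2 mm offset straight anterior
  expect_equal(frame_pixel_to_world(fr, 0, 4), cbind(x = 2, y = 0, z = 2),
               ignore_attr = TRUE)
  # theta = 90, depth 10 mm -> y = 12, z = 0
  fr90 <- fan_frame(matrix(0, 40, 30), 90, c(0.5, 0.5), 2)
  w <- frame_pixel_to_world(fr90, 20, 0)  # u*su = 10
  expect_equal(as.numeric(w), c(0, 12, 0), tolerance = 1e-12)
  # theta = 30, depth 10 mm -> y = 6, z = 12 cos 30
  fr30 <- fan_frame(matrix(0, 40, 30), 30, c(0.5, 0.5), 2)
  w <- frame_pixel_to_world(fr30, 20, 10)
  expect_equal(as.numeric(w), c(5, 6, 12 * sqrt(3) / 2), tolerance = 1e-12)

  expect_error(frame_pixel_to_world(fr, 40, 0), "bounds")
  expect_error(frame_pixel_to_world(fr, 0, -1), "bounds")
})

test_that("single zero-angle frame reconstructs to one identity plane", {
  px <- matrix(runif(40 * 30), 40, 30)
  fr <- fan_frame(px, 0, c(0.5, 0.5), offset_mm = 2)
  vol <- reconstruct_volume(fan_sweep(list(fr)))
  expect_equal(dim(vol$voxels)[2], 1)             # one plane at y = 0
  expect_equal(vol$origin[2], 0)
  # values equal the frame's: voxel (ix, 1, iz) <- pixel (u = iz offset rows)
  # z grid starts at the offset, so the mapping is exact
  expect_equal(vol$voxels[, 1, ], t(px), ignore_attr = TRUE)
})

test_that("uniform cylinder phantom reconstructs exactly inside", {
  # analytic scene: cylinder along x, radius 10 mm, centred (y=0, z=24)
  xs <- seq(0, 40, 1); ys <- seq(-20, 20, 1); zs <- seq(4, 44, 1)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X <- rep(xs, ny * nz); Y <- rep(rep(ys, each = nx), nz)
  Z <- rep(zs, each = nx * ny)
  inside <- (Y^2 + (Z - 24)^2) <= 10^2
  vol <- image_volume(array(as.numeric(inside) * 0.8, c(nx, ny, nz)),
                      c(1, 1, 1), c(0, -20, 4))
  scene <- structure(list(intensity_volume = vol), class = "phantom_scene")
  sw <- simulate_fan_sweep(scene, n_frames = 150, angle_range = c(-40, 40),
                           in_plane_spacing = c(0.5, 0.5), noise_sd = 0)
  rec <- reconstruct_volume(sw)
  # voxels strictly inside the cylinder (2 mm margin) hold the constant
  ax <- lapply(1:3, function(k) vol_axis(rec, k))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  deep <- (pts[, 2]^2 + (pts[, 3] - 24)^2) <= (10 - 2)^2 &
    pts[, 1] > 2 & pts[, 1] < 38
  expect_lt(max(abs(as.vector(rec$voxels)[deep] - 0.8)), 1e-6)
  # thresholded cylinder volume within 5% of analytic pi r^2 h
  vox <- sum(rec$voxels > 0.4) * prod(rec$spacing)
  analytic <- pi * 10^2 * 40
  expect_lt(abs(vox - analytic) / analytic, 0.05)
})

test_that("populated plane count matches the geometric bound", {
  # +/-60 deg sweep, max radial depth 40 mm at 2 mm offset:
  # y extent = +/- 42 sin 60 = +/- 36.4 -> 72-74 one-mm planes
  nu <- 81  # r = 2 + 0.5 * 80 = 42 mm
  frames <- lapply(seq(-60, 60, length.out = 121), function(a)
    fan_frame(matrix(1, nu, 5), a, c(0.5, 0.5), 2))
  rec <- reconstruct_volume(fan_sweep(frames), fill_holes = FALSE)
  expect_gte(dim(rec$voxels)[2], 72)
  expect_lte(dim(rec$voxels)[2], 74)
})

test_that("mean binning is order-independent and halfwidth is monotone", {
  sw <- fixture_sweep()
  rec1 <- reconstruct_volume(sw)
  perm <- sample(length(sw$frames))
  sw2 <- fan_sweep(sw$frames[perm])
  rec2 <- reconstruct_volume(sw2)
  expect_identical(rec1$voxels, rec2$voxels)

  # larger bin halfwidth never increases unfilled voxels (compared on the
  # common grid region)
  a <- reconstruct_volume(sw, bin_halfwidth_mm = 0.5, fill_holes = FALSE)
  b <- reconstruct_volume(sw, bin_halfwidth_mm = 0.8, fill_holes = FALSE)
  common_y <- intersect(round(vol_axis(a, 2)), round(vol_axis(b, 2)))
  ia <- match(common_y, round(vol_axis(a, 2)))
  ib <- match(common_y, round(vol_axis(b, 2)))
  na_a <- sum(!a$support[, ia, ])
  na_b <- sum(!b$support[, ib, ])
  expect_lte(na_b, na_a)
})

test_that("world-to-plane binning matches a brute-force assignment oracle", {
  # single-pixel frames at random angles: each contributes one sample at
  # y = offset * sin(theta); with halfwidth = spacing/2 the sample must
  # land on plane round(y / spacing)
  set.seed(31)
  angles <- sort(runif(25, -80, 80))
  frames <- lapply(angles, function(a)
    fan_frame(matrix(a, 1, 1), a, c(1, 1), offset_mm = 30))
  rec <- reconstruct_volume(fan_sweep(frames), plane_spacing_mm = 1,
                            bin_halfwidth_mm = 0.5, fill_holes = FALSE)
  ys <- vol_axis(rec, 2); zs <- vol_axis(rec, 3)
  # brute-force oracle: assign each sample to plane round(y), depth bin
  # round(z), average collisions, and require exact agreement
  y <- 30 * sin(angles * pi / 180)
  z <- 30 * cos(angles * pi / 180)
  key <- paste(round(y), round(z))
  means <- tapply(angles, key, mean)
  for (k in seq_along(means)) {
    jz <- as.numeric(strsplit(names(means)[k], " ")[[1]])
    voxel <- rec$voxels[1, which(ys == jz[1]), which(zs == jz[2])]
    expect_equal(voxel, unname(means[k]))
  }
  expect_equal(sum(rec$support), length(means))
})

test_that("degenerate sweeps are handled", {
  frames <- lapply(1:3, function(i) fan_frame(matrix(1, 10, 4), 0, c(1, 1), 2))
  expect_warning(reconstruct_volume(fan_sweep(frames)), "identical angle")
  expect_error(fan_sweep(list()), "empty")
  # missing angles are interpolated with a warning
  f1 <- fan_frame(matrix(1, 4, 4), 0, c(1, 1), 2)
  f2 <- fan_frame(matrix(1, 4, 4), NA, c(1, 1), 2)
  f3 <- fan_frame(matrix(1, 4, 4), 10, c(1, 1), 2)
  expect_warning(sw <- fan_sweep(list(f1, f2, f3)), "interpolated")
  expect_equal(sw$frames[[2]]$angle_deg, 5)
})
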