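# Image-quality metrics: 50% isocontour recovery, background variability,
# residual lung error and COV profiles.

test_that("VOI50 recovers an analytically constructed hard ball exactly", {
  grid <- voxel_grid(c(30, 30, 30), c(2, 2, 2), origin = c(-29, -29, -29))
  vals <- array(1, c(30, 30, 30))     # background b = 1
  gx <- grid_axis(grid, 1)
  d2 <- outer(outer(gx^2, gx^2, `+`), gx^2, `+`)
  vals[d2 <= 10^2] <- 7               # uniform ball value v = 7
  vol <- image_volume(vals, grid)
  sp <- sphere_spec(c(0, 0, 0), 20, 7)
  res <- voi50_recovery(vol, sp, background_mean = 1)
  expect_equal(res$measured_mean, 7)          # v exactly
  expect_equal(res$recovery_coefficient, 1)
  expect_false(res$invisible)
  expect_equal(res$voi_voxel_count, sum(d2 <= 10^2))
})

test_that("noiseless rasterized 37 mm sphere recovers RC = 1.00 +- 0.01", {
  dx <- 0.5
  n <- 96L
  grid <- voxel_grid(c(n, n, n), rep(dx, 3),
                     origin = rep(-(n - 1) / 2 * dx, 3))
  ph <- phantom_spec(
    sections = list(petiq:::body_section(c(-24, 24),
                                         list(shape = "cylinder",
                                              diameter = 46))),
    spheres = list(sphere_spec(c(0, 0, 0), 37, 10)),
    background_concentration = 1)
  vols <- rasterize(ph, grid, supersample = 4)
  vol <- image_volume(vols$activity, grid)
  res <- voi50_recovery(vol, ph$spheres[[1]], background_mean = 1)
  expect_equal(res$recovery_coefficient, 1, tolerance = 0.01)
})

test_that("invisible spheres are flagged at background level", {
  grid <- voxel_grid(c(20, 20, 20), c(2, 2, 2), origin = c(-19, -19, -19))
  vol <- image_volume(array(2, c(20, 20, 20)), grid)
  sp <- sphere_spec(c(0, 0, 0), 10, 8)
  res <- voi50_recovery(vol, sp, background_mean = 2)
  expect_true(res$invisible)
  expect_equal(res$recovery_coefficient, 2 / 8)
  expect_error(voi50_recovery(vol, sphere_spec(c(500, 0, 0), 10, 8), 2),
               "outside")
})

test_that("RC is non-decreasing in diameter under a fixed blur", {
  # deterministic partial-volume property: blur the noiseless phantom
  w <- fixture("nema10", small_nema_world)
  blurred <- gaussian_postfilter(w$vols$activity, 8, w$grid$spacing)
  vol <- image_volume(blurred, w$grid)
  rt <- recovery_table(vol, w$phantom, background_mean = 1)
  rc <- rt$recovery_coefficient[order(rt$diameter_mm)]
  expect_true(all(diff(rc) >= -1e-9))
})

test_that("background variability is zero for a constant volume", {
  w <- fixture("nema10", small_nema_world)
  vol <- image_volume(array(3, dim(w$vols$activity)), w$grid)
  bv <- background_variability(vol, w$phantom,
                               slice_offsets_mm = c(-10, 0, 10))
  expect_true(all(bv$variability_pct == 0))
  expect_true(all(bv$n_rois_used >= 36))
  # and positive once voxel noise is present
  set.seed(4)
  noisy <- image_volume(array(rpois(length(w$vols$activity), 50),
                              dim(w$vols$activity)), w$grid)
  bv2 <- background_variability(noisy, w$phantom,
                                slice_offsets_mm = c(-10, 0, 10))
  expect_true(all(bv2$variability_pct > 0))
})

test_that("residual lung error is definition arithmetic", {
  w <- fixture("nema10", small_nema_world)
  vals <- array(2, dim(w$vols$activity))
  vals[w$vols$labels == 2L] <- 0.18     # lung at 9% of background
  vol <- image_volume(vals, w$grid)
  le <- residual_lung_error(vol, w$phantom, background_mean = 2,
                            slice_offsets_mm = c(-10, 0, 10))
  expect_equal(le$mean, 9, tolerance = 0.01)
  expect_error(residual_lung_error(vol, w$phantom, background_mean = 0),
               "undefined")
  ph2 <- w$phantom; ph2$lung_insert <- NULL
  expect_error(residual_lung_error(vol, ph2), "no lung insert")
})

test_that("COV per slice uses the sample SD convention", {
  grid <- voxel_grid(c(3, 3, 2), c(2, 2, 2))
  vals <- array(5, c(3, 3, 2))
  vals[1:3, 1, 2] <- c(1, 2, 3)
  mask <- matrix(FALSE, 3, 3); mask[1:3, 1] <- TRUE
  vol <- image_volume(vals, grid)
  cp <- cov_per_slice(vol, mask)
  expect_equal(cp$cov[1], 0)                      # constant slice
  expect_equal(cp$mean[2], 2)
  expect_equal(cp$sd[2], 1)                       # sample (n-1) convention
  expect_equal(cp$cov[2], 0.5)
})

test_that("iid Poisson(100) voxels give COV near 0.10", {
  set.seed(8)
  nvox <- 4000
  vals <- array(rpois(nvox * 3, 100), c(20, 200, 3))
  vol <- image_volume(vals, voxel_grid(c(20, 200, 3), c(2, 2, 2)))
  cp <- cov_per_slice(vol, matrix(TRUE, 20, 200))
  expect_equal(mean(cp$cov), 0.10, tolerance = 0.01)
})

test_that("overlap annotation marks shared slices", {
  geom <- bed_geometry(9, 3, 2)
  vol <- image_volume(array(1, c(4, 4, 15)), voxel_grid(c(4, 4, 15), 2))
  cp <- cov_per_slice(vol, matrix(TRUE, 4, 4), geom)
  expect_equal(which(cp$in_overlap), 7:9)
  expect_equal(cp$n_beds[1], 1)
})
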