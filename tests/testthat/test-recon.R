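# Reconstruction: OSEM/MLEM, BSREM-RDP, post-filters and bed stitching.

test_that("OSEM on noiseless data converges to the ground truth interior", {
  w <- fixture("disk_noiseless", small_disk_world)
  cfg <- recon_config("OSEM", iterations = 40, subsets = 4,
                      postfilter_fwhm = 0, axial_weights = c(0, 1, 0))
  vol <- osem_reconstruct(w$sinos, cfg)
  truth <- w$vols$activity[, , 2]
  # deep interior: exclude the boundary ring where edge ringing persists
  er <- background_mask(w$vols, margin_mm = 14, slice = 2)
  rel <- abs(vol$values[, , 2][er] - truth[er]) / truth[er]
  expect_lt(max(rel), 0.02)
  expect_true(all(vol$values >= 0))
  # consistency: the error decreases from the first iteration
  cfg1 <- cfg; cfg1$iterations <- 1L
  vol1 <- osem_reconstruct(w$sinos, cfg1)
  rel1 <- abs(vol1$values[, , 2][er] - truth[er]) / truth[er]
  expect_lt(mean(rel), mean(rel1))
})

test_that("matched projector reproduces the data from the converged image", {
  w <- fixture("disk_noiseless", small_disk_world)
  cfg <- recon_config("OSEM", iterations = 40, subsets = 4,
                      postfilter_fwhm = 0, axial_weights = c(0, 1, 0))
  vol <- osem_reconstruct(w$sinos, cfg)
  fp <- forward_project(vol$values[, , 2], w$vols$attenuation[, , 2],
                        4, w$acq, sensitivity = w$sinos$profile[2],
                        time_s = petiq:::effective_scan_seconds(60))
  ref <- w$sinos$expected[[1]][, , 2]
  sig <- ref > 0.05 * max(ref)
  expect_lt(max(abs(fp$expected[sig] - ref[sig]) / ref[sig]), 0.02)
})

test_that("MLEM log-likelihood is non-decreasing over iterations", {
  w <- fixture("disk_noisy", function() small_disk_world(FALSE))
  bed <- petiq:::.reconstruct_bed(w$sinos, 1,
                                  recon_config("OSEM", iterations = 8,
                                               subsets = 1,
                                               postfilter_fwhm = 0),
                                  track = TRUE)
  tr <- attr(bed, "traces")[[2]]
  expect_length(tr, 8)
  expect_true(all(diff(tr) > -1e-6 * abs(tr[1])))
})

test_that("BSREM with beta 0 and unit relaxation matches OSEM's first pass", {
  w <- fixture("disk_noisy", function() small_disk_world(FALSE))
  osem1 <- petiq:::.recon_single_slice(
    w$sinos, 1, 2, recon_config("OSEM", iterations = 1, subsets = 12,
                                postfilter_fwhm = 0))
  bpl1 <- petiq:::.recon_single_slice(
    w$sinos, 1, 2, recon_config("BPL", subsets = 12, beta = 0,
                                bpl_max_passes = 1, relax0 = 1,
                                postfilter_fwhm = 0))
  expect_lt(max(abs(osem1 - bpl1)), 1e-10)
})

test_that("background COV decreases strictly with beta on fixed data", {
  w <- fixture("disk_noisy", function() small_disk_world(FALSE))
  mask <- background_mask(w$vols, margin_mm = 12)
  covs <- vapply(c(0.05, 0.3, 1.5), function(b) {
    img <- petiq:::.recon_single_slice(
      w$sinos, 1, 2, recon_config("BPL", subsets = 12, beta = b,
                                  bpl_max_passes = 30))
    sd(img[mask]) / mean(img[mask])
  }, numeric(1))
  expect_true(all(diff(covs) < 0))
  # and the roughness penalty of the output is non-increasing in beta
  pens <- vapply(c(0.05, 0.3, 1.5), function(b) {
    img <- petiq:::.recon_single_slice(
      w$sinos, 1, 2, recon_config("BPL", subsets = 12, beta = b,
                                  bpl_max_passes = 30))
    rdp_penalty(img, beta = 1, gamma = 2)$value
  }, numeric(1))
  expect_true(all(diff(pens) < 0))
})

test_that("penalized objective is non-decreasing under the relaxation", {
  w <- fixture("disk_noisy", function() small_disk_world(FALSE))
  bed <- petiq:::.reconstruct_bed(w$sinos, 1,
                                  recon_config("BPL", subsets = 12,
                                               beta = 0.5,
                                               bpl_max_passes = 15),
                                  track = TRUE)
  tr <- attr(bed, "traces")[[2]]
  expect_gt(length(tr), 3)
  expect_true(all(diff(tr) > -1e-5 * abs(tr[1])))
})

test_that("recon config is validated", {
  w <- fixture("disk_noisy", function() small_disk_world(FALSE))
  expect_error(osem_reconstruct(w$sinos, recon_config("OSEM", subsets = 7)),
               "divide")
  expect_error(recon_config("BPL", beta = -1), "beta")
  expect_error(osem_reconstruct(w$sinos, recon_config("BPL")), "bsrem")
})

test_that("Gaussian post-filter: identity, mass preservation, FWHM", {
  arr <- array(rexp(20 * 20 * 5), c(20, 20, 5))
  expect_identical(gaussian_postfilter(arr, 0, c(2, 2, 2)), arr)
  # interior support: totals preserved by the renormalized kernel
  pad <- array(0, c(40, 40, 21)); pad[11:30, 11:30, 9:13] <- arr
  sm <- gaussian_postfilter(pad, 6.4, c(2, 2, 3))
  expect_equal(sum(sm), sum(pad), tolerance = 1e-6)
  # delta response has the configured FWHM within half a voxel
  d <- array(0, c(41, 41, 1)); d[21, 21, 1] <- 1
  r <- gaussian_postfilter(d, 6.4, c(2, 2, 2))[, 21, 1]
  half <- max(r) / 2
  above <- which(r >= half)
  crossings <- c(min(above) - (r[min(above)] - half) /
                   (r[min(above)] - r[min(above) - 1]),
                 max(above) + (r[max(above)] - half) /
                   (r[max(above)] - r[max(above) + 1]))
  fwhm_mm <- diff(crossings) * 2
  expect_lt(abs(fwhm_mm - 6.4), 1)
})

test_that("axial weighted filter follows the convolution arithmetic", {
  arr <- array(rexp(6 * 6 * 9), c(6, 6, 9))
  expect_identical(axial_weighted_filter(arr, c(0, 1, 0)), arr)
  const <- array(2, c(6, 6, 9))
  expect_equal(axial_weighted_filter(const, c(1, 4, 1)), const,
               tolerance = 1e-12)
  # alternating +-1 pattern is scaled by (4 - 2)/6 = 1/3 in the interior
  alt <- aperm(array(rep(c(1, -1), length.out = 9), c(9, 6, 6)), c(2, 3, 1))
  f <- axial_weighted_filter(alt, c(1, 4, 1))
  expect_equal(f[1, 1, 5], alt[1, 1, 5] / 3, tolerance = 1e-12)
})

test_that("stitching is a sensitivity-weighted seamless combination", {
  geom1 <- bed_geometry(9, 3, 1)
  prof <- axial_sensitivity(9)
  v <- array(rexp(8 * 8 * 9), c(8, 8, 9))
  expect_equal(stitch_beds(list(v), prof, geom1), v, tolerance = 1e-12)
  # two beds of the same uniform volume: no seam
  geom2 <- bed_geometry(9, 3, 2)
  u <- array(5, c(8, 8, 9))
  st <- stitch_beds(list(u, u), prof, geom2)
  expect_equal(dim(st)[3], 15)
  expect_lt(max(abs(apply(st, 3, mean) - 5)), 1e-6)
  # overlap slices of independent noise: variance at most the worst input
  set.seed(9)
  reps <- 400
  var_in <- var_out <- numeric(reps)
  for (r in seq_len(reps)) {
    a <- array(rnorm(8 * 8 * 9), c(8, 8, 9))
    b <- array(rnorm(8 * 8 * 9), c(8, 8, 9))
    s <- stitch_beds(list(a, b), prof, geom2)
    var_in[r] <- a[1, 1, 8]    # overlap slice 8 of bed 1 = global slice 8
    var_out[r] <- s[1, 1, 8]
  }
  expect_lt(var(var_out), var(var_in))
  expect_error(stitch_beds(list(u, u[, , 1:5]), prof, geom2),
               "inconsistent")
})
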