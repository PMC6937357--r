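# Dose rule, cohort synthesis and the (scaled-down) experiment drivers.

test_that("dose rule applies the quadratic formula with the 120 MBq floor", {
  expect_equal(prescribe_activity(61), 120)          # 0.027*61^2 = 100.5
  expect_equal(prescribe_activity(80), 0.027 * 6400)  # 172.8
  wb <- sqrt(120 / 0.027)                            # floor boundary
  expect_equal(prescribe_activity(wb), 120)
  expect_equal(prescribe_activity(wb + 1e-6), 0.027 * (wb + 1e-6)^2)
  expect_error(prescribe_activity(0), "> 0")
  # continuous and non-decreasing; floor binds exactly below the boundary
  W <- seq(40, 90, by = 0.5)
  A <- prescribe_activity(W)
  expect_true(all(diff(A) >= 0))
  expect_true(all(A[W < wb] == 120))
  expect_true(all(A[W > wb] > 120))
})

test_that("cohort synthesis respects the selection rules", {
  cohort <- synthesize_cohort(8, seed = 5)
  expect_length(cohort, 8)   # 0.027*75^2 = 151.9 < 160: nobody filtered
  for (p in cohort) {
    expect_gte(p$administered_activity, 120)
    expect_lt(p$administered_activity, 160)
    expect_gte(p$weight, 44); expect_lte(p$weight, 75)
    expect_equal(sum(p$bed_plan$region == "leg"), 2)
    expect_equal(p$bed_plan$time_s, c(60, 60, 150))
    expect_gte(length(p$lesion_diameters), 1)
  }
  expect_identical(synthesize_cohort(8, seed = 5), cohort)
  expect_error(synthesize_cohort(0, seed = 1), ">= 1")
  expect_error(synthesize_cohort(3, seed = NULL), "seed")
  expect_error(synthesize_cohort(5, weight_range = c(80, 90), seed = 1,
                                 max_activity = 160), "empty cohort")
})

test_that("contrast series emits the full condition grid, reproducibly", {
  grid <- voxel_grid(c(64, 64, 13), c(5, 5, DZ))
  acq <- acquisition_config(seed = 1, angles = 48, calibration = 0.02)
  recons <- list(OSEM = recon_config("OSEM", subsets = 12),
                 BPL_low = recon_config("BPL", subsets = 12, beta = 0.3,
                                        bpl_max_passes = 8))
  res <- run_contrast_series(grid, acq, recons, ratio_cases = "10:1",
                             seed = 42, supersample = 2)
  expect_equal(nrow(res$recovery), 2 * (6 + 5))  # recons x (NEMA + micro)
  expect_setequal(unique(res$recovery$phantom), c("nema", "micro"))
  expect_true(all(c("recovery_coefficient", "invisible", "beta",
                    "ratio_case") %in% names(res$recovery)))
  expect_equal(nrow(res$lung), 2)                # NEMA only
  res2 <- run_contrast_series(grid, acq, recons, ratio_cases = "10:1",
                              seed = 42, supersample = 2)
  expect_identical(res$recovery, res2$recovery)  # bit-identical re-run
  # wide layout: one row per (phantom, sphere), one column per recon
  wide <- recovery_wide(res$recovery, "10:1")
  expect_equal(nrow(wide), 11)
  expect_true(all(c("OSEM", "BPL_low") %in% names(wide)))
})

test_that("time series: COV drops with time; thinning to source is exact", {
  geom <- bed_geometry(13, 3, 2)
  grid <- voxel_grid(c(64, 64, n_global_slices(geom)), c(5, 5, DZ))
  acq <- acquisition_config(seed = 2, angles = 48, calibration = 0.02)
  recons <- list(OSEM = recon_config("OSEM", subsets = 12))
  res <- run_time_series(grid, geom, acq, recons, times_min = c(1, 5),
                         seed = 31, central_slices = 5)
  cov1 <- res$cov$cov[res$cov$time_min == 1]
  cov5 <- res$cov$cov[res$cov$time_min == 5]
  expect_true(mean(cov1, na.rm = TRUE) > mean(cov5, na.rm = TRUE))
  # per annotation class
  ov <- res$cov$in_overlap
  expect_gt(mean(cov1[ov[res$cov$time_min == 1]], na.rm = TRUE),
            mean(cov5[ov[res$cov$time_min == 5]], na.rm = TRUE))
  expect_true(all(c("counts_per_voxel", "cov") %in% names(res$fit_points)))
})

test_that("overlap study reports edge-vs-centre band metrics", {
  geom <- bed_geometry(9, 3, 3)
  grid <- voxel_grid(c(48, 48, 9), c(6, 6, DZ))
  acq <- acquisition_config(seed = 3, angles = 48, calibration = 0.02)
  recons <- list(OSEM = recon_config("OSEM", subsets = 12))
  res <- run_overlap_study(grid, geom, acq, recons, n_patients = 2,
                           seed = 11, supersample = 1)
  expect_equal(nrow(res$bands), 1)
  expect_true(res$bands$cov_overlap_edge > res$bands$cov_bed_center)
  expect_equal(length(unique(res$profiles$slice)), n_global_slices(geom))
  expect_error(run_overlap_study(grid, bed_geometry(9, 3, 2), acq, recons,
                                 n_patients = 2, seed = 1), ">= 3")
})
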