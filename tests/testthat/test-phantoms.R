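# Phantom construction and rasterization.

test_that("NEMA phantom carries the printed fill concentrations per case", {
  cases <- list("10:1" = c(10, 1), "4:1" = c(6.5, 1.6), "2:1" = c(4.8, 2.6))
  for (nm in names(cases)) {
    ph <- build_nema_iq(nm)
    expect_equal(ph$spheres[[1]]$activity_concentration, cases[[nm]][1])
    expect_equal(ph$background_concentration, cases[[nm]][2])
    expect_length(ph$spheres, 6)
    expect_equal(sort(vapply(ph$spheres, `[[`, numeric(1),
                             "inner_diameter")),
                 c(10, 13, 17, 22, 28, 37))
    expect_equal(ph$lung_insert$diameter, 50)
    # nominal ratio recovered after integer rounding
    expect_equal(round(sphere_to_background_ratio(ph)),
                 as.integer(sub(":.*", "", nm)))
  }
  # alias spelling accepted, unknown case rejected
  expect_equal(build_nema_iq("4-to-1")$background_concentration, 1.6)
  expect_error(build_nema_iq("3:1"), "unknown ratio_case")
})

test_that("micro phantom has 4 spheres equiradial around the 10 mm sphere", {
  ph <- build_micro_sphere("10:1")
  expect_length(ph$spheres, 5)
  expect_equal(sort(vapply(ph$spheres, `[[`, numeric(1), "inner_diameter")),
               c(4, 5, 6, 8, 10))
  ctr <- ph$spheres[[5]]$center
  expect_equal(ctr[1:2], c(0, 0))
  radii <- vapply(ph$spheres[1:4], function(s)
    sqrt(sum((s$center[1:2] - ctr[1:2])^2)), numeric(1))
  expect_equal(radii, rep(radii[1], 4))
  angs <- sort(vapply(ph$spheres[1:4], function(s)
    atan2(s$center[2], s$center[1]), numeric(1)))
  expect_equal(diff(angs), rep(pi / 2, 3))
  expect_equal(build_micro_sphere("2:1")$background_concentration, 2.6)
})

test_that("ratio is undefined for zero background", {
  ph <- build_nema_iq("2:1")
  ph$background_concentration <- 0
  expect_error(sphere_to_background_ratio(ph), "undefined")
})

test_that("patient-like phantom spans beds and validates lesion placement", {
  ph <- build_patient_like(3)
  # 47 + 2 * (47 - 11) slices at the scanner slice pitch
  expect_equal(axial_length(ph) / (157 / 47), 119, tolerance = 1e-12)
  expect_error(build_patient_like(1), "n_beds")
  # lesion outside the leg cross-section
  bad <- sphere_spec(c(120, 0, 50), 10, 5)
  expect_error(build_patient_like(3, lesion_specs = list(bad)),
               "outside the body outline")
  les <- sphere_spec(c(0, 0, 47 / 2 * 157 / 47), 12, 6)
  ph2 <- build_patient_like(3, lesion_specs = list(les))
  grid <- voxel_grid(c(48, 48, 119), c(5, 5, 157 / 47))
  vols <- rasterize(ph2, grid, supersample = 1)
  labs <- setdiff(unique(as.integer(vols$labels)), c(0L, 1L))
  expect_equal(labs, 11L)   # exactly one sphere label
})

test_that("rasterized sphere volumes converge to the analytic volume", {
  grid <- voxel_grid(c(36, 36, 24), c(2, 2, 2),
                     origin = c(-35, -35, -23))
  ph <- phantom_spec(
    sections = list(petiq:::body_section(c(-24, 24),
                                         list(shape = "cylinder",
                                              diameter = 70))),
    spheres = list(sphere_spec(c(0.7, -1.3, 0.4), 37, 10)),
    background_concentration = 1)
  errs <- vapply(c(1, 2, 4), function(s) {
    vols <- rasterize(ph, grid, supersample = s)
    abs(sphere_volume_ml(vols, 1) - sphere_ml(37))
  }, numeric(1))
  expect_lt(errs[3] / sphere_ml(37), 0.01)     # within 1% of 26.5 ml
  expect_lt(errs[3], errs[1] + 1e-9)           # refinement helps overall
})

test_that("rasterization partitions the grid and zeroes the outside", {
  w <- fixture("nema10", small_nema_world)
  vols <- w$vols
  # strictly outside (one voxel beyond any partial-volume boundary ring)
  outside <- vols$labels == 0L
  strict <- outside
  for (k in seq_len(dim(outside)[3])) {
    m <- outside[, , k]; d <- dim(m); e <- m
    e[-1, ] <- e[-1, ] & m[-d[1], ]; e[-d[1], ] <- e[-d[1], ] & m[-1, ]
    e[, -1] <- e[, -1] & m[, -d[2]]; e[, -d[2]] <- e[, -d[2]] & m[, -1]
    strict[, , k] <- e
  }
  expect_true(all(vols$activity[strict] == 0))
  expect_true(all(vols$attenuation[strict] == 0))
  expect_true(all(vols$labels %in% c(0:2, 10 + seq_along(w$phantom$spheres))))
  # lung insert is cold and less attenuating than water
  lung <- vols$labels == 2L
  expect_true(any(lung))
  expect_true(all(vols$activity[lung] < 0.6))
  expect_lt(max(vols$attenuation[lung]), 0.096)
})

test_that("sub-voxel sphere with supersample 1 warns about quantization", {
  grid <- voxel_grid(c(24, 24, 9), c(5, 5, 5))
  ph <- build_micro_sphere("10:1", axial_length_mm = 45,
                           body_diameter_mm = 100)
  expect_warning(rasterize(ph, grid, supersample = 1), "quantized")
})

test_that("empty phantom rasterizes to zero activity", {
  grid <- voxel_grid(c(16, 16, 4), c(5, 5, 5))
  ph <- build_uniform_cylinder(60, 20, 0)
  vols <- rasterize(ph, grid)
  expect_true(all(vols$activity == 0))
})
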