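# Shared fixtures and independent oracles. Heavy objects are built lazily
# and memoized for the session so unit tests stay fast.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

DZ <- 157 / 47

# small single-bed NEMA world used across metric/recon tests
small_nema_world <- function(ratio = "10:1", seed = 7, minutes = 5) {
  nz <- 15L
  grid <- voxel_grid(c(96, 96, nz), c(3.5, 3.5, DZ))
  ph <- build_nema_iq(ratio, axial_length_mm = nz * DZ)
  vols <- rasterize(ph, grid, supersample = 2)
  geom <- bed_geometry(nz, 5L, 1L)
  acq <- acquisition_config(time_per_bed = minutes * 60, seed = seed,
                            angles = 96)
  list(grid = grid, phantom = ph, vols = vols, geom = geom, acq = acq,
       sinos = simulate_acquisition(vols, geom, acq))
}

# independent fine-step ray-marching projector oracle: integrates the
# bilinearly interpolated image along each ray; attenuation from the same
# integral of mu. Completely independent of the Joseph/sparse-matrix path.
oracle_project <- function(activity, attenuation, dx, n_angles, n_radial,
                           step = dx / 20) {
  nx <- nrow(activity); ny <- ncol(activity)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  interp <- function(img, x, y) {
    fx <- x / dx + cx; fy <- y / dx + cy
    i0 <- floor(fx); j0 <- floor(fy)
    wx <- fx - i0; wy <- fy - j0
    val <- numeric(length(x))
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      ok <- ii >= 0 & ii < nx & jj >= 0 & jj < ny
      w <- (if (di == 1) wx else 1 - wx) * (if (dj == 1) wy else 1 - wy)
      val[ok] <- val[ok] + w[ok] * img[cbind(ii[ok] + 1, jj[ok] + 1)]
    }
    val
  }
  half_len <- dx * (nx + ny)   # generous ray support
  ts <- seq(-half_len, half_len, by = step)
  out_act <- matrix(0, n_radial, n_angles)
  out_att <- matrix(0, n_radial, n_angles)
  rc <- (n_radial - 1) / 2
  for (a in seq_len(n_angles)) {
    th <- pi * (a - 1) / n_angles
    dvec <- c(cos(th), sin(th)); nvec <- c(-sin(th), cos(th))
    for (r in seq_len(n_radial)) {
      rr <- (r - 1 - rc) * dx
      px <- rr * nvec[1] + ts * dvec[1]
      py <- rr * nvec[2] + ts * dvec[2]
      out_act[r, a] <- sum(interp(activity, px, py)) * step
      out_att[r, a] <- sum(interp(attenuation, px, py)) * step
    }
  }
  list(activity = out_act, attenuation_line = out_att)
}

# analytic sphere volume in ml
sphere_ml <- function(d_mm) 4 / 3 * pi * (d_mm / 2)^3 / 1000

# small single-slab disk world for reconstruction oracles
small_disk_world <- function(noiseless = TRUE, seed = 21) {
  grid <- voxel_grid(c(48, 48, 3), c(4, 4, 4))
  ph <- build_uniform_cylinder(120, 12, 4)
  vols <- rasterize(ph, grid, supersample = 2)
  geom <- bed_geometry(3, 0, 1)
  acq <- acquisition_config(time_per_bed = 60, seed = seed, angles = 48,
                            psf_fwhm = 0, calibration = 0.05)
  sinos <- simulate_acquisition(vols, geom, acq)
  if (noiseless)
    for (b in seq_along(sinos$counts)) sinos$counts[[b]] <- sinos$expected[[b]]
  list(grid = grid, phantom = ph, vols = vols, geom = geom, acq = acq,
       sinos = sinos)
}
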