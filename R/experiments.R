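# Study drivers: dose prescription and synthetic cohort, beta calibration
# against the OSEM+PSF noise anchor, and the three end-to-end experiments
# (contrast series, acquisition-time series, overlap noise-band study).

#' Quadratic dose rule with a floor
#'
#' Weight-based activity prescription `A = c * W^2` (constant liver SNR)
#' with a minimum administered activity.
#'
#' @param coefficient MBq/kg^2 (default 0.027).
#' @param minimum_activity MBq floor (default 120).
#' @export
dose_rule <- function(coefficient = 0.027, minimum_activity = 120) {
  stopifnot(coefficient > 0, minimum_activity >= 0)
  structure(list(coefficient = coefficient,
                 minimum_activity = minimum_activity), class = "dose_rule")
}

#' Prescribed activity for a patient weight
#' @param W weight in kg, > 0.
#' @param rule a [dose_rule()].
#' @return administered activity, MBq: `max(c * W^2, minimum)`.
#' @export
prescribe_activity <- function(W, rule = dose_rule()) {
  if (any(!is.finite(W)) || any(W <= 0))
    stop("weight must be > 0", call. = FALSE)
  pmax(rule$coefficient * W^2, rule$minimum_activity)
}

#' Synthesize a patient cohort
#'
#' Weights drawn uniformly in `weight_range`, activities from the dose rule,
#' cohort restricted to activities below `max_activity` MBq; each patient
#' gets a bed plan with `n_leg_beds` leg beds at 1 min and one torso bed at
#' 2.5 min, and lesions sampled from a configurable size menu.
#'
#' @param n cohort size, >= 1.
#' @param weight_range kg.
#' @param seed RNG seed (required).
#' @param rule a [dose_rule()].
#' @param max_activity exclusion threshold, MBq.
#' @param lesion_menu_mm lesion diameters to sample from.
#' @param n_leg_beds leg bed positions (>= 2 per the selection criterion).
#' @return list of `patient_spec` lists (weight, administered_activity,
#'   bed_plan, lesion_diameters).
#' @export
synthesize_cohort <- function(n, weight_range = c(44, 75), seed,
                              rule = dose_rule(), max_activity = 160,
                              lesion_menu_mm = c(8, 10, 13, 17, 22),
                              n_leg_beds = 2) {
  if (n < 1) stop("cohort size must be >= 1", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("cohort seed is required", call. = FALSE)
  set.seed(seed)
  weights <- runif(n, weight_range[1], weight_range[2])
  activity <- prescribe_activity(weights, rule)
  keep <- activity < max_activity
  if (!any(keep))
    stop("empty cohort after the < ", max_activity, " MBq filter; widen ",
         "the weight range or adjust the rule", call. = FALSE)
  weights <- weights[keep]; activity <- activity[keep]
  lapply(seq_along(weights), function(i) {
    n_lesions <- sample(1:3, 1)
    list(weight = weights[i], administered_activity = activity[i],
         bed_plan = data.frame(
           bed = seq_len(n_leg_beds + 1L),
           region = c(rep("leg", n_leg_beds), "torso"),
           time_s = c(rep(60, n_leg_beds), 150)),
         lesion_diameters = sample(lesion_menu_mm, n_lesions,
                                   replace = TRUE))
  })
}

# muscle-like activity concentration (kBq/ml) implied by a patient's dose:
# SUV ~ 0.8 in muscle, concentration = SUV * activity / weight
patient_background_kbq_ml <- function(spec, suv_muscle = 0.8)
  suv_muscle * spec$administered_activity / spec$weight

# realize a patient spec as a phantom on a given bed geometry
patient_phantom <- function(spec, geometry, dz_mm,
                            lesion_contrast = 4) {
  n_beds <- nrow(spec$bed_plan)
  bg <- patient_background_kbq_ml(spec)
  pitch <- geometry$pitch
  lesions <- list()
  if (length(spec$lesion_diameters)) {
    # lesions at torso-bed centre height, spread in-plane
    zc <- ((n_beds - 1) * pitch + geometry$slices_per_bed / 2) * dz_mm
    xs <- seq(-40, 40, length.out = length(spec$lesion_diameters))
    lesions <- lapply(seq_along(spec$lesion_diameters), function(i)
      sphere_spec(c(xs[i], 15, zc), spec$lesion_diameters[i],
                  lesion_contrast * bg))
  }
  build_patient_like(n_beds = n_beds, lesion_specs = lesions,
                     background_concentration = bg,
                     slices_per_bed = geometry$slices_per_bed,
                     overlap_slices = geometry$overlap_slices,
                     dz_mm = dz_mm)
}

# single-slice reconstruction (used by the beta calibration and tests)
.recon_single_slice <- function(sinos, bed, slice, config) {
  nx <- sinos$grid$shape[1]; ny <- sinos$grid$shape[2]
  nr <- dim(sinos$counts[[bed]])[1]
  model <- projection_model(nx, ny, sinos$dx, sinos$config$angles, nr)
  subs <- .subset_models(model, config$subsets)
  eff_s <- effective_scan_seconds(sinos$times_s[bed],
                                  sinos$bed_start_min[bed],
                                  sinos$config$half_life)
  scale <- sinos$config$calibration * eff_s * sinos$profile[slice]
  sys <- .slice_system(as.numeric(sinos$counts[[bed]][, , slice]),
                       as.numeric(sinos$attenuation_factors[[bed]][, , slice]),
                       scale, model, subs,
                       fwhm_to_sigma(.model_psf(config, sinos)),
                       config$epsilon)
  res <- if (config$algorithm == "BPL")
    .bsrem_slice(sys, nx, ny, config) else
    .osem_slice(sys, nx * ny, config$iterations)
  img <- matrix(res$x, nx, ny)
  # in-plane part of the configured post-filter (single-slice context)
  if (config$postfilter_fwhm > 0)
    img <- gaussian_postfilter(img, config$postfilter_fwhm,
                               sinos$grid$spacing)
  img
}

.slice_cov <- function(img2d, mask) {
  v <- img2d[mask]
  sd(v) / mean(v)
}

#' Calibrate penalty-weight analogues against the OSEM+PSF noise anchor
#'
#' The vendor's beta scale does not transfer to this simulator, so the
#' high-beta analogue is defined operationally: the beta at which the BPL
#' background COV matches the OSEM+PSF background COV on the same (1 min)
#' data -- the published empirical anchor for beta = 700. The mid and low
#' analogues keep the vendor's ratios, beta_mid = beta_high * 550/700 and
#' beta_low = beta_high * 450/700.
#'
#' @param sinos a `sinogram_set` (1 min/bed for the anchor condition).
#' @param mask logical in-plane background mask for the COV.
#' @param bed,slice where the COV is measured (default: bed 1 centre slice).
#' @param osem_config the anchor reconstruction.
#' @param bpl_base a `recon_config("BPL")` providing everything but beta.
#' @param beta_range bracketing interval for the bisection.
#' @param tol relative COV-match tolerance.
#' @param max_iter bisection iterations.
#' @return list(beta_low, beta_mid, beta_high, target_cov, achieved_cov,
#'   betas = named vector of the three analogues).
#' @export
calibrate_beta <- function(sinos, mask, bed = 1,
                           slice = (sinos$geometry$slices_per_bed + 1) %/% 2,
                           osem_config = recon_config("OSEM_PSF"),
                           bpl_base = recon_config("BPL"),
                           beta_range = c(1e-4, 50), tol = 0.02,
                           max_iter = 20) {
  target <- .slice_cov(.recon_single_slice(sinos, bed, slice, osem_config),
                       mask)
  cov_at <- function(beta) {
    cfg <- bpl_base; cfg$beta <- beta
    .slice_cov(.recon_single_slice(sinos, bed, slice, cfg), mask)
  }
  lo <- beta_range[1]; hi <- beta_range[2]
  c_lo <- cov_at(lo); c_hi <- cov_at(hi)
  if (c_lo < target)
    stop("beta_range[1] already smoother than the OSEM+PSF anchor; ",
         "lower it", call. = FALSE)
  if (c_hi > target)
    stop("beta_range[2] still noisier than the OSEM+PSF anchor; raise it",
         call. = FALSE)
  beta <- achieved <- NA_real_
  for (i in seq_len(max_iter)) {
    beta <- sqrt(lo * hi)      # bisect in log space
    achieved <- cov_at(beta)
    if (abs(achieved - target) / target < tol) break
    if (achieved > target) lo <- beta else hi <- beta
  }
  list(beta_high = beta, beta_mid = beta * 550 / 700,
       beta_low = beta * 450 / 700, target_cov = target,
       achieved_cov = achieved,
       betas = c(low = beta * 450 / 700, mid = beta * 550 / 700,
                 high = beta))
}

#' Standard reconstruction-setting list
#'
#' OSEM, OSEM+PSF and one BPL entry per supplied beta analogue (named
#' `BPL_<name>`), as used by the experiment drivers.
#'
#' @param betas named numeric vector of penalty weights (e.g. from
#'   [calibrate_beta()]`$betas`).
#' @param subsets ordered subsets for every setting.
#' @param bpl_base template `recon_config("BPL")` for the BPL entries.
#' @return named list of `recon_config`s.
#' @export
recon_setting_list <- function(betas, subsets = 24, bpl_base = NULL) {
  if (is.null(bpl_base)) bpl_base <- recon_config("BPL", subsets = subsets)
  out <- list(
    OSEM = recon_config("OSEM", subsets = subsets),
    OSEM_PSF = recon_config("OSEM_PSF", subsets = subsets))
  for (nm in names(betas)) {
    cfg <- bpl_base
    cfg$subsets <- as.integer(subsets)
    cfg$beta <- unname(betas[nm])
    out[[paste0("BPL_", nm)]] <- cfg
  }
  out
}

#' Printed scan duration (minutes) for each contrast case
#' @param ratio_case `"10:1"`, `"4:1"` or `"2:1"`.
#' @export
scan_minutes_for_case <- function(ratio_case) {
  key <- .normalize_ratio_case(ratio_case)
  switch(key, "10:1" = 5, "4:1" = 7 + 10 / 60, "2:1" = 10)
}

#' Contrast-ratio series (recovery and lung-error tables)
#'
#' For each requested sphere-to-background case, simulates both phantoms at
#' the printed scan duration, reconstructs with every recon setting and
#' emits a recovery-coefficient table (one row per phantom x sphere x
#' setting) and a residual-lung-error table (NEMA only).
#'
#' @param grid a `voxel_grid` for one bed.
#' @param acq an `acquisition_config` (time is overridden per case).
#' @param recons named list of `recon_config`s.
#' @param ratio_cases subset of the three cases.
#' @param seed base RNG seed; case/phantom seeds are derived from it.
#' @param supersample rasterization supersampling.
#' @return list(recovery, lung, manifest).
#' @export
run_contrast_series <- function(grid, acq, recons,
                                ratio_cases = c("10:1", "4:1", "2:1"),
                                seed, supersample = 2) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  geometry <- bed_geometry(slices_per_bed = grid$shape[3], n_beds = 1)
  rec_rows <- list(); lung_rows <- list()
  for (ci in seq_along(ratio_cases)) {
    rc_case <- ratio_cases[ci]
    minutes <- scan_minutes_for_case(rc_case)
    for (ph_name in c("nema", "micro")) {
      axlen <- grid$shape[3] * grid$spacing[3]
      phantom <- if (ph_name == "nema")
        build_nema_iq(rc_case, axial_length_mm = axlen) else
        build_micro_sphere(rc_case, axial_length_mm = axlen)
      vols <- rasterize(phantom, grid, supersample = supersample)
      acq_c <- acq
      acq_c$time_per_bed <- minutes * 60
      acq_c$seed <- seed + 1000L * ci + ifelse(ph_name == "nema", 0L, 500L)
      sinos <- simulate_acquisition(vols, geometry, acq_c)
      for (rn in names(recons)) {
        vol <- reconstruct(sinos, recons[[rn]])
        bkg <- mean(background_roi_means(vol, phantom)$mean)
        rt <- recovery_table(vol, phantom, background_mean = bkg)
        rt$phantom <- ph_name; rt$ratio_case <- rc_case; rt$recon <- rn
        rt$beta <- recons[[rn]]$beta
        rec_rows[[length(rec_rows) + 1L]] <- rt
        if (ph_name == "nema") {
          le <- residual_lung_error(vol, phantom, background_mean = bkg)
          lung_rows[[length(lung_rows) + 1L]] <- data.frame(
            ratio_case = rc_case, recon = rn, beta = recons[[rn]]$beta,
            lung_error_mean_pct = le$mean, lung_error_sd_pct = le$sd)
        }
      }
    }
  }
  list(recovery = do.call(rbind, rec_rows),
       lung = do.call(rbind, lung_rows),
       manifest = list(seed = seed, ratio_cases = ratio_cases,
                       recons = names(recons)))
}

#' Acquisition-time series (COV profiles and the noise-counts relation)
#'
#' One long (max time) two-bed acquisition of the NEMA phantom is thinned to
#' each shorter time (emulating list-mode retro-reconstruction) and
#' reconstructed with every setting; per-slice COV profiles are measured in
#' the background ROI, and the counts-per-voxel versus COV relation is
#' fitted over the central slices of bed 1.
#'
#' @param grid a `voxel_grid` spanning the full two-bed axial range.
#' @param geometry a two(+)-bed `bed_geometry` consistent with the grid.
#' @param acq an `acquisition_config`.
#' @param recons named list of `recon_config`s.
#' @param times_min acquisition times to evaluate, minutes.
#' @param seed base RNG seed.
#' @param ratio_case phantom fill case.
#' @param central_slices how many central slices enter the noise-counts fit
#'   (11 per convention).
#' @param supersample rasterization supersampling.
#' @return list(cov = per-slice table, fit_points, fit, manifest).
#' @export
run_time_series <- function(grid, geometry, acq, recons, times_min = 1:5,
                            seed, ratio_case = "10:1", central_slices = 11,
                            supersample = 2) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!length(times_min)) stop("times_min must be nonempty", call. = FALSE)
  axlen <- grid$shape[3] * grid$spacing[3]
  phantom <- build_nema_iq(ratio_case, axial_length_mm = axlen,
                           sphere_plane_z =
                             (geometry$slices_per_bed / 2) * grid$spacing[3])
  vols <- rasterize(phantom, grid, supersample = supersample)
  mask <- background_mask(vols)
  acq_t <- acq
  acq_t$time_per_bed <- max(times_min) * 60
  acq_t$seed <- seed
  sinos_full <- simulate_acquisition(vols, geometry, acq_t)
  half <- (central_slices - 1) %/% 2
  csl <- (geometry$slices_per_bed + 1) %/% 2 + (-half:half)
  n_roi_vox <- sum(mask)
  cov_rows <- list(); pts <- list()
  for (ti in seq_along(sort(times_min, decreasing = TRUE))) {
    t_min <- sort(times_min, decreasing = TRUE)[ti]
    sinos <- thin_acquisition(sinos_full, t_min * 60, seed = seed + ti)
    # detected counts per background voxel over the central slices of bed 1
    counts_center <- sum(sinos$counts[[1]][, , csl])
    n_per_vox <- counts_center / (n_roi_vox * length(csl))
    for (rn in names(recons)) {
      vol <- reconstruct(sinos, recons[[rn]])
      cp <- cov_per_slice(vol, mask, geometry)
      cp$time_min <- t_min; cp$recon <- rn
      cov_rows[[length(cov_rows) + 1L]] <- cp
      pts[[length(pts) + 1L]] <- data.frame(
        time_min = t_min, recon = rn, counts_per_voxel = n_per_vox,
        cov = mean(cp$cov[csl], na.rm = TRUE))
    }
  }
  cov_tab <- do.call(rbind, cov_rows)
  fit_points <- do.call(rbind, pts)
  fits <- lapply(split(fit_points, fit_points$recon), function(df)
    if (nrow(df) >= 3) fit_noise_vs_counts(df$counts_per_voxel, df$cov)
    else NULL)
  list(cov = cov_tab, fit_points = fit_points, fits = fits,
       manifest = list(seed = seed, times_min = times_min,
                       ratio_case = ratio_case,
                       central_slices = csl))
}

#' Overlap noise-band study on a synthetic cohort
#'
#' Simulates each cohort patient on a >= 3-bed plan (leg beds at 1 min,
#' torso bed at 2.5 min), reconstructs with every setting, measures
#' per-slice muscle COV, averages the profiles over the cohort and reports
#' band metrics: COV at overlap-edge slices versus bed-centre slices.
#'
#' @param grid in-plane grid template (nz is derived from the geometry).
#' @param geometry a `bed_geometry` with `n_beds >= 3`.
#' @param acq an `acquisition_config` (per-bed times come from the plans).
#' @param recons named list of `recon_config`s.
#' @param n_patients cohort size.
#' @param seed base RNG seed.
#' @param supersample rasterization supersampling.
#' @return list(profiles = cohort-averaged per-slice COV, bands = edge vs
#'   centre metrics per recon, cohort, manifest).
#' @export
run_overlap_study <- function(grid, geometry, acq, recons, n_patients = 8,
                              seed, supersample = 2) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (geometry$n_beds < 3)
    stop("overlap study needs >= 3 bed positions", call. = FALSE)
  cohort <- synthesize_cohort(n_patients, seed = seed,
                              n_leg_beds = geometry$n_beds - 1L)
  ng <- n_global_slices(geometry)
  prof_acc <- list()
  for (pi in seq_along(cohort)) {
    spec <- cohort[[pi]]
    phantom <- patient_phantom(spec, geometry, dz_mm = grid$spacing[3])
    pgrid <- voxel_grid(c(grid$shape[1:2], ng), grid$spacing)
    vols <- rasterize(phantom, pgrid, supersample = supersample)
    # muscle mask from a lesion-free leg slice and a torso slice
    leg_mask <- background_mask(vols, slice = (geometry$slices_per_bed + 1)
                                %/% 2)
    torso_mask <- background_mask(vols, slice = ng - 2L)
    mask3d <- array(FALSE, c(grid$shape[1:2], ng))
    torso_from <- (geometry$n_beds - 1L) * geometry$pitch + 1L
    for (k in seq_len(ng))
      mask3d[, , k] <- if (k >= torso_from + geometry$overlap_slices)
        torso_mask else leg_mask
    acq_p <- acq
    acq_p$time_per_bed <- spec$bed_plan$time_s
    acq_p$seed <- seed + 37L * pi
    sinos <- simulate_acquisition(vols, geometry, acq_p)
    for (rn in names(recons)) {
      vol <- reconstruct(sinos, recons[[rn]])
      cp <- cov_per_slice(vol, mask3d, geometry)
      cp$patient <- pi; cp$recon <- rn
      prof_acc[[length(prof_acc) + 1L]] <- cp
    }
  }
  all_prof <- do.call(rbind, prof_acc)
  avg <- do.call(rbind, lapply(split(all_prof,
                                     list(all_prof$recon, all_prof$slice)),
    function(df) data.frame(recon = df$recon[1], slice = df$slice[1],
                            cov = mean(df$cov, na.rm = TRUE),
                            in_overlap = df$in_overlap[1],
                            n_beds = df$n_beds[1])))
  avg <- avg[order(avg$recon, avg$slice), ]
  # band metrics on the 1-min (leg) beds: overlap-edge vs bed-centre slices
  leg_beds <- seq_len(geometry$n_beds - 1L)
  centers <- (leg_beds - 1L) * geometry$pitch +
    (geometry$slices_per_bed + 1L) %/% 2
  edges <- unlist(lapply(leg_beds, function(b) {
    s0 <- (b - 1L) * geometry$pitch
    c(if (b > 1) s0 + 1L,                         # entering overlap with b-1
      s0 + geometry$pitch + 1L)                   # entering overlap with b+1
  }))
  edges <- unique(edges[edges >= 1 & edges <= ng])
  bands <- do.call(rbind, lapply(split(avg, avg$recon), function(df)
    data.frame(recon = df$recon[1],
               cov_overlap_edge = mean(df$cov[df$slice %in% edges]),
               cov_bed_center = mean(df$cov[df$slice %in% centers]),
               edge_center_ratio =
                 mean(df$cov[df$slice %in% edges]) /
                 mean(df$cov[df$slice %in% centers]))))
  list(profiles = avg, bands = bands, cohort = cohort,
       manifest = list(seed = seed, n_patients = length(cohort),
                       edge_slices = edges, center_slices = centers))
}
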