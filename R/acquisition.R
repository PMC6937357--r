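# Acquisition forward model: triangular axial sensitivity, multi-bed
# geometry with overlap, radioactive decay, attenuated line-integral
# projection with optional resolution blur, and Poisson counting.

F18_HALF_LIFE_MIN <- 109.77   # physical constant, minutes

#' Triangular axial sensitivity profile of one bed position
#'
#' Relative per-slice sensitivity of a single bed: 1 at the centre slice,
#' falling linearly to zero exactly one slice outside each edge of the axial
#' field of view. For 47 slices the edge slices have sensitivity 1/24, and
#' two beds overlapping by 11 slices sum to a constant 50% of peak across
#' the whole overlap region.
#'
#' @param slices_per_bed number of slices in the axial FOV, >= 3.
#' @return numeric vector in (0, 1], peak-normalized, symmetric.
#' @export
axial_sensitivity <- function(slices_per_bed = SLICES_PER_BED_DEFAULT) {
  n <- as.integer(slices_per_bed)
  if (n < 3) stop("slices_per_bed must be >= 3", call. = FALSE)
  k <- seq_len(n)
  s <- 1 - abs(k - (n + 1) / 2) / ((n + 1) / 2)
  s / max(s)
}

#' Bed geometry
#' @param slices_per_bed slices per bed position (default 47).
#' @param overlap_slices slices shared by adjacent beds (default 11).
#' @param n_beds number of bed positions, >= 1.
#' @return a `bed_geometry` list; `pitch` is slices_per_bed - overlap_slices.
#' @export
bed_geometry <- function(slices_per_bed = SLICES_PER_BED_DEFAULT,
                         overlap_slices = OVERLAP_SLICES_DEFAULT,
                         n_beds = 1) {
  slices_per_bed <- as.integer(slices_per_bed)
  overlap_slices <- as.integer(overlap_slices)
  n_beds <- as.integer(n_beds)
  if (overlap_slices < 0 || overlap_slices >= slices_per_bed)
    stop("need 0 <= overlap_slices < slices_per_bed", call. = FALSE)
  if (n_beds < 1) stop("n_beds must be >= 1", call. = FALSE)
  structure(list(slices_per_bed = slices_per_bed,
                 overlap_slices = overlap_slices, n_beds = n_beds,
                 pitch = slices_per_bed - overlap_slices),
            class = "bed_geometry")
}

#' Total number of distinct axial slices covered by a bed geometry
#' @param geometry a `bed_geometry`.
#' @export
n_global_slices <- function(geometry)
  geometry$slices_per_bed + (geometry$n_beds - 1L) * geometry$pitch

#' Bed overlap percentage
#' @param geometry a `bed_geometry`.
#' @return 100 * overlap_slices / slices_per_bed.
#' @export
overlap_fraction <- function(geometry)
  100 * geometry$overlap_slices / geometry$slices_per_bed

#' Combined multi-bed sensitivity per global slice
#'
#' Sum over beds of each bed's axial profile evaluated at the global slice.
#' With the triangular profile and the default 47/11 geometry the sum is
#' constant at 50% of single-bed peak across every interior overlap region.
#'
#' @param profile single-bed profile from [axial_sensitivity()].
#' @param geometry a `bed_geometry`.
#' @return numeric vector of length [n_global_slices()].
#' @export
combined_sensitivity <- function(profile, geometry) {
  stopifnot(length(profile) == geometry$slices_per_bed)
  total <- numeric(n_global_slices(geometry))
  for (b in seq_len(geometry$n_beds)) {
    idx <- (b - 1L) * geometry$pitch + seq_along(profile)
    total[idx] <- total[idx] + profile
  }
  total
}

# annotation helper: which beds contribute to each global slice
slice_bed_membership <- function(geometry) {
  nb <- matrix(FALSE, n_global_slices(geometry), geometry$n_beds)
  for (b in seq_len(geometry$n_beds))
    nb[(b - 1L) * geometry$pitch + seq_len(geometry$slices_per_bed), b] <- TRUE
  nb
}

#' Radioactive decay of an activity concentration
#' @param c0 start concentration, kBq/ml.
#' @param elapsed_min elapsed time in minutes, >= 0.
#' @param half_life_min isotope half-life in minutes (default F-18).
#' @export
decayed_concentration <- function(c0, elapsed_min,
                                  half_life_min = F18_HALF_LIFE_MIN) {
  if (half_life_min <= 0) stop("half_life must be > 0", call. = FALSE)
  if (any(elapsed_min < 0)) stop("elapsed time must be >= 0", call. = FALSE)
  c0 * 2^(-elapsed_min / half_life_min)
}

# Effective seconds of a scan window [t0, t0 + duration] with decay folded
# in: integral of 2^(-t/tau) dt, closed form. Expected counts are
# calibration * concentration(t = 0) * effective_seconds.
effective_scan_seconds <- function(duration_s, start_min = 0,
                                   half_life_min = F18_HALF_LIFE_MIN) {
  if (!is.finite(half_life_min)) return(duration_s)   # decay disabled
  lam <- log(2) / (half_life_min * 60)    # 1/s
  exp(-lam * start_min * 60) * (1 - exp(-lam * duration_s)) / lam
}

#' Acquisition configuration
#'
#' @param time_per_bed scan time per bed position in seconds (recycled over
#'   beds when scalar).
#' @param seed RNG seed for Poisson counting (required; reproducibility
#'   contract).
#' @param angles number of projection angles over 180 degrees.
#' @param radial_bins radial bins (default: grid size at projection time).
#' @param psf_fwhm detector resolution blur FWHM in projection space, mm.
#' @param calibration expected counts per (kBq/ml x mm x s) of attenuated
#'   line integral at unit sensitivity.
#' @param half_life isotope half-life, minutes.
#' @param start_time_offset minutes between the activity reference time and
#'   the start of the acquisition.
#' @return an `acquisition_config` list.
#' @export
acquisition_config <- function(time_per_bed = 60, seed = NULL, angles = 180L,
                               radial_bins = NULL, psf_fwhm = 5,
                               calibration = 0.01,
                               half_life = F18_HALF_LIFE_MIN,
                               start_time_offset = 0) {
  if (any(time_per_bed <= 0)) stop("time_per_bed must be > 0", call. = FALSE)
  if (calibration <= 0) stop("calibration must be > 0", call. = FALSE)
  structure(list(time_per_bed = as.numeric(time_per_bed), seed = seed,
                 angles = as.integer(angles), radial_bins = radial_bins,
                 psf_fwhm = psf_fwhm, calibration = calibration,
                 half_life = half_life,
                 start_time_offset = start_time_offset),
            class = "acquisition_config")
}

#' Forward-project one axial slice
#'
#' Parallel-beam line integrals of the activity slice, attenuated by
#' `exp(-integral of mu dl)` along the same lines, optionally blurred
#' radially by the detector PSF, and scaled by
#' `calibration x time x sensitivity`.
#'
#' @param activity_slice,attenuation_slice square matrices on the same grid;
#'   activity kBq/ml, attenuation 1/cm.
#' @param dx_mm in-plane voxel size.
#' @param config an `acquisition_config`.
#' @param sensitivity axial sensitivity of this slice in \[0, 1\].
#' @param time_s effective scan seconds (default: first `time_per_bed`).
#' @return list with `expected` matrix \[radial, angle\], the per-bin
#'   `attenuation_factors`, and the projection `model`.
#' @export
forward_project <- function(activity_slice, attenuation_slice, dx_mm, config,
                            sensitivity = 1,
                            time_s = config$time_per_bed[1]) {
  if (!identical(dim(activity_slice), dim(attenuation_slice)))
    stop("activity and attenuation slices must share the grid", call. = FALSE)
  nx <- nrow(activity_slice); ny <- ncol(activity_slice)
  nr <- if (is.null(config$radial_bins)) nx else as.integer(config$radial_bins)
  model <- projection_model(nx, ny, dx_mm, config$angles, nr)
  # LOR attenuation factor: exp(-line integral of mu), mu in 1/cm, A in mm
  att <- exp(-fwd_project_vec(model, as.numeric(attenuation_slice)) / 10)
  proj <- fwd_project_vec(model, as.numeric(activity_slice)) * att
  proj <- sino_radial_blur(proj, model, fwhm_to_sigma(config$psf_fwhm))
  scale <- config$calibration * time_s * sensitivity
  list(expected = matrix(proj * scale, nr, config$angles),
       attenuation_factors = matrix(att, nr, config$angles),
       model = model, scale = scale)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Simulate a multi-bed acquisition
#'
#' Computes expected sinograms for every bed and slice through
#' [forward_project()] with the triangular axial sensitivity and
#' within-scan decay folded in (beds are scanned sequentially), then draws
#' Poisson counts. A seed is mandatory: identical seed and configuration
#' give bit-identical counts.
#'
#' @param volumes a `labelled_volumes` from [rasterize()] spanning at least
#'   [n_global_slices()] slices.
#' @param geometry a `bed_geometry`.
#' @param config an `acquisition_config` carrying a seed.
#' @return a `sinogram_set`: per-bed arrays `counts[[b]]`, `expected[[b]]`
#'   and `attenuation_factors[[b]]` of shape \[radial, angle, slice\], plus
#'   geometry, profile and config echo.
#' @export
simulate_acquisition <- function(volumes, geometry, config) {
  if (is.null(config$seed))
    stop("acquisition seed is required for reproducibility", call. = FALSE)
  nz <- dim(volumes$activity)[3]
  need <- n_global_slices(geometry)
  if (nz < need)
    stop("volume has ", nz, " slices but the bed geometry needs ", need,
         call. = FALSE)
  if (abs(volumes$grid$spacing[1] - volumes$grid$spacing[2]) > 1e-9)
    stop("in-plane voxel spacing must be isotropic", call. = FALSE)
  dx <- volumes$grid$spacing[1]
  profile <- axial_sensitivity(geometry$slices_per_bed)
  times <- rep_len(config$time_per_bed, geometry$n_beds)
  bed_start_min <- config$start_time_offset +
    c(0, cumsum(times[-length(times)])) / 60
  set.seed(config$seed)
  counts <- expected <- attf <- vector("list", geometry$n_beds)
  for (b in seq_len(geometry$n_beds)) {
    eff_s <- effective_scan_seconds(times[b], bed_start_min[b],
                                    config$half_life)
    nr <- if (is.null(config$radial_bins)) dim(volumes$activity)[1] else
      as.integer(config$radial_bins)
    e <- array(0, c(nr, config$angles, geometry$slices_per_bed))
    a <- array(1, c(nr, config$angles, geometry$slices_per_bed))
    for (s in seq_len(geometry$slices_per_bed)) {
      gz <- (b - 1L) * geometry$pitch + s
      fp <- forward_project(volumes$activity[, , gz],
                            volumes$attenuation[, , gz], dx, config,
                            sensitivity = profile[s], time_s = eff_s)
      e[, , s] <- fp$expected
      a[, , s] <- fp$attenuation_factors
    }
    counts[[b]] <- array(rpois(length(e), e), dim(e))
    expected[[b]] <- e
    attf[[b]] <- a
  }
  structure(list(counts = counts, expected = expected,
                 attenuation_factors = attf, geometry = geometry,
                 profile = profile, config = config, dx = dx,
                 times_s = times, bed_start_min = bed_start_min,
                 grid = volumes$grid),
            class = "sinogram_set")
}

#' Thin an acquisition to a shorter effective scan time
#'
#' Emulates list-mode retro-reconstruction: each recorded count is kept
#' independently with probability equal to the ratio of effective (decay
#' weighted) scan seconds, so the thinned counts have exactly the Poisson
#' law of a direct shorter acquisition. Thinning to the original time
#' returns the identical counts.
#'
#' @param sinos a `sinogram_set`.
#' @param time_s target scan time per bed, seconds (scalar or per bed).
#' @param seed RNG seed for the thinning draws.
#' @return a new `sinogram_set` at the shorter time.
#' @export
thin_acquisition <- function(sinos, time_s, seed) {
  if (missing(seed) || is.null(seed))
    stop("thinning seed is required for reproducibility", call. = FALSE)
  times_new <- rep_len(as.numeric(time_s), sinos$geometry$n_beds)
  if (any(times_new > sinos$times_s + 1e-9))
    stop("cannot thin to a longer time than acquired", call. = FALSE)
  set.seed(seed)
  out <- sinos
  for (b in seq_len(sinos$geometry$n_beds)) {
    p <- effective_scan_seconds(times_new[b], sinos$bed_start_min[b],
                                sinos$config$half_life) /
         effective_scan_seconds(sinos$times_s[b], sinos$bed_start_min[b],
                                sinos$config$half_life)
    cc <- sinos$counts[[b]]
    if (p < 1 - 1e-12)
      cc <- array(rbinom(length(cc), as.integer(cc), p), dim(cc))
    out$counts[[b]] <- cc
    out$expected[[b]] <- sinos$expected[[b]] * p
  }
  out$times_s <- times_new
  out$config$time_per_bed <- times_new
  out
}

#' @export
print.sinogram_set <- function(x, ...) {
  cat("sinogram_set:", x$geometry$n_beds, "bed(s) x",
      x$geometry$slices_per_bed, "slices,",
      dim(x$counts[[1]])[1], "radial x", dim(x$counts[[1]])[2], "angles,",
      "time/bed", paste(signif(x$times_s, 4), collapse = "/"), "s\n")
  invisible(x)
}
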