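# Iterative reconstruction: OSEM (with or without resolution modelling in
# the projector) and BSREM with the relative difference penalty, operating
# slice-wise in 2D with per-slice axial sensitivity folded into the system
# normalization. Multi-bed outputs are stitched with sensitivity weights.

#' Reconstruction configuration
#'
#' @param algorithm `"OSEM"`, `"OSEM_PSF"` or `"BPL"` (BSREM with the
#'   relative difference penalty; resolution modelling included).
#' @param iterations OSEM iterations (default 2; early stopping is the
#'   conventional noise control for OSEM).
#' @param subsets ordered subsets; must divide the number of angles.
#' @param psf_fwhm resolution model FWHM (mm) used inside the projector for
#'   `OSEM_PSF`/`BPL`; `NULL` means "use the acquisition's PSF" (matched
#'   model), 0 disables.
#' @param beta relative-difference-penalty weight, >= 0 (BPL only).
#' @param gamma RDP edge parameter, > 0.
#' @param bpl_max_passes cap on BSREM full passes.
#' @param bpl_tol relative objective-change convergence tolerance.
#' @param relax0,relax_H relaxation schedule lambda_n = relax0/(1 + n/relax_H).
#' @param postfilter_fwhm Gaussian post-filter FWHM in mm (OSEM default 6.4;
#'   BPL default 0 -- penalized reconstructions are not post-filtered).
#' @param axial_weights three-slice axial filter weights (OSEM default
#'   \[1, 4, 1\]; BPL default identity).
#' @param epsilon small positive stabilizer for EM ratios.
#' @return a `recon_config` list.
#' @export
recon_config <- function(algorithm = c("OSEM", "OSEM_PSF", "BPL"),
                         iterations = 2, subsets = 24, psf_fwhm = NULL,
                         beta = 0, gamma = 2, bpl_max_passes = 200,
                         bpl_tol = 1e-5, relax0 = 1, relax_H = 10,
                         postfilter_fwhm = NULL, axial_weights = NULL,
                         epsilon = 1e-9) {
  algorithm <- match.arg(algorithm)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (is.null(postfilter_fwhm))
    postfilter_fwhm <- if (algorithm == "BPL") 0 else 6.4
  if (is.null(axial_weights))
    axial_weights <- if (algorithm == "BPL") c(0, 1, 0) else c(1, 4, 1)
  structure(list(algorithm = algorithm, iterations = as.integer(iterations),
                 subsets = as.integer(subsets), psf_fwhm = psf_fwhm,
                 beta = beta, gamma = gamma,
                 bpl_max_passes = as.integer(bpl_max_passes),
                 bpl_tol = bpl_tol, relax0 = relax0, relax_H = relax_H,
                 postfilter_fwhm = postfilter_fwhm,
                 axial_weights = axial_weights, epsilon = epsilon),
            class = "recon_config")
}

# model PSF: matched to the acquisition unless the algorithm is plain OSEM
.model_psf <- function(config, sinos) {
  if (config$algorithm == "OSEM") return(0)
  if (is.null(config$psf_fwhm)) sinos$config$psf_fwhm else config$psf_fwhm
}

# per-subset row-index and submatrix cache
.subset_models <- function(model, subsets) {
  if (model$n_angles %% subsets != 0)
    stop("subsets (", subsets, ") must divide the angle count (",
         model$n_angles, ")", call. = FALSE)
  key <- paste("sub", model$nx, model$ny, signif(model$dx, 10),
               model$n_angles, model$n_radial, subsets, sep = "_")
  if (!is.null(.petiq_cache[[key]])) return(.petiq_cache[[key]])
  out <- lapply(seq_len(subsets), function(m) {
    ang <- seq(m, model$n_angles, by = subsets)
    rows <- as.vector(outer(seq_len(model$n_radial),
                            (ang - 1L) * model$n_radial, `+`))
    list(rows = rows, A = model$A[rows, , drop = FALSE],
         n_ang = length(ang))
  })
  .petiq_cache[[key]] <- out
  out
}

# slice-level system: forward/adjoint closures for one slice's data
.slice_system <- function(y, att, scale, model, subs, psf_sigma, epsilon) {
  nr <- model$n_radial
  sb <- if (psf_sigma > 0) psf_sigma / model$bin_width else 0
  # matched to the acquisition operator: scale * blur(att (.) (A x))
  fwd <- function(S, x) {
    v <- as.numeric(S$A %*% x) * att[S$rows]
    if (sb > 0) v <- .radial_blur(v, nr, S$n_ang, sb)
    scale * v
  }
  adj <- function(S, r) {
    if (sb > 0) r <- .radial_blur(r, nr, S$n_ang, sb)
    scale * as.numeric(Matrix::crossprod(S$A, r * att[S$rows]))
  }
  sens <- lapply(subs, function(S) adj(S, rep(1, length(S$rows))))
  list(fwd = fwd, adj = adj, sens = sens, subs = subs, y = y,
       epsilon = epsilon, scale = scale)
}

.slice_loglik <- function(sys, x) {
  tot <- 0
  for (m in seq_along(sys$subs)) {
    S <- sys$subs[[m]]
    yh <- sys$fwd(S, x)
    tot <- tot + sum(sys$y[S$rows] * log(yh + sys$epsilon) - yh)
  }
  tot
}

.osem_slice <- function(sys, nvox, iterations, track = FALSE) {
  x <- rep(1, nvox)
  trace <- if (track) numeric(0) else NULL
  for (it in seq_len(iterations)) {
    for (m in seq_along(sys$subs)) {
      S <- sys$subs[[m]]
      yh <- sys$fwd(S, x)
      upd <- sys$adj(S, sys$y[S$rows] / (yh + sys$epsilon))
      x <- ifelse(sys$sens[[m]] > 0, x * upd / (sys$sens[[m]] + 1e-300), 0)
    }
    if (track) trace <- c(trace, .slice_loglik(sys, x))
  }
  list(x = x, loglik = trace)
}

.bsrem_slice <- function(sys, nx, ny, config, axial_ratio = 1,
                         track = FALSE) {
  M <- length(sys$subs)
  x <- rep(1, nx * ny)
  xfloor <- 1e-12
  obj <- -Inf
  trace <- numeric(0)
  n_decrease <- 0L
  for (pass in seq_len(config$bpl_max_passes)) {
    lam <- config$relax0 / (1 + (pass - 1) / config$relax_H)
    for (m in seq_len(M)) {
      S <- sys$subs[[m]]
      yh <- sys$fwd(S, x)
      g <- sys$adj(S, sys$y[S$rows] / (yh + sys$epsilon) - 1)
      # scaled-gradient ascent: the preconditioner x/S_m of plain block-EM,
      # augmented (beta > 0) with the separable RDP curvature majorizer so
      # large penalty weights cannot overshoot; reduces exactly to the
      # block-EM update at beta = 0
      den <- sys$sens[[m]] / pmax(x, xfloor)
      if (config$beta > 0) {
        pen <- rdp_penalty(matrix(x, nx, ny), beta = config$beta,
                           gamma = config$gamma, epsilon = config$epsilon)
        g <- g - as.numeric(pen$gradient) / M
        den <- den + as.numeric(pen$curvature) / M
      }
      xn <- ifelse(sys$sens[[m]] > 0, x + lam * g / den, x)
      if (config$beta > 0)
        xn <- pmin(pmax(xn, 0.1 * x), 10 * x)   # trust-region backstop
      x <- pmax(xn, xfloor)
    }
    pen_val <- if (config$beta > 0)
      rdp_penalty(matrix(x, nx, ny), beta = config$beta,
                  gamma = config$gamma, epsilon = config$epsilon)$value
      else 0
    new_obj <- .slice_loglik(sys, x) - pen_val
    trace <- c(trace, new_obj)
    if (is.finite(obj)) {
      rel <- abs(new_obj - obj) / (abs(obj) + 1e-300)
      n_decrease <- if (new_obj < obj) n_decrease + 1L else 0L
      if (n_decrease >= 5L)
        stop("BSREM diverging: objective decreased over 5 consecutive ",
             "passes (last values ",
             paste(signif(utils::tail(trace, 6), 8), collapse = ", "), ")",
             call. = FALSE)
      if (rel < config$bpl_tol) break
    }
    obj <- new_obj
  }
  list(x = x, objective = if (track) trace else NULL, passes = pass)
}

# reconstruct every slice of one bed -> [nx, ny, slices_per_bed] array
.reconstruct_bed <- function(sinos, bed, config, track = FALSE) {
  geom <- sinos$geometry
  nx <- sinos$grid$shape[1]; ny <- sinos$grid$shape[2]
  nr <- dim(sinos$counts[[bed]])[1]
  model <- projection_model(nx, ny, sinos$dx, sinos$config$angles, nr)
  subs <- .subset_models(model, config$subsets)
  psf_sigma <- fwhm_to_sigma(.model_psf(config, sinos))
  eff_s <- effective_scan_seconds(sinos$times_s[bed],
                                  sinos$bed_start_min[bed],
                                  sinos$config$half_life)
  out <- array(0, c(nx, ny, geom$slices_per_bed))
  traces <- vector("list", geom$slices_per_bed)
  for (s in seq_len(geom$slices_per_bed)) {
    scale <- sinos$config$calibration * eff_s * sinos$profile[s]
    sys <- .slice_system(as.numeric(sinos$counts[[bed]][, , s]),
                         as.numeric(sinos$attenuation_factors[[bed]][, , s]),
                         scale, model, subs, psf_sigma, config$epsilon)
    res <- if (config$algorithm == "BPL")
      .bsrem_slice(sys, nx, ny, config, track = track)
    else
      .osem_slice(sys, nx * ny, config$iterations, track = track)
    out[, , s] <- res$x
    traces[[s]] <- res[[2]]
  }
  attr(out, "traces") <- if (track) traces else NULL
  out
}

#' Image volume
#'
#' Reconstructed activity-concentration volume (kBq/ml) with its grid and
#' provenance (reconstruction config, geometry, seed).
#' @param values 3D array, nonnegative.
#' @param grid a `voxel_grid`.
#' @param provenance free-form list.
#' @export
image_volume <- function(values, grid, provenance = list()) {
  structure(list(values = values, grid = grid, provenance = provenance),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$values), collapse = " x "), "voxels",
      "(", x$provenance$algorithm %||% "?", ")\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' OSEM reconstruction of a multi-bed acquisition
#'
#' Standard ordered-subset EM over angle subsets with the matched projector
#' (resolution blur included iff `algorithm = "OSEM_PSF"`), per-slice axial
#' sensitivity in the normalization, Gaussian post-filter and three-slice
#' axial weighted smoothing, and sensitivity-weighted bed stitching.
#'
#' @param sinos a `sinogram_set`.
#' @param config a `recon_config` with algorithm `"OSEM"` or `"OSEM_PSF"`.
#' @return an `image_volume` spanning all global slices.
#' @export
osem_reconstruct <- function(sinos, config = recon_config("OSEM")) {
  if (config$algorithm == "BPL")
    stop("use bsrem_rdp_reconstruct() for BPL", call. = FALSE)
  .reconstruct_full(sinos, config)
}

#' BSREM reconstruction with the relative difference penalty
#'
#' Block-iterative ascent on the penalized Poisson log-likelihood with a
#' diminishing relaxation schedule, run to a relative objective-change
#' tolerance (not fixed early stopping). With `beta = 0`, full relaxation
#' and matching subsets the first full pass reproduces OSEM's first
#' iteration. Output is unfiltered by default.
#'
#' @param sinos a `sinogram_set`.
#' @param config a `recon_config` with algorithm `"BPL"`.
#' @return an `image_volume`.
#' @export
bsrem_rdp_reconstruct <- function(sinos, config = recon_config("BPL")) {
  config$algorithm <- "BPL"
  .reconstruct_full(sinos, config)
}

#' Reconstruct a `sinogram_set` with any configured algorithm
#' @inheritParams osem_reconstruct
#' @export
reconstruct <- function(sinos, config) {
  if (config$algorithm == "BPL") bsrem_rdp_reconstruct(sinos, config)
  else osem_reconstruct(sinos, config)
}

.reconstruct_full <- function(sinos, config) {
  geom <- sinos$geometry
  beds <- lapply(seq_len(geom$n_beds), function(b)
    .reconstruct_bed(sinos, b, config))
  beds <- lapply(beds, function(v) {
    v <- gaussian_postfilter(v, config$postfilter_fwhm, sinos$grid$spacing)
    axial_weighted_filter(v, config$axial_weights)
  })
  stitched <- stitch_beds(beds, sinos$profile, geom)
  grid <- voxel_grid(c(sinos$grid$shape[1:2], dim(stitched)[3]),
                     sinos$grid$spacing, sinos$grid$origin)
  image_volume(stitched, grid,
               provenance = list(algorithm = config$algorithm,
                                 beta = config$beta,
                                 config = unclass(config),
                                 geometry = unclass(geom),
                                 seed = sinos$config$seed))
}

#' Stitch per-bed volumes with sensitivity weights
#'
#' Slices covered by one bed are copied; slices in overlap regions are
#' combined as the sensitivity-weighted average
#' `(s1 v1 + s2 v2) / (s1 + s2)`, which is the minimum-variance convex
#' combination when noise scales inversely with sensitivity.
#'
#' @param bed_volumes list of `[nx, ny, slices_per_bed]` arrays (or
#'   `image_volume`s).
#' @param profile single-bed axial sensitivity.
#' @param geometry a `bed_geometry` with `n_beds = length(bed_volumes)`.
#' @return a `[nx, ny, n_global_slices]` array.
#' @export
stitch_beds <- function(bed_volumes, profile, geometry) {
  vols <- lapply(bed_volumes, function(v)
    if (inherits(v, "image_volume")) v$values else v)
  dims <- dim(vols[[1]])
  for (v in vols) if (!identical(dim(v), dims))
    stop("bed volumes have inconsistent grids", call. = FALSE)
  if (dims[3] != geometry$slices_per_bed)
    stop("bed volume slice count does not match the geometry", call. = FALSE)
  if (length(vols) != geometry$n_beds)
    stop("expected ", geometry$n_beds, " bed volumes", call. = FALSE)
  ng <- n_global_slices(geometry)
  num <- array(0, c(dims[1:2], ng))
  den <- numeric(ng)
  for (b in seq_along(vols)) {
    idx <- (b - 1L) * geometry$pitch + seq_len(dims[3])
    for (s in seq_len(dims[3])) {
      g <- idx[s]
      num[, , g] <- num[, , g] + profile[s] * vols[[b]][, , s]
      den[g] <- den[g] + profile[s]
    }
  }
  for (g in seq_len(ng)) num[, , g] <- num[, , g] / den[g]
  num
}
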