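# Image-quality metrics: 50%-isocontour recovery coefficients (background
# corrected), NU2-style background variability, residual lung error and
# per-slice COV profiles. All SDs use the sample (n-1) convention.

#' Sphere recovery coefficient from a 50% isocontour VOI
#'
#' Searches a box of 1.5x the sphere diameter around the known centre,
#' thresholds at `T = background + 0.5 * (local max - background)` (the
#' background-corrected 50% isocontour) and takes the connected component
#' (6-connectivity, ties included via >=) containing the maximum voxel. The
#' recovery coefficient is the VOI mean divided by the true concentration.
#' If the local maximum does not exceed the background the sphere is
#' invisible: the RC is reported at background level and flagged.
#'
#' @param volume an `image_volume`.
#' @param sphere a [sphere_spec()] giving centre, diameter and true
#'   concentration.
#' @param background_mean background activity level (same units as the
#'   volume), from background ROIs.
#' @return one-row data.frame: diameter_mm, measured_mean, true_concentration,
#'   recovery_coefficient, voi_voxel_count, invisible.
#' @export
voi50_recovery <- function(volume, sphere, background_mean) {
  v <- volume$values; grid <- volume$grid
  half <- 0.75 * sphere$inner_diameter        # 1.5x diameter box
  idx <- lapply(1:3, function(d) {
    ax <- grid_axis(grid, d)
    which(abs(ax - sphere$center[d]) <= pmax(half, grid$spacing[d]))
  })
  if (any(lengths(idx) == 0))
    stop("sphere centre lies outside the volume", call. = FALSE)
  box <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  mx <- max(box)
  if (sphere$activity_concentration <= 0)
    stop("recovery undefined: true concentration is zero", call. = FALSE)
  if (mx <= background_mean) {
    return(data.frame(diameter_mm = sphere$inner_diameter,
                      measured_mean = background_mean,
                      true_concentration = sphere$activity_concentration,
                      recovery_coefficient =
                        background_mean / sphere$activity_concentration,
                      voi_voxel_count = 0L, invisible = TRUE))
  }
  thr <- background_mean + 0.5 * (mx - background_mean)
  mask <- box >= thr
  seed <- array(FALSE, dim(box))
  seed[which.max(box)] <- TRUE
  comp <- .flood_fill(seed, mask)
  data.frame(diameter_mm = sphere$inner_diameter,
             measured_mean = mean(box[comp]),
             true_concentration = sphere$activity_concentration,
             recovery_coefficient =
               mean(box[comp]) / sphere$activity_concentration,
             voi_voxel_count = sum(comp), invisible = FALSE)
}

# 6-connected 3D flood fill by iterative dilation within `mask`
.flood_fill <- function(seed, mask) {
  comp <- seed & mask
  repeat {
    grown <- comp
    d <- dim(comp)
    if (d[1] > 1) {
      grown[-1, , ] <- grown[-1, , ] | comp[-d[1], , ]
      grown[-d[1], , ] <- grown[-d[1], , ] | comp[-1, , ]
    }
    if (d[2] > 1) {
      grown[, -1, ] <- grown[, -1, ] | comp[, -d[2], ]
      grown[, -d[2], ] <- grown[, -d[2], ] | comp[, -1, ]
    }
    if (d[3] > 1) {
      grown[, , -1] <- grown[, , -1] | comp[, , -d[3]]
      grown[, , -d[3]] <- grown[, , -d[3]] | comp[, , -1]
    }
    grown <- grown & mask
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}

#' Recovery coefficients for every sphere of a phantom
#'
#' @param volume an `image_volume`.
#' @param phantom the `phantom_spec` that generated it.
#' @param background_mean background level; when `NULL` it is measured with
#'   [background_roi_means()] on the sphere-centre slice.
#' @return data.frame, one row per sphere (ordered as in the phantom).
#' @export
recovery_table <- function(volume, phantom, background_mean = NULL) {
  if (is.null(background_mean))
    background_mean <- mean(background_roi_means(volume, phantom)$mean)
  do.call(rbind, lapply(phantom$spheres, function(sp)
    voi50_recovery(volume, sp, background_mean)))
}

# Deterministic placement of n background ROI centres on the sphere plane:
# greedy farthest-point selection among in-body candidates that keep clear
# of the spheres, the lung insert and the body boundary.
background_roi_centers <- function(phantom, grid, n = 12,
                                   roi_diameter = max(vapply(phantom$spheres,
                                     `[[`, numeric(1), "inner_diameter"))) {
  z <- phantom$spheres[[1]]$center[3]
  sec <- .section_at(phantom, z)
  step <- max(grid$spacing[1], 4)
  gx <- seq(-200, 200, by = step); gy <- seq(-200, 200, by = step)
  cand <- expand.grid(x = gx, y = gy)
  margin <- roi_diameter / 2
  # inside the body with margin: all four ROI-edge points must be inside
  ok <- outline_inside(sec$outline, cand$x, cand$y)
  for (sh in list(c(margin, 0), c(-margin, 0), c(0, margin), c(0, -margin)))
    ok <- ok & outline_inside(sec$outline, cand$x + sh[1], cand$y + sh[2])
  for (sp in phantom$spheres) {
    dist <- sqrt((cand$x - sp$center[1])^2 + (cand$y - sp$center[2])^2)
    ok <- ok & dist > sp$inner_diameter / 2 + margin + 2
  }
  if (!is.null(phantom$lung_insert)) {
    li <- phantom$lung_insert
    dist <- sqrt((cand$x - li$center[1])^2 + (cand$y - li$center[2])^2)
    ok <- ok & dist > li$diameter / 2 + margin + 2
  }
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) < n)
    stop("cannot place ", n, " background ROIs of ", roi_diameter,
         " mm in this phantom", call. = FALSE)
  sel <- which.min(cand$x + cand$y)   # deterministic start: lower-left
  while (length(sel) < n) {
    d2min <- rep(Inf, nrow(cand))
    for (s in sel)
      d2min <- pmin(d2min, (cand$x - cand$x[s])^2 + (cand$y - cand$y[s])^2)
    sel <- c(sel, which.max(d2min))
  }
  data.frame(x = cand$x[sel], y = cand$y[sel], z = z)
}

# mean of a circular in-plane ROI at (x, y) on slice k
.roi_mean <- function(volume, x, y, k, diameter) {
  gx <- grid_axis(volume$grid, 1); gy <- grid_axis(volume$grid, 2)
  m <- outer((gx - x)^2, (gy - y)^2, `+`) <= (diameter / 2)^2
  if (!any(m)) return(NA_real_)
  mean(volume$values[, , k][m])
}

#' Background ROI means on the sphere plane
#' @param volume an `image_volume`.
#' @param phantom its `phantom_spec`.
#' @param roi_diameter ROI diameter, mm (default 37 for the NEMA layout,
#'   capped by what fits in the phantom).
#' @param n number of ROIs.
#' @export
background_roi_means <- function(volume, phantom, roi_diameter = NULL,
                                 n = 12) {
  if (is.null(roi_diameter))
    roi_diameter <- max(vapply(phantom$spheres, `[[`, numeric(1),
                               "inner_diameter"))
  ctr <- background_roi_centers(phantom, volume$grid, n = n,
                                roi_diameter = roi_diameter)
  k <- which.min(abs(grid_axis(volume$grid, 3) - ctr$z[1]))
  ctr$mean <- vapply(seq_len(nrow(ctr)), function(i)
    .roi_mean(volume, ctr$x[i], ctr$y[i], k, roi_diameter), numeric(1))
  ctr
}

#' NU2-style background variability per sphere size
#'
#' For each sphere diameter, circular ROIs of that diameter are drawn at the
#' background positions on the central slice and on slices at the given
#' axial offsets (60 ROIs for the standard 12 positions x 5 slices); the
#' variability is `100 * SD(ROI means) / mean(ROI means)` (sample SD).
#'
#' @param volume an `image_volume`.
#' @param phantom its `phantom_spec`.
#' @param sphere_diameters diameters to evaluate, mm.
#' @param n_rois background positions per slice (>= 12 per convention).
#' @param slice_offsets_mm axial offsets of the evaluated slices.
#' @return data.frame(diameter_mm, variability_pct, n_rois_used).
#' @export
background_variability <- function(volume, phantom,
                                   sphere_diameters =
                                     vapply(phantom$spheres, `[[`,
                                            numeric(1), "inner_diameter"),
                                   n_rois = 12,
                                   slice_offsets_mm = c(-20, -10, 0, 10, 20)) {
  gz <- grid_axis(volume$grid, 3)
  z0 <- phantom$spheres[[1]]$center[3]
  ks <- unique(vapply(z0 + slice_offsets_mm, function(z)
    which.min(abs(gz - z)), integer(1)))
  out <- lapply(sphere_diameters, function(d) {
    ctr <- background_roi_centers(phantom, volume$grid, n = n_rois,
                                  roi_diameter = max(sphere_diameters))
    means <- unlist(lapply(ks, function(k)
      vapply(seq_len(nrow(ctr)), function(i)
        .roi_mean(volume, ctr$x[i], ctr$y[i], k, d), numeric(1))))
    means <- means[is.finite(means)]
    data.frame(diameter_mm = d,
               variability_pct = 100 * sd(means) / mean(means),
               n_rois_used = length(means))
  })
  do.call(rbind, out)
}

#' Residual lung error
#'
#' Apparent activity in the zero-activity lung insert relative to the
#' background mean, per evaluated slice:
#' `100 * mean(lung ROI) / background_mean`, summarized as mean +/- SD.
#'
#' @param volume an `image_volume`.
#' @param phantom a `phantom_spec` with a lung insert.
#' @param background_mean background level (measured when `NULL`).
#' @param roi_diameter lung ROI diameter, mm (30 mm circle by convention).
#' @param slice_offsets_mm evaluated slices relative to the sphere plane.
#' @return list(per_slice = data.frame(slice, error_pct), mean, sd).
#' @export
residual_lung_error <- function(volume, phantom, background_mean = NULL,
                                roi_diameter = 30,
                                slice_offsets_mm = c(-20, -10, 0, 10, 20)) {
  if (is.null(phantom$lung_insert))
    stop("phantom has no lung insert", call. = FALSE)
  if (is.null(background_mean))
    background_mean <- mean(background_roi_means(volume, phantom)$mean)
  if (background_mean <= 0)
    stop("residual lung error undefined: background mean <= 0",
         call. = FALSE)
  gz <- grid_axis(volume$grid, 3)
  z0 <- phantom$spheres[[1]]$center[3]
  ks <- unique(vapply(z0 + slice_offsets_mm, function(z)
    which.min(abs(gz - z)), integer(1)))
  li <- phantom$lung_insert
  err <- vapply(ks, function(k)
    100 * .roi_mean(volume, li$center[1], li$center[2], k, roi_diameter) /
      background_mean, numeric(1))
  list(per_slice = data.frame(slice = ks, error_pct = err),
       mean = mean(err), sd = if (length(err) > 1) sd(err) else NA_real_)
}

#' Background mask for COV profiles
#'
#' In-plane mask of background voxels on the label volume's sphere plane,
#' excluding spheres, the lung insert and a safety margin around them and
#' the body boundary (the "large ROI excluding the spheres" convention).
#'
#' @param vols a `labelled_volumes`.
#' @param margin_mm erosion margin, mm.
#' @param slice slice index whose labels define the mask (default: sphere
#'   plane when spheres exist, else the central slice).
#' @return logical \[nx, ny\] matrix.
#' @export
background_mask <- function(vols, margin_mm = 8, slice = NULL) {
  if (is.null(slice)) {
    slice <- if (length(vols$phantom$spheres)) {
      which.min(abs(grid_axis(vols$grid, 3) -
                      vols$phantom$spheres[[1]]$center[3]))
    } else dim(vols$labels)[3] %/% 2 + 1
  }
  lab <- vols$labels[, , slice]
  m <- lab == LABEL_BACKGROUND
  n_erode <- max(1L, as.integer(round(margin_mm / vols$grid$spacing[1])))
  for (i in seq_len(n_erode)) {
    d <- dim(m); e <- m
    e[-1, ] <- e[-1, ] & m[-d[1], ]; e[-d[1], ] <- e[-d[1], ] & m[-1, ]
    e[, -1] <- e[, -1] & m[, -d[2]]; e[, -d[2]] <- e[, -d[2]] & m[, -1]
    m <- e
  }
  m
}

#' Per-slice coefficient of variation profile
#'
#' COV = sample SD / mean of the ROI voxels, per axial slice, annotated with
#' bed membership and overlap status when a `bed_geometry` is supplied.
#'
#' @param volume an `image_volume`.
#' @param roi_mask logical \[nx, ny\] in-plane mask (applied to every slice)
#'   or \[nx, ny, nz\] mask.
#' @param geometry optional `bed_geometry` for overlap annotation.
#' @return data.frame(slice, mean, sd, cov, n_voxels, n_beds, in_overlap).
#' @export
cov_per_slice <- function(volume, roi_mask, geometry = NULL) {
  nz <- dim(volume$values)[3]
  mask3d <- length(dim(roi_mask)) == 3
  rows <- lapply(seq_len(nz), function(k) {
    m <- if (mask3d) roi_mask[, , k] else roi_mask
    vals <- volume$values[, , k][m]
    if (length(vals) < 2)
      return(data.frame(slice = k, mean = NA_real_, sd = NA_real_,
                        cov = NA_real_, n_voxels = length(vals)))
    mu <- mean(vals)
    data.frame(slice = k, mean = mu, sd = sd(vals),
               cov = if (mu > 0) sd(vals) / mu else NA_real_,
               n_voxels = length(vals))
  })
  out <- do.call(rbind, rows)
  out$flagged <- !is.finite(out$cov)
  if (!is.null(geometry)) {
    mem <- slice_bed_membership(geometry)
    nb <- rowSums(mem)[seq_len(nz)]
    out$n_beds <- nb
    out$in_overlap <- nb > 1
  }
  out
}
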