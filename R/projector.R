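# Parallel-beam projection model shared by the acquisition simulator and the
# iterative reconstructions. The system matrix (Joseph interpolation, entries
# in mm of intersection length) is built once per geometry and cached for the
# session.

#' Parallel-beam projection model
#'
#' Builds (or retrieves from the session cache) the sparse system matrix for
#' an isotropic in-plane grid and a set of projection angles spanning
#' \[0, 180) degrees, together with the radial binning metadata.
#'
#' @param nx,ny in-plane grid size in voxels.
#' @param dx_mm in-plane voxel size (isotropic), mm.
#' @param n_angles number of projection angles.
#' @param n_radial number of radial bins (default `nx`).
#' @param bin_width_mm radial bin width (default `dx_mm`).
#' @return a `projection_model` list with the `Matrix::dgCMatrix` system
#'   matrix `A` (rows: angle-major bins; columns: column-major voxels).
#' @export
projection_model <- function(nx, ny, dx_mm, n_angles, n_radial = nx,
                             bin_width_mm = dx_mm) {
  key <- paste("A", nx, ny, signif(dx_mm, 10), n_angles, n_radial,
               signif(bin_width_mm, 10), sep = "_")
  if (!is.null(.petiq_cache[[key]])) return(.petiq_cache[[key]])
  tr <- joseph_triplets(as.integer(nx), as.integer(ny), dx_mm,
                        as.integer(n_angles), as.integer(n_radial),
                        bin_width_mm)
  A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(n_angles * n_radial, nx * ny))
  m <- structure(list(A = A, nx = as.integer(nx), ny = as.integer(ny),
                      dx = dx_mm, n_angles = as.integer(n_angles),
                      n_radial = as.integer(n_radial),
                      bin_width = bin_width_mm),
                 class = "projection_model")
  .petiq_cache[[key]] <- m
  m
}

# Radial Gaussian blur of a sinogram vector (angle-major bin ordering), with
# an edge-renormalized truncated kernel so that blurring preserves totals and
# maps a flat sinogram to itself.
sino_radial_blur <- function(v, model, sigma_mm) {
  if (sigma_mm <= 0) return(v)
  .radial_blur(v, model$n_radial, model$n_angles, sigma_mm / model$bin_width)
}

# blur an angle-major sinogram vector along the radial axis; sigma in bins,
# edge-renormalized so a flat sinogram maps to itself
.radial_blur <- function(v, nr, na, sigma_bins) {
  if (sigma_bins <= 0) return(v)
  rad <- max(1L, as.integer(ceiling(3 * sigma_bins)))
  k <- exp(-0.5 * ((-rad):rad / sigma_bins)^2)
  k <- k / sum(k)
  m <- matrix(v, nrow = nr, ncol = na)
  nm <- .conv_cols(matrix(1, nr, 1), k)[, 1]
  m <- .conv_cols(m, k) / nm
  as.numeric(m)
}

# column-wise 1D convolution (same length, zero padding)
.conv_cols <- function(m, k) {
  rad <- (length(k) - 1L) / 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(k)) {
    o <- t - rad - 1L
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[t] * m[src[ok], , drop = FALSE]
  }
  out
}

fwd_project_vec <- function(model, x) as.numeric(model$A %*% x)

back_project_vec <- function(model, y) as.numeric(Matrix::crossprod(model$A, y))
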