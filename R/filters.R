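# Post-reconstruction filters: 3D Gaussian smoothing specified by FWHM in
# mm, and the scanner's three-slice axial weighted filter.

# sparse 1D smoothing operator with edge-renormalized truncated kernel
.smooth_operator <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(NULL)
  rad <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-0.5 * ((-rad):rad / sigma_vox)^2)
  .band_operator(n, k / sum(k))
}

.band_operator <- function(n, k) {
  rad <- (length(k) - 1L) / 2L
  ii <- jj <- integer(0); xx <- numeric(0)
  for (t in seq_along(k)) {
    o <- t - rad - 1L
    i <- seq_len(n); j <- i + o
    ok <- j >= 1L & j <= n
    ii <- c(ii, i[ok]); jj <- c(jj, j[ok]); xx <- c(xx, rep(k[t], sum(ok)))
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  # renormalize rows clipped at the edges so constants are preserved
  K / Matrix::rowSums(K)
}

.apply_along <- function(arr, d, K) {
  if (is.null(K)) return(arr)
  dims <- dim(arr)
  perm <- c(d, setdiff(seq_along(dims), d))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = dims[d])
  m <- as.matrix(K %*% m)
  dim(m) <- dims[perm]
  aperm(m, order(perm))
}

#' Gaussian post-filter
#'
#' Separable 3D Gaussian smoothing with a given FWHM in mm, converted to
#' voxels per axis by the grid spacing. `fwhm_mm = 0` is the identity. The
#' truncated kernel is edge-renormalized, so constants (and interior totals)
#' are preserved.
#'
#' @param values 3D array (or matrix, treated as a single slice).
#' @param fwhm_mm filter width, >= 0 (scalar, applied isotropically in mm).
#' @param spacing voxel spacing (dx, dy, dz), mm.
#' @return filtered array of the same shape.
#' @export
gaussian_postfilter <- function(values, fwhm_mm, spacing) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(values)
  d2 <- is.matrix(values)
  arr <- if (d2) array(values, c(dim(values), 1)) else values
  sig <- fwhm_to_sigma(fwhm_mm) / spacing
  for (d in 1:3) {
    if (dim(arr)[d] > 1)
      arr <- .apply_along(arr, d, .smooth_operator(dim(arr)[d], sig[d]))
  }
  if (d2) arr[, , 1] else arr
}

#' Three-slice axial weighted filter
#'
#' Convolution along the slice axis with normalized weights (default
#' \[1, 4, 1\]); edge slices are renormalized over the available support.
#'
#' @param values 3D array.
#' @param weights positive length-3 weights.
#' @return filtered array.
#' @export
axial_weighted_filter <- function(values, weights = c(1, 4, 1)) {
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  if (dim(values)[3] < 2 || identical(which(weights > 0), 2L)) return(values)
  K <- .band_operator(dim(values)[3], weights / sum(weights))
  .apply_along(values, 3, K)
}
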