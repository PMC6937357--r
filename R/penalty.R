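# Relative difference penalty (RDP): an edge-preserving roughness penalty,
# a function of the difference between neighbouring voxels divided by a
# function of their sum,
#   U(f) = beta * sum_{j} sum_{k in N_j, k > j}
#            w_jk (f_j - f_k)^2 / (f_j + f_k + gamma |f_j - f_k| + eps)
# with inverse-distance neighbourhood weights (8-neighbourhood in-plane plus
# the two axial neighbours for 3D input).

# neighbour half-offsets and inverse-distance weights; spacing in voxel units
.rdp_offsets <- function(ndim, axial_ratio = 1) {
  off <- list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
  w <- c(1, 1, 1 / sqrt(2), 1 / sqrt(2))
  if (ndim == 3) {
    off <- c(off, list(c(0, 0, 1)))
    w <- c(w, 1 / axial_ratio)
  }
  list(offsets = off, weights = w)
}

#' Relative difference penalty value and gradient
#'
#' @param image nonnegative 2D matrix or 3D array of voxel values.
#' @param beta penalty weight, >= 0.
#' @param gamma edge-preservation parameter, > 0 (larger gamma penalizes
#'   large edges less).
#' @param epsilon small stabilizer added to the denominator.
#' @param axial_ratio voxel dz/dx, used for the axial neighbour weight.
#' @return list(value, gradient) where `gradient` has the shape of `image`.
#' @export
rdp_penalty <- function(image, beta = 1, gamma = 2, epsilon = 1e-9,
                        axial_ratio = 1) {
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  d <- dim(image)
  if (is.null(d)) stop("image must be a matrix or 3D array", call. = FALSE)
  arr <- if (length(d) == 2) array(image, c(d, 1)) else image
  dims <- dim(arr)
  nb <- .rdp_offsets(if (dims[3] > 1) 3 else 2, axial_ratio)
  value <- 0
  grad <- array(0, dims)
  curv <- array(0, dims)
  for (q in seq_along(nb$offsets)) {
    o <- nb$offsets[[q]]; w <- nb$weights[q]
    # index ranges of the "left" voxel a such that a + o stays in bounds
    ax <- if (o[1] >= 0) seq_len(dims[1] - o[1]) else seq(1 - o[1], dims[1])
    ay <- if (o[2] >= 0) seq_len(dims[2] - o[2]) else seq(1 - o[2], dims[2])
    az <- if (o[3] >= 0) seq_len(dims[3] - o[3]) else seq(1 - o[3], dims[3])
    bx <- ax + o[1]; by <- ay + o[2]; bz <- az + o[3]
    a <- arr[ax, ay, az, drop = FALSE]
    b <- arr[bx, by, bz, drop = FALSE]
    dd <- a - b
    s <- a + b + gamma * abs(dd) + epsilon
    value <- value + w * sum(dd^2 / s)
    sg <- sign(dd)
    ga <- w * (2 * dd * s - dd^2 * (1 + gamma * sg)) / s^2
    gb <- w * (-2 * dd * s - dd^2 * (1 - gamma * sg)) / s^2
    grad[ax, ay, az] <- grad[ax, ay, az, drop = FALSE] + ga
    grad[bx, by, bz] <- grad[bx, by, bz, drop = FALSE] + gb
    # separable curvature majorizer (2/s per pair), used as a stable
    # penalty-aware preconditioner in BSREM
    cc <- w * 2 / s
    curv[ax, ay, az] <- curv[ax, ay, az, drop = FALSE] + cc
    curv[bx, by, bz] <- curv[bx, by, bz, drop = FALSE] + cc
  }
  if (length(d) == 2) { dim(grad) <- d; dim(curv) <- d }
  list(value = beta * value, gradient = beta * grad,
       curvature = beta * curv)
}
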