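# Separable Gaussian smoothing on regular 3D grids.
#
# The 1D kernel is a sampled Gaussian truncated at 4 sigma; edge handling is
# renormalization of the truncated kernel (equivalent to smoothing value*1 and
# dividing by the smoothed indicator of the grid), so a constant field stays
# constant.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# dense n x n smoothing matrix for one axis, sigma in voxel units
smoothing_matrix <- function(n, sigma_vox, normalize = TRUE) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  d <- outer(seq_len(n), seq_len(n), `-`)
  k <- exp(-d^2 / (2 * sigma_vox^2))
  k[abs(d) > r] <- 0
  if (normalize) k <- k / rowSums(k)
  k
}

# smooth a 3D array along each axis; sigma_vox length 3 (voxel units)
smooth3d <- function(a, sigma_vox, normalize = TRUE) {
  d <- dim(a)
  stopifnot(length(d) == 3L)
  sigma_vox <- rep_len(sigma_vox, 3L)
  if (sigma_vox[1] > 0) {
    S <- smoothing_matrix(d[1], sigma_vox[1], normalize)
    a <- array(S %*% matrix(a, d[1]), dim = d)
  }
  if (sigma_vox[2] > 0) {
    S <- smoothing_matrix(d[2], sigma_vox[2], normalize)
    ap <- aperm(a, c(2, 1, 3))
    ap <- array(S %*% matrix(ap, d[2]), dim = d[c(2, 1, 3)])
    a <- aperm(ap, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    S <- smoothing_matrix(d[3], sigma_vox[3], normalize)
    ap <- aperm(a, c(3, 1, 2))
    ap <- array(S %*% matrix(ap, d[3]), dim = d[c(3, 1, 2)])
    a <- aperm(ap, c(2, 3, 1))
  }
  a
}

#' Mask-normalized Gaussian smoothing of a metric map
#'
#' Convolves the map with a Gaussian kernel of the given FWHM (mm), excluding
#' values outside the mask: the map times the mask indicator and the indicator
#' itself are smoothed with the same kernel and their ratio is taken, then the
#' result is re-masked. A constant map therefore stays constant over the mask,
#' and out-of-mask zeros do not dilute boundary voxels.
#'
#' @param map a [metric_map()].
#' @param fwhm_mm kernel full width at half maximum in mm (>= 0); sigma per
#'   axis is `fwhm / (2 sqrt(2 log 2))` converted to voxel units.
#' @return A smoothed [metric_map()] of the same kind.
#' @export
smooth_map <- function(map, fwhm_mm = 6) {
  stopifnot(inherits(map, "metric_map"))
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  if (fwhm_mm == 0) return(map)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / map$voxel_size_mm
  num <- smooth3d(map$values * map$mask, sigma_vox, normalize = FALSE)
  den <- smooth3d(array(as.numeric(map$mask), dim(map$mask)), sigma_vox,
                  normalize = FALSE)
  out <- array(0, dim(map$values))
  out[map$mask] <- num[map$mask] / den[map$mask]
  mm <- map
  mm$values <- out
  mm$provenance <- c(map$provenance, list(smooth_fwhm_mm = fwhm_mm))
  mm
}

# zero-padded shift of a 3D array by integer offset (dx, dy, dz):
# result[v] = a[v + off] where available, else 0
shift3d <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o) + o
      dst[[ax]] <- seq_len(d[ax] - o)
    } else {
      src[[ax]] <- seq_len(d[ax] + o)
      dst[[ax]] <- seq_len(d[ax] + o) - o
    }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# spatial smoothing of a 4D (x,y,z,t) array: one banded matrix multiply per
# axis across all volumes at once
smooth4d_spatial <- function(a, sigma_vox, normalize = TRUE) {
  d <- dim(a)
  stopifnot(length(d) == 4L)
  sigma_vox <- rep_len(sigma_vox, 3L)
  if (sigma_vox[1] > 0) {
    S <- smoothing_matrix(d[1], sigma_vox[1], normalize)
    a <- array(S %*% matrix(a, d[1]), dim = d)
  }
  if (sigma_vox[2] > 0) {
    S <- smoothing_matrix(d[2], sigma_vox[2], normalize)
    ap <- aperm(a, c(2, 1, 3, 4))
    ap <- array(S %*% matrix(ap, d[2]), dim = d[c(2, 1, 3, 4)])
    a <- aperm(ap, c(2, 1, 3, 4))
  }
  if (sigma_vox[3] > 0) {
    S <- smoothing_matrix(d[3], sigma_vox[3], normalize)
    ap <- aperm(a, c(3, 1, 2, 4))
    ap <- array(S %*% matrix(ap, d[3]), dim = d[c(3, 1, 2, 4)])
    a <- aperm(ap, c(2, 3, 1, 4))
  }
  a
}

# neighborhood offset table: 7 (center + 6 face), 19 (+12 edge), 27 (+8 corner)
neighborhood_offsets <- function(n = 7) {
  if (!n %in% c(7L, 19L, 27L)) stop("neighborhood must be 7, 19 or 27")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  if (n == 7L) g[ord <= 1, , drop = FALSE]
  else if (n == 19L) g[ord <= 2, , drop = FALSE]
  else g
}
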