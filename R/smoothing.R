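# Separable Gaussian smoothing via FFT, plus pyramid helpers for
# multi-resolution registration. Arrays are zero-padded by 3 sigma before
# the circular convolution so that wrap-around cannot leak signal across
# opposite faces.

gaussian_kernel_1d <- function(n, sigma) {
  # Kernel sampled on the circular frequency grid of length n, centered
  # at index 0 (wrap-around layout for FFT convolution).
  d <- ((seq_len(n) - 1 + n %/% 2) %% n) - n %/% 2
  k <- exp(-d^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian-smooth a 3D array
#'
#' @param arr 3D numeric array.
#' @param sigma Standard deviation(s) in voxels; scalar or length 3.
#' @return Smoothed array of the same dimensions.
#' @keywords internal
#' @export
gaussian_smooth <- function(arr, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (all(sigma <= 1e-8)) return(arr)
  d <- dim(arr)
  pad <- pmin(ceiling(3 * sigma), d)
  dp <- d + 2L * pad
  big <- array(0, dim = dp)
  big[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
      pad[3] + seq_len(d[3])] <- arr
  K <- outer(outer(stats::fft(gaussian_kernel_1d(dp[1], sigma[1])),
                   stats::fft(gaussian_kernel_1d(dp[2], sigma[2]))),
             stats::fft(gaussian_kernel_1d(dp[3], sigma[3])))
  sm <- Re(stats::fft(stats::fft(big) * K, inverse = TRUE)) / prod(dp)
  sm[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])]
}

# Downsample a volume_image by integer factor per axis: Gaussian
# pre-smooth (anti-alias) then pick block-center samples. The new affine
# keeps voxel centers aligned with the centers of the averaged blocks.
downsample_volume <- function(img, factor) {
  if (all(factor == 1L)) return(img)
  arr <- gaussian_smooth(img$values, sigma = factor / 2)
  d <- dim(arr)
  nshape <- pmax(d %/% factor, 1L)
  ix <- lapply(1:3, function(k)
    pmin((seq_len(nshape[k]) - 1L) * factor[k] + (factor[k] - 1) / 2 + 1,
         d[k]))
  # Fractional block centers: sample with trilinear for exact centering.
  idx <- as.matrix(expand.grid(ix[[1]] - 1, ix[[2]] - 1, ix[[3]] - 1))
  vals <- sample_trilinear(arr, idx, clamp = TRUE)
  S <- diag(4)
  S[1:3, 1:3] <- diag(factor)
  S[1:3, 4] <- (factor - 1) / 2
  grid <- grid_spec(nshape, affine = img$grid$affine %*% S)
  volume_image(array(vals, dim = nshape), grid, units = img$units,
               space = img$space)
}

# Upsample a displacement matrix (N x 3 on `from` grid) onto `to` grid by
# trilinear interpolation of each component.
resample_field_to_grid <- function(field, to_grid) {
  xyz <- grid_world_coords(to_grid)
  disp <- sample_field_world(field, xyz)
  s <- to_grid$shape
  deformation_field(list(array(disp[, 1], dim = s), array(disp[, 2], dim = s),
                         array(disp[, 3], dim = s)),
                    to_grid, direction = field$direction)
}

# Central-difference gradient of a 3D array along world axes (mm^-1 units
# assume the affine is axis-aligned up to rotation: gradient is taken in
# index space then mapped through the inverse affine transpose).
world_gradient <- function(arr, grid) {
  d <- dim(arr)
  gi <- list()
  for (k in 1:3) {
    lo <- arr; hi <- arr
    idx_hi <- c(2:d[k], d[k])
    idx_lo <- c(1, 1:(d[k] - 1))
    if (k == 1) { hi <- arr[idx_hi, , , drop = FALSE]
                  lo <- arr[idx_lo, , , drop = FALSE] }
    if (k == 2) { hi <- arr[, idx_hi, , drop = FALSE]
                  lo <- arr[, idx_lo, , drop = FALSE] }
    if (k == 3) { hi <- arr[, , idx_hi, drop = FALSE]
                  lo <- arr[, , idx_lo, drop = FALSE] }
    gi[[k]] <- (hi - lo) / 2
  }
  # d/dworld = t(inv(A3)) %*% d/dindex
  M <- t(solve(grid$affine[1:3, 1:3]))
  n <- prod(d)
  G <- cbind(as.vector(gi[[1]]), as.vector(gi[[2]]), as.vector(gi[[3]])) %*%
    t(M)
  list(array(G[, 1], dim = d), array(G[, 2], dim = d), array(G[, 3], dim = d))
}
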