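# Vectorized sampling of a 3D array at continuous voxel coordinates.
# Workhorse behind resampling, warping, field inversion and composition.

# vox: N x 3 matrix of continuous 0-based voxel indices into `arr`.
# Out-of-domain points (outside [0, dim-1] on any axis) return `fill`
# unless clamp = TRUE, which instead samples the nearest edge value
# (used for deformation-field components, where a zero fill would
# fabricate a displacement discontinuity at the boundary).
sample_trilinear <- function(arr, vox, fill = 0, clamp = FALSE) {
  d <- dim(arr)
  x <- vox[, 1L]; y <- vox[, 2L]; z <- vox[, 3L]
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  if (clamp) {
    x <- pmin(pmax(x, 0), d[1] - 1)
    y <- pmin(pmax(y, 0), d[2] - 1)
    z <- pmin(pmax(z, 0), d[3] - 1)
  }
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x0 <- pmin(pmax(x0, 0), d[1] - 1); y0 <- pmin(pmax(y0, 0), d[2] - 1)
  z0 <- pmin(pmax(z0, 0), d[3] - 1)
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  n12 <- d[1] * d[2]
  at <- function(ix, iy, iz) arr[1 + ix + d[1] * iy + n12 * iz]
  out <-
    at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
    at(x1, y1, z0) * fx       * fy       * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx       * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy       * fz +
    at(x1, y1, z1) * fx       * fy       * fz
  if (!clamp) out[!inside] <- fill
  out
}

sample_nearest <- function(arr, vox, fill = 0L) {
  d <- dim(arr)
  ix <- round(vox[, 1L]); iy <- round(vox[, 2L]); iz <- round(vox[, 3L])
  inside <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
    iz >= 0 & iz <= d[3] - 1
  ix <- pmin(pmax(ix, 0), d[1] - 1); iy <- pmin(pmax(iy, 0), d[2] - 1)
  iz <- pmin(pmax(iz, 0), d[3] - 1)
  out <- arr[1 + ix + d[1] * iy + d[1] * d[2] * iz]
  out[!inside] <- fill
  out
}

# Sample an image (volume_image or label_map) at world-mm points.
sample_image_world <- function(img, xyz, interp) {
  if (inherits(img, "label_map")) {
    if (interp != "nearest")
      nq_stop("label maps must be sampled with nearest-neighbor ",
              "interpolation", class = "contract_error")
    arr <- img$labels
  } else {
    arr <- img$values
  }
  vox <- world_to_voxel(img$grid, xyz)
  if (interp == "nearest") sample_nearest(arr, vox, fill = 0L)
  else sample_trilinear(arr, vox, fill = 0)
}
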