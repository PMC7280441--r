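#' Define a sampling grid for a 3D volume
#'
#' A grid couples an array shape with a 4x4 affine mapping 0-based voxel
#' indices to world coordinates in mm (RAS axes: +x right, +y anterior,
#' +z superior). Voxel spacing is derived from the affine's 3x3 block.
#'
#' @param shape Integer vector of length 3, voxels per axis (each >= 1).
#' @param affine 4x4 numeric matrix, voxel index -> world mm. Defaults to
#'   `diag(c(spacing, 1))` when only `spacing` is given.
#' @param spacing Optional length-3 voxel size in mm, used to build a
#'   diagonal affine when `affine` is missing.
#' @return An object of class `grid_spec` with fields `shape`, `affine`,
#'   and `spacing` (column norms of the affine's 3x3 block).
#' @examples
#' g <- grid_spec(c(64, 64, 64), spacing = c(2, 2, 2))
#' g$spacing
#' @export
grid_spec <- function(shape, affine = NULL, spacing = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L))
    nq_stop("shape must be 3 positive integers", class = "validation_error")
  if (is.null(affine)) {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (length(spacing) != 3L || any(spacing <= 0))
      nq_stop("spacing must be 3 positive lengths (mm)",
              class = "validation_error")
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
    nq_stop("affine must be a finite 4x4 matrix", class = "validation_error")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    nq_stop("affine is singular", class = "validation_error")
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(shape = shape, affine = affine, spacing = sp),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", fmt3(x$spacing), " mm\n", sep = "")
  invisible(x)
}

#' Map voxel indices to world coordinates
#'
#' @param grid A [grid_spec()].
#' @param idx N x 3 matrix of 0-based voxel indices (may be fractional).
#' @return N x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(idx %*% t(grid$affine[1:3, 1:3]), 2L, grid$affine[1:3, 4], "+")
}

#' Map world coordinates to (fractional, 0-based) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz N x 3 matrix of world coordinates in mm.
#' @return N x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  inv <- solve(grid$affine)
  sweep(xyz %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4], "+")
}

# World coordinates of every voxel center, as an N x 3 matrix in array order
# (first index fastest), N = prod(shape).
grid_world_coords <- function(grid) {
  s <- grid$shape
  idx <- cbind(
    rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  )
  voxel_to_world(grid, idx)
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && max(abs(a$affine - b$affine)) <= tol
}

is_grid_spec <- function(x) inherits(x, "grid_spec")
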