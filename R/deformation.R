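#' Dense deformation fields (pull convention)
#'
#' A deformation field stores one displacement 3-vector per voxel of its
#' *target* grid, in mm on world RAS axes. Applying a field pulls values
#' from the source space: the output at target voxel `x` is the input
#' sampled at world position `x + d(x)`. The `direction` tag records which
#' normalization direction the field realizes:
#' \describe{
#'   \item{forward}{subject -> MNI normalization: the field lives on the
#'     MNI grid and pulls subject-space images into MNI space (RSIAT).}
#'   \item{inverse}{MNI -> subject: lives on the subject grid and pulls
#'     MNI-space images (the atlas) into native space (RATSI).}
#' }
#'
#' @param displacement List of three 3D arrays (dx, dy, dz in mm), or a
#'   4D array with the component along the 4th dimension.
#' @param grid [grid_spec()] of the target space.
#' @param direction `"forward"` or `"inverse"`.
#' @return A `deformation_field`.
#' @export
deformation_field <- function(displacement, grid,
                              direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  stopifnot(is_grid_spec(grid))
  if (is.array(displacement) && length(dim(displacement)) == 4L)
    displacement <- list(displacement[, , , 1], displacement[, , , 2],
                         displacement[, , , 3])
  if (!is.list(displacement) || length(displacement) != 3L)
    nq_stop("displacement must be 3 component arrays",
            class = "validation_error")
  for (k in 1:3) {
    if (!all(dim(displacement[[k]]) == grid$shape))
      nq_stop("displacement component ", k, " does not match the grid",
              class = "validation_error")
    if (any(!is.finite(displacement[[k]])))
      nq_stop("displacement must be finite everywhere",
              class = "validation_error")
  }
  structure(list(displacement = displacement, grid = grid,
                 direction = direction),
            class = "deformation_field")
}

#' @rdname deformation_field
#' @param shape,spacing Convenience constructor for an all-zero field.
#' @export
zero_field <- function(grid, direction = "forward") {
  z <- array(0, dim = grid$shape)
  deformation_field(list(z, z, z), grid, direction = direction)
}

#' @export
print.deformation_field <- function(x, ...) {
  mags <- sqrt(x$displacement[[1]]^2 + x$displacement[[2]]^2 +
                 x$displacement[[3]]^2)
  cat("<deformation_field> ", x$direction, ", ",
      paste(x$grid$shape, collapse = "x"),
      ", max |d| = ", signif(max(mags), 4), " mm\n", sep = "")
  invisible(x)
}

# Maximum displacement magnitude in mm.
field_max_mm <- function(field) {
  max(sqrt(field$displacement[[1]]^2 + field$displacement[[2]]^2 +
             field$displacement[[3]]^2))
}

# Sample the field's displacement vectors at world points (N x 3), with
# edge clamping: a zero fill outside the domain would invent a step in
# the transform, so the nearest edge displacement is extended instead.
sample_field_world <- function(field, xyz) {
  vox <- world_to_voxel(field$grid, xyz)
  cbind(sample_trilinear(field$displacement[[1]], vox, clamp = TRUE),
        sample_trilinear(field$displacement[[2]], vox, clamp = TRUE),
        sample_trilinear(field$displacement[[3]], vox, clamp = TRUE))
}

#' Apply a deformation field to an image (pull warp)
#'
#' Output value at target voxel `x` is the input image sampled at world
#' position `x + d(x)`; points outside the input domain become background
#' (0). The output lives on the field's grid and is tagged with the
#' field's target space (forward -> MNI, inverse -> subject).
#'
#' @param img [volume_image()] or [label_map()].
#' @param field A [deformation_field()].
#' @param interp `"trilinear"` or `"nearest"`; label maps require nearest.
#' @return Warped image on `field$grid`.
#' @export
apply_deformation <- function(img, field,
                              interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(field, "deformation_field"))
  if (inherits(img, "label_map") && interp != "nearest")
    nq_stop("label maps must be warped with nearest-neighbor interpolation",
            class = "contract_error")
  xyz <- grid_world_coords(field$grid)
  pts <- xyz + cbind(as.vector(field$displacement[[1]]),
                     as.vector(field$displacement[[2]]),
                     as.vector(field$displacement[[3]]))
  vals <- sample_image_world(img, pts, interp)
  out_space <- if (field$direction == "forward") "MNI" else "subject"
  if (inherits(img, "label_map")) {
    label_map(array(as.integer(vals), dim = field$grid$shape), field$grid,
              space = out_space)
  } else {
    volume_image(array(vals, dim = field$grid$shape), field$grid,
                 units = img$units, space = out_space)
  }
}

#' Compose two deformation fields
#'
#' Returns the field `h` on `g`'s grid with
#' `h(x) = g(x) + f(x + g(x))`, i.e. applying `h` is equivalent to
#' applying `f` and then `g` in sequence (both as pull warps). `f` is
#' sampled at the displaced points with edge clamping.
#'
#' @param f,g [deformation_field()] objects; `f` must live on the space
#'   that `g` pulls from (e.g. `compose_fields(forward, inverse)` measures
#'   the subject-space round trip).
#' @return A `deformation_field` on `g`'s grid, tagged with `g`'s
#'   direction.
#' @export
compose_fields <- function(f, g) {
  stopifnot(inherits(f, "deformation_field"),
            inherits(g, "deformation_field"))
  if (f$direction == g$direction)
    nq_stop("cannot compose two fields with direction '", f$direction,
            "': f must pull from the space g maps into",
            class = "contract_error")
  xyz <- grid_world_coords(g$grid)
  gx <- cbind(as.vector(g$displacement[[1]]), as.vector(g$displacement[[2]]),
              as.vector(g$displacement[[3]]))
  fs <- sample_field_world(f, xyz + gx)
  h <- gx + fs
  s <- g$grid$shape
  deformation_field(list(array(h[, 1], dim = s), array(h[, 2], dim = s),
                         array(h[, 3], dim = s)),
                    g$grid, direction = g$direction)
}

#' Invert a deformation field by fixed-point iteration
#'
#' Solves `g(x) = -f(x + g(x))` on `target_grid`, so that composing the
#' two fields yields displacements below `tol` (in voxel units of the
#' field's minimum spacing). Errors if the residual bound is not reached,
#' reporting the worst residual: a field whose Jacobian collapses is not
#' numerically invertible at the requested tolerance.
#'
#' @param field A [deformation_field()].
#' @param target_grid Grid of the inverted field (defaults to the
#'   field's own grid, appropriate when subject and MNI grids coincide).
#' @param tol Residual tolerance in voxels (default 0.1).
#' @param max_iter Maximum fixed-point iterations (default 50).
#' @return A `deformation_field` with the opposite direction tag.
#' @export
invert_field <- function(field, target_grid = field$grid, tol = 0.1,
                         max_iter = 50L) {
  stopifnot(inherits(field, "deformation_field"))
  if (tol <= 0) nq_stop("tol must be > 0", class = "validation_error")
  xyz <- grid_world_coords(target_grid)
  n <- nrow(xyz)
  g <- matrix(0, n, 3L)
  vox_mm <- min(field$grid$spacing)
  fs <- sample_field_world(field, xyz + g)
  resid <- max(sqrt(rowSums((fs + g)^2))) / vox_mm
  # Iterate toward a quarter of the requested tolerance while progress
  # lasts, so downstream compositions (e.g. double inversion) stay well
  # inside the contract.
  for (it in seq_len(max_iter)) {
    if (resid <= 0.25 * tol) break
    # Full fixed-point step; fall back to a damped step whenever the
    # residual fails to contract (fields near the invertibility limit).
    g_new <- -fs
    fs_new <- sample_field_world(field, xyz + g_new)
    resid_new <- max(sqrt(rowSums((fs_new + g_new)^2))) / vox_mm
    if (resid_new >= resid) {
      g_new <- 0.5 * g - 0.5 * fs
      fs_new <- sample_field_world(field, xyz + g_new)
      resid_new <- max(sqrt(rowSums((fs_new + g_new)^2))) / vox_mm
      if (resid_new >= resid) break
    }
    g <- g_new; fs <- fs_new; resid <- resid_new
  }
  if (resid > tol)
    nq_stop("field not invertible to tolerance: worst residual ",
            signif(resid, 4), " voxels after ", max_iter, " iterations",
            class = "non_invertible_error")
  s <- target_grid$shape
  deformation_field(
    list(array(g[, 1], dim = s), array(g[, 2], dim = s),
         array(g[, 3], dim = s)),
    target_grid,
    direction = if (field$direction == "forward") "inverse" else "forward")
}
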