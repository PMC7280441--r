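#' Volumetric image containers
#'
#' Three lightweight S3 containers carry all voxel data in the package:
#' `volume_image` for scalar volumes (T1 intensity, tracer activity in
#' kBq/mL, or unitless SUV), `label_map` for integer parcellations
#' (0 = background), and `binary_mask` for single-region membership.
#' All three pair a numeric array with a [grid_spec()] and a `space`
#' tag ("subject" or "MNI").
#'
#' @param values Numeric 3D array matching `grid$shape`.
#' @param grid A [grid_spec()].
#' @param units One of `"intensity"`, `"kBq/mL"`, `"SUV"`.
#' @param space `"subject"` or `"MNI"`.
#' @return A `volume_image`.
#' @examples
#' g <- grid_spec(c(4, 4, 4), spacing = c(1, 1, 1))
#' v <- volume_image(array(1, dim = c(4, 4, 4)), g, units = "SUV")
#' @export
volume_image <- function(values, grid,
                         units = c("intensity", "kBq/mL", "SUV"),
                         space = c("subject", "MNI")) {
  units <- match.arg(units)
  space <- match.arg(space)
  stopifnot(is_grid_spec(grid))
  values <- check_values_array(values, grid)
  if (units %in% c("kBq/mL", "SUV")) {
    if (any(!is.finite(values)))
      nq_stop("activity/SUV values must be finite", class = "validation_error")
    if (units == "kBq/mL" && any(values < 0))
      nq_stop("activity values must be >= 0", class = "validation_error")
  }
  structure(list(values = values, grid = grid, units = units, space = space),
            class = "volume_image")
}

#' @rdname volume_image
#' @param labels Integer-valued 3D array (0 = background).
#' @export
label_map <- function(labels, grid, space = c("subject", "MNI")) {
  space <- match.arg(space)
  stopifnot(is_grid_spec(grid))
  labels <- check_values_array(labels, grid)
  bad <- sum(labels != round(labels) | labels < 0, na.rm = TRUE) +
    sum(is.na(labels))
  if (bad > 0L)
    nq_stop(bad, " voxel(s) hold non-integral or negative values; ",
            "not a valid label map", class = "validation_error")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, grid = grid, space = space),
            class = "label_map")
}

#' @rdname volume_image
#' @param membership Logical 3D array.
#' @export
binary_mask <- function(membership, grid, space = c("subject", "MNI")) {
  space <- match.arg(space)
  stopifnot(is_grid_spec(grid))
  membership <- check_values_array(membership, grid, logical_ok = TRUE)
  if (!is.logical(membership)) {
    if (any(!(membership %in% c(0, 1))))
      nq_stop("mask values must be logical or 0/1", class = "validation_error")
    membership <- array(as.logical(membership), dim = grid$shape)
  }
  structure(list(membership = membership, grid = grid, space = space),
            class = "binary_mask")
}

check_values_array <- function(values, grid, logical_ok = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    nq_stop("values must be a 3D array", class = "validation_error")
  if (!all(dim(values) == grid$shape))
    nq_stop("array dimensions ", paste(dim(values), collapse = "x"),
            " do not match grid shape ", paste(grid$shape, collapse = "x"),
            class = "validation_error")
  if (!logical_ok && !is.numeric(values))
    nq_stop("values must be numeric", class = "validation_error")
  values
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(x$grid$shape, collapse = "x"),
      ", units=", x$units, ", space=", x$space,
      ", range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  labs <- label_set(x)
  cat("<label_map> ", paste(x$grid$shape, collapse = "x"),
      ", space=", x$space, ", ", length(labs), " nonzero labels\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(x$grid$shape, collapse = "x"),
      ", space=", x$space, ", |A| = ", sum(x$membership), "\n", sep = "")
  invisible(x)
}

#' Nonzero labels present in a label map
#' @param map A [label_map()].
#' @return Sorted integer vector of distinct nonzero labels.
#' @export
label_set <- function(map) {
  stopifnot(inherits(map, "label_map"))
  sort(unique(as.vector(map$labels[map$labels != 0L])))
}
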