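#' Resample an image onto a target grid
#'
#' Values are sampled at the target grid's voxel centers, mapped through
#' both affines into the source volume. Target voxels falling outside the
#' source domain receive 0 (background) rather than a clamped edge value,
#' so warped atlases never smear edge labels outward.
#'
#' @param img A [volume_image()] or [label_map()].
#' @param target A [grid_spec()] to resample onto.
#' @param interp `"trilinear"` or `"nearest"`. Label maps require
#'   `"nearest"` (exact label membership is preserved end-to-end).
#' @return The same kind of object as `img`, on `target`.
#' @examples
#' g <- grid_spec(c(8, 8, 8), spacing = c(2, 2, 2))
#' v <- volume_image(array(rnorm(512), dim = c(8, 8, 8)), g)
#' identical(resample(v, g, "trilinear")$values, v$values)
#' @export
resample <- function(img, target, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(is_grid_spec(target))
  if (inherits(img, "label_map") && interp != "nearest")
    nq_stop("trilinear interpolation requested for a label map; ",
            "labels require interp = \"nearest\"", class = "contract_error")
  if (grids_equal(img$grid, target)) return(img)
  xyz <- grid_world_coords(target)
  vals <- sample_image_world(img, xyz, interp)
  if (inherits(img, "label_map")) {
    label_map(array(as.integer(vals), dim = target$shape), target,
              space = img$space)
  } else {
    volume_image(array(vals, dim = target$shape), target,
                 units = img$units, space = img$space)
  }
}
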