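#' Read a NIfTI-1 volume
#'
#' Reconstructs the sampling grid from the header affine (sform preferred)
#' and wraps the voxel data as a [volume_image()] or, with `as_labels`,
#' a [label_map()] after verifying that every voxel is integral.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param as_labels Logical; validate and return an integer parcellation.
#' @param units,space Passed to the container constructor.
#' @return A `volume_image` or `label_map`.
#' @export
read_volume <- function(path, as_labels = FALSE, units = "intensity",
                        space = "subject") {
  if (!file.exists(path))
    nq_stop("file not found: ", path, class = "io_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) nq_stop("cannot read NIfTI file ", path,
                                              ": ", conditionMessage(e),
                                              class = "io_error"))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    nq_stop(path, " is not a 3D volume", class = "io_error")
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  grid <- grid_spec(dim(arr), affine = rbind(unclass(aff)[1:3, , drop = FALSE],
                                             c(0, 0, 0, 1)))
  if (as_labels) {
    bad <- sum(arr != round(arr) | arr < 0 | !is.finite(arr))
    if (bad > 0L)
      nq_stop(bad, " voxel(s) in ", path, " are non-integral or negative; ",
              "refusing to interpret as labels", class = "validation_error")
    label_map(array(as.integer(round(arr)), dim = dim(arr)), grid,
              space = space)
  } else {
    volume_image(array(as.numeric(arr), dim = dim(arr)), grid,
                 units = units, space = space)
  }
}

#' Write a volume or label map as NIfTI-1
#'
#' Label maps are stored in an integer datatype (int32); scalar volumes in
#' float64. The grid affine is written to both sform and qform.
#'
#' @param img A [volume_image()] or [label_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    nq_stop("directory does not exist: ", dir, class = "io_error")
  if (inherits(img, "label_map")) {
    arr <- img$labels
    dtype <- "int32"
  } else if (inherits(img, "volume_image")) {
    arr <- img$values
    dtype <- "double"
  } else if (inherits(img, "binary_mask")) {
    arr <- array(as.integer(img$membership), dim = img$grid$shape)
    dtype <- "uint8"
  } else {
    nq_stop("unsupported object of class ", paste(class(img), collapse = "/"),
            class = "validation_error")
  }
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- img$grid$spacing
  nii <- RNifti::`sform<-`(nii, structure(img$grid$affine, code = 2L))
  nii <- RNifti::`qform<-`(nii, structure(img$grid$affine, code = 2L))
  RNifti::writeNifti(nii, path, datatype = dtype)
  invisible(path)
}

#' Serialize a deformation field as 4D NIfTI plus a JSON sidecar
#'
#' Displacement components (mm, world axes) are stored along the fourth
#' dimension; the sidecar records the direction tag and the pull-warp
#' convention so a field can never be silently applied backwards.
#'
#' @param field A [deformation_field()].
#' @param path Output `.nii`/`.nii.gz` path; the sidecar is written next
#'   to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "deformation_field"))
  arr <- array(0, dim = c(field$grid$shape, 3L))
  for (k in 1:3) arr[, , , k] <- field$displacement[[k]]
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- field$grid$spacing
  nii <- RNifti::`sform<-`(nii, structure(field$grid$affine, code = 2L))
  nii <- RNifti::`qform<-`(nii, structure(field$grid$affine, code = 2L))
  RNifti::writeNifti(nii, path, datatype = "double")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(direction = field$direction,
         convention = "pull; displacement in mm on world RAS axes",
         grid_shape = field$grid$shape),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @param default_direction Direction tag used when no sidecar is found.
#' @export
read_field <- function(path, default_direction = "forward") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 5L) arr <- array(arr, dim = dim(arr)[c(1:3, 5)])
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    nq_stop(path, " is not a 3-component 4D field", class = "io_error")
  aff <- unclass(RNifti::xform(img))
  grid <- grid_spec(dim(arr)[1:3],
                    affine = rbind(aff[1:3, , drop = FALSE], c(0, 0, 0, 1)))
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  direction <- default_direction
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    direction <- meta$direction %||% default_direction
  }
  deformation_field(list(arr[, , , 1], arr[, , , 2], arr[, , , 3]),
                    grid, direction = direction)
}

#' Read a region table (TSV with columns label, name)
#'
#' @param path TSV path.
#' @return data.frame with integer `label` and character `name`.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path))
    nq_stop("region table not found: ", path, class = "io_error")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "name") %in% names(tab)))
    nq_stop("region table must have columns 'label' and 'name'",
            class = "validation_error")
  tab$label <- as.integer(tab$label)
  tab
}
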