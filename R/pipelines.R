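#' Segmentation results from the two atlas-based pipelines
#'
#' A `segmentation_result` couples a label map with the method that
#' produced it (`"RATSI"`, `"RSIAT"`, or `"manual"`) and the
#' normalization it came from. RATSI and manual segmentations live in
#' subject space; RSIAT segmentations live in MNI space.
#'
#' @param labels A [label_map()].
#' @param method `"RATSI"`, `"RSIAT"`, or `"manual"`.
#' @param provenance Optional `normalization_result` reference.
#' @return A `segmentation_result`.
#' @export
segmentation_result <- function(labels, method = c("RATSI", "RSIAT",
                                                   "manual"),
                                provenance = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(labels, "label_map"))
  want <- if (method == "RSIAT") "MNI" else "subject"
  if (labels$space != want)
    nq_stop(method, " segmentations must be tagged ", want, " space",
            class = "validation_error")
  structure(list(method = method, labels = labels, provenance = provenance),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> method=", x$method, ", space=",
      x$labels$space, ", ", length(label_set(x$labels)),
      " labels present\n", sep = "")
  invisible(x)
}

#' RATSI: warp the atlas into the subject's native space
#'
#' Registering the atlas template to the subject's images: the labeled
#' parcellation is pull-warped through the inverse deformation field with
#' nearest-neighbor interpolation, producing a personalized atlas on the
#' subject grid. PET is then quantified in native space, untouched by
#' any resampling.
#'
#' @param atlas An [atlas_template()].
#' @param norm A `normalization_result` with an `inverse` field.
#' @param subject_grid Target [grid_spec()]; defaults to the grid of the
#'   inverse field.
#' @return A `segmentation_result` (method RATSI, subject space).
#' @export
ratsi_segment <- function(atlas, norm, subject_grid = NULL) {
  stopifnot(inherits(atlas, "atlas_template"))
  if (is.null(norm$inverse))
    nq_stop("normalization result carries no inverse field",
            class = "contract_error")
  inv <- norm$inverse
  if (!is.null(subject_grid) && !grids_equal(inv$grid, subject_grid))
    inv <- resample_field_to_grid(inv, subject_grid)
  personalized <- apply_deformation(atlas$parcellation, inv,
                                    interp = "nearest")
  segmentation_result(personalized, method = "RATSI", provenance = norm)
}

#' RSIAT: normalize the subject's PET into MNI space
#'
#' Registering the subject's images to the atlas template: the PET volume
#' is pull-warped through the forward deformation field with trilinear
#' interpolation onto the atlas grid (no Jacobian intensity modulation —
#' SUV is a concentration), and segmented directly by the fixed atlas
#' parcellation.
#'
#' @param atlas An [atlas_template()].
#' @param norm A `normalization_result` with a `forward` field.
#' @param pet Subject-space [volume_image()].
#' @return List with `normalized_pet` (MNI-space volume) and
#'   `segmentation` (a `segmentation_result`, method RSIAT, whose labels
#'   are the atlas parcellation itself).
#' @export
rsiat_segment <- function(atlas, norm, pet) {
  stopifnot(inherits(atlas, "atlas_template"),
            inherits(pet, "volume_image"))
  if (is.null(norm$forward))
    nq_stop("normalization result carries no forward field",
            class = "contract_error")
  if (pet$space != "subject")
    nq_stop("pet must be a subject-space volume", class = "contract_error")
  fwd <- norm$forward
  if (!grids_equal(fwd$grid, atlas$parcellation$grid))
    fwd <- resample_field_to_grid(fwd, atlas$parcellation$grid)
  warped <- apply_deformation(pet, fwd, interp = "trilinear")
  total_in <- sum(pet$values) * prod(pet$grid$spacing)
  total_out <- sum(warped$values) * prod(warped$grid$spacing)
  nq_log("RSIAT warp changed total activity by ",
         signif(100 * (total_out - total_in) / max(total_in, 1e-12), 3),
         "% (no conservation enforced)")
  seg <- segmentation_result(atlas$parcellation, method = "RSIAT",
                             provenance = norm)
  list(normalized_pet = warped, segmentation = seg)
}
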