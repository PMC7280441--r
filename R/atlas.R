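#' Atlas template: parcellation, region table, reference T1
#'
#' Bundles an MNI-space labeled parcellation (integer labels, 0 =
#' background), a region table mapping each label to a name (e.g.
#' `23 -> CAU_L`), and the reference structural volume the parcellation
#' is defined on. Every nonzero label present in the parcellation must
#' appear in the table.
#'
#' @param parcellation A [label_map()] in MNI space.
#' @param regions data.frame with columns `label` (int) and `name`.
#' @param reference_t1 A [volume_image()] in MNI space.
#' @return An `atlas_template`.
#' @export
atlas_template <- function(parcellation, regions, reference_t1) {
  stopifnot(inherits(parcellation, "label_map"),
            inherits(reference_t1, "volume_image"))
  if (parcellation$space != "MNI" || reference_t1$space != "MNI")
    nq_stop("atlas parcellation and reference must be tagged MNI",
            class = "validation_error")
  present <- label_set(parcellation)
  orphans <- setdiff(present, regions$label)
  if (length(orphans))
    nq_stop("parcellation labels missing from the region table: {",
            paste(orphans, collapse = ", "), "}",
            class = "validation_error")
  if (anyDuplicated(regions$label))
    nq_stop("duplicate labels in the region table",
            class = "validation_error")
  structure(list(parcellation = parcellation, regions = regions,
                 reference_t1 = reference_t1),
            class = "atlas_template")
}

#' @export
print.atlas_template <- function(x, ...) {
  cat("<atlas_template> ", nrow(x$regions), " regions, ",
      length(label_set(x$parcellation)), " present in the parcellation\n",
      sep = "")
  invisible(x)
}

#' Load an atlas template from files
#'
#' @param parcellation_path NIfTI parcellation (integer labels).
#' @param region_table_path TSV with columns `label`, `name`.
#' @param reference_path NIfTI reference T1.
#' @return An [atlas_template()].
#' @export
load_atlas <- function(parcellation_path, region_table_path,
                       reference_path) {
  parc <- read_volume(parcellation_path, as_labels = TRUE, space = "MNI")
  regions <- read_region_table(region_table_path)
  ref <- read_volume(reference_path, units = "intensity", space = "MNI")
  atlas_template(parc, regions, ref)
}

#' Look up a region label by name, or a name by label
#'
#' @param atlas An [atlas_template()].
#' @param name,label Exactly one of the two.
#' @return Integer label or character name.
#' @export
region_lookup <- function(atlas, name = NULL, label = NULL) {
  if (!is.null(name)) {
    hit <- atlas$regions$label[atlas$regions$name == name]
    if (!length(hit))
      nq_stop("region name not found: ", name, class = "validation_error")
    return(hit[1])
  }
  if (!is.null(label)) {
    hit <- atlas$regions$name[atlas$regions$label == label]
    if (!length(hit))
      nq_stop("label not found: ", label, class = "validation_error")
    return(hit[1])
  }
  nq_stop("supply name or label", class = "validation_error")
}

#' Extract the binary mask of one region
#'
#' An absent label yields an empty mask with a warning (so cohort runs
#' survive single-region dropouts); quantifying that empty region later
#' is the hard error.
#'
#' @param seg A `segmentation_result` or [label_map()].
#' @param label Integer region label.
#' @return A [binary_mask()].
#' @export
region_mask <- function(seg, label) {
  map <- if (inherits(seg, "segmentation_result")) seg$labels else seg
  stopifnot(inherits(map, "label_map"))
  label <- as.integer(label)
  mem <- map$labels == label
  if (!any(mem))
    warning("label ", label, " is absent from the map; returning an ",
            "empty mask", call. = FALSE)
  binary_mask(array(mem, dim = map$grid$shape), map$grid, space = map$space)
}
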