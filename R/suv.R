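#' Injection metadata for SUV computation
#'
#' SUV = r / (a'/w), where r is the tissue radioactivity concentration
#' in kBq/mL, a' the decay-corrected injected activity in kBq at the
#' reference time, and w the body weight in grams. The decay-correction
#' reference defaults to scan start.
#'
#' @param injected_activity_kBq Injected activity in kBq at injection
#'   time.
#' @param weight_g Body weight in grams.
#' @param injection_time,reference_time Timestamps (`POSIXct`) or
#'   numbers interpreted as minutes; `reference_time` must not precede
#'   `injection_time`.
#' @param isotope_half_life_min Isotope half-life in minutes
#'   (default 109.77, F-18).
#' @return An `suv_inputs` list.
#' @export
suv_inputs <- function(injected_activity_kBq, weight_g,
                       injection_time = 0, reference_time = injection_time,
                       isotope_half_life_min = 109.77) {
  if (!is_scalar_number(weight_g) || weight_g <= 0)
    nq_stop("weight must be > 0 g", class = "validation_error")
  if (!is_scalar_number(injected_activity_kBq) || injected_activity_kBq <= 0)
    nq_stop("injected activity must be > 0 kBq", class = "validation_error")
  elapsed <- elapsed_minutes(injection_time, reference_time)
  if (elapsed < 0)
    nq_stop("reference_time precedes injection_time",
            class = "validation_error")
  structure(list(injected_activity_kBq = injected_activity_kBq,
                 weight_g = weight_g,
                 injection_time = injection_time,
                 reference_time = reference_time,
                 isotope_half_life_min = isotope_half_life_min),
            class = "suv_inputs")
}

elapsed_minutes <- function(from, to) {
  if (inherits(from, "POSIXt") && inherits(to, "POSIXt"))
    as.numeric(difftime(to, from, units = "mins"))
  else as.numeric(to) - as.numeric(from)
}

#' Radioactive decay correction
#'
#' @param activity_kBq Activity in kBq.
#' @param elapsed_min Minutes elapsed (>= 0).
#' @param half_life_min Isotope half-life in minutes (> 0).
#' @return `activity_kBq * 2^(-elapsed_min / half_life_min)`.
#' @examples
#' decay_correct(100000, 109.77, 109.77)  # one half-life -> 50000
#' @export
decay_correct <- function(activity_kBq, elapsed_min,
                          half_life_min = 109.77) {
  if (any(elapsed_min < 0))
    nq_stop("elapsed time must be >= 0", class = "validation_error")
  if (half_life_min <= 0)
    nq_stop("half-life must be > 0", class = "validation_error")
  activity_kBq * 2^(-elapsed_min / half_life_min)
}

#' Convert an administered dose from mCi to MBq
#'
#' 1 mCi = 37 MBq exactly.
#'
#' @param value_mCi Dose in millicuries (>= 0).
#' @return Dose in MBq.
#' @examples
#' convert_dose(0.1)  # 3.7 MBq
#' @export
convert_dose <- function(value_mCi) {
  if (any(value_mCi < 0))
    nq_stop("dose must be >= 0", class = "validation_error")
  value_mCi * 37
}

#' Convert a PET activity-concentration volume to SUV
#'
#' Applies SUV = r * w / a' voxelwise, with a' the injected activity
#' decay-corrected from injection time to the reference time.
#'
#' @param pet A [volume_image()] with units `"kBq/mL"`.
#' @param inputs An [suv_inputs()].
#' @return A [volume_image()] with units `"SUV"`.
#' @export
suv_image <- function(pet, inputs) {
  stopifnot(inherits(pet, "volume_image"), inherits(inputs, "suv_inputs"))
  if (pet$units != "kBq/mL")
    nq_stop("pet must carry activity units kBq/mL, got ", pet$units,
            class = "contract_error")
  elapsed <- elapsed_minutes(inputs$injection_time, inputs$reference_time)
  a_prime <- decay_correct(inputs$injected_activity_kBq, elapsed,
                           inputs$isotope_half_life_min)
  if (a_prime <= 0)
    nq_stop("decay-corrected activity must be > 0",
            class = "validation_error")
  volume_image(pet$values * inputs$weight_g / a_prime, pet$grid,
               units = "SUV", space = pet$space)
}

#' Regional SUV statistics through a segmentation
#'
#' For each requested label, the arithmetic mean and maximum SUV over the
#' region's voxels (plain mask overlap, no thresholding), with voxel
#' count and physical volume. An empty region among the requested labels
#' is a hard per-region error: a silent zero would corrupt downstream
#' group statistics.
#'
#' @param suv An SUV [volume_image()].
#' @param seg A `segmentation_result` or [label_map()] on the same grid
#'   and space.
#' @param regions Integer labels to quantify; default all labels in the
#'   region table of `seg`'s provenance, else all present labels.
#' @param region_names Optional character names matching `regions`.
#' @return data.frame with columns `label`, `name`, `suv_mean`,
#'   `suv_max`, `voxel_count`, `volume_mm3`.
#' @export
regional_quantify <- function(suv, seg, regions = NULL,
                              region_names = NULL) {
  stopifnot(inherits(suv, "volume_image"))
  map <- if (inherits(seg, "segmentation_result")) seg$labels else seg
  stopifnot(inherits(map, "label_map"))
  if (!grids_equal(suv$grid, map$grid))
    nq_stop("SUV volume and segmentation are on different grids",
            class = "contract_error")
  if (suv$space != map$space)
    nq_stop("SUV volume (", suv$space, ") and segmentation (", map$space,
            ") are in different spaces", class = "contract_error")
  if (is.null(regions)) regions <- label_set(map)
  regions <- as.integer(regions)
  if (is.null(region_names)) region_names <- as.character(regions)
  vol_per_voxel <- abs(det(map$grid$affine[1:3, 1:3]))
  labv <- as.vector(map$labels)
  suvv <- as.vector(suv$values)
  out <- lapply(seq_along(regions), function(i) {
    sel <- labv == regions[i]
    n <- sum(sel)
    if (n == 0L)
      nq_stop("region ", regions[i], " (", region_names[i],
              ") is empty in the segmentation", class = "empty_region_error")
    v <- suvv[sel]
    data.frame(label = regions[i], name = region_names[i],
               suv_mean = mean(v), suv_max = max(v), voxel_count = n,
               volume_mm3 = n * vol_per_voxel)
  })
  do.call(rbind, out)
}
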