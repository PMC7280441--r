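#' Dice overlap coefficient between two masks
#'
#' DC = 2|A intersect B| / (|A| + |B|): 1 for identical segmentations,
#' 0 for disjoint ones.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return Numeric in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!grids_equal(a$grid, b$grid))
    nq_stop("masks are on different grids", class = "contract_error")
  na <- sum(a$membership); nb <- sum(b$membership)
  if (na == 0L && nb == 0L)
    nq_stop("Dice is undefined for two empty masks",
            class = "undefined_input_error")
  2 * sum(a$membership & b$membership) / (na + nb)
}

# 6-connectivity boundary of a logical array: voxels of the mask with at
# least one face neighbor outside it (array edges count as outside).
mask_boundary <- function(m) {
  d <- dim(m)
  inner <- array(TRUE, dim = d)
  shift_and <- function(arr, axis, by) {
    out <- array(FALSE, dim = d)
    if (axis == 1) {
      if (by == 1) out[2:d[1], , ] <- arr[1:(d[1] - 1), , ]
      else out[1:(d[1] - 1), , ] <- arr[2:d[1], , ]
    } else if (axis == 2) {
      if (by == 1) out[, 2:d[2], ] <- arr[, 1:(d[2] - 1), ]
      else out[, 1:(d[2] - 1), ] <- arr[, 2:d[2], ]
    } else {
      if (by == 1) out[, , 2:d[3]] <- arr[, , 1:(d[3] - 1)]
      else out[, , 1:(d[3] - 1)] <- arr[, , 2:d[3]]
    }
    out
  }
  for (ax in 1:3) for (by in c(1, -1))
    inner <- inner & shift_and(m, ax, by)
  m & !inner
}

mask_index_coords <- function(m) {
  d <- dim(m)
  w <- which(m) - 1L
  cbind(w %% d[1], (w %/% d[1]) %% d[2], w %/% (d[1] * d[2]))
}

# max over x in A of d(x, B), Euclidean in index units. For x in A & B
# the distance is 0; for x outside B the nearest member of B lies on B's
# 6-connectivity boundary, so only A \ B against boundary(B) is scanned.
directed_hausdorff_idx <- function(ma, mb, percentile = 100) {
  outside <- ma & !mb
  if (!any(outside)) return(0)
  X <- mask_index_coords(outside)
  Y <- mask_index_coords(mask_boundary(mb))
  dmin <- numeric(nrow(X))
  chunk <- max(1L, floor(2e6 / nrow(Y)))
  for (s in seq(1L, nrow(X), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(X))
    Xi <- X[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Xi^2), rowSums(Y^2), "+") - 2 * tcrossprod(Xi, Y)
    dmin[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  if (percentile >= 100) max(dmin)
  else as.numeric(stats::quantile(dmin, percentile / 100, type = 7))
}

#' Hausdorff distance between two masks, in voxel ("pixel") units
#'
#' Symmetric exact-Euclidean Hausdorff distance over voxel-center
#' coordinates in index space. Grids are assumed isotropic (callers
#' evaluating in a common space resample to isotropic voxels first); a
#' warning is raised otherwise.
#'
#' @param a,b Nonempty [binary_mask()] objects on the same grid.
#' @param percentile Distance percentile (100 = classic maximum
#'   Hausdorff; 95 gives the robust HD95 variant).
#' @return Distance in voxels.
#' @export
hausdorff <- function(a, b, percentile = 100) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!grids_equal(a$grid, b$grid))
    nq_stop("masks are on different grids", class = "contract_error")
  if (!any(a$membership) || !any(b$membership))
    nq_stop("Hausdorff distance is undefined for an empty mask",
            class = "undefined_input_error")
  sp <- a$grid$spacing
  if (max(sp) - min(sp) > 1e-6 * max(sp))
    warning("grid is anisotropic; Hausdorff reported in voxel units of ",
            "unequal physical size", call. = FALSE)
  max(directed_hausdorff_idx(a$membership, b$membership, percentile),
      directed_hausdorff_idx(b$membership, a$membership, percentile))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `y - x`; the limits of agreement are
#' bias +/- 1.96 * SD of the differences. `fraction_within` counts pairs
#' strictly inside the open interval (loa_low, loa_high): ties on a
#' limit line count as outside.
#'
#' @param x,y Paired numeric vectors, equal length >= 3.
#' @return A `bland_altman_result` with `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `fraction_within`, `pairs`, and the per-pair `means` /
#'   `differences` for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    nq_stop("x and y must have equal length", class = "validation_error")
  if (length(x) < 3L)
    nq_stop("Bland-Altman needs at least 3 pairs",
            class = "validation_error")
  d <- y - x
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * sdd
  within <- d > loa[1] & d < loa[2]
  structure(list(bias = bias, loa_low = loa[1], loa_high = loa[2],
                 sd_diff = sdd, fraction_within = mean(within),
                 pairs = length(d), means = (x + y) / 2, differences = d),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat("<bland_altman> bias ", signif(x$bias, 4), ", LoA [",
      signif(x$loa_low, 4), ", ", signif(x$loa_high, 4), "], ",
      round(100 * x$fraction_within, 1), "% of ", x$pairs,
      " pairs within\n", sep = "")
  invisible(x)
}

#' Evaluate a segmentation against ground truth in its own working space
#'
#' Each pipeline touches the PET through masks in a particular space, so
#' accuracy is judged there: RATSI and manual segmentations are compared
#' with the truth labels directly on the native subject grid, while an
#' RSIAT segmentation (the fixed atlas, MNI space) is compared with the
#' truth labels pull-warped into MNI through the *estimated* forward
#' field — exactly what normalizing a reference segmentation would do in
#' practice. This captures the resampling cost RSIAT pays for moving
#' subject data onto the coarser template grid, which
#' [evaluate_in_common_space()] deliberately cancels.
#'
#' @param seg A `segmentation_result`.
#' @param truth_labels Ground-truth [label_map()] on the subject grid.
#' @param norm The `normalization_result` used by the pipeline (needed
#'   for MNI-space segmentations).
#' @param regions Integer labels to evaluate.
#' @param region_names Optional names matching `regions`.
#' @return data.frame with columns `label`, `name`, `dice`,
#'   `hausdorff_pixels`, `space`, `note`.
#' @export
evaluate_vs_truth <- function(seg, truth_labels, norm = NULL, regions,
                              region_names = NULL) {
  stopifnot(inherits(seg, "segmentation_result"),
            inherits(truth_labels, "label_map"))
  if (seg$labels$space == "subject") {
    ref <- truth_labels
    cmp <- seg$labels
    spc <- "subject"
  } else {
    if (is.null(norm$forward))
      nq_stop("evaluating an MNI-space segmentation needs the forward ",
              "field", class = "contract_error")
    ref <- apply_deformation(truth_labels, norm$forward, "nearest")
    cmp <- seg$labels
    spc <- "MNI"
  }
  if (is.null(region_names)) region_names <- as.character(regions)
  rows <- lapply(seq_along(regions), function(i) {
    lab <- regions[i]
    inc <- any(cmp$labels == lab); inr <- any(ref$labels == lab)
    if (!inc || !inr)
      return(data.frame(label = lab, name = region_names[i],
                        dice = NA_real_, hausdorff_pixels = NA_real_,
                        hausdorff_mm = NA_real_, space = spc,
                        note = "region empty in segmentation or truth"))
    a <- binary_mask(array(cmp$labels == lab, dim = cmp$grid$shape),
                     cmp$grid, space = cmp$space)
    b <- binary_mask(array(ref$labels == lab, dim = ref$grid$shape),
                     ref$grid, space = ref$space)
    hd <- hausdorff(a, b)
    data.frame(label = lab, name = region_names[i], dice = dice(a, b),
               hausdorff_pixels = hd,
               hausdorff_mm = hd * min(cmp$grid$spacing), space = spc,
               note = NA_character_)
  })
  do.call(rbind, rows)
}

#' Compare segmentations per region in a common (MNI) space
#'
#' Follows the evaluation protocol of normalizing all segmentations into
#' the same MNI space before computing agreement: any subject-space label
#' map is pull-warped to MNI through the forward field with
#' nearest-neighbor interpolation, then Dice and Hausdorff are computed
#' region by region. If the MNI grid is anisotropic, both maps are first
#' resampled to isotropic voxels at the smallest spacing.
#'
#' @param auto,manual `segmentation_result` objects (or [label_map()]s,
#'   taken as subject-space manual maps).
#' @param norm A `normalization_result` whose forward field performs the
#'   warp for subject-space inputs.
#' @param regions Integer labels to evaluate.
#' @param region_names Optional names matching `regions`.
#' @return data.frame with columns `label`, `name`, `dice`,
#'   `hausdorff_pixels`, `space`, `note` (NA metrics plus a note for
#'   regions empty after warping).
#' @export
evaluate_in_common_space <- function(auto, manual, norm, regions,
                                     region_names = NULL) {
  to_mni <- function(seg) {
    map <- if (inherits(seg, "segmentation_result")) seg$labels else seg
    stopifnot(inherits(map, "label_map"))
    if (map$space == "MNI") return(map)
    if (is.null(norm$forward))
      nq_stop("subject-space input needs a forward field",
              class = "contract_error")
    apply_deformation(map, norm$forward, interp = "nearest")
  }
  a <- to_mni(auto)
  m <- to_mni(manual)
  sp <- a$grid$spacing
  if (max(sp) - min(sp) > 1e-6 * max(sp)) {
    iso <- grid_spec(ceiling(a$grid$shape * sp / min(sp)),
                     affine = a$grid$affine %*%
                       diag(c(rep(min(sp), 3) / sp, 1)))
    a <- resample(a, iso, "nearest")
    m <- resample(m, iso, "nearest")
  }
  if (is.null(region_names)) region_names <- as.character(regions)
  rows <- lapply(seq_along(regions), function(i) {
    lab <- regions[i]
    ina <- any(a$labels == lab); inm <- any(m$labels == lab)
    if (!ina || !inm) {
      return(data.frame(label = lab, name = region_names[i], dice = NA_real_,
                        hausdorff_pixels = NA_real_, hausdorff_mm = NA_real_,
                        space = "MNI",
                        note = paste0("region empty after warping in ",
                                      if (!ina) "auto" else "manual")))
    }
    ma <- binary_mask(array(a$labels == lab, dim = a$grid$shape), a$grid,
                      space = "MNI")
    mm <- binary_mask(array(m$labels == lab, dim = m$grid$shape), m$grid,
                      space = "MNI")
    hd <- hausdorff(ma, mm)
    data.frame(label = lab, name = region_names[i], dice = dice(ma, mm),
               hausdorff_pixels = hd, hausdorff_mm = hd * min(a$grid$spacing),
               space = "MNI", note = NA_character_)
  })
  do.call(rbind, rows)
}
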