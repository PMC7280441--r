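#' Phantom generation settings
#'
#' The phantom emulates the study conditions of an FDG PET/MR cohort: a
#' 70-region atlas on a 64^3 grid covering a 128 mm field of view, smooth
#' subject-specific anatomical deformations of a few mm, PET partial-
#' volume blur at scanner-like resolution, and additive measurement
#' noise. Every output is a pure function of the spec and its seed.
#'
#' @param grid_shape Voxels per axis (scalar, >= 16); default 64.
#' @param spacing mm per voxel; defaults to `128 / grid_shape` so the
#'   anatomy keeps its physical size when the grid is scaled down.
#' @param n_regions Number of atlas parcels (70 for the conformant
#'   atlas).
#' @param deform_amplitude Maximum displacement magnitude of the random
#'   subject deformation, mm (must stay below the smallest nucleus
#'   radius, ~8 mm, to keep the truth invertible).
#' @param atrophy Named numeric vector of per-region shrinkage factors
#'   in (0, 1], names = atlas labels; e.g. `c("23" = 0.85)` shrinks
#'   region 23 to 85% linear size in subject space.
#' @param noise_sd Additive PET noise SD in SUV units.
#' @param psf_fwhm Gaussian point-spread FWHM in mm (partial-volume
#'   blur); 0 disables.
#' @param subject_factor Integer >= 1: subject volumes are acquired on a
#'   grid this many times finer than the template grid, emulating
#'   native-resolution structural imaging versus a coarser template
#'   (default 2).
#' @param seed Master integer seed.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = 64L, spacing = 128 / grid_shape,
                         n_regions = 70L, deform_amplitude = 4,
                         atrophy = NULL, noise_sd = 0.3, psf_fwhm = 4,
                         subject_factor = 2L, seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  if (grid_shape < 16L)
    nq_stop("grid_shape must be >= 16", class = "validation_error")
  if (deform_amplitude < 0 || deform_amplitude > 8)
    nq_stop("deform_amplitude must be in [0, 8] mm (below the smallest ",
            "nucleus radius)", class = "validation_error")
  if (!is.null(atrophy)) {
    if (is.null(names(atrophy)) || any(atrophy <= 0) || any(atrophy > 1))
      nq_stop("atrophy must be a named vector of factors in (0, 1]",
              class = "validation_error")
  }
  if (noise_sd < 0 || psf_fwhm < 0)
    nq_stop("noise_sd and psf_fwhm must be >= 0",
            class = "validation_error")
  subject_factor <- as.integer(subject_factor)
  if (subject_factor < 1L)
    nq_stop("subject_factor must be >= 1", class = "validation_error")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 n_regions = as.integer(n_regions),
                 deform_amplitude = deform_amplitude, atrophy = atrophy,
                 noise_sd = noise_sd, psf_fwhm = psf_fwhm,
                 subject_factor = subject_factor,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Fixed labels of the six named nuclei (bilateral pairs k map to labels
# 2k-1 / 2k; caudate pair 12, putamen pair 13, cerebellar GM pair 15).
NUCLEUS_LABELS <- c(CAU_L = 23L, CAU_R = 24L, PUT_L = 25L, PUT_R = 26L,
                    CGM_L = 29L, CGM_R = 30L)

#' Labels of the named phantom nuclei
#'
#' @return Named integer vector (CAU_L/R, PUT_L/R, CGM_L/R).
#' @export
nucleus_labels <- function() NUCLEUS_LABELS

#' Group uptake profile (per-region true SUV_mean and SD)
#'
#' Defaults encode the regional FDG uptake pattern of the PD and MSA
#' groups: caudate, putamen and cerebellar gray-matter means and
#' between-subject SDs per group, with all remaining parcels set to a
#' common cortical level that does not differ between groups. The
#' between-group contrast is strong in the cerebellar gray matter and
#' moderate (sub-significant at n = 20 vs 8) in the caudate/putamen.
#'
#' @param n_regions Number of parcels.
#' @param other_mean,other_sd Uptake for unnamed parcels (both groups).
#'   The default places the background below every named nucleus (a
#'   mixed gray/white tissue level), so the striatal and cerebellar
#'   targets are locally the hottest structures, as in FDG physiology.
#' @return data.frame with columns `label`, `name`, `pd_mean`, `pd_sd`,
#'   `msa_mean`, `msa_sd`.
#' @export
group_uptake_profile <- function(n_regions = 70L, other_mean = 4.5,
                                 other_sd = 0.8) {
  pair <- rep(seq_len(ceiling(n_regions / 2)), each = 2)[seq_len(n_regions)]
  side <- rep(c("L", "R"), length.out = n_regions)
  name <- sprintf("REG%02d_%s", pair, side)
  prof <- data.frame(label = seq_len(n_regions), name = name,
                     pd_mean = other_mean, pd_sd = other_sd,
                     msa_mean = other_mean, msa_sd = other_sd)
  nuc <- data.frame(
    label = unname(NUCLEUS_LABELS),
    name = names(NUCLEUS_LABELS),
    pd_mean = c(6.60, 6.84, 8.59, 8.48, 5.49, 5.32),
    pd_sd = c(1.37, 1.36, 1.72, 1.67, 0.70, 0.79),
    msa_mean = c(5.46, 5.87, 7.27, 7.32, 3.93, 3.59),
    msa_sd = c(1.78, 1.77, 1.81, 1.83, 1.05, 1.06))
  keep <- nuc$label <= n_regions
  prof[nuc$label[keep], ] <- nuc[keep, ]
  prof
}

#' Draw one subject's true regional SUV_mean values from a group profile
#'
#' Regional uptake within a subject is correlated: a shared global
#' metabolic factor (injected dose, weight, glycemia) scales every
#' region together. Draws therefore decompose each region's
#' between-subject SD into a common component (`global_cv` times the
#' regional mean, capped at 90% of the marginal SD) plus an independent
#' residual, so the marginal mean and SD of every region match the
#' profile exactly while regions co-vary as in real cohorts. Values
#' <= 0.2 are redrawn (truncated positive). This is the sampler
#' [make_subject()] uses to assign activity.
#'
#' @param profile A [group_uptake_profile()] table.
#' @param group `"PD"` or `"MSA"`.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @param global_cv Coefficient of variation of the shared global
#'   factor (default 0.25, giving inter-regional correlations around
#'   0.7 as observed for FDG SUVs).
#' @return Numeric vector of per-region SUV_mean, in profile row order.
#' @export
draw_regional_uptake <- function(profile, group = c("PD", "MSA"),
                                 seed = NULL, global_cv = 0.25) {
  group <- match.arg(group)
  mcol <- if (group == "PD") "pd_mean" else "msa_mean"
  scol <- if (group == "PD") "pd_sd" else "msa_sd"
  mu <- profile[[mcol]]
  sd_marg <- profile[[scol]]
  shared <- pmin(global_cv * mu, 0.9 * sd_marg)
  resid <- sqrt(sd_marg^2 - shared^2)
  draw <- function() {
    gfac <- stats::rnorm(1)
    vals <- mu + gfac * shared + stats::rnorm(length(mu), 0, resid)
    while (any(vals <= 0.2))
      vals[vals <= 0.2] <- mu[vals <= 0.2] + gfac * shared[vals <= 0.2] +
        stats::rnorm(sum(vals <= 0.2), 0, resid[vals <= 0.2])
    vals
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Ellipsoid semi-axes (mm) for a given spec: fractions of the half
# field of view, leaving a margin for deformation.
phantom_semiaxes <- function(spec) {
  half_fov <- spec$grid_shape * spec$spacing / 2
  c(0.78, 0.90, 0.72) * half_fov
}

# Normalized seed positions (fractions of the semi-axes) for the named
# nuclei and for three fixed cold separator parcels that stand in for
# the anatomy isolating them: lateral-ventricle tissue between the
# caudate heads, the internal capsule between caudate and putamen, and
# the vermis midline between the cerebellar hemispheres. Left side
# only; the right side mirrors x.
nucleus_seed_fractions <- function() {
  rbind(VEN = c(-0.06, 0.18, 0.14),
        CAU = c(-0.32, 0.21, 0.17),
        PUT = c(-0.52, 0.07, 0.04),
        CAP = c(-0.42, 0.14, 0.105),
        CGM = c(-0.36, -0.72, -0.52),
        VR1 = c(-0.035, -0.72, -0.52),
        VR2 = c(-0.035, -0.56, -0.40))
}

#' Generate the synthetic 70-region atlas template
#'
#' A brain-shaped ellipsoid is partitioned into `n_regions` contiguous
#' parcels by nearest-seed (Voronoi) assignment with bilaterally
#' mirrored seeds, so left/right homologues are exact mirror images.
#' Six designated parcels carry the names CAU_L/R, PUT_L/R, CGM_L/R at
#' anatomically plausible positions (caudate and putamen deep and
#' paramedian, cerebellar gray matter inferior-posterior). The reference
#' T1 assigns each bilateral pair its own tissue intensity plus a smooth
#' low-frequency modulation, giving the registration boundary contrast
#' everywhere. This atlas is geometric, not anatomical.
#'
#' @param spec A [phantom_spec()].
#' @return An [atlas_template()] in MNI space.
#' @export
make_atlas_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$grid_shape < 32L)
    nq_stop("grid too small to host ", spec$n_regions,
            " parcels; need at least 32 voxels per axis",
            class = "validation_error")
  s <- spec$grid_shape
  sp <- spec$spacing
  # World origin centered so the mirror plane x = 0 falls exactly between
  # the two central voxel columns: mirrored seeds produce mirrored parcels.
  aff <- diag(c(sp, sp, sp, 1))
  aff[1:3, 4] <- -sp * (s - 1) / 2
  grid <- grid_spec(c(s, s, s), affine = aff)
  ax <- phantom_semiaxes(spec)

  n_pairs <- ceiling(spec$n_regions / 2)
  nuc_frac <- nucleus_seed_fractions()
  nuc_pairs <- c(VEN = 11L, CAU = 12L, PUT = 13L, CAP = 14L, CGM = 15L,
                 VR1 = 16L, VR2 = 17L)
  seeds_left <- with_seed(spec$seed, {
    out <- matrix(NA_real_, n_pairs, 3)
    out[nuc_pairs, ] <- nuc_frac
    min_sep <- 0.16
    for (k in setdiff(seq_len(n_pairs), nuc_pairs)) {
      repeat {
        cand <- stats::runif(3, -1, 1)
        if (sum(cand^2) > 0.92 || cand[1] > -0.08) next
        done <- all(is.na(out[, 1])) ||
          min(sqrt(rowSums(sweep(out[!is.na(out[, 1]), , drop = FALSE],
                                 2, cand)^2))) >= min_sep
        if (done) { out[k, ] <- cand; break }
      }
    }
    out
  })
  seeds_world_l <- sweep(seeds_left, 2, ax, "*")
  seeds_world_r <- seeds_world_l * matrix(rep(c(-1, 1, 1), each = n_pairs),
                                          ncol = 3)
  # Interleave: pair k -> labels 2k-1 (left), 2k (right).
  seeds <- matrix(NA_real_, 2 * n_pairs, 3)
  seeds[seq(1, 2 * n_pairs, 2), ] <- seeds_world_l
  seeds[seq(2, 2 * n_pairs, 2), ] <- seeds_world_r
  seeds <- seeds[seq_len(spec$n_regions), , drop = FALSE]

  xyz <- grid_world_coords(grid)
  inside <- (xyz[, 1] / ax[1])^2 + (xyz[, 2] / ax[2])^2 +
    (xyz[, 3] / ax[3])^2 <= 1
  pts <- xyz[inside, , drop = FALSE]
  best <- rep(Inf, nrow(pts))
  lab_in <- rep(0L, nrow(pts))
  for (k in seq_len(nrow(seeds))) {
    d2 <- (pts[, 1] - seeds[k, 1])^2 + (pts[, 2] - seeds[k, 2])^2 +
      (pts[, 3] - seeds[k, 3])^2
    hit <- d2 < best
    best[hit] <- d2[hit]
    lab_in[hit] <- k
  }
  labels <- integer(nrow(xyz))
  labels[inside] <- lab_in
  parc <- label_map(array(labels, dim = grid$shape), grid, space = "MNI")

  # Reference T1: tissue-realistic contrast. Deep parcels are nearly
  # isointense (one weak intensity per bilateral pair, identical
  # left/right), so registration is driven by the brain outline and a
  # strong smooth low-frequency texture rather than by parcel borders —
  # deep nuclei show poor T1 contrast in vivo and atlas-based methods
  # cannot rely on their edges. Background stays 0.
  pair_int <- with_seed(spec$seed + 1L, stats::runif(n_pairs, 385, 415))
  vox_int <- numeric(nrow(xyz))
  pair_of_label <- rep(seq_len(n_pairs), each = 2)[seq_len(spec$n_regions)]
  vox_int[inside] <- pair_int[pair_of_label[lab_in]]
  modul <- 55 * sin(xyz[, 1] / 23) + 45 * cos(xyz[, 2] / 31) +
    35 * sin(xyz[, 3] / 17) +
    30 * sin(xyz[, 1] / 6.5) * cos(xyz[, 2] / 7.5) +
    25 * sin(xyz[, 2] / 5.5 + 1) * cos(xyz[, 3] / 8.5) +
    22 * sin(xyz[, 3] / 6 + 2) * cos(xyz[, 1] / 9)
  vox_int[inside] <- vox_int[inside] + modul[inside]
  t1 <- gaussian_smooth(array(vox_int, dim = grid$shape), 0.6)
  reference <- volume_image(t1, grid, units = "intensity", space = "MNI")

  regions <- group_uptake_profile(spec$n_regions)[, c("label", "name")]
  atlas_template(parc, regions, reference)
}

# Smooth random displacement field plus optional per-region atrophy, on
# `grid`, scaled so the random part's maximum magnitude equals
# `amplitude` mm. Assumes the caller seeded the RNG. `atrophy_geom` is a
# list of (center, r_eff, factor) computed on the atlas grid.
random_smooth_field <- function(grid, amplitude, smooth_mm = 14,
                                atrophy_geom = NULL) {
  s <- grid$shape
  comps <- lapply(1:3, function(k) {
    if (amplitude <= 0) return(array(0, dim = s))
    gaussian_smooth(array(stats::rnorm(prod(s)), dim = s),
                    smooth_mm / grid$spacing[k])
  })
  if (amplitude > 0) {
    mag <- sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2)
    sc <- amplitude / max(mag, 1e-12)
    comps <- lapply(comps, function(a) a * sc)
  }
  if (length(atrophy_geom)) {
    xyz <- grid_world_coords(grid)
    for (ag in atrophy_geom) {
      u <- sqrt((xyz[, 1] - ag$center[1])^2 + (xyz[, 2] - ag$center[2])^2 +
                  (xyz[, 3] - ag$center[3])^2) / ag$r_eff
      # Radial expansion of the pull map inside the nucleus: subject
      # points within fac*r map out to the full atlas nucleus -> the
      # structure shrinks by `fac` in subject space.
      w <- ifelse(u <= ag$factor, 1, exp(-((u - ag$factor) / 0.45)^2))
      g <- (1 / ag$factor - 1) * w
      for (k in 1:3)
        comps[[k]] <- comps[[k]] +
          array(g * (xyz[, k] - ag$center[k]), dim = s)
    }
  }
  comps
}

# Geometry of the atrophied regions (centroid, effective radius) on the
# atlas grid, for the analytic atrophy displacement term.
atrophy_geometry <- function(atlas, atrophy) {
  if (is.null(atrophy) || !length(atrophy)) return(NULL)
  xyz <- grid_world_coords(atlas$parcellation$grid)
  labv <- as.vector(atlas$parcellation$labels)
  vox_vol <- prod(atlas$parcellation$grid$spacing)
  out <- list()
  for (nm in names(atrophy)) {
    sel <- labv == as.integer(nm)
    if (!any(sel)) next
    out[[nm]] <- list(center = colMeans(xyz[sel, , drop = FALSE]),
                      r_eff = (3 * sum(sel) * vox_vol / (4 * pi))^(1 / 3),
                      factor = atrophy[[nm]])
  }
  out
}

#' Simulate one phantom subject
#'
#' Draws a smooth random deformation (plus optional per-region atrophy),
#' warps the atlas T1 and parcellation into subject space (the warped
#' parcellation *is* the ground-truth segmentation), assigns each region
#' a per-subject activity drawn from the group profile (normal,
#' truncated positive), then applies the Gaussian PSF and additive
#' noise. Injection metadata is fixed at a nominal 370 MBq decay-
#' corrected dose and 74 kg body weight with a 40-minute uptake period,
#' so SUV has a closed-form inverse during construction.
#'
#' @param atlas An [atlas_template()] from [make_atlas_phantom()].
#' @param profile A [group_uptake_profile()] table.
#' @param group `"PD"` or `"MSA"`.
#' @param spec A [phantom_spec()].
#' @param seed Seed for this subject (defaults to `spec$seed`).
#' @param subject_id Identifier string.
#' @return A `subject_case`: `t1`, `pet` (kBq/mL), `truth_labels`,
#'   `true_forward`, `true_inverse`, `group`, `suv_inputs`,
#'   `true_uptake` (drawn per-region SUV_mean).
#' @export
make_subject <- function(atlas, profile, group = c("PD", "MSA"),
                         spec = phantom_spec(), seed = spec$seed,
                         subject_id = "sub01") {
  group <- match.arg(group)
  stopifnot(inherits(atlas, "atlas_template"))
  mni_grid <- atlas$parcellation$grid
  # Subject volumes are acquired at native resolution: a grid
  # subject_factor x finer than the template, covering the same FOV.
  f <- spec$subject_factor
  subj_aff <- mni_grid$affine %*%
    rbind(cbind(diag(3) / f, -(f - 1) / (2 * f) * rep(1, 3)), c(0, 0, 0, 1))
  subj_grid <- grid_spec(mni_grid$shape * f, affine = subj_aff)

  comps <- with_seed(seed, random_smooth_field(
    subj_grid, spec$deform_amplitude,
    atrophy_geom = atrophy_geometry(atlas, spec$atrophy)))
  true_inverse <- deformation_field(comps, subj_grid,
                                    direction = "inverse")
  true_forward <- invert_field(true_inverse, target_grid = mni_grid,
                               tol = 0.1, max_iter = 100L)

  t1 <- apply_deformation(atlas$reference_t1, true_inverse, "trilinear")
  truth_labels <- apply_deformation(atlas$parcellation, true_inverse,
                                    "nearest")

  uptake <- draw_regional_uptake(profile, group, seed = seed + 1L)

  # SUV -> activity: r = SUV * a'/w with a' = 370000 kBq, w = 74000 g.
  a_prime <- 370000
  weight <- 74000
  uptake_min <- 40
  half_life <- 109.77
  k <- a_prime / weight  # kBq/mL per SUV unit
  lut <- c(0, uptake * k)  # label 0 = cold background
  act <- array(lut[truth_labels$labels + 1L], dim = subj_grid$shape)
  if (spec$psf_fwhm > 0)
    act <- gaussian_smooth(act, spec$psf_fwhm / 2.3548 / subj_grid$spacing)
  if (spec$noise_sd > 0)
    act <- act + with_seed(seed + 2L, array(
      stats::rnorm(prod(subj_grid$shape), 0, spec$noise_sd * k),
      dim = subj_grid$shape))
  act[act < 0] <- 0
  pet <- volume_image(act, subj_grid, units = "kBq/mL", space = "subject")

  inputs <- suv_inputs(
    injected_activity_kBq = a_prime * 2^(uptake_min / half_life),
    weight_g = weight, injection_time = 0, reference_time = uptake_min,
    isotope_half_life_min = half_life)

  structure(list(id = subject_id, group = group, t1 = t1, pet = pet,
                 truth_labels = truth_labels, true_forward = true_forward,
                 true_inverse = true_inverse, suv_inputs = inputs,
                 true_uptake = data.frame(label = profile$label,
                                          name = profile$name,
                                          suv_mean = uptake),
                 seed = seed),
            class = "subject_case")
}

#' @export
print.subject_case <- function(x, ...) {
  cat("<subject_case> ", x$id, " (", x$group, "), deformation max ",
      signif(field_max_mm(x$true_inverse), 4), " mm\n", sep = "")
  invisible(x)
}

#' Simulate a grouped phantom cohort
#'
#' Subjects are generated independently from a per-subject seed stream
#' derived from the master seed; two cohorts built from the same spec
#' are identical.
#'
#' @param atlas,profile,spec As in [make_subject()].
#' @param n_pd,n_msa Group sizes (defaults 20 and 8).
#' @param out_dir Optional directory: writes per-subject NIfTI files,
#'   truth fields, the region table and a manifest TSV.
#' @return List with `subjects` (list of `subject_case`) and `manifest`
#'   (data.frame subject_id, group, seed).
#' @export
make_cohort <- function(atlas, profile, n_pd = 20L, n_msa = 8L,
                        spec = phantom_spec(), out_dir = NULL) {
  if (n_pd < 0 || n_msa < 0)
    nq_stop("group sizes must be >= 0", class = "validation_error")
  groups <- c(rep("PD", n_pd), rep("MSA", n_msa))
  subjects <- vector("list", length(groups))
  manifest <- data.frame(subject_id = character(0), group = character(0),
                         seed = integer(0))
  for (i in seq_along(groups)) {
    sid <- sprintf("sub%02d", i)
    sd_i <- derive_seed(spec$seed, i)
    subjects[[i]] <- make_subject(atlas, profile, groups[i], spec,
                                  seed = sd_i, subject_id = sid)
    manifest <- rbind(manifest,
                      data.frame(subject_id = sid, group = groups[i],
                                 seed = sd_i))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(atlas$regions, file.path(out_dir, "regions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_volume(atlas$parcellation, file.path(out_dir, "atlas.nii.gz"))
    write_volume(atlas$reference_t1,
                 file.path(out_dir, "template_t1.nii.gz"))
    for (s in subjects) {
      write_volume(s$t1, file.path(out_dir, paste0(s$id, "_T1.nii.gz")))
      write_volume(s$pet, file.path(out_dir, paste0(s$id, "_PET.nii.gz")))
      write_volume(s$truth_labels,
                   file.path(out_dir, paste0(s$id, "_truth.nii.gz")))
      write_field(s$true_forward,
                  file.path(out_dir, paste0(s$id, "_fwd.nii.gz")))
      write_field(s$true_inverse,
                  file.path(out_dir, paste0(s$id, "_inv.nii.gz")))
    }
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(subjects = subjects, manifest = manifest)
}
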