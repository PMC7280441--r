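test_that("the phantom atlas carries exactly 70 mirrored parcels", {
  atlas <- small_atlas()
  expect_identical(label_set(atlas$parcellation), 1:70)
  nl <- nucleus_labels()
  vols <- vapply(nl, function(l) sum(atlas$parcellation$labels == l), 1L)
  # bilateral mirror: left/right homologue volumes within 20%
  for (i in c(1, 3, 5))
    expect_lt(abs(vols[i] - vols[i + 1]) / vols[i], 0.2)
  expect_true(all(vols > 0))
  # region table resolves all six named nuclei
  expect_true(all(names(nl) %in% atlas$regions$name))
})

test_that("atlas generation is deterministic in the seed", {
  spec <- small_spec()
  a1 <- make_atlas_phantom(spec)
  a2 <- make_atlas_phantom(spec)
  expect_identical(a1$parcellation$labels, a2$parcellation$labels)
  expect_identical(a1$reference_t1$values, a2$reference_t1$values)
})

test_that("grids too small for 70 parcels are rejected", {
  expect_error(make_atlas_phantom(phantom_spec(grid_shape = 16L)),
               class = "validation_error")
})

test_that("phantom_spec validates atrophy, noise and amplitude", {
  expect_error(phantom_spec(atrophy = c("23" = 1.5)),
               class = "validation_error")
  expect_error(phantom_spec(atrophy = c(0.8)), class = "validation_error")
  expect_error(phantom_spec(noise_sd = -1), class = "validation_error")
  expect_error(phantom_spec(deform_amplitude = 20),
               class = "validation_error")
})

test_that("the noiseless closed loop returns the drawn uptake exactly", {
  atlas <- small_atlas()
  spec0 <- small_spec(deform_amplitude = 0, noise_sd = 0, psf_fwhm = 0)
  subj <- make_subject(atlas, default_profile(), "PD", spec0, seed = 81)
  suv <- suv_image(subj$pet, subj$suv_inputs)
  q <- regional_quantify(suv, subj$truth_labels, 1:70)
  expect_equal(q$suv_mean, subj$true_uptake$suv_mean, tolerance = 1e-9)
  expect_equal(q$suv_max, subj$true_uptake$suv_mean, tolerance = 1e-9)

  # with zero between-subject SD the drawn values are the profile means
  prof0 <- default_profile()
  prof0$pd_sd <- 0
  subj0 <- make_subject(atlas, prof0, "PD", spec0, seed = 82)
  q0 <- regional_quantify(suv_image(subj0$pet, subj0$suv_inputs),
                          subj0$truth_labels, nucleus_labels(),
                          names(nucleus_labels()))
  expect_equal(q0$suv_mean,
               prof0$pd_mean[match(nucleus_labels(), prof0$label)],
               tolerance = 1e-9)
})

test_that("the default uptake profile encodes the group contrast", {
  prof <- default_profile()
  nl <- nucleus_labels()
  expect_equal(prof$pd_mean[match(nl, prof$label)],
               c(6.60, 6.84, 8.59, 8.48, 5.49, 5.32))
  expect_equal(prof$msa_mean[match(nl, prof$label)],
               c(5.46, 5.87, 7.27, 7.32, 3.93, 3.59))
  expect_equal(prof$pd_sd[match(nl, prof$label)],
               c(1.37, 1.36, 1.72, 1.67, 0.70, 0.79))
  expect_equal(prof$msa_sd[match(nl, prof$label)],
               c(1.78, 1.77, 1.81, 1.83, 1.05, 1.06))
  expect_true(all(prof$pd_mean > 0 & prof$msa_sd > 0))
})

test_that("truth labels are the atlas warped by the true inverse field", {
  atlas <- small_atlas()
  subj <- make_subject(atlas, default_profile(), "MSA", small_spec(),
                       seed = 83)
  rebuilt <- apply_deformation(atlas$parcellation, subj$true_inverse,
                               "nearest")
  expect_identical(subj$truth_labels$labels, rebuilt$labels)
  # the stored field pair is consistent: fwd o inv is below half a voxel
  comp <- compose_fields(subj$true_forward, subj$true_inverse)
  expect_lt(neuroquant:::field_max_mm(comp),
            0.5 * min(atlas$parcellation$grid$spacing))
})

test_that("the PSF biases hot-region SUV_mean downward (partial volume)", {
  atlas <- small_atlas()
  prof_hot <- default_profile()
  hot <- nucleus_labels()[["PUT_L"]]
  prof_hot$pd_mean <- 2; prof_hot$pd_sd <- 0
  prof_hot$pd_mean[prof_hot$label == hot] <- 10
  spec_psf <- small_spec(deform_amplitude = 0, noise_sd = 0, psf_fwhm = 8)
  subj <- make_subject(atlas, prof_hot, "PD", spec_psf, seed = 84)
  q <- regional_quantify(suv_image(subj$pet, subj$suv_inputs),
                         subj$truth_labels, hot)
  expect_lt(q$suv_mean, 10)
  expect_gt(q$suv_mean, 2)
})

test_that("subjects are acquired on a finer native grid when requested", {
  atlas <- small_atlas()
  spec2 <- small_spec()
  spec2$subject_factor <- 2L
  subj <- make_subject(atlas, default_profile(), "PD", spec2, seed = 85)
  expect_identical(subj$t1$grid$shape, atlas$parcellation$grid$shape * 2L)
  # same field of view: identical world extents of the voxel lattice
  mni <- atlas$parcellation$grid
  lo_m <- voxel_to_world(mni, c(-0.5, -0.5, -0.5))
  lo_s <- voxel_to_world(subj$t1$grid, c(-0.5, -0.5, -0.5))
  expect_equal(lo_m, lo_s, tolerance = 1e-9)
})

test_that("cohorts are seed-deterministic with correct group structure", {
  atlas <- small_atlas()
  spec <- small_spec()
  c1 <- make_cohort(atlas, default_profile(), n_pd = 2, n_msa = 1, spec)
  c2 <- make_cohort(atlas, default_profile(), n_pd = 2, n_msa = 1, spec)
  expect_equal(c1$manifest$group, c("PD", "PD", "MSA"))
  expect_identical(c1$subjects[[1]]$pet$values,
                   c2$subjects[[1]]$pet$values)
  expect_identical(c1$subjects[[3]]$truth_labels$labels,
                   c2$subjects[[3]]$truth_labels$labels)
  # subjects differ from one another
  expect_false(identical(c1$subjects[[1]]$pet$values,
                         c1$subjects[[2]]$pet$values))

  c0 <- make_cohort(atlas, default_profile(), n_pd = 0, n_msa = 0, spec)
  expect_equal(nrow(c0$manifest), 0L)
})

test_that("cohort export writes volumes, fields and a manifest", {
  atlas <- small_atlas()
  dir <- withr::local_tempdir()
  make_cohort(atlas, default_profile(), n_pd = 1, n_msa = 0,
              small_spec(), out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "atlas.nii.gz")))
  expect_true(file.exists(file.path(dir, "sub01_T1.nii.gz")))
  expect_true(file.exists(file.path(dir, "sub01_fwd.nii.gz")))
  truth <- read_volume(file.path(dir, "sub01_truth.nii.gz"),
                       as_labels = TRUE)
  expect_true(all(label_set(truth) %in% 1:70))
})

test_that("uptake draws are reproducible and truncated positive", {
  prof <- default_profile()
  u1 <- draw_regional_uptake(prof, "MSA", seed = 86)
  u2 <- draw_regional_uptake(prof, "MSA", seed = 86)
  expect_identical(u1, u2)
  expect_true(all(u1 > 0.2))
  expect_length(u1, 70L)
})
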