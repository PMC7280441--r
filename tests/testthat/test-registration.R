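# Field algebra: apply, compose, invert.

test_that("a zero field reproduces the input on the field's grid", {
  withr::local_seed(10)
  g <- grid_spec(c(8, 8, 8), spacing = c(2, 2, 2))
  v <- volume_image(array(rnorm(512), dim = c(8, 8, 8)), g)
  out <- apply_deformation(v, zero_field(g, "forward"), "trilinear")
  expect_equal(out$values, v$values)
  expect_equal(out$space, "MNI")
})

test_that("a uniform integer-voxel displacement shifts the image", {
  withr::local_seed(11)
  g <- grid_spec(c(8, 8, 8), spacing = c(2, 2, 2))
  arr <- array(rnorm(512), dim = c(8, 8, 8))
  v <- volume_image(arr, g)
  d <- array(4, dim = c(8, 8, 8))  # +2 voxels along x (4 mm)
  f <- deformation_field(list(d, d * 0, d * 0), g, "forward")
  out <- apply_deformation(v, f, "trilinear")
  expect_equal(out$values[1:6, , ], arr[3:8, , ])
  expect_true(all(out$values[7:8, , ] == 0))
})

test_that("warped label sets stay inside the source set plus background", {
  withr::local_seed(12)
  g <- grid_spec(c(10, 10, 10), spacing = c(2, 2, 2))
  lab <- label_map(array(sample(0:6, 1000, TRUE), dim = c(10, 10, 10)), g)
  for (i in 1:10) {
    f <- random_test_field(g, amplitude_vox = 2)
    out <- apply_deformation(lab, f, "nearest")
    expect_true(all(label_set(out) %in% c(0L, label_set(lab))))
  }
  expect_error(apply_deformation(lab, random_test_field(g), "trilinear"),
               class = "contract_error")
})

test_that("inverting the zero field gives the zero field", {
  g <- grid_spec(c(8, 8, 8), spacing = c(2, 2, 2))
  inv <- invert_field(zero_field(g, "forward"))
  expect_equal(neuroquant:::field_max_mm(inv), 0)
  expect_equal(inv$direction, "inverse")
})

test_that("a uniform translation inverts to its exact negative", {
  g <- grid_spec(c(8, 8, 8), spacing = c(2, 2, 2))
  z <- array(0, dim = c(8, 8, 8))
  f <- deformation_field(list(z + 3, z - 1.5, z + 0.5), g, "forward")
  inv <- invert_field(f, tol = 1e-6)
  expect_equal(inv$displacement[[1]], z - 3, tolerance = 1e-6)
  expect_equal(inv$displacement[[2]], z + 1.5, tolerance = 1e-6)
  expect_equal(inv$displacement[[3]], z - 0.5, tolerance = 1e-6)
})

test_that("smooth random fields invert below the residual tolerance", {
  withr::local_seed(13)
  g <- grid_spec(c(16, 16, 16), spacing = c(2, 2, 2))
  for (i in 1:5) {
    f <- random_test_field(g, amplitude_vox = 2, smooth_vox = 4)
    inv <- invert_field(f, tol = 0.1)
    comp <- compose_fields(f, inv)
    expect_lt(neuroquant:::field_max_mm(comp) / min(g$spacing), 0.1)
    expect_equal(inv$direction, "inverse")
  }
})

test_that("double inversion recovers a gently varying field", {
  withr::local_seed(17)
  g <- grid_spec(c(16, 16, 16), spacing = c(2, 2, 2))
  for (i in 1:5) {
    f <- random_test_field(g, amplitude_vox = 1.5, smooth_vox = 6,
                           margin = 6)
    back <- invert_field(invert_field(f, tol = 0.1), tol = 0.1)
    dmax <- max(abs(back$displacement[[1]] - f$displacement[[1]]),
                abs(back$displacement[[2]] - f$displacement[[2]]),
                abs(back$displacement[[3]] - f$displacement[[3]]))
    # within twice the inversion tolerance
    expect_lt(dmax / min(g$spacing), 0.2)
  }
})

test_that("composition has the zero field as identity and sums shifts", {
  withr::local_seed(14)
  g <- grid_spec(c(8, 8, 8), spacing = c(2, 2, 2))
  f <- random_test_field(g, amplitude_vox = 1.5, direction = "forward")
  z <- zero_field(g, "inverse")
  comp <- compose_fields(f, z)
  for (k in 1:3)
    expect_equal(comp$displacement[[k]], f$displacement[[k]],
                 tolerance = 1e-12)
  za <- array(0, dim = c(8, 8, 8))
  t1 <- deformation_field(list(za + 2, za, za - 1), g, "forward")
  t2 <- deformation_field(list(za + 1, za + 3, za), g, "inverse")
  both <- compose_fields(t1, t2)
  expect_equal(both$displacement[[1]], za + 3)
  expect_equal(both$displacement[[2]], za + 3)
  expect_equal(both$displacement[[3]], za - 1)
  expect_error(compose_fields(t1, t1), class = "contract_error")
})

test_that("an unreachable residual tolerance is a reported error", {
  withr::local_seed(16)
  g <- grid_spec(c(10, 10, 10), spacing = c(2, 2, 2))
  f <- random_test_field(g, amplitude_vox = 3)
  expect_error(invert_field(f, tol = 1e-4, max_iter = 2L),
               "residual", class = "non_invertible_error")
})

test_that("fields serialize to 4D NIfTI with a sidecar and read back", {
  withr::local_seed(15)
  g <- grid_spec(c(8, 8, 8), spacing = c(2, 2, 2))
  f <- random_test_field(g, amplitude_vox = 1.5, direction = "inverse")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_field(f, path)
  expect_true(file.exists(sub("\\.nii\\.gz$", ".json", path)))
  f2 <- read_field(path)
  expect_equal(f2$direction, "inverse")
  for (k in 1:3)
    expect_equal(f2$displacement[[k]], f$displacement[[k]],
                 tolerance = 1e-9)
})

# Normalization estimation.

test_that("self-registration yields a near-identity forward field", {
  atlas <- small_atlas()
  norm <- estimate_normalization(
    volume_image(atlas$reference_t1$values, atlas$reference_t1$grid,
                 units = "intensity", space = "subject"),
    atlas$reference_t1,
    registration_params(nonlinear_grid_spacings = c(8)))
  expect_lt(neuroquant:::field_max_mm(norm$forward),
            0.5 * min(atlas$reference_t1$grid$spacing))
})

test_that("constant images are rejected for registration", {
  g <- grid_spec(c(16, 16, 16), spacing = c(2, 2, 2))
  flat <- volume_image(array(1, dim = c(16, 16, 16)), g,
                       units = "intensity")
  expect_error(estimate_normalization(flat, flat),
               class = "validation_error")
})

test_that("the similarity trace is non-increasing under msd", {
  atlas <- small_atlas()
  spec <- small_spec()
  subj <- make_subject(atlas, default_profile(), "PD", spec, seed = 31)
  norm <- estimate_normalization(subj$t1, atlas$reference_t1,
                                 registration_params(
                                   nonlinear_grid_spacings = c(8, 4)))
  expect_gte(length(norm$similarity_trace), 1L)
  for (lvl in norm$similarity_trace)
    expect_true(all(diff(lvl) <= 1e-12))
})

test_that("a known translation is recovered within half a millimetre", {
  atlas <- mid_atlas()
  g <- atlas$parcellation$grid
  z <- array(0, dim = g$shape)
  truth <- deformation_field(list(z + 4, z, z), g, "inverse")
  shifted <- apply_deformation(atlas$reference_t1, truth, "trilinear")
  norm <- estimate_normalization(
    shifted, atlas$reference_t1,
    registration_params(nonlinear_grid_spacings = NULL))
  brain <- as.vector(atlas$parcellation$labels) > 0
  rec <- c(mean(as.vector(norm$forward$displacement[[1]])[brain]),
           mean(as.vector(norm$forward$displacement[[2]])[brain]),
           mean(as.vector(norm$forward$displacement[[3]])[brain]))
  expect_lt(sqrt(sum((rec - c(-4, 0, 0))^2)), 0.5)
})
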