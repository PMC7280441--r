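test_that("decay correction follows the half-life law", {
  expect_equal(decay_correct(12345, 0), 12345)
  expect_equal(decay_correct(100000, 109.77, 109.77), 50000)
  expect_equal(decay_correct(1, 40, 109.77), 2^(-40 / 109.77))
  expect_error(decay_correct(1, -5), class = "validation_error")
})

test_that("dose conversion is exactly 37 MBq per mCi", {
  expect_equal(convert_dose(0.1), 3.7)
  expect_equal(convert_dose(0), 0)
  expect_equal(convert_dose(1), 37)
  expect_error(convert_dose(-1), class = "validation_error")
})

test_that("suv_image reproduces the SUV definition voxelwise", {
  g <- grid_spec(c(4, 4, 4))
  pet <- volume_image(array(10, dim = c(4, 4, 4)), g, units = "kBq/mL")
  inputs <- suv_inputs(370000, 74000)
  suv <- suv_image(pet, inputs)
  expect_equal(suv$values, array(2, dim = c(4, 4, 4)))
  expect_equal(suv$units, "SUV")

  zero <- volume_image(array(0, dim = c(4, 4, 4)), g, units = "kBq/mL")
  expect_true(all(suv_image(zero, inputs)$values == 0))

  # decay correction folds in: injecting double and waiting one
  # half-life gives the same SUV
  delayed <- suv_inputs(740000, 74000, injection_time = 0,
                        reference_time = 109.77,
                        isotope_half_life_min = 109.77)
  expect_equal(suv_image(pet, delayed)$values, suv$values,
               tolerance = 1e-12)
})

test_that("SUV scales linearly with body weight", {
  withr::local_seed(50)
  g <- grid_spec(c(6, 6, 6))
  pet <- volume_image(array(runif(216, 0, 20), dim = c(6, 6, 6)), g,
                      units = "kBq/mL")
  s1 <- suv_image(pet, suv_inputs(370000, 74000))
  s2 <- suv_image(pet, suv_inputs(370000, 148000))
  expect_equal(s2$values, 2 * s1$values)
})

test_that("suv_inputs validates its physiology", {
  expect_error(suv_inputs(370000, -1), class = "validation_error")
  expect_error(suv_inputs(0, 74000), class = "validation_error")
  expect_error(suv_inputs(370000, 74000, injection_time = 10,
                          reference_time = 5),
               class = "validation_error")
  expect_error(
    suv_image(volume_image(array(1, dim = c(2, 2, 2)),
                           grid_spec(c(2, 2, 2)), units = "SUV"),
              suv_inputs(370000, 74000)),
    class = "contract_error")
})

test_that("regional statistics match hand-computable cases", {
  g <- grid_spec(c(4, 4, 4), spacing = c(2, 2, 2))
  lab <- array(0L, dim = c(4, 4, 4)); lab[1:5] <- 1L; lab[6:7] <- 2L
  seg <- label_map(lab, g)
  vals <- array(0, dim = c(4, 4, 4)); vals[1:5] <- 4; vals[6] <- 1
  vals[7] <- 3
  suv <- volume_image(vals, g, units = "SUV")
  q <- regional_quantify(suv, seg, c(1L, 2L))
  expect_equal(q$suv_mean, c(4, 2))
  expect_equal(q$suv_max, c(4, 3))
  expect_equal(q$voxel_count, c(5L, 2L))
  expect_equal(q$volume_mm3, c(40, 16))
  expect_error(regional_quantify(suv, seg, 3L),
               class = "empty_region_error")
})

test_that("regional quantification equals an exhaustive voxel loop", {
  withr::local_seed(51)
  g <- grid_spec(c(12, 12, 12), spacing = c(2, 2, 2))
  lab <- label_map(array(sample(0:8, 12^3, TRUE), dim = c(12, 12, 12)), g)
  suv <- volume_image(array(runif(12^3, 0, 15), dim = c(12, 12, 12)), g,
                      units = "SUV")
  q <- regional_quantify(suv, lab, 1:8)
  for (r in 1:8) {
    tot <- 0; mx <- -Inf; n <- 0L
    for (i in seq_len(12^3)) {
      if (lab$labels[i] == r) {
        tot <- tot + suv$values[i]
        mx <- max(mx, suv$values[i])
        n <- n + 1L
      }
    }
    expect_identical(q$voxel_count[q$label == r], n)
    expect_equal(q$suv_mean[q$label == r], tot / n)
    expect_equal(q$suv_max[q$label == r], mx)
  }
  expect_true(all(q$suv_max >= q$suv_mean))
})

test_that("regional SUV_mean is local: relabeling other regions is inert", {
  withr::local_seed(52)
  g <- grid_spec(c(10, 10, 10))
  lab <- array(sample(0:5, 1000, TRUE), dim = c(10, 10, 10))
  suv <- volume_image(array(runif(1000, 0, 10), dim = c(10, 10, 10)), g,
                      units = "SUV")
  q1 <- regional_quantify(suv, label_map(lab, g), 1L)
  relab <- lab; relab[relab %in% 2:5] <- 9L
  q2 <- regional_quantify(suv, label_map(relab, g), 1L)
  expect_equal(q1$suv_mean, q2$suv_mean)
  expect_equal(q1$suv_max, q2$suv_max)
})

test_that("SUV_max survives mask perturbations that keep the argmax", {
  withr::local_seed(53)
  g <- grid_spec(c(10, 10, 10))
  vals <- array(runif(1000, 0, 5), dim = c(10, 10, 10))
  vals[5, 5, 5] <- 50  # hot voxel well inside the region
  suv <- volume_image(vals, g, units = "SUV")
  lab <- array(0L, dim = c(10, 10, 10)); lab[3:8, 3:8, 3:8] <- 1L
  q_full <- regional_quantify(suv, label_map(lab, g), 1L)
  eroded <- array(0L, dim = c(10, 10, 10)); eroded[4:7, 4:7, 4:7] <- 1L
  dilated <- array(0L, dim = c(10, 10, 10)); dilated[2:9, 2:9, 2:9] <- 1L
  q_ero <- regional_quantify(suv, label_map(eroded, g), 1L)
  q_dil <- regional_quantify(suv, label_map(dilated, g), 1L)
  expect_equal(q_ero$suv_max, q_full$suv_max)
  expect_equal(q_dil$suv_max, q_full$suv_max)
  expect_false(isTRUE(all.equal(q_ero$suv_mean, q_full$suv_mean)))
})

test_that("grid or space mismatches are contract errors", {
  g1 <- grid_spec(c(4, 4, 4)); g2 <- grid_spec(c(4, 4, 4), spacing = c(2, 2, 2))
  suv <- volume_image(array(1, dim = c(4, 4, 4)), g1, units = "SUV")
  seg2 <- label_map(array(1L, dim = c(4, 4, 4)), g2)
  expect_error(regional_quantify(suv, seg2, 1L), class = "contract_error")
  seg_mni <- label_map(array(1L, dim = c(4, 4, 4)), g1, space = "MNI")
  expect_error(regional_quantify(suv, seg_mni, 1L),
               class = "contract_error")
})
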