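test_that("dice matches its definition on anchor cases", {
  g <- grid_spec(c(6, 6, 6))
  a <- array(FALSE, dim = c(6, 6, 6)); a[1:4] <- TRUE
  b <- array(FALSE, dim = c(6, 6, 6)); b[3:6] <- TRUE
  ma <- binary_mask(a, g); mb <- binary_mask(b, g)
  expect_equal(dice(ma, ma), 1)
  disj <- array(FALSE, dim = c(6, 6, 6)); disj[10:12] <- TRUE
  expect_equal(dice(ma, binary_mask(disj, g)), 0)
  expect_equal(dice(ma, mb), 0.5)  # |A|=4, |B|=4, |A.B|=2
  empty <- binary_mask(array(FALSE, dim = c(6, 6, 6)), g)
  expect_error(dice(empty, empty), class = "undefined_input_error")
  g2 <- grid_spec(c(6, 6, 6), spacing = c(2, 2, 2))
  expect_error(dice(ma, binary_mask(b, g2)), class = "contract_error")
})

test_that("hausdorff matches anchors and is undefined on empty masks", {
  g <- grid_spec(c(6, 6, 6))
  a <- array(FALSE, dim = c(6, 6, 6)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, dim = c(6, 6, 6)); b[4, 1, 1] <- TRUE
  expect_equal(hausdorff(binary_mask(a, g), binary_mask(b, g)), 3)
  expect_equal(hausdorff(binary_mask(a, g), binary_mask(a, g)), 0)
  empty <- binary_mask(array(FALSE, dim = c(6, 6, 6)), g)
  expect_error(hausdorff(binary_mask(a, g), empty),
               class = "undefined_input_error")
})

test_that("dice and hausdorff equal brute force on random mask pairs", {
  withr::local_seed(60)
  for (i in 1:25) {
    s <- sample(4:10, 1)
    g <- grid_spec(c(s, s, s))
    a <- random_mask(g, p = runif(1, 0.05, 0.4))
    b <- random_mask(g, p = runif(1, 0.05, 0.4))
    if (!any(a$membership) || !any(b$membership)) next
    expect_equal(dice(a, b), brute_dice(a, b))
    expect_equal(hausdorff(a, b), brute_hausdorff(a, b))
    expect_equal(hausdorff(a, b), hausdorff(b, a))  # symmetry
  }
})

test_that("hausdorff satisfies the triangle inequality on mask triples", {
  withr::local_seed(61)
  g <- grid_spec(c(8, 8, 8))
  for (i in 1:10) {
    a <- random_mask(g, connected = TRUE)
    b <- random_mask(g, connected = TRUE)
    c <- random_mask(g, connected = TRUE)
    expect_lte(hausdorff(a, c),
               hausdorff(a, b) + hausdorff(b, c) + 1e-12)
  }
})

test_that("the A-minus-B / boundary reduction equals full-mask brute force", {
  # The directed distance only needs A \ B against the boundary of B;
  # this is the exact reduction the implementation uses, checked here
  # against the unreduced all-pairs scan (including nested shapes where
  # naive boundary-vs-boundary reasoning fails).
  g <- grid_spec(c(9, 9, 9))
  big <- array(FALSE, dim = c(9, 9, 9)); big[2:8, 2:8, 2:8] <- TRUE
  small <- array(FALSE, dim = c(9, 9, 9)); small[4:6, 4:6, 4:6] <- TRUE
  shell <- big & !small
  cases <- list(list(big, small), list(small, big), list(big, shell),
                list(shell, small))
  for (cs in cases) {
    a <- binary_mask(cs[[1]], g); b <- binary_mask(cs[[2]], g)
    expect_equal(hausdorff(a, b), brute_hausdorff(a, b))
  }
})

test_that("the HD95 option never exceeds the maximum Hausdorff", {
  withr::local_seed(62)
  g <- grid_spec(c(8, 8, 8))
  a <- random_mask(g, connected = TRUE)
  b <- random_mask(g, connected = TRUE)
  expect_lte(hausdorff(a, b, percentile = 95), hausdorff(a, b))
})

test_that("bland_altman handles degenerate and offset pairs", {
  x <- c(1, 2, 3, 4, 5)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)

  ba2 <- bland_altman(x, x + 2)
  expect_equal(ba2$bias, 2)
  # all differences sit exactly on the (collapsed) limits: strictly
  # inside counts none
  expect_equal(ba2$fraction_within, 0)
  expect_error(bland_altman(1:2, 1:2), class = "validation_error")
  expect_error(bland_altman(1:4, 1:5), class = "validation_error")
})

test_that("about 95% of normal differences fall within the limits", {
  withr::local_seed(63)
  x <- rnorm(1000, 10, 2)
  y <- x + rnorm(1000, 0, 0.5)
  ba <- bland_altman(x, y)
  expect_gt(ba$fraction_within, 0.93)
  expect_lt(ba$fraction_within, 0.97)
  expect_lte(ba$loa_low, ba$bias)
  expect_gte(ba$bias, ba$loa_low)
  expect_lte(ba$bias, ba$loa_high)
})

test_that("identical segmentations evaluate to dice 1 and HD 0 everywhere", {
  atlas <- small_atlas()
  g <- atlas$parcellation$grid
  idn <- normalization_from_fields(zero_field(g, "forward"),
                                   zero_field(g, "inverse"))
  subj_labels <- label_map(atlas$parcellation$labels, g, space = "subject")
  auto <- segmentation_result(subj_labels, "RATSI")
  manual <- segmentation_result(subj_labels, "manual")
  nl <- nucleus_labels()[1:4]
  ev <- evaluate_in_common_space(auto, manual, idn, nl, names(nl))
  expect_equal(ev$dice, rep(1, 4))
  expect_equal(ev$hausdorff_pixels, rep(0, 4))
  expect_equal(ev$space, rep("MNI", 4))
})

test_that("with identity normalization the RSIAT and RATSI eval paths agree", {
  atlas <- small_atlas()
  g <- atlas$parcellation$grid
  idn <- normalization_from_fields(zero_field(g, "forward"),
                                   zero_field(g, "inverse"))
  subj_labels <- label_map(atlas$parcellation$labels, g, space = "subject")
  manual <- segmentation_result(subj_labels, "manual")
  ratsi <- ratsi_segment(atlas, idn)
  rsiat_seg <- segmentation_result(atlas$parcellation, "RSIAT")
  nl <- nucleus_labels()[1:2]
  ev_r <- evaluate_in_common_space(ratsi, manual, idn, nl, names(nl))
  ev_s <- evaluate_in_common_space(rsiat_seg, manual, idn, nl, names(nl))
  expect_equal(ev_r$dice, ev_s$dice)
  expect_equal(ev_r$hausdorff_pixels, ev_s$hausdorff_pixels)
})

test_that("regions lost in warping yield per-region notes, not failures", {
  atlas <- small_atlas()
  g <- atlas$parcellation$grid
  idn <- normalization_from_fields(zero_field(g, "forward"),
                                   zero_field(g, "inverse"))
  # manual map missing label CAU_L entirely
  lab <- atlas$parcellation$labels
  lab[lab == nucleus_labels()[["CAU_L"]]] <- 0L
  manual <- segmentation_result(label_map(lab, g, space = "subject"),
                                "manual")
  ratsi <- ratsi_segment(atlas, idn)
  ev <- evaluate_in_common_space(ratsi, manual, idn,
                                 nucleus_labels()[1:2],
                                 names(nucleus_labels())[1:2])
  expect_true(is.na(ev$dice[1]))
  expect_match(ev$note[1], "empty")
  expect_false(is.na(ev$dice[2]))
})
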