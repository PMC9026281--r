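test_that("window/normalize clips, centres on the median and rescales", {
  v <- array(c(-400, 400, 1300), c(3, 1, 1))
  out <- window_and_normalize(v, segmentation_config())
  # clip window [-500, 1300] leaves values unchanged; median 400 subtracted;
  # affine rescale of {-800, 0, 900} is (x + 800) / 1700
  expect_equal(as.vector(out), c(0, 800 / 1700, 1), tolerance = 1e-12)
  # values beyond the window saturate before rescaling
  v2 <- array(c(-900, -500, 400, 1300), c(4, 1, 1))
  out2 <- window_and_normalize(v2, segmentation_config())
  expect_equal(out2[1], out2[2])
})

test_that("normalization output spans [0, 1] and preserves ordering", {
  set.seed(10)
  v <- array(rnorm(4 * 5 * 6, 100, 300), c(4, 5, 6))
  out <- window_and_normalize(v, segmentation_config())
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_equal(order(out), order(pmin(pmax(v, -500), 1300)))
  expect_error(window_and_normalize(array(7, c(2, 2, 2))), "degenerate")
})

test_that("initial contour uses a closed >= comparison on raw HU", {
  v <- array(c(100, 119.9, 120, 121), c(4, 1, 1))
  expect_equal(as.vector(initial_contour(v, 120)), c(FALSE, FALSE, TRUE, TRUE))
  expect_warning(m <- initial_contour(array(-1000, c(2, 2, 2)), 120), "empty")
  expect_equal(sum(m), 0)
})

test_that("threshold monotonicity: raising the threshold never adds voxels", {
  set.seed(11)
  v <- array(rnorm(1000, 120, 80), c(10, 10, 10))
  for (th in c(105, 150, 300)) {
    lower <- initial_contour(v, th)
    higher <- initial_contour(v, th + 40)
    expect_true(all(lower[higher]))
  }
})

test_that("a uniform image drives no data flips (exact-tie rule)", {
  img <- array(0.5, c(12, 12, 12))
  mask <- array(FALSE, c(12, 12, 12))
  mask[4:9, 4:9, 4:9] <- TRUE
  st <- acwe_step(img, acwe_state(mask))
  # c1 = c2 so every force term is an exact tie: the step must equal pure
  # curvature smoothing (which, as in the reference operators, rounds the
  # sharp 3-D edges of the block -- the mask itself need not be unchanged)
  expect_equal(st$c1, st$c2)
  expect_identical(st$mask, vncaskel:::curvature_smooth(mask, 1L))
  expect_equal(st$iteration, 1L)
})

test_that("the contour converges onto a bright ball", {
  img <- bright_ball(32, radius = 10)
  truth <- ball_mask(32, radius = 10)
  inner <- ball_mask(32, radius = 6)
  st <- run_acwe(img, inner, n_iter = 10)
  expect_gte(dice_coefficient(st$mask, truth), 0.99)
  expect_gt(dice_coefficient(st$mask, truth), dice_coefficient(inner, truth))
})

test_that("a true two-phase partition is data-stable under the contour step", {
  img <- array(0, c(14, 14, 14))
  img[3:11, 3:11, 3:11] <- 1
  mask <- img == 1
  st <- acwe_step(img, acwe_state(mask))
  # the data term re-selects exactly the bright phase; only the curvature
  # term may act, so one step equals pure smoothing of the mask
  expect_identical(st$mask, vncaskel:::curvature_smooth(mask, 1L))
  # repeated stepping does not drift from a partition with a smooth boundary
  # (a sharp-edged cube, by contrast, is legitimately rounded by curvature)
  ball_img <- bright_ball(32, radius = 10)
  ball <- ball_mask(32, radius = 10)
  st10 <- run_acwe(ball_img, ball, n_iter = 10)
  expect_gte(dice_coefficient(st10$mask, ball), 0.98)
})

test_that("degenerate contour regions warn by default and error in strict mode", {
  img <- bright_ball(10, radius = 3)
  empty <- array(FALSE, c(10, 10, 10))
  expect_warning(st <- acwe_step(img, acwe_state(empty)), "degenerate")
  expect_identical(st$mask, empty)
  expect_true(st$degenerate)
  expect_error(acwe_step(img, acwe_state(empty),
                         segmentation_config(strict = TRUE)), "degenerate")
})

test_that("run_acwe composes steps and rejects n_iter below one", {
  img <- bright_ball(16, radius = 5)
  m0 <- ball_mask(16, radius = 3)
  two <- run_acwe(img, m0, n_iter = 2)
  composed <- acwe_step(img, acwe_step(img, acwe_state(m0)))
  expect_identical(two$mask, composed$mask)
  expect_equal(two$iteration, 2L)
  expect_error(run_acwe(img, m0, n_iter = 0), "at least 1")
})

test_that("refinement fills listed slices, removes metal, and is otherwise identity", {
  dm <- c(16, 16, 8)
  annulus <- array(FALSE, dm)
  x <- seq_len(16)
  r2 <- outer((x - 8.5)^2, (x - 8.5)^2, "+")
  ring <- r2 <= 36 & r2 > 9
  for (z in 1:8) annulus[, , z] <- ring
  raw <- array(500, dm)

  # identity when no rules fire
  same <- refine_mask(annulus, raw, segmentation_config())
  expect_identical(same$mask, annulus)

  # hole fill on one listed slice only
  filled <- refine_mask(annulus, raw,
                        segmentation_config(extra_fill_slices = 3))
  expect_true(all(filled$mask[, , 3][r2 <= 36]))
  expect_identical(filled$mask[, , 4], annulus[, , 4])
  expect_true(all(filled$provenance[, , 3][r2 <= 9] == "fill"))
  expect_error(refine_mask(annulus, raw,
                           segmentation_config(extra_fill_slices = 99)),
               "outside")

  # metal cap removes the voxel and one ring around it
  raw2 <- raw
  raw2[8, 8, 5] <- 10000
  metal <- refine_mask(annulus, raw2, segmentation_config())
  expect_false(any(metal$mask[7:9, 7:9, 4:6] & raw2[7:9, 7:9, 4:6] > 3000))
  expect_true(all(metal$mask[!annulus] == FALSE))

  # crop boxes delete voxels
  cropped <- refine_mask(annulus, raw, segmentation_config(),
                         crop_boxes = list(list(x = 1:16, y = 1:16, z = 7:8)))
  expect_equal(sum(cropped$mask[, , 7:8]), 0)
})

test_that("refinement never keeps voxels above the prosthesis cap", {
  set.seed(12)
  dm <- c(10, 10, 6)
  mask <- array(runif(prod(dm)) > 0.4, dm)
  raw <- array(runif(prod(dm), 0, 6000), dm)
  out <- refine_mask(mask, raw, segmentation_config())
  expect_false(any(raw[out$mask] > 3000))
})

test_that("whole-skeleton segmentation recovers the noiseless phantom", {
  ph <- build_phantom(default_truth(), noise_sd = 0)
  gt <- ph$truth_masks
  mask <- segment_skeleton(ph$volume)
  expect_gte(dice_coefficient(mask$mask, gt$skeleton_mask), 0.95)
  expect_equal(sum(mask$mask & gt$cavity_mask), 0)
  expect_equal(mask$voxel_count, sum(mask$mask))
  expect_true(all(mask$provenance[mask$mask] %in%
                    c("threshold", "acwe", "fill")))
})

test_that("segmentation is deterministic and survives noise", {
  ph <- build_phantom(default_truth(), noise_sd = 15, seed = 21)
  a <- segment_skeleton(ph$volume)
  b <- segment_skeleton(ph$volume)
  expect_identical(a$mask, b$mask)
  expect_gte(dice_coefficient(a$mask, ph$truth_masks$skeleton_mask), 0.85)
})

test_that("prosthesis voxels are absent from the final mask", {
  ph <- build_phantom(default_truth(prosthesis = TRUE), noise_sd = 0)
  mask <- segment_skeleton(ph$volume)
  expect_equal(sum(mask$mask & ph$truth_masks$prosthesis_mask), 0)
  expect_gte(dice_coefficient(mask$mask, ph$truth_masks$skeleton_mask), 0.95)
})
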