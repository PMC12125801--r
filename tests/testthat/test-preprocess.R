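test_that("hu_convert is the affine rescale map and invertible", {
  expect_equal(hu_convert(0, 1, -1024), -1024)
  expect_equal(hu_convert(1024, 1, -1024), 0)
  expect_equal(hu_convert(100, 2, -50), 150)
  expect_error(hu_convert(1, slope = 0), "slope")
  # round trip through the inverse affine
  raw <- matrix(runif(64, 0, 4096), 8, 8)
  hu <- hu_convert(raw, 1.5, -1024)
  back <- (hu - (-1024)) / 1.5
  expect_equal(back, raw, tolerance = 1e-12)
})

test_that("apply_window maps the window linearly onto [0,1] with clipping", {
  w <- window_spec(center = 40, width = 400)
  expect_equal(apply_window(-160, w), 0)
  expect_equal(apply_window(240, w), 1)
  expect_equal(apply_window(40, w), 0.5)
  expect_equal(apply_window(-1000, w), 0)
  expect_equal(apply_window(3000, w), 1)
  expect_error(window_spec(width = 0), "width")
  # monotone non-decreasing
  hu <- sort(runif(200, -500, 500))
  out <- apply_window(hu, w)
  expect_true(all(diff(out) >= 0))
})

test_that("adaptive_hist_eq keeps range contracts and stretches low contrast", {
  const <- matrix(0.42, 64, 64)
  out <- adaptive_hist_eq(const)
  expect_equal(max(out) - min(out), 0) # constant in, constant out
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  out <- adaptive_hist_eq(img)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  expect_identical(out, adaptive_hist_eq(img)) # deterministic
  # low-contrast ramp occupying [0.4, 0.6] gets a strictly wider range
  ramp <- matrix(seq(0.4, 0.6, length.out = 64), 64, 64, byrow = TRUE)
  eq <- adaptive_hist_eq(ramp)
  expect_gt(diff(range(eq)), diff(range(ramp)))
  expect_error(adaptive_hist_eq(matrix(c(NA, 1), 2, 2)), "non-finite")
  expect_error(adaptive_hist_eq(matrix(2, 4, 4)), "\\[0, 1\\]")
})

test_that("augment_pair identity case and binary-mask contract", {
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- random_mask(64, 64, 0.2)
  a0 <- augmentation_spec(0, 0, 0, c(1, 1))
  out <- augment_pair(img, mask, a0)
  expect_identical(out$image, img)
  expect_identical(out$mask, mask)
  a <- augmentation_spec(seed = 4L)
  out <- augment_pair(img, mask, a)
  expect_true(all(out$mask %in% c(0, 1)))
  expect_identical(out$image, augment_pair(img, mask, a)$image) # seeded
  expect_error(augment_pair(img, mask[1:10, 1:10], a), "shapes differ")
})

test_that("90-degree rotation maps an off-center pixel to the hand-computed spot", {
  # 9x9 grid, center c = (5,5).  Forward rotation by 90 degrees maps
  # p - c = (dr, dc) to (cos t * dr - sin t * dc, sin t * dr + cos t * dc)
  # = (-dc, dr).  Pixel (2,5): dr=-3, dc=0 -> (0,-3) -> lands at (5,2).
  img <- matrix(0, 9, 9)
  mask <- matrix(0, 9, 9)
  mask[2, 5] <- 1
  img[2, 5] <- 1
  out <- apply_affine(img, mask, angle = 90)
  expect_equal(out$mask[5, 2], 1)
  expect_equal(sum(out$mask), 1)
  expect_equal(out$image[5, 2], 1, tolerance = 1e-9)
})

test_that("image and mask receive the identical geometric map", {
  # landmark check: transform a delta image bilinearly and a delta mask by
  # nearest neighbor; the mask pixel must sit at the argmax of the image.
  for (seed in 1:5) {
    img <- matrix(0, 33, 33)
    mask <- matrix(0, 33, 33)
    img[9, 23] <- 1
    mask[9, 23] <- 1
    a <- augmentation_spec(rotation_range = 20, shift_range = 0.08,
                           shear_range = 4, zoom_range = c(0.95, 1.1),
                           seed = seed)
    out <- augment_pair(img, mask, a, fill = 0)
    if (sum(out$mask) == 0) next # landmark pushed out of frame
    peak <- which(out$image == max(out$image), arr.ind = TRUE)[1, ]
    hit <- which(out$mask == 1, arr.ind = TRUE)
    d <- sqrt(min((hit[, 1] - peak[1])^2 + (hit[, 2] - peak[2])^2))
    expect_lte(d, 1.5) # nearest-neighbor vs bilinear peak differ < 1 px + tie
  }
})

test_that("out-of-frame fill uses image minimum and mask zero", {
  img <- matrix(5, 32, 32)
  img[1, 1] <- 2
  mask <- matrix(1, 32, 32)
  out <- apply_affine(img, mask, shift = c(16, 0))
  expect_equal(min(out$image), 2) # filled with min(img)
  expect_true(all(out$mask[1:10, ] == 0))
})
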