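test_that("phantom generation is byte-identical under a fixed seed", {
  spec <- tiny_phantom_spec(seed = 11L)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  p3 <- generate_phantom(tiny_phantom_spec(seed = 12L))
  expect_false(identical(p1$image, p3$image))
})

test_that("spec invariants are enforced with the offending field named", {
  expect_error(phantom_spec(height = 16), "height")
  expect_error(phantom_spec(width = 16), "width")
  expect_error(phantom_spec(irregularity = 1.2), "irregularity")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(target_axes = c(40, 6)), "target_axes")
  expect_error(phantom_spec(target_axes = c(-1, 6)), "target_axes")
})

test_that("zero irregularity and zero noise give an exact discretized ellipse", {
  # brute-force oracle: count pixels satisfying the ellipse inequality
  for (axes in list(c(8, 8), c(10, 8), c(12, 9))) {
    spec <- tiny_phantom_spec(target_axes = axes, irregularity = 0,
                              noise_sd = 0, n_neighbors = 0L, seed = 3L)
    p <- generate_phantom(spec)
    ctr <- p$geometry$center
    inside <- outer(seq_len(64), seq_len(64), function(r, c) {
      ((r - ctr[1]) / axes[1])^2 + ((c - ctr[2]) / axes[2])^2 <= 1
    })
    expect_identical(p$mask, inside * 1)
    expect_lt(abs(sum(p$mask) - pi * axes[1] * axes[2]),
              0.05 * pi * axes[1] * axes[2])
    # interior is exactly the target mean, outside exactly background
    expect_true(all(p$image[p$mask == 1] == spec$target_mean_hu))
    expect_true(all(p$image[p$mask == 0] == spec$background_hu))
  }
})

test_that("mask pixels satisfy the recorded boundary function", {
  p <- generate_phantom(tiny_phantom_spec(irregularity = 0.5, seed = 21L))
  rows <- matrix(seq_len(64), 64, 64)
  cols <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  inside <- msaunet:::perturbed_ellipse_inside(rows, cols, p$geometry)
  expect_identical(p$mask, inside * 1)
  expect_gt(sum(p$mask), 0)
})

test_that("pure-noise phantom has no interior/exterior contrast (Monte Carlo)", {
  # target mean == background: the signed difference of region means over
  # 100 seeds should stay within 3 * sd / sqrt(area) of zero.
  diffs <- vapply(1:100, function(s) {
    spec <- tiny_phantom_spec(target_mean_hu = 60, background_hu = 60,
                              neighbor_mean_hu = 60, noise_sd = 10,
                              n_neighbors = 0L, irregularity = 0, seed = s)
    p <- generate_phantom(spec)
    mean(p$image[p$mask == 1]) - mean(p$image[p$mask == 0])
  }, numeric(1))
  area <- sum(generate_phantom(tiny_phantom_spec(
    target_mean_hu = 60, background_hu = 60, neighbor_mean_hu = 60,
    noise_sd = 10, n_neighbors = 0L, irregularity = 0, seed = 1L))$mask)
  expect_lt(abs(mean(diffs)), 3 * 10 / sqrt(area))
})

test_that("contrast control: larger HU offsets give larger mean differences", {
  offsets <- c(0, 10, 25, 50)
  sep <- vapply(offsets, function(off) {
    d <- vapply(1:20, function(s) {
      p <- generate_phantom(tiny_phantom_spec(
        target_mean_hu = 60 - off, background_hu = 60,
        neighbor_mean_hu = 60, n_neighbors = 0L, noise_sd = 10, seed = s))
      abs(mean(p$image[p$mask == 1]) - mean(p$image[p$mask == 0]))
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("neighbors are disjoint from the target and near its gray level", {
  p <- generate_phantom(tiny_phantom_spec(noise_sd = 0, seed = 5L))
  expect_gt(length(p$neighbors), 0)
  rows <- matrix(seq_len(64), 64, 64)
  cols <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  for (ng in p$neighbors) {
    inside <- msaunet:::perturbed_ellipse_inside(rows, cols, ng)
    expect_equal(sum(inside & p$mask == 1), 0)
    expect_true(all(p$image[inside] == p$spec$neighbor_mean_hu))
  }
  expect_lte(abs(p$spec$neighbor_mean_hu - p$spec$target_mean_hu), 10)
})

test_that("dataset split arithmetic matches the 7:1:7 protocol", {
  expect_identical(unname(msaunet:::split_sizes(15, c(7, 1, 7))), c(7, 1, 7))
  expect_identical(unname(msaunet:::split_sizes(152, c(7, 1, 7))),
                   c(70, 11, 71))
  ds <- generate_dataset(15, tiny_phantom_spec(), seed = 2L)
  expect_identical(as.integer(table(ds$split)), c(7L, 1L, 7L))
  expect_error(generate_dataset(2, tiny_phantom_spec()), "at least 3")
  expect_error(generate_dataset(3, tiny_phantom_spec(), ratio = c(7, 1, 7)),
               "too small")
})

test_that("dataset generation is deterministic and per-case independent", {
  jit <- list(target_axes = 2, target_mean_hu = 5)
  d1 <- generate_dataset(8, tiny_phantom_spec(), jitter = jit, seed = 9L)
  d2 <- generate_dataset(8, tiny_phantom_spec(), jitter = jit, seed = 9L)
  expect_identical(d1$split, d2$split)
  for (i in seq_along(d1$pairs)) {
    expect_identical(d1$pairs[[i]]$image, d2$pairs[[i]]$image)
  }
  # distinct cases differ
  expect_false(identical(d1$pairs[[1]]$image, d1$pairs[[2]]$image))
  expect_error(generate_dataset(8, tiny_phantom_spec(),
                                jitter = list(bogus = 1)), "jitter")
})
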