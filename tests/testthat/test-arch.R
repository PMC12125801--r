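ns <- asNamespace("msaunet")

test_that("sSE attention: sigmoid-at-rest, bounds and contraction", {
  set.seed(1)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  out <- sse_attention(x, seed = 2L)
  expect_true(all(out$weights > 0 & out$weights < 1))
  expect_true(all(abs(out$recalibrated) <= abs(as_hwcn_arr(x))))
  # zero weights and bias -> sigmoid(0) = 0.5 everywhere, recalibrated = 0
  zero_weights(out$module)
  at_rest <- sse_attention(array(0, c(8, 8, 4)), module = out$module)
  expect_true(all(at_rest$weights == 0.5))
  expect_true(all(at_rest$recalibrated == 0))
})

test_that("MSSA attention: zero propagation, bounds, distinct scale maps", {
  set.seed(2)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  out <- mssa_attention(x, seed = 3L)
  expect_true(all(out$weights > 0 & out$weights < 1))
  expect_true(all(abs(out$recalibrated) <= abs(as_hwcn_arr(x))))
  expect_length(out$scale_maps, 3L) # sSE + two pooled scales
  expect_true(all(vapply(out$scale_maps,
                         function(m) identical(dim(m)[1:2], c(16L, 16L)),
                         logical(1))))

  # zero input with all-zero convolutions: every map is exactly 0.5
  zero_weights(out$module)
  rest <- mssa_attention(array(0, c(16, 16, 4)), module = out$module)
  for (m in rest$scale_maps) expect_true(all(m == 0.5))
  expect_true(all(rest$weights == 0.5))
  expect_true(all(rest$recalibrated == 0))

  # single high-magnitude 4x4 patch: the per-scale maps are not identical
  patch <- array(0, c(16, 16, 1))
  patch[5:8, 5:8, 1] <- 10
  pm <- mssa_attention(patch, seed = 7L)
  expect_false(isTRUE(all.equal(pm$scale_maps[[1]], pm$scale_maps[[2]])))
  expect_false(isTRUE(all.equal(pm$scale_maps[[2]], pm$scale_maps[[3]])))

  expect_error(mssa_attention(array(0, c(3, 3, 1))), "pool factor")
})

test_that("MSFEF: shape contract, zero-weight linearity and parameter count", {
  set.seed(3)
  x <- array(rnorm(12 * 12 * 8), c(12, 12, 8))
  for (bank in list(c(3L, 5L, 7L), c(5L, 7L, 9L))) {
    out <- msfef(x, kernels = bank, out_channels = 16L, seed = 4L)
    expect_identical(dim(out$output), c(12L, 12L, 16L, 1L))
  }
  out <- msfef(x, out_channels = 16L, seed = 4L)
  zero_weights(out$module)
  z <- msfef(x, module = out$module)
  expect_true(all(z$output == 0))
  expect_error(msfef(x, kernels = c(3L, 4L)), "odd")

  # hand-expanded parameter count for C_in=8, C_out=16, kernels (3,5,7),
  # branch width = out_channels, concat + 1x1 fusion, BN after every conv:
  #   branches: sum_k (k^2*8*16 + 16) + BN(2*16 each)
  #   fusion:   1*1*48*16 + 16 + BN(2*16)
  expected <- sum(vapply(c(3, 5, 7), function(k) k^2 * 8 * 16 + 16 + 32,
                         numeric(1))) + (48 * 16 + 16 + 32)
  m <- ns$nn_msfef(8L, 16L, c(3L, 5L, 7L))
  expect_identical(count_parameters(m), expected)
})

test_that("MSA block: residual identity, shape preservation, V2 > V1", {
  set.seed(4)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  for (v in c("V1", "V2")) {
    for (att in c("sSE", "MSSA")) {
      out <- msa_block(x, out_channels = 8L, version = v, attention = att,
                       seed = 5L)
      expect_identical(dim(out$output), c(16L, 16L, 8L, 1L))
    }
  }
  # equal channels, all learned transforms zeroed -> pure pass-through
  out <- msa_block(x, out_channels = 8L, seed = 6L)
  zero_weights(out$module)
  z <- msa_block(x, module = out$module)
  expect_equal(z$output[, , , 1], x, tolerance = 1e-12)
  # channel change engages the projection; still shape preserving
  out2 <- msa_block(x, out_channels = 12L, seed = 6L)
  expect_identical(dim(out2$output), c(16L, 16L, 12L, 1L))
  # V2 has strictly more parameters than V1 at identical widths
  v1 <- ns$nn_msa_block(8L, 16L, "V1", "MSSA")
  v2 <- ns$nn_msa_block(8L, 16L, "V2", "MSSA")
  expect_gt(count_parameters(v2), count_parameters(v1))
})

test_that("model config validation and defaults", {
  expect_identical(model_config("V1")$n_msa_blocks, 3L)
  expect_identical(model_config("V2")$n_msa_blocks, 2L)
  expect_error(model_config("V1", n_msa_blocks = 5), "n_msa_blocks")
  expect_error(model_config("V1", n_msa_blocks = 3, depth = 2),
               "n_msa_blocks")
  expect_error(model_config("V1", output_threshold = 1.5),
               "output_threshold")
})

test_that("built models preserve shape, emit probabilities, count monotone", {
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  counts <- c()
  for (n in 0:2) {
    cfg <- model_config("V1", n_msa_blocks = n, base_channels = 2L,
                        depth = 2L)
    m <- build_model(cfg, seed = 3L)
    p <- m$forward(x)$value
    expect_identical(dim(p), c(32L, 32L, 1L, 1L))
    expect_true(all(p > 0 & p < 1))
    counts <- c(counts, count_parameters(m))
  }
  expect_true(all(diff(counts) > 0)) # capacity strictly increasing in n
})

test_that("predict_mask thresholds the probability map", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 2L)
  img <- matrix(runif(32 * 32), 32, 32)
  pr <- predict_prob(m, img)
  mk <- predict_mask(m, img)
  expect_identical(mk, (pr >= 0.5) * 1)
  expect_identical(predict_mask(m, img, threshold = max(pr) + 1e-9),
                   matrix(0, 32, 32))
  expect_identical(predict_mask(m, img, threshold = min(pr) - 1e-9) ,
                   matrix(1, 32, 32))
})

test_that("checkpoint round trip reproduces the forward pass exactly", {
  cfg <- tiny_model_config(n = 2L)
  m <- build_model(cfg, seed = 9L)
  img <- matrix(runif(32 * 32), 32, 32)
  p1 <- predict_prob(m, img)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_identical(predict_prob(m2, img), p1)
})
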