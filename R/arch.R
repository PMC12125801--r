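# MSAU-Net architecture: sSE and MSSA spatial attention, the MSFEF
# multi-scale convolution module, the MSA block (V1: one MSFEF branch bank,
# V2: two parallel banks), and the U-Net builder that swaps MSA blocks into
# the deepest encoder stages.

#' Model configuration for MSAU-Net
#'
#' Describes an MSAU-Net (or plain improved U-Net when `n_msa_blocks = 0`).
#' V1 places a single MSFEF module (kernel bank 3/5/7) in each MSA block;
#' V2 uses two parallel MSFEF modules (banks 3/5/7 and 5/7/9) whose outputs
#' are fused.  Defaults for `n_msa_blocks` are the configurations found
#' optimal with MSSA attention: three blocks for V1 and two for V2.
#'
#' @param version `"V1"` or `"V2"`.
#' @param n_msa_blocks Number of encoder stages (counted upward from the
#'   deepest stage) whose double convolution is replaced by an MSA block;
#'   0 to 4, must not exceed `depth`. Default 3 (V1) or 2 (V2).
#' @param attention Spatial attention used inside MSA blocks: `"MSSA"`
#'   (multi-scale) or `"sSE"` (single-scale channel-squeeze gate).
#' @param base_channels Channels of the first encoder stage; stage s has
#'   `base_channels * 2^(s-1)` channels.
#' @param depth Number of encoder stages (each followed by 2x2 max-pooling).
#' @param mssa_pool_factors Average-pooling factors of the two MSSA scales.
#' @param kernel_bank_a,kernel_bank_b Odd kernel sizes of the MSFEF branch
#'   banks; V1 uses only bank a.
#' @param output_threshold Probability cut used by [predict_mask()].
#' @return An object of class `model_config`.
#' @export
model_config <- function(version = c("V1", "V2"), n_msa_blocks = NULL,
                         attention = c("MSSA", "sSE"), base_channels = 32L,
                         depth = 4L, mssa_pool_factors = c(2L, 4L),
                         kernel_bank_a = c(3L, 5L, 7L),
                         kernel_bank_b = c(5L, 7L, 9L),
                         output_threshold = 0.5) {
  version <- match.arg(version)
  attention <- match.arg(attention)
  if (is.null(n_msa_blocks)) n_msa_blocks <- if (version == "V1") 3L else 2L
  n_msa_blocks <- as.integer(n_msa_blocks)
  depth <- as.integer(depth)
  if (n_msa_blocks < 0L || n_msa_blocks > 4L) {
    stop_field("n_msa_blocks", "must be between 0 and 4")
  }
  if (n_msa_blocks > depth) {
    stop_field("n_msa_blocks", sprintf("exceeds model depth (%d)", depth))
  }
  if (depth < 1L) stop_field("depth", "must be at least 1")
  if (base_channels < 1L) stop_field("base_channels", "must be positive")
  if (any(kernel_bank_a %% 2L == 0L) || any(kernel_bank_b %% 2L == 0L)) {
    stop_field("kernel_bank", "kernel sizes must be odd")
  }
  if (output_threshold <= 0 || output_threshold >= 1) {
    stop_field("output_threshold", "must lie strictly in (0, 1)")
  }
  structure(list(version = version, n_msa_blocks = n_msa_blocks,
                 attention = attention,
                 base_channels = as.integer(base_channels), depth = depth,
                 mssa_pool_factors = as.integer(mssa_pool_factors),
                 kernel_bank_a = as.integer(kernel_bank_a),
                 kernel_bank_b = as.integer(kernel_bank_b),
                 output_threshold = output_threshold),
            class = "model_config")
}

# ---- attention modules -----------------------------------------------------

# Channel squeeze / spatial excitation: 1x1 conv to one channel + sigmoid,
# broadcast-multiplied into the input.
nn_sse <- function(channels) {
  conv <- nn_conv(channels, 1L, 1L, act = "none", bn = FALSE)
  new_module(sub = list(squeeze = conv), fwd = function(x, training) {
    w <- op_sigmoid(conv$fwd(x, training))
    list(weights = w, recal = op_gate(x, w), maps = list(w))
  })
}

# Multi-scale spatial attention: the sSE map plus one attention map per
# pooled scale (avg-pool -> 3x3 conv -> sigmoid -> bilinear upsample), all
# fused by a final 3x3 conv + sigmoid into the gating weights.
nn_mssa <- function(channels, pool_factors = c(2L, 4L)) {
  sse <- nn_conv(channels, 1L, 1L, act = "none", bn = FALSE)
  scales <- lapply(pool_factors, function(f) {
    nn_conv(channels, 1L, 3L, act = "none", bn = FALSE)
  })
  names(scales) <- paste0("scale", pool_factors)
  fuse <- nn_conv(length(pool_factors) + 1L, 1L, 3L, act = "none", bn = FALSE)
  new_module(
    sub = c(list(sse = sse), scales, list(fuse = fuse)),
    fwd = function(x, training) {
      d <- dim(x$value)
      maps <- vector("list", length(pool_factors) + 1L)
      maps[[1L]] <- op_sigmoid(sse$fwd(x, training))
      for (i in seq_along(pool_factors)) {
        p <- op_avgpool(x, pool_factors[i])
        m <- op_sigmoid(scales[[i]]$fwd(p, training))
        maps[[i + 1L]] <- op_upsample(m, d[1L], d[2L])
      }
      w <- op_sigmoid(fuse$fwd(op_concat(maps), training))
      list(weights = w, recal = op_gate(x, w), maps = maps)
    }
  )
}

nn_attention <- function(kind, channels, pool_factors) {
  switch(kind,
         sSE = nn_sse(channels),
         MSSA = nn_mssa(channels, pool_factors),
         stop("unknown attention kind: ", kind))
}

# ---- MSFEF and the MSA block -----------------------------------------------

# Multi-scale feature extraction and fusion: one conv-BN-ReLU branch per
# kernel size (each with `co` channels), concatenated and fused by a 1x1
# conv-BN-ReLU back to `co` channels.
nn_msfef <- function(ci, co, kernels) {
  if (any(kernels %% 2L == 0L) || any(kernels < 3L)) {
    stop("MSFEF kernels must be odd and >= 3")
  }
  branches <- lapply(kernels, function(k) nn_conv(ci, co, k))
  names(branches) <- paste0("k", kernels)
  fuse <- nn_conv(length(kernels) * co, co, 1L)
  new_module(
    sub = c(branches, list(fuse = fuse)),
    fwd = function(x, training) {
      outs <- lapply(branches, function(b) b$fwd(x, training))
      fuse$fwd(op_concat(outs), training)
    }
  )
}

# MSA block: MSFEF (one bank in V1; two parallel banks fused in V2),
# followed by spatial attention, wrapped in a residual shortcut.  A channel
# mismatch on the shortcut is handled by a learned 1x1 projection.
nn_msa_block <- function(ci, co, version = "V1", attention = "MSSA",
                         pool_factors = c(2L, 4L),
                         bank_a = c(3L, 5L, 7L), bank_b = c(5L, 7L, 9L)) {
  sub <- list(msfef_a = nn_msfef(ci, co, bank_a))
  if (version == "V2") {
    sub$msfef_b <- nn_msfef(ci, co, bank_b)
    sub$branch_fuse <- nn_conv(2L * co, co, 1L)
  }
  sub$att <- nn_attention(attention, co, pool_factors)
  if (ci != co) sub$proj <- nn_conv(ci, co, 1L, act = "none", bn = FALSE)
  new_module(sub = sub, fwd = function(x, training) {
    f <- sub$msfef_a$fwd(x, training)
    if (version == "V2") {
      f2 <- sub$msfef_b$fwd(x, training)
      f <- sub$branch_fuse$fwd(op_concat(list(f, f2)), training)
    }
    f <- sub$att$fwd(f, training)$recal
    shortcut <- if (ci != co) sub$proj$fwd(x, training) else x
    op_add(f, shortcut)
  })
}

# Decoder stage: bilinear 2x upsample -> 3x3 conv-BN-ReLU (channel halving),
# concat with the skip, then a residual double convolution.
nn_decoder_block <- function(ci_deep, c_skip, co) {
  up <- nn_conv(ci_deep, co, 3L)
  c1 <- nn_conv(c_skip + co, co, 3L)
  c2 <- nn_conv(co, co, 3L)
  proj <- nn_conv(c_skip + co, co, 1L, act = "none", bn = FALSE)
  new_module(
    sub = list(up = up, c1 = c1, c2 = c2, proj = proj),
    fwd = function(xs, training) {
      deep <- xs$deep
      skip <- xs$skip
      ds <- dim(skip$value)
      u <- up$fwd(op_upsample(deep, ds[1L], ds[2L]), training)
      cat_in <- op_concat(list(u, skip))
      y <- c2$fwd(c1$fwd(cat_in, training), training)
      op_add(y, proj$fwd(cat_in, training))
    }
  )
}

# ---- model builder ---------------------------------------------------------

#' Build an MSAU-Net segmentation model
#'
#' Constructs a U-Net encoder-decoder with skip connections in which the
#' deepest `n_msa_blocks` encoder stages use an MSA block in place of the
#' standard double convolution; the bottleneck and decoder follow the
#' improved-U-Net design (conv-BN-ReLU with residual connections, bilinear
#' upsampling).  A final 1x1 convolution and sigmoid produce per-pixel
#' foreground probabilities.  `n_msa_blocks = 0` yields the improved U-Net
#' baseline.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `msau_model` with elements `cfg`, `net`,
#'   `params` and the closure `forward(x, training = FALSE)` mapping an
#'   input array (H, W) / (H, W, 1, N) to a probability array of the same
#'   spatial shape.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(seed, {
    widths <- cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)
    enc <- vector("list", cfg$depth)
    ci <- 1L
    for (s in seq_len(cfg$depth)) {
      use_msa <- s > cfg$depth - cfg$n_msa_blocks
      enc[[s]] <- if (use_msa) {
        nn_msa_block(ci, widths[s], cfg$version, cfg$attention,
                     cfg$mssa_pool_factors, cfg$kernel_bank_a,
                     cfg$kernel_bank_b)
      } else {
        nn_double_conv(ci, widths[s])
      }
      ci <- widths[s]
    }
    names(enc) <- paste0("enc", seq_len(cfg$depth))
    bottleneck <- nn_double_conv(ci, 2L * ci)
    dec <- vector("list", cfg$depth)
    ci <- 2L * widths[cfg$depth]
    for (s in rev(seq_len(cfg$depth))) {
      dec[[s]] <- nn_decoder_block(ci, widths[s], widths[s])
      ci <- widths[s]
    }
    names(dec) <- paste0("dec", seq_len(cfg$depth))
    head <- nn_conv(widths[1L], 1L, 1L, act = "sigmoid", bn = FALSE)

    net <- new_module(
      sub = c(enc, list(bottleneck = bottleneck), dec, list(head = head)),
      fwd = function(x, training) {
        skips <- vector("list", cfg$depth)
        for (s in seq_len(cfg$depth)) {
          x <- enc[[s]]$fwd(x, training)
          skips[[s]] <- x
          x <- op_maxpool2(x)
        }
        x <- bottleneck$fwd(x, training)
        for (s in rev(seq_len(cfg$depth))) {
          x <- dec[[s]]$fwd(list(deep = x, skip = skips[[s]]), training)
        }
        head$fwd(x, training)
      }
    )

    model <- list(cfg = cfg, net = net, params = module_params(net),
                  states = module_states(net))
    model$forward <- function(x, training = FALSE) {
      xn <- as_node(as_hwcn(x))
      net$fwd(xn, training)
    }
    structure(model, class = "msau_model")
  })
}

#' @export
print.msau_model <- function(x, ...) {
  cat(sprintf(
    "MSAU-Net %s | %d MSA block(s) [%s] | depth %d, base %d channels | %d parameters\n",
    x$cfg$version, x$cfg$n_msa_blocks, x$cfg$attention, x$cfg$depth,
    x$cfg$base_channels, count_parameters(x)))
  invisible(x)
}

#' Predict a binary mask from a model
#'
#' Runs the model in evaluation mode and thresholds the probability map.
#'
#' @param model An `msau_model`.
#' @param img Input array (H, W) or (H, W, 1, N), already preprocessed to
#'   the model input range.
#' @param threshold Probability cut; defaults to the configured
#'   `output_threshold`.
#' @return A binary matrix (or (H, W, 1, N) array for batched input).
#' @export
predict_mask <- function(model, img, threshold = NULL) {
  stopifnot(inherits(model, "msau_model"))
  if (is.null(threshold)) threshold <- model$cfg$output_threshold
  x <- as_hwcn(img)
  p <- model$forward(x, training = FALSE)$value
  m <- (p >= threshold) * 1
  if (length(dim(img)) == 2L || is.null(dim(img))) {
    m <- m[, , 1L, 1L]
  }
  m
}

#' Forward probabilities for an input batch
#'
#' @param model An `msau_model`.
#' @param img Input array (H, W) or (H, W, 1, N).
#' @return Probability array with the input's spatial shape.
#' @export
predict_prob <- function(model, img) {
  p <- model$forward(as_hwcn(img), training = FALSE)$value
  if (length(dim(img)) == 2L) p <- p[, , 1L, 1L]
  p
}

# ---- standalone functional wrappers (array in / array out) -----------------

standalone_forward <- function(mod, x, training = TRUE) {
  mod$fwd(as_node(as_hwcn(x)), training)
}

#' Channel-squeeze / spatial-excitation attention
#'
#' Applies an sSE gate (1x1 convolution squeezing channels to one, sigmoid,
#' broadcast multiplication) to a feature map.  A fresh module is
#' initialized from `seed` unless one is supplied.
#'
#' @param x Feature array (H, W), (H, W, C) or (H, W, C, N).
#' @param module Optional module from a previous call (for reuse/zeroing).
#' @param seed Seed for weight initialization when `module` is NULL.
#' @return List with `weights` ((H, W, 1, N) map in (0,1)), `recalibrated`
#'   (same shape as the promoted input) and `module`.
#' @export
sse_attention <- function(x, module = NULL, seed = 1L) {
  xa <- as_hwcn(x)
  if (is.null(module)) {
    module <- with_seed(seed, nn_sse(dim(xa)[3L]))
  }
  out <- standalone_forward(module, xa)
  list(weights = out$weights$value, recalibrated = out$recal$value,
       module = module)
}

#' Multi-scale spatial attention (MSSA)
#'
#' Extends sSE with attention maps computed at average-pooled scales,
#' upsampled back to full resolution and fused with the sSE map by a final
#' convolution + sigmoid; the fused weights gate the input.
#'
#' @inheritParams sse_attention
#' @param pool_factors Integer pooling factors of the extra scales.
#' @return List with `weights`, `recalibrated`, `scale_maps` (the per-scale
#'   maps at input resolution: sSE first, then one per pool factor) and
#'   `module`.
#' @export
mssa_attention <- function(x, pool_factors = c(2L, 4L), module = NULL,
                           seed = 1L) {
  xa <- as_hwcn(x)
  d <- dim(xa)
  if (max(pool_factors) > min(d[1L], d[2L])) {
    stop("pool factor larger than spatial dimension")
  }
  if (is.null(module)) {
    module <- with_seed(seed, nn_mssa(dim(xa)[3L], pool_factors))
  }
  out <- standalone_forward(module, xa)
  list(weights = out$weights$value, recalibrated = out$recal$value,
       scale_maps = lapply(out$maps, function(m) m$value),
       module = module)
}

#' Multi-scale feature extraction and fusion (MSFEF)
#'
#' Parallel same-padding convolutions with the given odd kernel sizes, each
#' producing `out_channels` features, concatenated and fused by a 1x1
#' convolution back to `out_channels`.
#'
#' @inheritParams sse_attention
#' @param kernels Odd kernel sizes (e.g. `c(3, 5, 7)` or `c(5, 7, 9)`).
#' @param out_channels Channels of the fused output.
#' @return List with `output` ((H, W, out_channels, N) array) and `module`.
#' @export
msfef <- function(x, kernels = c(3L, 5L, 7L), out_channels = 16L,
                  module = NULL, seed = 1L) {
  xa <- as_hwcn(x)
  if (is.null(module)) {
    module <- with_seed(seed, nn_msfef(dim(xa)[3L], out_channels, kernels))
  }
  out <- standalone_forward(module, xa)
  list(output = out$value, module = module)
}

#' Apply a single MSA block
#'
#' MSFEF (one kernel bank in V1, two parallel banks fused in V2) followed
#' by spatial attention, wrapped in a residual shortcut (with a learned 1x1
#' projection when channel counts differ).
#'
#' @inheritParams sse_attention
#' @param out_channels Output channels of the block.
#' @param version `"V1"` or `"V2"`.
#' @param attention `"MSSA"` or `"sSE"`.
#' @param pool_factors MSSA pooling factors.
#' @return List with `output` and `module`.
#' @export
msa_block <- function(x, out_channels = 16L, version = "V1",
                      attention = "MSSA", pool_factors = c(2L, 4L),
                      module = NULL, seed = 1L) {
  xa <- as_hwcn(x)
  if (is.null(module)) {
    module <- with_seed(seed, nn_msa_block(dim(xa)[3L], out_channels,
                                           version, attention, pool_factors))
  }
  out <- standalone_forward(module, xa)
  list(output = out$value, module = module)
}
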