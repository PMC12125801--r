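# A minimal reverse-mode automatic-differentiation engine over dense R
# arrays.  Feature tensors use the layout (H, W, C, N); convolution weights
# (kh, kw, Cin, Cout).  Nodes are environments so parameter updates and
# gradient accumulation happen by reference.  The graph is rebuilt on every
# forward pass (define-by-run); `ag_backward()` walks it in reverse creation
# order, which is a valid topological order.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

ag_next_id <- function() {
  .ag$id <- .ag$id + 1L
  .ag$id
}

ag_node <- function(value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$requires_grad <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  n$id <- ag_next_id()
  class(n) <- "ag_node"
  n
}

#' @noRd
ag_leaf <- function(value, requires_grad = FALSE) {
  n <- ag_node(value)
  n$requires_grad <- requires_grad
  n
}

ag_param <- function(value) ag_leaf(value, requires_grad = TRUE)

as_node <- function(x) if (inherits(x, "ag_node")) x else ag_leaf(x)

# Reverse-mode sweep from a scalar (or array) root.  Gradients accumulate
# into node$grad; call ag_zero_grad() on parameters between steps.
ag_backward <- function(root) {
  nodes <- vector("list", 64L)
  nn <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) length(nodes) <- 2L * length(nodes)
    nodes[[nn]] <- nd
    for (p in nd$parents) if (p$requires_grad) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  root$grad <- if (is.null(dim(root$value))) 1 else array(1, dim(root$value))
  for (k in ord) {
    nd <- nodes[[k]]
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!p$requires_grad || is.null(gs[[i]])) next
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
    nd$grad <- NULL # free intermediate gradients early
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- array helpers ---------------------------------------------------------

# Promote (H,W) or (H,W,C) to the canonical (H,W,C,N) layout.
as_hwcn <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array input")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 2-, 3- or 4-dimensional array")
  x
}

# Collapse channel dimension to matrix (H*W*N) x C for per-channel reductions.
to_channel_mat <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xp) <- c(prod(d[c(1L, 2L, 4L)]), d[3L])
  xp
}

from_channel_mat <- function(m, d) {
  dim(m) <- c(d[1L], d[2L], d[4L], d[3L])
  aperm(m, c(1L, 2L, 4L, 3L))
}

# ---- primitive ops ---------------------------------------------------------

op_conv2d <- function(x, w, b) {
  y <- cpp_conv2d_fw(x$value, w$value, b$value)
  ag_node(y, list(x, w, b), function(g) {
    need_dx <- x$requires_grad
    r <- cpp_conv2d_bw(x$value, w$value, g, need_dx)
    db <- colSums(to_channel_mat(g))
    list(r$dx, r$dw, db)
  })
}

op_relu <- function(x) {
  mask <- x$value > 0
  ag_node(x$value * mask, list(x), function(g) list(g * mask))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

op_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

# Spatial gate: x is (H,W,C,N), w a single-channel (H,W,1,N) weight map
# broadcast over channels.
op_gate <- function(x, w) {
  d <- dim(x$value)
  wexp <- x$value
  wexp[] <- w$value[, , rep(1L, d[3L]), , drop = FALSE]
  ag_node(x$value * wexp, list(x, w), function(g) {
    dw <- rowSums(to_channel_mat(g * x$value))
    dim(dw) <- c(d[1L], d[2L], d[4L])
    dim(dw) <- c(d[1L], d[2L], 1L, d[4L])
    list(g * wexp, dw)
  })
}

op_concat <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  Cs <- vapply(ds, function(d) d[3L], numeric(1))
  d1 <- ds[[1L]]
  y <- array(0, c(d1[1L], d1[2L], sum(Cs), d1[4L]))
  off <- 0L
  for (i in seq_along(xs)) {
    y[, , off + seq_len(Cs[i]), ] <- xs[[i]]$value
    off <- off + Cs[i]
  }
  ag_node(y, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , off + seq_len(Cs[i]), , drop = FALSE]
      off <- off + Cs[i]
    }
    out
  })
}

op_maxpool2 <- function(x) {
  d <- dim(x$value)
  if (d[1L] %% 2L || d[2L] %% 2L) {
    stop("maxpool: spatial dimensions must be even, got ",
         d[1L], "x", d[2L])
  }
  i1 <- seq(1L, d[1L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2L], 2L); j2 <- j1 + 1L
  a <- x$value[i1, j1, , , drop = FALSE]
  b <- x$value[i2, j1, , , drop = FALSE]
  cc <- x$value[i1, j2, , , drop = FALSE]
  dd <- x$value[i2, j2, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  ag_node(y, list(x), function(g) {
    dx <- array(0, d)
    m <- a == y
    dx[i1, j1, , ] <- g * m
    rem <- !m
    m <- (b == y) & rem
    dx[i2, j1, , ] <- g * m
    rem <- rem & !m
    m <- (cc == y) & rem
    dx[i1, j2, , ] <- g * m
    dx[i2, j2, , ] <- g * (rem & !m)
    list(dx)
  })
}

# Separable linear resampling y[,,c,n] = Ar %*% x[,,c,n] %*% t(Ac); used for
# average pooling and bilinear upsampling; backward uses the transposes.
sep_lin <- function(x, Ar, Ac) {
  d <- dim(x)
  y <- Ar %*% matrix(x, d[1L], prod(d[-1L]))
  d1 <- c(nrow(Ar), d[2L], d[3L], d[4L])
  dim(y) <- d1
  y <- aperm(y, c(2L, 1L, 3L, 4L))
  y <- Ac %*% matrix(y, d1[2L], prod(d1[c(1L, 3L, 4L)]))
  dim(y) <- c(nrow(Ac), d1[1L], d1[3L], d1[4L])
  aperm(y, c(2L, 1L, 3L, 4L))
}

mat_avgpool <- function(n, f) {
  m <- matrix(0, n / f, n)
  for (i in seq_len(n / f)) m[i, ((i - 1L) * f + 1L):(i * f)] <- 1 / f
  m
}

# Bilinear interpolation matrix (half-pixel centers, edges clamped).
mat_bilinear <- function(nout, nin) {
  m <- matrix(0, nout, nin)
  for (i in seq_len(nout)) {
    s <- (i - 0.5) * nin / nout + 0.5 # fractional 1-based source index
    s0 <- floor(s)
    t <- s - s0
    lo <- min(max(s0, 1L), nin)
    hi <- min(max(s0 + 1L, 1L), nin)
    m[i, lo] <- m[i, lo] + (1 - t)
    m[i, hi] <- m[i, hi] + t
  }
  m
}

op_avgpool <- function(x, f) {
  d <- dim(x$value)
  if (f > min(d[1L], d[2L])) {
    stop("avgpool: pool factor ", f, " exceeds spatial size ",
         d[1L], "x", d[2L])
  }
  if (d[1L] %% f || d[2L] %% f) {
    stop("avgpool: spatial dims ", d[1L], "x", d[2L],
         " not divisible by pool factor ", f)
  }
  Ar <- mat_avgpool(d[1L], f)
  Ac <- mat_avgpool(d[2L], f)
  ag_node(sep_lin(x$value, Ar, Ac), list(x),
          function(g) list(sep_lin(g, t(Ar), t(Ac))))
}

op_upsample <- function(x, hout, wout) {
  d <- dim(x$value)
  Ar <- mat_bilinear(hout, d[1L])
  Ac <- mat_bilinear(wout, d[2L])
  ag_node(sep_lin(x$value, Ar, Ac), list(x),
          function(g) list(sep_lin(g, t(Ar), t(Ac))))
}

# Batch normalization over (H, W, N) per channel; biased variance for both
# the normalization and the running estimates.
op_bn <- function(x, gamma, beta, state, training, momentum = 0.1,
                  eps = 1e-5) {
  d <- dim(x$value)
  xp <- to_channel_mat(x$value)
  m <- nrow(xp)
  if (training) {
    mu <- colMeans(xp)
    xc <- sweep(xp, 2L, mu)
    v <- colMeans(xc * xc)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- sweep(xp, 2L, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  ym <- sweep(sweep(xhat, 2L, gamma$value, `*`), 2L, beta$value, `+`)
  ag_node(from_channel_mat(ym, d), list(x, gamma, beta), function(g) {
    gp <- to_channel_mat(g)
    dgamma <- colSums(gp * xhat)
    dbeta <- colSums(gp)
    if (training) {
      t1 <- sweep(gp, 2L, dbeta / m)
      t2 <- sweep(xhat, 2L, dgamma / m, `*`)
      dx <- sweep(t1 - t2, 2L, gamma$value * inv, `*`)
    } else {
      dx <- sweep(gp, 2L, gamma$value * inv, `*`)
    }
    list(from_channel_mat(dx, d), dgamma, dbeta)
  })
}

# Soft Dice loss node over a batch of single-channel probability maps.
# Literal form: 1 - 2*(I + eps)/(G + P + eps); symmetric form replaces the
# numerator by (2*I + eps).
op_dice_loss <- function(pred, gt, eps = 1e-6, symmetric = FALSE) {
  d <- dim(pred$value)
  n <- d[4L]
  pv <- matrix(pred$value, ncol = n)
  gv <- matrix(gt, ncol = n)
  inter <- colSums(pv * gv)
  gsum <- colSums(gv)
  psum <- colSums(pv)
  num <- if (symmetric) 2 * inter + eps else 2 * (inter + eps)
  den <- gsum + psum + eps
  losses <- 1 - num / den
  ag_node(mean(losses), list(pred), function(g) {
    dnum <- 2 * gv
    dl <- -(sweep(dnum, 2L, den, `*`) -
              matrix(num, nrow(pv), n, byrow = TRUE)) /
      matrix(den^2, nrow(pv), n, byrow = TRUE)
    dp <- g * dl / n
    dim(dp) <- d
    list(dp)
  })
}
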