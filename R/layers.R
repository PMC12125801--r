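# Lightweight "module" containers over the autodiff engine.  A module is a
# list with named parameter nodes, named batch-norm state environments,
# named submodules, and a forward closure `fwd(x, training)` operating on
# graph nodes.  Parameters are environments, so checkpoint loading mutates
# them in place and every closure that captured them sees the new values.

new_module <- function(params = list(), states = list(), sub = list(), fwd) {
  m <- list(params = params, states = states, sub = sub, fwd = fwd)
  class(m) <- "msau_module"
  m
}

#' Collect all trainable parameter nodes of a module
#'
#' @param m A module (or model) object.
#' @param prefix Name prefix used during recursion.
#' @return Named list of parameter nodes.
#' @keywords internal
module_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$sub)) {
    out <- c(out, module_params(m$sub[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

module_states <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$states)) out[[paste0(prefix, nm)]] <- m$states[[nm]]
  for (nm in names(m$sub)) {
    out <- c(out, module_states(m$sub[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Count trainable parameters
#'
#' Total number of scalar trainable parameters (convolution weights and
#' biases, batch-norm scale and shift) in a module or built model.
#'
#' @param x A module returned by the `new_*` constructors or a model from
#'   [build_model()].
#' @return Integer scalar.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "msau_model")) x <- x$net
  sum(vapply(module_params(x), function(p) length(p$value), numeric(1)))
}

#' Set all learned weights of a module to zero
#'
#' Zeroes convolution weights and biases and batch-norm shifts, leaving
#' batch-norm scales at their current value.  Used to verify residual
#' pass-through and attention-at-rest behaviour.
#'
#' @param x A module or model.
#' @return The input, invisibly (parameters are mutated in place).
#' @export
zero_weights <- function(x) {
  ps <- if (inherits(x, "msau_model")) x$params else module_params(x)
  for (nm in names(ps)) {
    if (grepl("(^|\\.)gamma$", nm)) next
    ps[[nm]]$value[] <- 0
  }
  invisible(x)
}

# He-normal initialization for a (kh, kw, ci, co) convolution kernel.
init_conv <- function(kh, kw, ci, co) {
  fan_in <- kh * kw * ci
  w <- array(stats::rnorm(kh * kw * ci * co, sd = sqrt(2 / fan_in)),
             c(kh, kw, ci, co))
  list(w = ag_param(w), b = ag_param(numeric(co)))
}

nn_bn <- function(channels) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(channels)
  st$var <- rep(1, channels)
  gamma <- ag_param(rep(1, channels))
  beta <- ag_param(numeric(channels))
  new_module(params = list(gamma = gamma, beta = beta),
             states = list(bn = st),
             fwd = function(x, training) op_bn(x, gamma, beta, st, training))
}

# conv -> (BN) -> activation; same padding, stride 1.
nn_conv <- function(ci, co, k, act = "relu", bn = TRUE) {
  if (k %% 2 == 0) stop("kernel size must be odd, got ", k)
  p <- init_conv(k, k, ci, co)
  bnm <- if (bn) nn_bn(co) else NULL
  new_module(
    params = list(w = p$w, b = p$b),
    sub = if (bn) list(bn = bnm) else list(),
    fwd = function(x, training) {
      y <- op_conv2d(x, p$w, p$b)
      if (bn) y <- bnm$fwd(y, training)
      switch(act, relu = op_relu(y), sigmoid = op_sigmoid(y), none = y)
    }
  )
}

nn_seq <- function(mods) {
  new_module(sub = mods, fwd = function(x, training) {
    for (m in mods) x <- m$fwd(x, training)
    x
  })
}

# Standard U-Net double convolution (two 3x3 conv-BN-ReLU).
nn_double_conv <- function(ci, co) {
  nn_seq(list(c1 = nn_conv(ci, co, 3L), c2 = nn_conv(co, co, 3L)))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st
}

adam_step <- function(params, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  invisible(NULL)
}
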