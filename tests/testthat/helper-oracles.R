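# Independent brute-force oracles and shared fixtures.  These deliberately
# use naive loops / explicit set arithmetic so they share no code path with
# the package implementations they check.

# ---- metric oracles (explicit pixel-set operations) ------------------------

oracle_overlap <- function(gt, pred) {
  A <- which(gt == 1)
  B <- which(pred == 1)
  tp <- length(intersect(A, B))
  un <- length(union(A, B))
  c(dsc = if (length(A) + length(B) > 0) 2 * tp / (length(A) + length(B)) else NA_real_,
    jsc = if (un > 0) tp / un else NA_real_,
    ppv = if (length(B) > 0) tp / length(B) else NA_real_,
    se = if (length(A) > 0) tp / length(A) else NA_real_)
}

oracle_volume <- function(gt, pred) {
  A <- which(gt == 1)
  B <- which(pred == 1)
  tp <- length(intersect(A, B))
  un <- length(union(A, B))
  c(rvd = abs(length(B) - length(A)) / length(A), voe = 1 - tp / un)
}

# 8-connected boundary by explicit neighbor loop.
oracle_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pts <- NULL
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (mask[i, j] != 1) next
      edge <- FALSE
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > h || jj < 1 || jj > w || mask[ii, jj] == 0) {
            edge <- TRUE
          }
        }
      }
      if (edge) pts <- rbind(pts, c(i, j))
    }
  }
  pts
}

# All-pairs brute-force Hausdorff over boundary pixels.
oracle_hausdorff <- function(gt, pred) {
  a <- oracle_boundary(gt)
  b <- oracle_boundary(pred)
  dmin <- function(p, q) {
    # all-pairs: for each boundary point of p, the distance to every point
    # of q is evaluated explicitly and the minimum kept
    out <- numeric(nrow(p))
    for (i in seq_len(nrow(p))) {
      out[i] <- min(sqrt((p[i, 1] - q[, 1])^2 + (p[i, 2] - q[, 2])^2))
    }
    out
  }
  max(max(dmin(a, b)), max(dmin(b, a)))
}

# Literal Dice-loss formula evaluated directly.
oracle_dice_loss <- function(gt, pred, eps, symmetric = FALSE) {
  I <- sum(gt * pred)
  num <- if (symmetric) 2 * I + eps else 2 * (I + eps)
  1 - num / (sum(gt) + sum(pred) + eps)
}

random_mask <- function(h = 32, w = 32, p = 0.3) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# ---- shared tiny fixtures --------------------------------------------------

tiny_model_config <- function(version = "V1", n = 1L, attention = "MSSA",
                              depth = 2L) {
  model_config(version, n_msa_blocks = n, attention = attention,
               base_channels = 2L, depth = depth)
}

tiny_phantom_spec <- function(...) {
  phantom_spec(height = 64L, width = 64L, ...)
}

as_hwcn_arr <- function(x) msaunet:::as_hwcn(x)

# central finite-difference gradient for scalar-valued f(array)
fd_grad <- function(f, x, h = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
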