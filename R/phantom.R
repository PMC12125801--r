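# Seeded synthetic CT phantom generator.  Each phantom is a 2-D HU-valued
# slice containing one small, irregular, low-contrast target (the
# gallbladder surrogate) among a configurable number of gray-level-similar
# neighbor blobs on a noisy background.  Everything other modules need --
# preprocessing, training, metrics -- is testable against these phantoms
# without patient data.

#' Specification of a synthetic CT phantom
#'
#' The target is a perturbed ellipse: the elliptical radius is modulated by
#' a truncated Fourier series (first four harmonics) whose normalized
#' amplitude is `irregularity`, so `irregularity = 0` gives an exact
#' discretized ellipse.  Neighbor structures are disjoint elliptical blobs
#' whose mean intensity is close to the target's (the gray-scale
#' confusability of adjacent organs); noise is additive Gaussian in HU.
#'
#' Defaults emulate a portal-venous abdominal slice: liver-like background
#' (60 HU), bile-like target (20 HU), neighbors 8 HU above the target, and
#' 15 HU noise.
#'
#' @param height,width Frame size in pixels (each at least 32).
#' @param background_hu Mean background intensity, HU.
#' @param target_mean_hu Mean intensity inside the target, HU.
#' @param neighbor_mean_hu Mean intensity of neighbor blobs, HU.
#' @param target_axes Length-2 vector, ellipse semi-axes (rows, cols) in
#'   pixels.
#' @param irregularity Amplitude in `[0, 1]` of the radial boundary
#'   perturbation.
#' @param noise_sd Gaussian noise standard deviation, HU (>= 0).
#' @param n_neighbors Number of neighbor blobs (>= 0).
#' @param seed Integer seed; identical specs yield byte-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64L, width = 64L, background_hu = 60,
                         target_mean_hu = 20, neighbor_mean_hu = 28,
                         target_axes = c(10, 6), irregularity = 0.3,
                         noise_sd = 15, n_neighbors = 3L, seed = 1L) {
  height <- as.integer(height)
  width <- as.integer(width)
  if (is.na(height) || height < 32L) stop_field("height", "must be >= 32")
  if (is.na(width) || width < 32L) stop_field("width", "must be >= 32")
  if (length(target_axes) != 2L || any(target_axes <= 0)) {
    stop_field("target_axes", "must be two positive semi-axes")
  }
  if (irregularity < 0 || irregularity > 1) {
    stop_field("irregularity", "must lie in [0, 1]")
  }
  if (noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (n_neighbors < 0) stop_field("n_neighbors", "must be >= 0")
  reach <- max(target_axes) * (1 + irregularity)
  if (2 * reach + 2 >= min(height, width)) {
    stop_field("target_axes",
               "target (with irregularity margin) does not fit in the frame")
  }
  structure(list(height = height, width = width,
                 background_hu = background_hu,
                 target_mean_hu = target_mean_hu,
                 neighbor_mean_hu = neighbor_mean_hu,
                 target_axes = as.numeric(target_axes),
                 irregularity = irregularity, noise_sd = noise_sd,
                 n_neighbors = as.integer(n_neighbors),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Inside test for the perturbed ellipse in normalized elliptical
# coordinates: a pixel is inside iff
#   (dr/ax)^2 + (dc/ay)^2 <= (1 + irr * sum_k a_k cos(k*phi + p_k))^2
# with the harmonic amplitudes normalized so the perturbation magnitude
# never exceeds `irr`.
perturbed_ellipse_inside <- function(rows, cols, geom) {
  dr <- (rows - geom$center[1L]) / geom$axes[1L]
  dc <- (cols - geom$center[2L]) / geom$axes[2L]
  phi <- atan2(dc, dr)
  pert <- 0
  if (geom$irregularity > 0) {
    for (k in seq_along(geom$amp)) {
      pert <- pert + geom$amp[k] * cos(k * phi + geom$phase[k])
    }
  }
  dr^2 + dc^2 <= (1 + pert)^2
}

#' Generate one phantom image/mask pair
#'
#' Deterministic under `spec$seed`: the same spec always yields
#' byte-identical output.  The returned object records the target geometry
#' (center, axes, harmonic amplitudes and phases) so the boundary function
#' can be re-evaluated independently of the stored mask.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_pair`: list with `image` (HU
#'   matrix), `mask` (binary matrix), `spec` and `geometry`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$height
    w <- spec$width
    reach <- max(spec$target_axes) * (1 + spec$irregularity) + 2
    center <- c(stats::runif(1, reach + 1, h - reach),
                stats::runif(1, reach + 1, w - reach))
    amp <- phase <- numeric(4L)
    if (spec$irregularity > 0) {
      raw <- stats::runif(4L, -1, 1)
      amp <- spec$irregularity * raw / sum(abs(raw))
      phase <- stats::runif(4L, 0, 2 * pi)
    }
    geom <- list(center = center, axes = spec$target_axes,
                 irregularity = spec$irregularity, amp = amp, phase = phase)

    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask <- perturbed_ellipse_inside(rows, cols, geom) * 1

    image <- matrix(spec$background_hu, h, w)
    image[mask == 1] <- spec$target_mean_hu

    # Disjoint neighbor blobs: smaller ellipses, gray level near the target.
    placed <- mask
    neighbors <- vector("list", spec$n_neighbors)
    n_placed <- 0L
    if (spec$n_neighbors > 0L) {
      for (k in seq_len(spec$n_neighbors)) {
        for (try in seq_len(100L)) {
          ax <- stats::runif(2L, 3, 6)
          m <- max(ax) + 2
          ctr <- c(stats::runif(1, m + 1, h - m), stats::runif(1, m + 1, w - m))
          ng <- list(center = ctr, axes = ax, irregularity = 0,
                     amp = numeric(4L), phase = numeric(4L))
          inside <- perturbed_ellipse_inside(rows, cols, ng)
          # enforce disjointness with a 1-pixel guard band
          grown <- perturbed_ellipse_inside(
            rows, cols, list(center = ctr, axes = ax + 1.5, irregularity = 0,
                             amp = numeric(4L), phase = numeric(4L)))
          if (!any(grown & placed == 1)) {
            image[inside] <- spec$neighbor_mean_hu
            placed[inside] <- 1
            n_placed <- n_placed + 1L
            neighbors[[n_placed]] <- ng
            break
          }
        }
      }
    }

    if (spec$noise_sd > 0) {
      image <- image + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }

    structure(list(image = image, mask = mask, spec = spec, geometry = geom,
                   neighbors = neighbors[seq_len(n_placed)]),
              class = "phantom_pair")
  })
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("phantom %dx%d | target area %d px | %d neighbor blob(s) | seed %d\n",
              x$spec$height, x$spec$width, sum(x$mask), length(x$neighbors),
              x$spec$seed))
  invisible(x)
}

# Split sizes for a ratio (train : val : test): validation and test sizes
# are rounded up to the nearest case, training receives the remainder --
# 152 cases at 7:1:7 gives (70, 11, 71).
split_sizes <- function(n, ratio = c(7, 1, 7)) {
  s <- sum(ratio)
  n_val <- ceiling(n * ratio[2L] / s)
  n_test <- ceiling(n * ratio[3L] / s)
  n_train <- n - n_val - n_test
  c(train = n_train, val = n_val, test = n_test)
}

#' Generate a seeded phantom dataset with train/val/test split
#'
#' Each case gets an independent sub-seed derived from `seed` plus optional
#' per-field jitter around `base_spec`.  Cases are split per-phantom (the
#' analogue of a per-patient split) at the given ratio; validation and test
#' sizes round up, training takes the remainder, so 152 cases at the
#' default 7:1:7 ratio give the canonical (70, 11, 71) partition.
#'
#' @param n Number of cases (>= 3, enough to populate all three splits).
#' @param base_spec A [phantom_spec()] used as the jitter center.
#' @param jitter Named list of additive uniform jitter half-ranges or
#'   ranges, e.g. `list(target_mean_hu = 5, target_axes = 2,
#'   irregularity = 0.1)`.  A scalar `r` means U(-r, r); a length-2 vector
#'   gives the range directly.  Jittered values are clamped to validity.
#' @param seed Master seed controlling sub-seeds, jitter and the split.
#' @param ratio Length-3 split ratio (train, val, test).
#' @return Object of class `phantom_dataset`: list with `pairs` (list of
#'   `phantom_pair`), `split` (factor with levels train/val/test) and
#'   `sizes`.
#' @export
generate_dataset <- function(n, base_spec = phantom_spec(), jitter = NULL,
                             seed = 1L, ratio = c(7, 1, 7)) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("`n` must be at least 3")
  if (length(ratio) != 3L || any(ratio <= 0)) {
    stop("`ratio` must be three positive numbers")
  }
  sizes <- split_sizes(n, ratio)
  if (any(sizes < 1L)) {
    stop("`n` too small to populate all three splits at this ratio")
  }
  jitter_fields <- c("background_hu", "target_mean_hu", "neighbor_mean_hu",
                     "target_axes", "irregularity", "noise_sd")
  if (!is.null(jitter) && !all(names(jitter) %in% jitter_fields)) {
    stop("unknown jitter field(s): ",
         paste(setdiff(names(jitter), jitter_fields), collapse = ", "))
  }
  with_seed(seed, {
    case_seeds <- sample.int(.Machine$integer.max - 1L, n)
    pairs <- vector("list", n)
    for (i in seq_len(n)) {
      args <- unclass(base_spec)
      for (f in names(jitter)) {
        r <- jitter[[f]]
        rng <- if (length(r) == 2L) sort(r) else c(-abs(r), abs(r))
        delta <- stats::runif(length(args[[f]]), rng[1L], rng[2L])
        args[[f]] <- args[[f]] + delta
      }
      args$target_axes <- pmax(args$target_axes, 2)
      args$irregularity <- min(max(args$irregularity, 0), 1)
      args$noise_sd <- max(args$noise_sd, 0)
      args$seed <- case_seeds[i]
      pairs[[i]] <- generate_phantom(do.call(phantom_spec, args))
    }
    idx <- sample.int(n)
    split <- character(n)
    split[idx[seq_len(sizes["train"])]] <- "train"
    split[idx[sizes["train"] + seq_len(sizes["val"])]] <- "val"
    split[idx[sizes["train"] + sizes["val"] + seq_len(sizes["test"])]] <- "test"
    structure(list(pairs = pairs,
                   split = factor(split, levels = c("train", "val", "test")),
                   sizes = sizes, seed = seed, ratio = ratio),
              class = "phantom_dataset")
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("phantom dataset: %d cases (train %d / val %d / test %d), seed %d\n",
              length(x$pairs), x$sizes["train"], x$sizes["val"],
              x$sizes["test"], x$seed))
  invisible(x)
}
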