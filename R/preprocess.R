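# CT intensity preprocessing and paired geometric augmentation.
# Pipeline: stored units -> HU (rescale slope/intercept) -> window/level to
# [0, 1] -> optional contrast-limited adaptive histogram equalization.
# Augmentation samples one affine transform (rotation, shift, shear, zoom)
# and applies it to image (bilinear) and mask (nearest-neighbor) alike.

#' CT display window
#'
#' @param center Window level in HU.  The default 50/400 window is a
#'   standard abdominal soft-tissue setting covering liver and gallbladder.
#' @param width Window width in HU (> 0).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(center = 50, width = 400) {
  if (!is.numeric(width) || width <= 0) stop_field("width", "must be > 0")
  structure(list(center = center, width = width), class = "window_spec")
}

#' Convert stored pixel values to Hounsfield units
#'
#' Elementwise affine rescale `hu = raw * slope + intercept` (the standard
#' CT rescale tags).
#'
#' @param raw Numeric array in stored units.
#' @param slope Rescale slope in HU per stored unit (non-zero).
#' @param intercept Rescale intercept in HU.
#' @return Array of HU values with the input's shape.
#' @export
hu_convert <- function(raw, slope = 1, intercept = -1024) {
  if (!is.numeric(slope) || slope == 0) stop_field("slope", "must be non-zero")
  raw * slope + intercept
}

#' Apply a window/level transform
#'
#' Maps `[center - width/2, center + width/2]` linearly onto `[0, 1]`,
#' clipping outside; monotone non-decreasing in HU.
#'
#' @param hu Numeric array of HU values.
#' @param w A [window_spec()].
#' @return Array in `[0, 1]`.
#' @export
apply_window <- function(hu, w = window_spec()) {
  stopifnot(inherits(w, "window_spec"))
  lo <- w$center - w$width / 2
  out <- (hu - lo) / w$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tiled histogram equalization with a clip limit and bilinear
#' interpolation between the per-tile mappings.  Deterministic for fixed
#' parameters; output stays in `[0, 1]`.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param tiles Length-2 integer vector, tile grid (rows, cols).
#' @param clip_limit Histogram clip limit as a fraction of the tile pixel
#'   count; excess mass is redistributed uniformly.
#' @param nbins Number of histogram bins.
#' @return Equalized matrix in `[0, 1]`.
#' @export
adaptive_hist_eq <- function(img, tiles = c(8L, 8L), clip_limit = 0.01,
                             nbins = 256L) {
  if (!all(is.finite(img))) stop("adaptive_hist_eq: non-finite pixels")
  if (min(img) < 0 || max(img) > 1) {
    stop("adaptive_hist_eq: input must lie in [0, 1]")
  }
  h <- nrow(img)
  w <- ncol(img)
  t1 <- as.integer(tiles[1L])
  t2 <- as.integer(tiles[2L])
  th <- ceiling(h / t1)
  tw <- ceiling(w / t2)
  # edge-replicate pad so tiles are full
  ri <- pmin(seq_len(t1 * th), h)
  ci <- pmin(seq_len(t2 * tw), w)
  pad <- img[ri, ci, drop = FALSE]

  bin <- function(v) pmin(floor(v * nbins) + 1L, nbins)
  npix <- th * tw
  clip <- max(clip_limit * npix, 1)
  maps <- array(0, c(nbins, t1, t2))
  for (i in seq_len(t1)) {
    for (j in seq_len(t2)) {
      tile <- pad[((i - 1L) * th + 1L):(i * th), ((j - 1L) * tw + 1L):(j * tw)]
      cnt <- tabulate(bin(tile), nbins)
      excess <- sum(pmax(cnt - clip, 0))
      cnt <- pmin(cnt, clip) + excess / nbins
      maps[, i, j] <- cumsum(cnt) / npix
    }
  }

  # bilinear interpolation between the four surrounding tile mappings
  b <- bin(img)
  u <- (row(img) - 0.5) / th + 0.5 # fractional tile index, 1-based centers
  v <- (col(img) - 0.5) / tw + 0.5
  i0 <- pmin(pmax(floor(u), 1L), t1)
  i1 <- pmin(i0 + 1L, t1)
  j0 <- pmin(pmax(floor(v), 1L), t2)
  j1 <- pmin(j0 + 1L, t2)
  fu <- pmin(pmax(u - floor(u), 0), 1)
  fu[u < 1] <- 0
  fu[u > t1] <- 1
  fv <- pmin(pmax(v - floor(v), 0), 1)
  fv[v < 1] <- 0
  fv[v > t2] <- 1
  look <- function(ii, jj) maps[b + (ii - 1L) * nbins + (jj - 1L) * nbins * t1]
  out <- (1 - fu) * (1 - fv) * look(i0, j0) +
    fu * (1 - fv) * look(i1, j0) +
    (1 - fu) * fv * look(i0, j1) +
    fu * fv * look(i1, j1)
  out <- matrix(pmin(pmax(out, 0), 1), h, w)
  out
}

#' Augmentation specification
#'
#' Ranges for the four geometric augmentations (rotation, shift, shear,
#' zoom).  All-zero ranges (and unit zoom) make [augment_pair()] the
#' identity.  Defaults are mild and mask-preserving.
#'
#' @param rotation_range Max absolute rotation, degrees.
#' @param shift_range Max absolute shift as a fraction of each dimension.
#' @param shear_range Max absolute shear, degrees.
#' @param zoom_range Length-2 vector `(min_factor, max_factor)`, both > 0.
#' @param seed Integer seed for transform sampling.
#' @return Object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation_range = 15, shift_range = 0.1,
                              shear_range = 5, zoom_range = c(0.9, 1.1),
                              seed = 1L) {
  if (rotation_range < 0) stop_field("rotation_range", "must be >= 0")
  if (shift_range < 0) stop_field("shift_range", "must be >= 0")
  if (shear_range < 0) stop_field("shear_range", "must be >= 0")
  if (length(zoom_range) != 2L || any(zoom_range <= 0)) {
    stop_field("zoom_range", "must be two positive factors")
  }
  structure(list(rotation_range = rotation_range, shift_range = shift_range,
                 shear_range = shear_range, zoom_range = as.numeric(zoom_range),
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Apply one explicit affine transform to an image/mask pair
#'
#' The forward map takes a point `p` (row, col) around the image center `c`
#' to `A (p - c) + c + t` with `A = R(angle) . Shear(shear) . zoom`.
#' Output pixels are backward-mapped through the inverse; the image is
#' bilinearly resampled (out-of-frame filled with `fill`, default the image
#' minimum), the mask with nearest-neighbor and zero fill so it stays
#' binary.
#'
#' @param img Numeric matrix.
#' @param mask Binary matrix of the same shape (optional).
#' @param angle Rotation in degrees (counterclockwise in (row, col) axes).
#' @param shift Length-2 translation in pixels (rows, cols).
#' @param shear Shear angle in degrees.
#' @param zoom Isotropic scale factor.
#' @param fill Image fill value for out-of-frame samples.
#' @return List with transformed `image` and `mask`.
#' @export
apply_affine <- function(img, mask = NULL, angle = 0, shift = c(0, 0),
                         shear = 0, zoom = 1, fill = NULL) {
  h <- nrow(img)
  w <- ncol(img)
  if (!is.null(mask) && !identical(dim(mask), dim(img))) {
    stop("image and mask shapes differ")
  }
  if (is.null(fill)) fill <- min(img)
  th <- angle * pi / 180
  sh <- tan(shear * pi / 180)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  shm <- matrix(c(1, 0, sh, 1), 2L)
  A <- rot %*% shm * zoom
  Ainv <- solve(A)
  ctr <- c((h + 1) / 2, (w + 1) / 2)

  rows <- as.vector(row(img))
  cols <- as.vector(col(img))
  dr <- rows - ctr[1L] - shift[1L]
  dc <- cols - ctr[2L] - shift[2L]
  sr <- Ainv[1L, 1L] * dr + Ainv[1L, 2L] * dc + ctr[1L]
  sc <- Ainv[2L, 1L] * dr + Ainv[2L, 2L] * dc + ctr[2L]

  bilinear <- function(m, f) {
    r0 <- floor(sr)
    c0 <- floor(sc)
    fr <- sr - r0
    fc <- sc - c0
    px <- function(ri, ci) {
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      v <- rep(f, length(ri))
      v[ok] <- m[cbind(ri[ok], ci[ok])]
      v
    }
    v <- (1 - fr) * (1 - fc) * px(r0, c0) + fr * (1 - fc) * px(r0 + 1, c0) +
      (1 - fr) * fc * px(r0, c0 + 1) + fr * fc * px(r0 + 1, c0 + 1)
    matrix(v, h, w)
  }
  nearest <- function(m, f) {
    ri <- round(sr)
    ci <- round(sc)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- rep(f, length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    matrix(v, h, w)
  }
  list(image = bilinear(img, fill),
       mask = if (is.null(mask)) NULL else nearest(mask, 0))
}

#' Randomly augment an image/mask pair
#'
#' Samples one transform from the spec's ranges (seeded) and applies the
#' identical geometric map to both image and mask; the mask is resampled
#' with nearest-neighbor so it stays binary.  All-zero ranges return the
#' pair unchanged.
#'
#' @param img Numeric matrix.
#' @param mask Binary matrix of the same shape.
#' @param a An [augmentation_spec()].
#' @param fill Image fill value (default: image minimum).
#' @param seed Seed override for the transform draw (defaults to `a$seed`);
#'   pass a varying value to draw fresh transforms across epochs.
#' @return List with `image`, `mask` and the sampled `transform`.
#' @export
augment_pair <- function(img, mask, a = augmentation_spec(), fill = NULL,
                         seed = NULL) {
  stopifnot(inherits(a, "augmentation_spec"))
  if (!identical(dim(mask), dim(img))) stop("image and mask shapes differ")
  identity_spec <- a$rotation_range == 0 && a$shift_range == 0 &&
    a$shear_range == 0 && all(a$zoom_range == 1)
  if (identity_spec) {
    return(list(image = img, mask = mask,
                transform = list(angle = 0, shift = c(0, 0), shear = 0,
                                 zoom = 1)))
  }
  if (is.null(seed)) seed <- a$seed
  tr <- with_seed(seed, list(
    angle = stats::runif(1, -a$rotation_range, a$rotation_range),
    shift = c(stats::runif(1, -a$shift_range, a$shift_range) * nrow(img),
              stats::runif(1, -a$shift_range, a$shift_range) * ncol(img)),
    shear = stats::runif(1, -a$shear_range, a$shear_range),
    zoom = stats::runif(1, a$zoom_range[1L], a$zoom_range[2L])
  ))
  out <- apply_affine(img, mask, angle = tr$angle, shift = tr$shift,
                      shear = tr$shear, zoom = tr$zoom, fill = fill)
  list(image = out$image, mask = out$mask, transform = tr)
}

#' Preprocess a phantom (or HU image) for model input
#'
#' Window/level to `[0, 1]` with optional CLAHE.
#'
#' @param hu HU-valued matrix.
#' @param w A [window_spec()].
#' @param clahe Apply [adaptive_hist_eq()] after windowing?
#' @return Matrix in `[0, 1]`.
#' @export
preprocess_slice <- function(hu, w = window_spec(), clahe = FALSE) {
  x <- apply_window(hu, w)
  if (clahe) x <- adaptive_hist_eq(x)
  x
}
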