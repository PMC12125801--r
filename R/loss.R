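# Soft Dice loss for training on heavily imbalanced small-target masks.

#' Dice loss specification
#'
#' @param epsilon Small positive stabilizer added to avoid division by
#'   zero.
#' @param symmetric_eps If `FALSE` (default), use the literal form
#'   `1 - 2*(I + eps) / (G + P + eps)`, which evaluates to -1 when both
#'   ground truth and prediction are empty.  If `TRUE`, use
#'   `1 - (2*I + eps) / (G + P + eps)`, which gives 0 for the empty-empty
#'   case.  See the methods vignette for why both are provided.
#' @param reduction `"mean"` (batch mean) or `"per_sample"`.
#' @return Object of class `dice_loss_spec`.
#' @export
dice_loss_spec <- function(epsilon = 1e-6, symmetric_eps = FALSE,
                           reduction = c("mean", "per_sample")) {
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop_field("epsilon", "must be > 0")
  }
  structure(list(epsilon = epsilon, symmetric_eps = isTRUE(symmetric_eps),
                 reduction = match.arg(reduction)),
            class = "dice_loss_spec")
}

#' Soft Dice loss
#'
#' `1 - 2*(|GT intersect Pred| + eps) / (|GT| + |Pred| + eps)` with the
#' soft intersection `sum(gt * pred)` and soft sizes `sum(gt)`,
#' `sum(pred)`; differentiable in `pred`.  Accepts single masks (matrices)
#' or batches in the (H, W, 1, N) layout.
#'
#' @param gt Binary ground-truth mask (values in {0, 1}).
#' @param pred Predicted probabilities in `[0, 1]`, same shape as `gt`.
#' @param spec A [dice_loss_spec()].
#' @return Scalar loss (or per-sample vector when
#'   `reduction = "per_sample"`).
#' @export
dice_loss <- function(gt, pred, spec = dice_loss_spec()) {
  stopifnot(inherits(spec, "dice_loss_spec"))
  if (!identical(dim(as_hwcn(gt)), dim(as_hwcn(pred)))) {
    stop("gt and pred shapes differ")
  }
  if (!is_binary_mask(gt)) stop("gt must be binary (values in {0, 1})")
  if (min(pred) < 0 || max(pred) > 1) stop("pred must lie in [0, 1]")
  ga <- as_hwcn(gt)
  pa <- as_hwcn(pred)
  n <- dim(ga)[4L]
  gm <- matrix(ga, ncol = n)
  pm <- matrix(pa, ncol = n)
  inter <- colSums(gm * pm)
  gsum <- colSums(gm)
  psum <- colSums(pm)
  eps <- spec$epsilon
  num <- if (spec$symmetric_eps) 2 * inter + eps else 2 * (inter + eps)
  losses <- 1 - num / (gsum + psum + eps)
  if (spec$reduction == "mean") mean(losses) else losses
}

#' Gradient of the Dice loss with respect to the prediction
#'
#' Analytic gradient of [dice_loss()] (mean reduction); finite everywhere
#' for `epsilon > 0`.
#'
#' @inheritParams dice_loss
#' @return Array with `pred`'s shape.
#' @export
dice_loss_grad <- function(gt, pred, spec = dice_loss_spec()) {
  ga <- as_hwcn(gt)
  pa <- as_hwcn(pred)
  n <- dim(ga)[4L]
  gm <- matrix(ga, ncol = n)
  pm <- matrix(pa, ncol = n)
  inter <- colSums(gm * pm)
  gsum <- colSums(gm)
  psum <- colSums(pm)
  eps <- spec$epsilon
  num <- if (spec$symmetric_eps) 2 * inter + eps else 2 * (inter + eps)
  den <- gsum + psum + eps
  dl <- -(sweep(2 * gm, 2L, den, `*`) -
            matrix(num, nrow(gm), n, byrow = TRUE)) /
    matrix(den^2, nrow(gm), n, byrow = TRUE)
  out <- dl / n
  dim(out) <- dim(pa)
  if (is.matrix(pred)) out <- out[, , 1L, 1L]
  out
}
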