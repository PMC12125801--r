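# Seven-metric segmentation evaluation: overlap family (DSC, JSC, PPV, SE)
# and boundary/volume family (HD, RVD, VOE), with per-case records and
# mean +/- SD aggregation.  Degenerate cases (empty masks) are flagged and
# excluded from aggregates rather than crashing.

check_mask_pair <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred))) stop("gt and pred shapes differ")
  if (!is_binary_mask(gt) || !is_binary_mask(pred)) {
    stop("masks must be binary (values in {0, 1})")
  }
}

#' Overlap metrics: DSC, JSC, PPV, SE
#'
#' With `TP = |gt & pred|`: `dsc = 2 TP / (|gt| + |pred|)`,
#' `jsc = TP / |gt | pred|`, `ppv = TP / |pred|`, `se = TP / |gt|`.
#' `se` is `NA` for an empty ground truth and `ppv` is `NA` for an empty
#' prediction (flagged, excluded from aggregates); when both masks are
#' empty, dsc and jsc are also `NA`.
#'
#' @param gt,pred Binary masks of identical shape.
#' @return Named numeric vector `(dsc, jsc, ppv, se)`.
#' @export
overlap_metrics <- function(gt, pred) {
  check_mask_pair(gt, pred)
  tp <- sum(gt * pred)
  g <- sum(gt)
  p <- sum(pred)
  u <- g + p - tp
  c(dsc = if (g + p > 0) 2 * tp / (g + p) else NA_real_,
    jsc = if (u > 0) tp / u else NA_real_,
    ppv = if (p > 0) tp / p else NA_real_,
    se = if (g > 0) tp / g else NA_real_)
}

# 8-connected boundary: foreground pixels with at least one background
# pixel (or the frame edge) among their 8 neighbors.
boundary_points <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- matrix(TRUE, h, w)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      inner <- inner & pad[(2:(h + 1L)) + di, (2:(w + 1L)) + dj] == 1
    }
  }
  which(mask == 1 & !inner, arr.ind = TRUE)
}

directed_dists <- function(a, b) {
  # for each point in a, Euclidean distance to the nearest point of b
  d2 <- outer(a[, 1L], b[, 1L], `-`)^2 + outer(a[, 2L], b[, 2L], `-`)^2
  sqrt(apply(d2, 1L, min))
}

#' Hausdorff distance between mask boundaries
#'
#' Symmetric Hausdorff distance between the 8-connected boundary point
#' sets of two masks under the Euclidean pixel metric.
#' `percentile < 100` gives the robust variant (the percentile of each
#' directed nearest-distance set replaces its maximum).  If either mask is
#' empty, the defined fallback -- the image diagonal
#' `sqrt((H-1)^2 + (W-1)^2)` -- is returned with attribute
#' `flagged = TRUE`.
#'
#' @param gt,pred Binary masks of identical shape.
#' @param percentile Percentile in (0, 100]; 100 is the classic maximum.
#' @return Distance in pixels (possibly with a `flagged` attribute).
#' @export
hausdorff_distance <- function(gt, pred, percentile = 100) {
  check_mask_pair(gt, pred)
  if (sum(gt) == 0 || sum(pred) == 0) {
    d <- sqrt((nrow(gt) - 1)^2 + (ncol(gt) - 1)^2)
    attr(d, "flagged") <- TRUE
    return(d)
  }
  a <- boundary_points(gt)
  b <- boundary_points(pred)
  dab <- directed_dists(a, b)
  dba <- directed_dists(b, a)
  if (percentile >= 100) {
    max(max(dab), max(dba))
  } else {
    max(stats::quantile(dab, percentile / 100, names = FALSE),
        stats::quantile(dba, percentile / 100, names = FALSE))
  }
}

#' Volume metrics: RVD and VOE
#'
#' `rvd = ||pred| - |gt|| / |gt|` (absolute relative volume difference)
#' and `voe = 1 - |gt & pred| / |gt | pred|` (volumetric overlap error,
#' i.e. one minus Jaccard).
#'
#' @param gt,pred Binary masks of identical shape; `gt` must be nonempty.
#' @return Named numeric vector `(rvd, voe)`.
#' @export
volume_metrics <- function(gt, pred) {
  check_mask_pair(gt, pred)
  g <- sum(gt)
  if (g == 0) stop("volume_metrics: empty ground-truth mask")
  p <- sum(pred)
  tp <- sum(gt * pred)
  u <- g + p - tp
  c(rvd = abs(p - g) / g, voe = 1 - tp / u)
}

#' All seven metrics for one case
#'
#' @param gt,pred Binary masks of identical shape.
#' @param case_id Identifier recorded in the result.
#' @param hd_percentile Percentile for [hausdorff_distance()].
#' @return One-row data frame with columns case_id, dsc, jsc, ppv, se, hd,
#'   rvd, voe and a logical `flagged` marking degenerate cases.
#' @export
case_metrics <- function(gt, pred, case_id = "case", hd_percentile = 100) {
  ov <- overlap_metrics(gt, pred)
  hd <- hausdorff_distance(gt, pred, hd_percentile)
  flagged <- isTRUE(attr(hd, "flagged")) || anyNA(ov)
  vol <- if (sum(gt) > 0) {
    volume_metrics(gt, pred)
  } else {
    c(rvd = NA_real_, voe = NA_real_)
  }
  data.frame(case_id = case_id, dsc = ov[["dsc"]], jsc = ov[["jsc"]],
             ppv = ov[["ppv"]], se = ov[["se"]], hd = as.numeric(hd),
             rvd = vol[["rvd"]], voe = vol[["voe"]], flagged = flagged,
             row.names = NULL)
}

#' Evaluate a set of mask pairs
#'
#' Computes the seven metrics per case plus mean and (sample) SD
#' aggregates.  `NA` metric values from degenerate cases are excluded from
#' the aggregates metric by metric; the flagged Hausdorff fallback for
#' empty masks is kept (so degenerate predictions score poorly).
#'
#' @param pairs List of `list(gt = , pred = )` binary mask pairs, or a list
#'   of `phantom_pair`-like objects with `mask` treated as ground truth
#'   plus a parallel list of predictions.
#' @param label Model/group name stored in the report.
#' @param hd_percentile Percentile for [hausdorff_distance()].
#' @return Object of class `metrics_report` with `per_case` (data frame)
#'   and `aggregate` (mean, sd, n per metric).
#' @export
evaluate_masks <- function(pairs, label = "model", hd_percentile = 100) {
  if (length(pairs) < 1L) stop("need at least one mask pair")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    id <- if (!is.null(p$case_id)) p$case_id else sprintf("case_%03d", i)
    case_metrics(p$gt, p$pred, id, hd_percentile)
  })
  per_case <- do.call(rbind, rows)
  metric_cols <- c("dsc", "jsc", "ppv", "se", "hd", "rvd", "voe")
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_case[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_case[[m]],
                                                   na.rm = TRUE),
                numeric(1)),
    n = vapply(metric_cols, function(m) sum(!is.na(per_case[[m]])),
               numeric(1)),
    row.names = NULL
  )
  structure(list(label = label, per_case = per_case, aggregate = aggregate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics report for '%s' (%d cases):\n", x$label,
              nrow(x$per_case)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-4s %6.4f +/- %6.4f (n=%d)\n", toupper(agg$metric[i]),
                agg$mean[i], agg$sd[i], agg$n[i]))
  }
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Per-case records as CSV and the aggregate as JSON.
#'
#' @param report A `metrics_report`.
#' @param csv,json Output paths (either may be NULL to skip).
#' @return The report, invisibly.
#' @export
write_metrics_report <- function(report, csv = NULL, json = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  if (!is.null(csv)) utils::write.csv(report$per_case, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(label = report$label,
                              aggregate = report$aggregate),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
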