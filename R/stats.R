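# Model-comparison statistics: one-way ANOVA across model groups with
# Fisher's least-significant-difference (LSD) pairwise t-tests computed
# from the pooled within-group mean square.

#' One-way ANOVA with Fisher LSD post-hoc comparisons
#'
#' Classical one-way analysis of variance
#' (`F = MS_between / MS_within`, p from the F distribution) over per-case
#' metric values from two or more model groups, followed by unadjusted
#' pairwise t-tests using the pooled within-group mean square (Fisher's
#' LSD).  The full pairwise table is always returned; in the standard
#' protected-LSD protocol a pair is declared significant only when the
#' omnibus test is itself significant, which is what the `significant`
#' column reports.
#'
#' `NA` values (cases whose metric was undefined) are dropped per group and
#' the exclusion counts reported.
#'
#' @param groups Named list of numeric vectors, each with at least two
#'   finite values after `NA` removal.
#' @param alpha Significance level of the omnibus gate (default 0.05).
#' @return Object of class `anova_lsd`: `f_stat`, `p_value`, `df_between`,
#'   `df_within`, `group_means` (data frame with mean, sd, n, t-based 95%
#'   CI), `lsd_pairs` (data frame with group_i, group_j, mean_diff --
#'   magnitude of the difference of means -- t, p_value, significant),
#'   `n_excluded`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  n_excluded <- vapply(groups, function(g) sum(!is.finite(g)), numeric(1))
  groups <- lapply(groups, function(g) g[is.finite(g)])
  ns <- vapply(groups, length, numeric(1))
  if (any(ns < 2L)) stop("every group needs at least 2 finite values")

  k <- length(groups)
  n_tot <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  gm <- sum(ns * means) / n_tot
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- as.integer(k - 1L)
  df_w <- as.integer(n_tot - k)

  if (ss_within == 0 && ss_between == 0) {
    f <- 0
    p <- 1
    msw <- 0
  } else {
    msw <- ss_within / df_w
    f <- (ss_between / df_b) / msw
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }

  sds <- vapply(groups, stats::sd, numeric(1))
  ci_half <- stats::qt(0.975, ns - 1L) * sds / sqrt(ns)
  group_means <- data.frame(group = names(groups), mean = means, sd = sds,
                            n = ns, ci_lo = means - ci_half,
                            ci_hi = means + ci_half, row.names = NULL)

  pairs <- utils::combn(seq_len(k), 2L)
  lsd <- data.frame(
    group_i = names(groups)[pairs[1L, ]],
    group_j = names(groups)[pairs[2L, ]],
    mean_diff = abs(means[pairs[1L, ]] - means[pairs[2L, ]]),
    t = NA_real_, p_value = NA_real_, significant = FALSE,
    row.names = NULL
  )
  if (msw > 0) {
    se <- sqrt(msw * (1 / ns[pairs[1L, ]] + 1 / ns[pairs[2L, ]]))
    lsd$t <- (means[pairs[1L, ]] - means[pairs[2L, ]]) / se
    lsd$p_value <- 2 * stats::pt(-abs(lsd$t), df_w)
    lsd$significant <- p < alpha & lsd$p_value < alpha
  }

  structure(list(f_stat = f, p_value = p, df_between = df_b,
                 df_within = df_w, ms_within = msw,
                 group_means = group_means, lsd_pairs = lsd, alpha = alpha,
                 n_excluded = n_excluded),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g%s\n",
              x$df_between, x$df_within, x$f_stat, x$p_value,
              if (x$p_value < x$alpha) " *" else ""))
  for (i in seq_len(nrow(x$group_means))) {
    g <- x$group_means[i, ]
    cat(sprintf("  %-12s %8.4f +/- %.4f (n=%d)\n", g$group, g$mean, g$sd,
                g$n))
  }
  if (any(x$lsd_pairs$significant)) {
    cat("LSD significant pairs:\n")
    sig <- x$lsd_pairs[x$lsd_pairs$significant, ]
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s vs %s: |diff| = %.4f, p = %.4g\n", sig$group_i[i],
                  sig$group_j[i], sig$mean_diff[i], sig$p_value[i]))
    }
  }
  invisible(x)
}

#' Compare metrics reports across models
#'
#' Runs [one_way_anova()] per metric over the per-case values of two or
#' more [evaluate_masks()] reports, mirroring a mean +/- SD comparison
#' table with one F and p per metric.
#'
#' @param reports List of `metrics_report` objects (names taken from their
#'   labels unless the list is named).
#' @param metrics Metric columns to compare.
#' @param alpha Omnibus significance level.
#' @return Object of class `model_comparison`: list with `table` (one row
#'   per metric: F, p, df) and `anova` (the per-metric `anova_lsd`
#'   objects).
#' @export
compare_reports <- function(reports,
                            metrics = c("dsc", "jsc", "ppv", "se", "hd",
                                        "rvd", "voe"),
                            alpha = 0.05) {
  if (length(reports) < 2L) stop("need at least 2 reports")
  labels <- names(reports)
  if (is.null(labels)) {
    labels <- vapply(reports, function(r) r$label, character(1))
  }
  anovas <- list()
  rows <- list()
  for (m in metrics) {
    groups <- lapply(reports, function(r) r$per_case[[m]])
    names(groups) <- labels
    a <- one_way_anova(groups, alpha)
    anovas[[m]] <- a
    rows[[m]] <- data.frame(metric = m, f_stat = a$f_stat,
                            p_value = a$p_value, df_between = a$df_between,
                            df_within = a$df_within,
                            significant = a$p_value < alpha,
                            row.names = NULL)
  }
  structure(list(table = do.call(rbind, rows), anova = anovas,
                 labels = labels),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (one F and p per metric):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
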