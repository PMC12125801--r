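test_that("overlap metric identities on canonical cases", {
  gt <- matrix(0, 8, 8)
  gt[3:4, 3:4] <- 1 # 4-pixel square
  expect_equal(unname(overlap_metrics(gt, gt)), c(1, 1, 1, 1))
  pred <- matrix(0, 8, 8)
  pred[3, 3:4] <- 1 # 2 of the 4 pixels
  ov <- overlap_metrics(gt, pred)
  expect_equal(ov[["dsc"]], 2 * 2 / (4 + 2))
  expect_equal(ov[["jsc"]], 0.5)
  expect_equal(ov[["ppv"]], 1)
  expect_equal(ov[["se"]], 0.5)
  disj <- matrix(0, 8, 8)
  disj[7:8, 7:8] <- 1
  expect_equal(unname(overlap_metrics(gt, disj)), c(0, 0, 0, 0))
})

test_that("hausdorff distance on hand-computable geometries", {
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[4, 5] <- 1 # displacement (3, 4) -> 5
  expect_equal(hausdorff_distance(a, b), 5)
  expect_equal(hausdorff_distance(a, a), 0)
  sq1 <- matrix(0, 10, 10); sq1[3:6, 3:6] <- 1
  sq2 <- matrix(0, 10, 10); sq2[3:6, 4:7] <- 1 # shift 1 px horizontally
  expect_equal(hausdorff_distance(sq1, sq2), 1)
  # empty-mask fallback: diagonal, flagged
  e <- matrix(0, 10, 10)
  d <- hausdorff_distance(sq1, e)
  expect_equal(as.numeric(d), sqrt(81 + 81))
  expect_true(attr(d, "flagged"))
})

test_that("volume metrics on counted fixtures", {
  gt <- matrix(0, 20, 20); gt[1:10, 1:10] <- 1 # 100 px
  pred <- gt; pred[11:12, 1:10] <- 1           # 120 px, superset
  vm <- volume_metrics(gt, pred)
  expect_equal(vm[["rvd"]], 0.2)
  expect_equal(vm[["voe"]], 1 - 100 / 120)
  expect_equal(unname(volume_metrics(gt, gt)), c(0, 0))
  disj <- matrix(0, 20, 20); disj[15, 15] <- 1
  expect_equal(volume_metrics(gt, disj)[["voe"]], 1)
  expect_error(volume_metrics(matrix(0, 5, 5), disj[1:5, 1:5]), "empty")
})

test_that("all seven metrics match brute-force oracles on random pairs", {
  # reduced draw here; the full 200-pair sweep is in test-acceptance.R
  set.seed(99)
  for (i in 1:25) {
    gt <- random_mask(16, 16, runif(1, 0.15, 0.5))
    pred <- random_mask(16, 16, runif(1, 0.15, 0.5))
    if (sum(gt) == 0 || sum(pred) == 0) next
    expect_equal(overlap_metrics(gt, pred), oracle_overlap(gt, pred),
                 tolerance = 1e-12)
    expect_equal(volume_metrics(gt, pred), oracle_volume(gt, pred),
                 tolerance = 1e-12)
    expect_equal(hausdorff_distance(gt, pred), oracle_hausdorff(gt, pred),
                 tolerance = 1e-12)
  }
})

test_that("symmetry and coupled identities hold", {
  set.seed(17)
  for (i in 1:10) {
    gt <- random_mask(12, 12, 0.3)
    pred <- random_mask(12, 12, 0.3)
    if (sum(gt) == 0 || sum(pred) == 0) next
    a <- overlap_metrics(gt, pred)
    b <- overlap_metrics(pred, gt)
    expect_equal(a[["dsc"]], b[["dsc"]])
    expect_equal(a[["jsc"]], b[["jsc"]])
    expect_equal(a[["ppv"]], b[["se"]])
    expect_equal(hausdorff_distance(gt, pred), hausdorff_distance(pred, gt))
    vm <- volume_metrics(gt, pred)
    expect_equal(vm[["voe"]], 1 - a[["jsc"]], tolerance = 1e-12)
    expect_equal(a[["dsc"]], 2 * a[["jsc"]] / (1 + a[["jsc"]]),
                 tolerance = 1e-12)
  }
})

test_that("degenerate masks are flagged, not fatal", {
  gt <- matrix(0, 8, 8); gt[2:3, 2:3] <- 1
  empty <- matrix(0, 8, 8)
  ov <- overlap_metrics(gt, empty)
  expect_true(is.na(ov[["ppv"]]))
  expect_equal(ov[["se"]], 0)
  ov2 <- overlap_metrics(empty, gt)
  expect_true(is.na(ov2[["se"]]))
  cm <- case_metrics(gt, empty)
  expect_true(cm$flagged)
})

test_that("report aggregation matches hand computation and is self-consistent", {
  gt <- matrix(0, 12, 12); gt[3:6, 3:6] <- 1 # 16 px
  r <- evaluate_masks(list(list(gt = gt, pred = gt),
                           list(gt = gt, pred = gt)), label = "ident")
  agg <- r$aggregate
  expect_equal(agg$mean[agg$metric %in% c("dsc", "jsc", "ppv", "se")],
               rep(1, 4))
  expect_equal(agg$mean[agg$metric %in% c("hd", "rvd", "voe")], rep(0, 3))
  expect_equal(agg$sd, rep(0, 7))
  # cases engineered to dsc 0.6 (tp=12, |p|=24) and 0.8 (tp=16, |p|=24):
  # aggregate must be mean 0.7, sample SD 0.14142
  p1 <- matrix(0, 12, 12); p1[3:5, 3:6] <- 1; p1[9:12, 9:11] <- 1
  p2 <- gt; p2[9:12, 9:10] <- 1
  expect_equal(overlap_metrics(gt, p1)[["dsc"]], 0.6, tolerance = 1e-12)
  expect_equal(overlap_metrics(gt, p2)[["dsc"]], 0.8, tolerance = 1e-12)
  r68 <- evaluate_masks(list(list(gt = gt, pred = p1),
                             list(gt = gt, pred = p2)), label = "dsc68")
  expect_equal(r68$aggregate$mean[r68$aggregate$metric == "dsc"], 0.7)
  expect_equal(r68$aggregate$sd[r68$aggregate$metric == "dsc"],
               sqrt(0.02), tolerance = 1e-9)
  # aggregate is recomputable from per_case
  r2 <- evaluate_masks(list(list(gt = gt, pred = p1),
                            list(gt = gt, pred = gt)), label = "x")
  for (m in c("dsc", "hd", "voe")) {
    expect_equal(r2$aggregate$mean[r2$aggregate$metric == m],
                 mean(r2$per_case[[m]]))
  }
  expect_error(evaluate_masks(list()), "at least one")
})

test_that("robust percentile variant never exceeds the classic maximum", {
  set.seed(3)
  for (i in 1:5) {
    gt <- random_mask(20, 20, 0.3)
    pred <- random_mask(20, 20, 0.3)
    if (sum(gt) == 0 || sum(pred) == 0) next
    expect_lte(hausdorff_distance(gt, pred, percentile = 95),
               hausdorff_distance(gt, pred))
  }
})

test_that("reports round-trip through CSV/JSON writers", {
  gt <- matrix(0, 8, 8); gt[2:5, 2:5] <- 1
  r <- evaluate_masks(list(list(gt = gt, pred = gt)), label = "io")
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_metrics_report(r, csv = csv, json = js)
  back <- read.csv(csv)
  expect_equal(back$dsc, r$per_case$dsc)
  agg <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(agg$label, "io")
})
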