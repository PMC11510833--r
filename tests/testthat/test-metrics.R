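# Evaluation metrics: matching rules, precision/recall, AP interpolation
# and the mAP threshold range, checked against brute-force oracles.

mk_det <- function(image_id, class_id, conf, x1, y1, x2, y2) {
  data.frame(image_id = image_id, class_id = class_id, confidence = conf,
             x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}
mk_gt <- function(image_id, class_id, x1, y1, x2, y2) {
  data.frame(image_id = image_id, class_id = class_id,
             x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

test_that("precision and recall follow their defining ratios", {
  expect_equal(precision(8, 2), 0.8)
  expect_equal(recall(3, 1), 0.75)
  expect_warning(p0 <- precision(0, 0), "undefined")
  expect_equal(p0, 0)
  expect_warning(r0 <- recall(0, 0), "undefined")
  expect_equal(r0, 0)
})

test_that("matching applies the threshold, greedy consumption and class separation", {
  gt <- mk_gt(1, 0, 0, 0, 10, 10)
  # IoU 0.6 vs threshold 0.5 -> TP
  m <- match_detections(mk_det(1, 0, 0.9, 0, 0, 10, 6), gt, 0.5)
  expect_true(m$tp)
  # IoU 0.4 -> FP
  m <- match_detections(mk_det(1, 0, 0.9, 0, 0, 10, 4), gt, 0.5)
  expect_false(m$tp)
  # two detections on one gt: the higher-confidence one consumes it
  d2 <- rbind(mk_det(1, 0, 0.6, 0, 0, 10, 9), mk_det(1, 0, 0.8, 0, 0, 10, 8))
  m <- match_detections(d2, gt, 0.5)
  expect_equal(m$confidence, c(0.8, 0.6))
  expect_equal(m$tp, c(TRUE, FALSE))
  # a detection cannot match a gt of another class
  m <- match_detections(mk_det(1, 1, 0.9, 0, 0, 10, 10), gt, 0.5)
  expect_false(m$tp)
})

test_that("AP of a perfect detector is 1 and of pure false positives is 0", {
  expect_equal(average_precision(pr_curve(c(TRUE, TRUE), 2)), 1)
  expect_equal(average_precision(pr_curve(c(FALSE, FALSE, FALSE), 2)), 0)
  expect_error(average_precision(pr_curve(logical(0), 0)), "no ground truths")
})

test_that("AP envelope handles the TP/FP/TP pattern exactly", {
  # 2 gts, flags ordered by confidence: precision envelope gives
  # 0.5 * 1 + 0.5 * (2/3)
  expect_equal(average_precision(pr_curve(c(TRUE, FALSE, TRUE), 2)), 5 / 6)
})

test_that("AP equals a brute-force threshold-sweep oracle", {
  # oracle: precision/recall at every distinct confidence cut, trapezoid-free
  # max-precision-at-recall integration over the exact recall support
  ap_sweep <- function(conf, tp, n_gt) {
    ord <- order(-conf)
    tp <- tp[ord]; conf <- conf[ord]
    cuts <- unique(conf)
    pr <- t(vapply(cuts, function(ct) {
      sel <- conf >= ct
      c(sum(tp[sel]) / max(sum(sel), 1), sum(tp[sel]) / n_gt)
    }, numeric(2)))
    rec <- c(0, pr[, 2]); prec <- c(1, pr[, 1])
    area <- 0
    for (i in seq_along(cuts)) {
      dr <- rec[i + 1] - rec[i]
      if (dr > 0) area <- area + dr * max(prec[(i + 1):length(prec)])
    }
    area
  }
  set.seed(10)
  for (trial in 1:25) {
    n <- sample(3:30, 1)
    conf <- sample(seq(0.001, 0.999, length.out = 999), n)   # distinct scores
    tp <- runif(n) < 0.5
    n_gt <- sum(tp) + sample(0:3, 1)
    if (n_gt == 0) next
    ord <- order(-conf)
    got <- average_precision(pr_curve(tp[ord], n_gt))
    expect_equal(got, ap_sweep(conf, tp, n_gt), tolerance = 1e-10)
  }
})

test_that("AP is invariant to uniform confidence rescaling", {
  set.seed(11)
  gt <- do.call(rbind, lapply(1:3, function(i) mk_gt(i, 0, c(0, 20), 0, c(10, 30), 10)))
  d <- do.call(rbind, lapply(1:3, function(i) {
    mk_det(i, 0, runif(2), c(1, 21), 0, c(11, 31), 10)
  }))
  a1 <- evaluate_detections(d, gt, 0.5)$map
  d$confidence <- d$confidence * 0.37
  expect_equal(evaluate_detections(d, gt, 0.5)$map, a1)
})

test_that("mean AP and the 10-threshold range behave as defined", {
  expect_equal(mean_ap(c(0.5, 1.0)), 0.75)
  expect_error(mean_ap(numeric(0)), "empty")
  # detections identical to ground truths: perfect at every threshold
  gt <- rbind(mk_gt(1, 0, 0, 0, 10, 10), mk_gt(1, 1, 20, 0, 30, 10))
  d <- rbind(mk_det(1, 0, 0.9, 0, 0, 10, 10), mk_det(1, 1, 0.8, 20, 0, 30, 10))
  mr <- map_range(d, gt)
  expect_equal(mr$map50, 1)
  expect_equal(mr$map50_95, 1)
  expect_length(mr$by_threshold, 10L)
  expect_equal(names(mr$by_threshold)[c(1, 10)], c("0.50", "0.95"))
})

test_that("tighter thresholds never raise mAP", {
  set.seed(12)
  gt <- do.call(rbind, lapply(1:4, function(i) {
    k <- sample(1:3, 1)
    x <- runif(k, 0, 40)
    mk_gt(i, sample(0:1, k, TRUE), x, 0, x + runif(k, 5, 15), 10)
  }))
  d <- do.call(rbind, lapply(seq_len(nrow(gt)), function(j) {
    mk_det(gt$image_id[j], gt$class_id[j], runif(1),
           gt$x1[j] + rnorm(1, 0, 2), gt$y1[j], gt$x2[j] + rnorm(1, 0, 2), gt$y2[j])
  }))
  d$x2 <- pmax(d$x2, d$x1 + 1)
  mr <- map_range(d, gt)
  expect_lte(mr$map50_95, mr$map50 + 1e-12)
})

test_that("package mAP agrees with an independent 101-point evaluator on a random fixture", {
  # independent reference evaluator: per-class greedy matching plus 101-point
  # interpolated AP, written from scratch with plain loops
  ref_eval <- function(dets, gts, thr) {
    aps <- c()
    for (cid in sort(unique(gts$class_id))) {
      dc <- dets[dets$class_id == cid, , drop = FALSE]
      dc <- dc[order(-dc$confidence), , drop = FALSE]
      gc <- gts[gts$class_id == cid, , drop = FALSE]
      used <- logical(nrow(gc))
      tp <- logical(nrow(dc))
      for (i in seq_len(nrow(dc))) {
        best <- 0; bj <- 0
        for (j in seq_len(nrow(gc))) {
          if (used[j] || gc$image_id[j] != dc$image_id[i]) next
          xx1 <- max(dc$x1[i], gc$x1[j]); yy1 <- max(dc$y1[i], gc$y1[j])
          xx2 <- min(dc$x2[i], gc$x2[j]); yy2 <- min(dc$y2[i], gc$y2[j])
          inter <- max(xx2 - xx1, 0) * max(yy2 - yy1, 0)
          un <- (dc$x2[i] - dc$x1[i]) * (dc$y2[i] - dc$y1[i]) +
            (gc$x2[j] - gc$x1[j]) * (gc$y2[j] - gc$y1[j]) - inter
          v <- inter / un
          if (v > best) { best <- v; bj <- j }
        }
        if (best >= thr && bj > 0) { tp[i] <- TRUE; used[bj] <- TRUE }
      }
      ctp <- cumsum(tp); cfp <- cumsum(!tp)
      rec <- ctp / nrow(gc); prec <- ctp / pmax(ctp + cfp, 1)
      ap <- 0
      for (r in seq(0, 1, 0.01)) {
        pmaxr <- if (any(rec >= r)) max(prec[rec >= r]) else 0
        ap <- ap + pmaxr / 101
      }
      aps <- c(aps, ap)
    }
    mean(aps)
  }
  set.seed(13)
  gt <- do.call(rbind, lapply(1:6, function(i) {
    k <- sample(2:4, 1)
    x <- runif(k, 0, 50); y <- runif(k, 0, 50)
    mk_gt(i, sample(0:2, k, TRUE), x, y, x + runif(k, 6, 14), y + runif(k, 6, 14))
  }))
  d <- do.call(rbind, lapply(seq_len(nrow(gt)), function(j) {
    reps <- sample(1:2, 1)
    do.call(rbind, lapply(seq_len(reps), function(r) {
      mk_det(gt$image_id[j], gt$class_id[j], runif(1),
             gt$x1[j] + rnorm(1, 0, 3), gt$y1[j] + rnorm(1, 0, 3),
             gt$x2[j] + rnorm(1, 0, 3), gt$y2[j] + rnorm(1, 0, 3))
    }))
  }))
  d$x2 <- pmax(d$x2, d$x1 + 1); d$y2 <- pmax(d$y2, d$y1 + 1)
  got <- evaluate_detections(d, gt, 0.5, method = "c101")$map
  want <- ref_eval(d, gt, 0.5)
  expect_lt(abs(got - want), 0.01)
})

test_that("detection records survive a JSON-lines round trip", {
  dir <- withr::local_tempdir()
  d <- mk_det(c(1, 2), c(0, 3), c(0.5, 0.25), 0, 0, c(10, 5), c(10, 5))
  p <- file.path(dir, "dets.jsonl")
  write_detections_jsonl(d, p)
  d2 <- read_detections_jsonl(p)
  expect_equal(d2$confidence, d$confidence)
  expect_equal(d2$x2, d$x2)
  expect_equal(nrow(read_detections_jsonl(write_detections_jsonl(d[0, ], p))), 0L)
})

test_that("classes without ground truths are excluded from the mean with a warning", {
  gt <- mk_gt(1, 0, 0, 0, 10, 10)
  d <- rbind(mk_det(1, 0, 0.9, 0, 0, 10, 10), mk_det(1, 5, 0.9, 0, 0, 10, 10))
  expect_warning(ev <- evaluate_detections(d, gt, 0.5), "without ground truths")
  expect_equal(ev$per_class$class_id, 0)
  expect_equal(ev$map, 1)
})
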