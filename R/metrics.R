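# Detection evaluation: precision, recall, average precision, mAP.
#
# Detections and ground truths are data frames sharing `image_id`,
# `class_id` (0-based) and corner columns x1, y1, x2, y2 (pixels);
# detections additionally carry `confidence` in [0, 1].

#' Precision and recall from counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`.  The undefined
#' zero-denominator case returns 0 with a warning, which keeps
#' precision-recall curves well defined at their ends.
#'
#' @param tp,fp,fn non-negative counts.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' precision(8, 2)  # 0.8
#' recall(3, 1)     # 0.75
precision <- function(tp, fp) {
  stopifnot(tp >= 0, fp >= 0)
  if (tp + fp == 0) {
    warning("precision undefined for TP + FP = 0; returning 0")
    return(0)
  }
  tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(tp, fn) {
  stopifnot(tp >= 0, fn >= 0)
  if (tp + fn == 0) {
    warning("recall undefined for TP + FN = 0; returning 0")
    return(0)
  }
  tp / (tp + fn)
}

#' Greedily match detections to ground truths
#'
#' Detections are processed in decreasing confidence (ties keep input
#' order).  A detection is a true positive iff the best-IoU not-yet-matched
#' ground truth of the same class in the same image reaches `iou_thr`; it
#' then consumes that ground truth.  Everything else is a false positive.
#'
#' @param dets detections data frame.
#' @param gts ground-truth data frame.
#' @param iou_thr matching threshold.
#' @return `dets` reordered by decreasing confidence with a logical `tp`
#'   column added.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  need <- c("image_id", "class_id", "confidence", "x1", "y1", "x2", "y2")
  stopifnot(all(need %in% names(dets)))
  ord <- order(-dets$confidence)
  dets <- dets[ord, , drop = FALSE]
  dets$tp <- logical(nrow(dets))
  if (nrow(gts)) {
    taken <- logical(nrow(gts))
    gkey <- paste(gts$image_id, gts$class_id)
    dkey <- paste(dets$image_id, dets$class_id)
    for (i in seq_len(nrow(dets))) {
      cand <- which(gkey == dkey[i] & !taken)
      if (!length(cand)) next
      ious <- suppressWarnings(box_iou(
        as.matrix(dets[i, c("x1", "y1", "x2", "y2")]),
        as.matrix(gts[cand, c("x1", "y1", "x2", "y2")])))
      j <- which.max(ious)
      if (ious[j] >= iou_thr) {
        dets$tp[i] <- TRUE
        taken[cand[j]] <- TRUE
      }
    }
  }
  dets
}

#' Precision-recall curve from ordered match flags
#'
#' @param tp logical flags in decreasing-confidence order.
#' @param n_gt number of ground truths of the class.
#' @return list of cumulative `precision`, `recall` vectors plus counts.
#' @export
pr_curve <- function(tp, n_gt) {
  stopifnot(n_gt >= 0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  list(precision = if (length(tp)) ctp / (ctp + cfp) else numeric(0),
       recall = if (length(tp) && n_gt > 0) ctp / n_gt else rep(0, length(tp)),
       tp = ctp, fp = cfp, n_gt = n_gt)
}

#' Average precision (area under the precision-recall curve)
#'
#' Default is all-point interpolation: the precision envelope is made
#' non-increasing and integrated over the exact recall increments.
#' `method = "c101"` instead averages the interpolated precision at 101
#' evenly spaced recall points (the COCO convention).
#'
#' @param curve a [pr_curve()].
#' @param method `"continuous"` or `"c101"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(curve, method = c("continuous", "c101")) {
  method <- match.arg(method)
  if (curve$n_gt == 0) stop("AP undefined for a class with no ground truths")
  if (!length(curve$recall)) return(0)
  r <- c(0, curve$recall, curve$recall[length(curve$recall)])
  p <- c(1, curve$precision, 0)
  # non-increasing precision envelope (from the right)
  p <- rev(cummax(rev(p)))
  if (method == "continuous") {
    sum(diff(r) * p[-1])
  } else {
    grid <- seq(0, 1, length.out = 101)
    mean(vapply(grid, function(g) {
      ok <- r >= g
      if (any(ok)) max(p[ok]) else 0
    }, numeric(1)))
  }
}

#' Mean average precision over classes
#'
#' @param aps numeric vector of per-class APs.
#' @return their arithmetic mean.
#' @export
mean_ap <- function(aps) {
  if (!length(aps)) stop("mean AP over an empty class list")
  mean(aps)
}

#' Evaluate detections at one IoU threshold
#'
#' @param dets,gts data frames (see [match_detections()]).
#' @param iou_thr matching threshold.
#' @param method AP interpolation, see [average_precision()].
#' @return list: `per_class` data frame (class_id, n_gt, n_det, ap) and
#'   `map`.  Classes present in detections but without ground truths are
#'   excluded from the mean with a warning.
#' @export
evaluate_detections <- function(dets, gts, iou_thr = 0.5,
                                method = c("continuous", "c101")) {
  method <- match.arg(method)
  classes <- sort(unique(gts$class_id))
  if (!length(classes)) stop("no ground-truth classes to evaluate")
  ghost <- setdiff(unique(dets$class_id), classes)
  if (length(ghost)) {
    warning("detections for classes without ground truths ignored: ",
            paste(ghost, collapse = ", "))
  }
  m <- match_detections(dets, gts, iou_thr)
  rows <- lapply(classes, function(cid) {
    dc <- m[m$class_id == cid, , drop = FALSE]
    n_gt <- sum(gts$class_id == cid)
    ap <- average_precision(pr_curve(dc$tp, n_gt), method)
    data.frame(class_id = cid, n_gt = n_gt, n_det = nrow(dc), ap = ap)
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class, map = mean_ap(per_class$ap))
}

#' mAP at 0.5 and averaged over 0.50:0.05:0.95
#'
#' @param dets,gts data frames (see [match_detections()]).
#' @param method AP interpolation.
#' @return list `map50`, `map50_95`, `by_threshold` (named vector over the
#'   ten thresholds).
#' @export
map_range <- function(dets, gts, method = c("continuous", "c101")) {
  method <- match.arg(method)
  thrs <- seq(0.5, 0.95, by = 0.05)
  stopifnot(length(thrs) == 10L)
  maps <- vapply(thrs, function(t) evaluate_detections(dets, gts, t, method)$map,
                 numeric(1))
  names(maps) <- sprintf("%.2f", thrs)
  list(map50 = maps[["0.50"]], map50_95 = mean(maps), by_threshold = maps)
}

# ---- detection record I/O --------------------------------------------------

#' Read / write detection records as JSON lines
#'
#' One JSON object per line with fields image_id, class_id, confidence,
#' x1, y1, x2, y2.
#'
#' @param dets detections data frame.
#' @param path file path.
#' @return `read_detections_jsonl`: the data frame.
#' @export
write_detections_jsonl <- function(dets, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(dets))) {
    writeLines(jsonlite::toJSON(as.list(dets[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_detections_jsonl
#' @export
read_detections_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(image_id = integer(0), class_id = integer(0),
                      confidence = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0)))
  }
  do.call(rbind, lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l))
  }))
}
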