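# Prediction decoding and non-maximum suppression.
#
# The anchor-free head predicts, per grid cell, a discrete distribution over
# reg_max bins for each of the four box sides (distances from the cell
# center in stride units) plus independent per-class logits.  Decoding takes
# the distribution expectation; a detection's confidence is its best class
# probability.

# anchor centers (pixels) and per-anchor strides for a prediction list,
# ordered exactly like the flattened (C, h, w) -> (h*w, C) matrices
anchor_grid <- function(preds) {
  ax <- c(); ay <- c(); st <- c()
  for (p in preds) {
    hi <- rep(seq_len(p$h), times = p$w)
    wi <- rep(seq_len(p$w), each = p$h)
    ax <- c(ax, (wi - 0.5) * p$stride)
    ay <- c(ay, (hi - 0.5) * p$stride)
    st <- c(st, rep(p$stride, p$h * p$w))
  }
  list(x = ax, y = ay, stride = st)
}

# numeric flatten of one image's raw predictions: (A, 4*reg_max) and (A, nc)
flatten_preds <- function(preds, n) {
  box <- do.call(rbind, lapply(preds, function(p) {
    v <- ag_v(p$box)[, , , n, drop = FALSE]
    dim(v) <- c(dim(v)[1], p$h * p$w)
    t(v)
  }))
  cls <- do.call(rbind, lapply(preds, function(p) {
    v <- ag_v(p$cls)[, , , n, drop = FALSE]
    dim(v) <- c(dim(v)[1], p$h * p$w)
    t(v)
  }))
  list(box = box, cls = cls)
}

softmax_rows_num <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e / rowSums(e)
}

# decode (A, 4*reg_max) distribution logits into corner boxes (pixels)
decode_boxes_num <- function(box_logits, anch, reg_max) {
  A <- nrow(box_logits)
  b3 <- box_logits
  dim(b3) <- c(A, reg_max, 4L)
  b3 <- aperm(b3, c(1, 3, 2))
  dim(b3) <- c(A * 4L, reg_max)
  ex <- as.numeric(softmax_rows_num(b3) %*% (seq_len(reg_max) - 1))
  dim(ex) <- c(A, 4L)
  cbind(anch$x - ex[, 1] * anch$stride,
        anch$y - ex[, 2] * anch$stride,
        anch$x + ex[, 3] * anch$stride,
        anch$y + ex[, 4] * anch$stride)
}

#' Greedy non-maximum suppression
#'
#' @param boxes n x 4 corner matrix.
#' @param scores length-n confidences.
#' @param iou_thr suppression IoU threshold.
#' @return indices of the kept boxes, in decreasing score order.
#' @export
nms <- function(boxes, scores, iou_thr = 0.45) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord)) {
      ious <- suppressWarnings(box_iou(boxes[rep(i, length(ord)), , drop = FALSE],
                                       boxes[ord, , drop = FALSE]))
      ord <- ord[ious <= iou_thr]
    }
  }
  keep
}

#' Detect objects in images
#'
#' Runs the network in eval mode, decodes the distributional box predictions,
#' thresholds class confidences and applies per-class non-maximum
#' suppression.
#'
#' @param model an `ev_model`.
#' @param x images, array (H, W, 3, N) in `[0, 1]` (a single (H, W, 3) image
#'   is promoted).
#' @param conf_thr minimum class confidence.
#' @param iou_thr NMS IoU threshold.
#' @param max_det maximum detections per image.
#' @return data frame with columns `image_id`, `class_id` (0-based),
#'   `confidence`, `x1`, `y1`, `x2`, `y2` (pixels).
#' @export
predict_boxes <- function(model, x, conf_thr = 0.25, iou_thr = 0.45, max_det = 300) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  preds <- forward_model(model, x, training = FALSE)
  anch <- anchor_grid(preds)
  N <- dim(x)[4]
  out <- list()
  for (n in seq_len(N)) {
    fp <- flatten_preds(preds, n)
    boxes <- decode_boxes_num(fp$box, anch, model$cfg$reg_max)
    probs <- stats::plogis(fp$cls)
    conf <- apply(probs, 1, max)
    cls <- max.col(probs, ties.method = "first") - 1L
    sel <- which(conf >= conf_thr)
    if (!length(sel)) next
    keep <- integer(0)
    for (cid in unique(cls[sel])) {
      ci <- sel[cls[sel] == cid]
      keep <- c(keep, ci[nms(boxes[ci, , drop = FALSE], conf[ci], iou_thr)])
    }
    if (length(keep) > max_det) {
      keep <- keep[order(conf[keep], decreasing = TRUE)[seq_len(max_det)]]
    }
    out[[n]] <- data.frame(image_id = n, class_id = cls[keep],
                           confidence = conf[keep],
                           x1 = boxes[keep, 1], y1 = boxes[keep, 2],
                           x2 = boxes[keep, 3], y2 = boxes[keep, 4])
  }
  if (!length(out)) {
    return(data.frame(image_id = integer(0), class_id = integer(0),
                      confidence = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  }
  do.call(rbind, out)
}
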