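# Task-aligned label assignment.
#
# Each ground-truth box selects the top-k anchor points (grid-cell centers
# lying inside it) by the alignment metric s^alpha * IoU^beta, where s is the
# predicted probability of the true class and IoU the overlap between the
# decoded box and the target.  Anchors claimed by several boxes go to the one
# they overlap most.  Target classification scores are the alignment metric
# rescaled per box so its best anchor scores that box's best IoU.

assign_targets <- function(scores, boxes, anch, gt_boxes, gt_cls,
                           topk = 10, alpha = 0.5, beta = 6) {
  A <- nrow(scores)
  nc <- ncol(scores)
  G <- if (is.null(gt_boxes)) 0L else nrow(gt_boxes)
  out <- list(fg = logical(A), gt_idx = integer(A),
              target_scores = matrix(0, A, nc))
  if (G == 0L) return(out)
  inside <- matrix(FALSE, A, G)
  iou <- matrix(0, A, G)
  for (g in seq_len(G)) {
    inside[, g] <- anch$x > gt_boxes[g, 1] & anch$x < gt_boxes[g, 3] &
      anch$y > gt_boxes[g, 2] & anch$y < gt_boxes[g, 4]
    iou[, g] <- suppressWarnings(
      box_iou(boxes, gt_boxes[g, , drop = FALSE]))
  }
  metric <- (scores[, gt_cls + 1L, drop = FALSE]^alpha) * (iou^beta) * inside
  chosen <- matrix(FALSE, A, G)
  for (g in seq_len(G)) {
    cand <- which(metric[, g] > 0)
    if (!length(cand)) {
      # degenerate cases: no positive metric inside the box (early training),
      # or a box too small to contain any anchor center.  Fall back to the
      # best-IoU interior anchor, or to the nearest anchor center in stride
      # units, so every target trains at least one anchor.
      cand <- which(inside[, g])
      if (!length(cand)) {
        cx <- (gt_boxes[g, 1] + gt_boxes[g, 3]) / 2
        cy <- (gt_boxes[g, 2] + gt_boxes[g, 4]) / 2
        dist <- sqrt((anch$x - cx)^2 + (anch$y - cy)^2) / anch$stride
        cand <- which.min(dist)
      }
      chosen[cand[which.max(iou[cand, g])], g] <- TRUE
    } else {
      k <- min(topk, length(cand))
      chosen[cand[order(metric[cand, g], decreasing = TRUE)[seq_len(k)]], g] <- TRUE
    }
  }
  # resolve anchors claimed by several boxes: keep the highest-IoU claim
  multi <- which(rowSums(chosen) > 1L)
  for (a in multi) {
    gs <- which(chosen[a, ])
    keep <- gs[which.max(iou[a, gs])]
    chosen[a, ] <- FALSE
    chosen[a, keep] <- TRUE
  }
  fg <- rowSums(chosen) > 0L
  gt_idx <- integer(A)
  gt_idx[fg] <- apply(chosen[fg, , drop = FALSE], 1, which.max)
  # normalize: each box's anchors scaled so max metric -> max IoU
  tsc <- matrix(0, A, nc)
  for (g in seq_len(G)) {
    sel <- which(chosen[, g])
    if (!length(sel)) next
    mmax <- max(metric[sel, g])
    imax <- max(iou[sel, g])
    # degenerate (zero-metric) assignments get a small positive target so
    # their anchors still receive classification and box gradients
    val <- if (mmax > 0) metric[sel, g] / mmax * imax else rep(max(imax, 0.25), length(sel))
    tsc[cbind(sel, rep(gt_cls[g] + 1L, length(sel)))] <- val
  }
  list(fg = fg, gt_idx = gt_idx, target_scores = tsc)
}
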