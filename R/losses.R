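# Bounding-box regression losses.
#
# Boxes use the corner convention (x1, y1, x2, y2) in continuous image
# coordinates with the origin at the top-left, x2 > x1 and y2 > y1.  All
# functions are vectorized over matrix rows and recycle a single box.

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  b <- as.matrix(b)
  if (ncol(b) != 4) stop("boxes must have 4 columns (x1, y1, x2, y2)")
  if (any(!is.finite(b))) stop("boxes must be finite")
  b
}

#' Intersection over union of box pairs
#'
#' @param a,b boxes as length-4 vectors or n x 4 matrices (rows are paired;
#'   a single row recycles against the other argument).
#' @return numeric vector of IoU values in `[0, 1]`.  Degenerate (zero-area)
#'   boxes overlap nothing by convention and give 0 with a warning.
#' @export
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
box_iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L) b <- b[rep(1L, n), , drop = FALSE]
  area_a <- pmax(a[, 3] - a[, 1], 0) * pmax(a[, 4] - a[, 2], 0)
  area_b <- pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  degen <- area_a <= 0 | area_b <= 0
  if (any(degen)) warning("zero-area box; IoU defined as 0")
  iw <- pmax(pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]), 0)
  ih <- pmax(pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]), 0)
  inter <- iw * ih
  un <- area_a + area_b - inter
  out <- ifelse(degen | un <= 0, 0, inter / un)
  as.numeric(out)
}

#' IoU-family regression losses
#'
#' `loss = 1 - score(variant)`: plain IoU; GIoU (penalizes the empty part of
#' the smallest enclosing box, loss in `[0, 2]`); DIoU (adds the squared
#' center distance over the enclosing diagonal); CIoU (DIoU plus an aspect
#' ratio consistency term).  All are 0 iff the boxes coincide and invariant
#' under joint translation and joint uniform scaling.
#'
#' @param a predicted boxes, `b` targets (vector or n x 4 matrix).
#' @param variant one of `"iou"`, `"giou"`, `"diou"`, `"ciou"`.
#' @return numeric loss vector.
#' @export
#' @examples
#' iou_loss(c(0, 0, 1, 1), c(2, 0, 3, 1), "giou")  # 4/3
iou_loss <- function(a, b, variant = c("iou", "giou", "diou", "ciou")) {
  variant <- match.arg(variant)
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L) b <- b[rep(1L, n), , drop = FALSE]
  iou <- box_iou(a, b)
  if (variant == "iou") return(1 - iou)
  ex1 <- pmin(a[, 1], b[, 1]); ey1 <- pmin(a[, 2], b[, 2])
  ex2 <- pmax(a[, 3], b[, 3]); ey2 <- pmax(a[, 4], b[, 4])
  if (variant == "giou") {
    enclose <- (ex2 - ex1) * (ey2 - ey1)
    inter <- iou * ((a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
                      (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])) / (1 + iou)
    union <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
      (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
    return(1 - (iou - (enclose - union) / pmax(enclose, 1e-12)))
  }
  c2 <- (ex2 - ex1)^2 + (ey2 - ey1)^2
  d2 <- ((a[, 1] + a[, 3]) / 2 - (b[, 1] + b[, 3]) / 2)^2 +
    ((a[, 2] + a[, 4]) / 2 - (b[, 2] + b[, 4]) / 2)^2
  pen <- d2 / pmax(c2, 1e-12)
  if (variant == "diou") return(1 - iou + pen)
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  wb <- b[, 3] - b[, 1]; hb <- b[, 4] - b[, 2]
  v <- (4 / pi^2) * (atan(wb / hb) - atan(wa / ha))^2
  alpha <- v / pmax(1 - iou + v, 1e-12)
  1 - iou + pen + alpha * v
}

#' Running state of the Wise-IoU loss
#'
#' Holds the exponential moving average of the (gradient-detached) IoU loss
#' that normalizes each box's outlier degree, plus the focusing
#' hyper-parameters of the dynamic non-monotonic gain.
#'
#' @param alpha gain base (> 1) of the focusing curve.
#' @param delta gain scale; a box whose outlier degree equals `delta` gets
#'   gain exactly 1.
#' @param momentum EMA retention factor in (0, 1); the running mean keeps
#'   `momentum` of its value per training step.
#' @param init initial running mean (the loss scale expected early in
#'   training; 1 is the ceiling of the plain IoU loss).
#' @return an environment of class `wiou_state` with fields `running_mean`,
#'   `alpha`, `delta`, `momentum`.
#' @export
wiou_state <- function(alpha = 1.9, delta = 3, momentum = 1 - 1 / 2000, init = 1) {
  stopifnot(alpha > 1, delta > 0, momentum > 0, momentum < 1)
  st <- new.env(parent = emptyenv())
  st$alpha <- alpha
  st$delta <- delta
  st$momentum <- momentum
  st$running_mean <- init
  class(st) <- "wiou_state"
  st
}

#' @export
print.wiou_state <- function(x, ...) {
  cat(sprintf("<wiou_state mean=%.4f alpha=%.2f delta=%.1f momentum=%.4f>\n",
              x$running_mean, x$alpha, x$delta, x$momentum))
  invisible(x)
}

# non-monotonic focusing gain r(beta); vanishes as beta -> 0 and beta -> Inf
wiou_gain <- function(beta, alpha, delta) beta / (delta * alpha^(beta - delta))

#' Wise-IoU loss with dynamic non-monotonic focusing
#'
#' The distance-attended base term is `R * L_iou` with
#' `R = exp(d^2 / c^2)` (`d` the center distance, `c` the enclosing-box
#' diagonal, treated as a constant for gradients).  Each box's outlier
#' degree `beta = L_iou / running_mean` (both detached) sets a gradient gain
#' `r = beta / (delta * alpha^(beta - delta))`, so boxes of middling quality
#' receive the largest updates while very good and very poor ones are
#' damped.  During training steps the running mean moves toward the batch
#' mean IoU loss by `1 - momentum`.
#'
#' @param pred,gt predicted and target boxes (vector or n x 4 matrix).
#' @param state a [wiou_state()]; its running mean is updated in place when
#'   `training`.
#' @param training logical; update the running mean.
#' @return list with `loss` (numeric vector), `gain` (the per-box `r`), and
#'   `base` (the unfocused `R * L_iou` term).
#' @export
#' @examples
#' st <- wiou_state()
#' st$running_mean <- 2 / 3
#' wiou_loss(c(0, 0, 2, 2), c(1, 0, 3, 2), st)$loss  # ~0.866
wiou_loss <- function(pred, gt, state, training = FALSE) {
  stopifnot(inherits(state, "wiou_state"))
  pred <- as_box_matrix(pred); gt <- as_box_matrix(gt)
  n <- max(nrow(pred), nrow(gt))
  if (nrow(pred) == 1L) pred <- pred[rep(1L, n), , drop = FALSE]
  if (nrow(gt) == 1L) gt <- gt[rep(1L, n), , drop = FALSE]
  l_iou <- iou_loss(pred, gt, "iou")
  ex1 <- pmin(pred[, 1], gt[, 1]); ey1 <- pmin(pred[, 2], gt[, 2])
  ex2 <- pmax(pred[, 3], gt[, 3]); ey2 <- pmax(pred[, 4], gt[, 4])
  c2 <- (ex2 - ex1)^2 + (ey2 - ey1)^2
  d2 <- ((pred[, 1] + pred[, 3]) / 2 - (gt[, 1] + gt[, 3]) / 2)^2 +
    ((pred[, 2] + pred[, 4]) / 2 - (gt[, 2] + gt[, 4]) / 2)^2
  r_att <- exp(d2 / pmax(c2, 1e-12))
  mean_ref <- state$running_mean
  beta <- if (mean_ref > 0) l_iou / mean_ref else rep(1, n)
  gain <- wiou_gain(beta, state$alpha, state$delta)
  if (training) {
    state$running_mean <- state$momentum * state$running_mean +
      (1 - state$momentum) * mean(l_iou)
  }
  list(loss = gain * r_att * l_iou, gain = gain, base = r_att * l_iou)
}

# ---------------------------------------------------------------------------
# Differentiable Wise-IoU over decoded box coordinate nodes (training path).
# `px1..py2` are ag vectors; `gt` a numeric n x 4 matrix.  The gain, the
# outlier normalization and the R denominator use detached numerics, exactly
# as in the closed form above; gradients flow through L_iou and the R
# numerator only.
wiou_loss_ag <- function(px1, py1, px2, py2, gt, state, training = TRUE) {
  iw <- ag_pmax2(ag_sub(ag_pmin2(px2, gt[, 3]), ag_pmax2(px1, gt[, 1])), 0)
  ih <- ag_pmax2(ag_sub(ag_pmin2(py2, gt[, 4]), ag_pmax2(py1, gt[, 2])), 0)
  inter <- ag_mul(iw, ih)
  area_p <- ag_mul(ag_sub(px2, px1), ag_sub(py2, py1))
  area_g <- (gt[, 3] - gt[, 1]) * (gt[, 4] - gt[, 2])
  un <- ag_sub(ag_add(area_p, area_g), inter)
  iou <- ag_div(inter, ag_pmax2(un, 1e-9))
  l_iou <- ag_sub(1, iou)
  # enclosing diagonal (detached) and center distance (live numerator)
  ex1 <- pmin(ag_v(px1), gt[, 1]); ey1 <- pmin(ag_v(py1), gt[, 2])
  ex2 <- pmax(ag_v(px2), gt[, 3]); ey2 <- pmax(ag_v(py2), gt[, 4])
  c2 <- pmax((ex2 - ex1)^2 + (ey2 - ey1)^2, 1e-9)
  dx <- ag_sub(ag_mul(ag_add(px1, px2), 0.5), (gt[, 1] + gt[, 3]) / 2)
  dy <- ag_sub(ag_mul(ag_add(py1, py2), 0.5), (gt[, 2] + gt[, 4]) / 2)
  r_att <- ag_exp(ag_div(ag_add(ag_sq(dx), ag_sq(dy)), c2))
  l_det <- ag_v(l_iou)
  mean_ref <- state$running_mean
  beta <- if (mean_ref > 0) l_det / mean_ref else rep(1, length(l_det))
  gain <- wiou_gain(beta, state$alpha, state$delta)
  if (training) {
    state$running_mean <- state$momentum * state$running_mean +
      (1 - state$momentum) * mean(l_det)
  }
  ag_mul(ag_mul(r_att, l_iou), gain)
}
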