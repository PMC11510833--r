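# Forward passes.
#
# `ev_forward(module, x, ctx)` maps a module onto the differentiable op
# library; `forward_model()` executes the assembled graph.  `x` is an ag node
# (or plain array) of dim (H, W, C, N).  `ctx$training` selects batch-norm
# behaviour and gradient recording.

ev_forward <- function(m, x, ctx = list(training = FALSE)) UseMethod("ev_forward")

#' @export
ev_forward.ev_conv <- function(m, x, ctx = list(training = FALSE)) {
  cx <- dim(ag_v(x))[1]
  if (cx != m$cin) {
    stop(sprintf("channel mismatch: input has %d channels, conv expects %d", cx, m$cin))
  }
  w <- ag_leaf(m$pars$w)
  out <- if (m$g == 1L) {
    ag_conv_dense(x, w, m$s, m$d)
  } else {
    ag_conv_grouped(x, w, m$g, m$s, m$d)
  }
  if (m$norm) {
    out <- ag_batchnorm(out, ag_leaf(m$pars$bn_g), ag_leaf(m$pars$bn_b),
                        m$pars$bn_rm, m$pars$bn_rv, training = isTRUE(ctx$training))
  }
  if (m$bias) out <- ag_bias_c(out, ag_leaf(m$pars$b))
  switch(m$act, silu = ag_silu(out), relu = ag_relu(out), none = out)
}

#' @export
ev_forward.ev_bottleneck <- function(m, x, ctx = list(training = FALSE)) {
  y <- ev_forward(m$cv2, ev_forward(m$cv1, x, ctx), ctx)
  if (m$add) ag_add(x, y) else y
}

#' @export
ev_forward.ev_c2f <- function(m, x, ctx = list(training = FALSE)) {
  h <- ev_forward(m$cv1, x, ctx)
  a <- ag_slice_c(h, 1L, m$c)
  b <- ag_slice_c(h, m$c + 1L, 2L * m$c)
  ys <- list(a, b)
  cur <- b
  for (bt in m$m) {
    cur <- ev_forward(bt, cur, ctx)
    ys[[length(ys) + 1L]] <- cur
  }
  ev_forward(m$cv2, ag_concat_c(ys), ctx)
}

#' @export
ev_forward.ev_c2 <- function(m, x, ctx = list(training = FALSE)) {
  h <- ev_forward(m$cv1, x, ctx)
  a <- ag_slice_c(h, 1L, m$c)
  b <- ag_slice_c(h, m$c + 1L, 2L * m$c)
  cur <- a
  for (bt in m$m) cur <- ev_forward(bt, cur, ctx)
  ev_forward(m$cv2, ag_concat_c(list(cur, b)), ctx)
}

sppf_pyramid <- function(m, x, ctx) {
  h <- ev_forward(m$cv1, x, ctx)
  p1 <- ag_maxpool_same(h, m$pool_k)
  p2 <- ag_maxpool_same(p1, m$pool_k)
  p3 <- ag_maxpool_same(p2, m$pool_k)
  ag_concat_c(list(h, p1, p2, p3))
}

#' @export
ev_forward.ev_sppf <- function(m, x, ctx = list(training = FALSE)) {
  ev_forward(m$cv2, sppf_pyramid(m, x, ctx), ctx)
}

#' @export
ev_forward.ev_sppf_lska <- function(m, x, ctx = list(training = FALSE)) {
  ev_forward(m$cv2, ev_forward(m$lska, sppf_pyramid(m, x, ctx), ctx), ctx)
}

#' @export
ev_forward.ev_lse <- function(m, x, ctx = list(training = FALSE)) {
  d <- dim(ag_v(x))
  if (m$g > min(d[2], d[3])) {
    warning(sprintf("LSE pool grid %d exceeds spatial dims %dx%d; clamping",
                    m$g, d[2], d[3]))
  }
  p <- ag_avgpool_adaptive(x, m$g)
  att <- ag_sigmoid(ag_chan_conv1d(p, ag_leaf(m$pars$w), ag_leaf(m$pars$b)))
  ag_mul(x, ag_gate_upsample(att, d[2], d[3]))
}

#' @export
ev_forward.ev_mgefa <- function(m, x, ctx = list(training = FALSE)) {
  acc <- NULL
  for (br in m$branches) {
    y <- ev_forward(br$lse, ev_forward(br$conv, x, ctx), ctx)
    acc <- if (is.null(acc)) y else ag_add(acc, y)
  }
  ag_add(x, acc)
}

#' @export
ev_forward.ev_mgefac2f <- function(m, x, ctx = list(training = FALSE)) {
  ev_forward(m$mgefa, ev_forward(m$c2f, x, ctx), ctx)
}

#' @export
ev_forward.ev_lska <- function(m, x, ctx = list(training = FALSE)) {
  a <- ev_forward(m$conv0h, x, ctx)
  a <- ev_forward(m$conv0v, a, ctx)
  a <- ev_forward(m$convsh, a, ctx)
  a <- ev_forward(m$convsv, a, ctx)
  a <- ev_forward(m$conv1, a, ctx)
  ag_mul(x, a)
}

#' @export
ev_forward.ev_upsample <- function(m, x, ctx = list(training = FALSE)) ag_upsample2(x)

# concat handled at graph level; detect returns per-scale raw prediction pairs
#' @export
ev_forward.ev_detect <- function(m, x, ctx = list(training = FALSE)) {
  stopifnot(is.list(x), length(x) == length(m$ch))
  lapply(seq_along(x), function(i) {
    xi <- x[[i]]
    box <- xi
    for (cv in m$box[[i]]) box <- ev_forward(cv, box, ctx)
    cls <- xi
    for (cv in m$cls[[i]]) cls <- ev_forward(cv, cls, ctx)
    d <- dim(ag_v(xi))
    list(box = box, cls = cls, stride = m$strides[i], h = d[2], w = d[3])
  })
}

#' Run the assembled network
#'
#' @param model an `ev_model`.
#' @param x input images: array (H, W, 3, N) of values in `[0, 1]` (converted
#'   internally to the channels-first layout the blocks use).
#' @param training logical; training mode uses batch statistics in the
#'   normalization layers and records the gradient tape.
#' @return a list with one element per detection scale, each holding `box`
#'   (raw distribution logits, `(4*reg_max, h, w, N)`), `cls` (class logits,
#'   `(nc, h, w, N)`), `stride`, `h`, `w`.
#' @export
forward_model <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "ev_model"))
  xv <- ag_v(x)
  d <- dim(xv)
  stopifnot(length(d) == 4L, d[3] == 3L)
  smax <- max(model$cfg$strides)
  if (d[1] %% smax != 0 || d[2] %% smax != 0) {
    stop(sprintf("input %dx%d not divisible by the largest stride %d", d[1], d[2], smax))
  }
  if (!any(is.finite(xv))) stop("input contains no finite values")
  ctx <- list(training = isTRUE(training))
  x <- ag_const(aperm(xv, c(3, 1, 2, 4)))
  vals <- vector("list", length(model$nodes))
  for (nd in model$nodes) {
    inp <- if (nd$from[1] == 0L) x else vals[[nd$from[1]]]
    vals[[nd$i]] <- if (inherits(nd$m, "ev_concat")) {
      ag_concat_c(vals[nd$from])
    } else if (inherits(nd$m, "ev_detect")) {
      ev_forward(nd$m, vals[nd$from], ctx)
    } else {
      ev_forward(nd$m, inp, ctx)
    }
  }
  vals[[model$head_idx]]
}
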