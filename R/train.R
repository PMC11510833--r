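# Training: composite detection loss, SGD and the fit loop.

#' Composite detection loss
#'
#' Box term: Wise-IoU over assigned anchor/target pairs, weighted by the
#' assigner's normalized alignment scores.  Classification term: binary
#' cross-entropy between class logits and the task-aligned soft targets.
#' Distribution term: cross-entropy of the per-side bin distributions
#' against the two bins bracketing each true distance.  Each term is
#' normalized by the summed target scores and the total is the weighted sum
#' `w_box * box + w_cls * cls + w_dfl * dfl`, averaged over the batch.
#'
#' @param model an `ev_model`.
#' @param preds output of [forward_model()] (training mode for gradients).
#' @param targets list with one element per image: `list(boxes = G x 4 corner
#'   matrix in pixels, cls = 0-based integer classes)`; `NULL` or zero-row
#'   boxes mean a negative image.
#' @param state a [wiou_state()] (updated in place when `training`).
#' @param weights numeric c(box, cls, dfl) loss weights.
#' @param training update the Wise-IoU running mean.
#' @return list: `total` (ag scalar node), `box`, `cls`, `dfl` (numeric
#'   per-batch means), `n_assigned`.
#' @export
detection_loss <- function(model, preds, targets, state = wiou_state(),
                           weights = c(box = 7.5, cls = 0.5, dfl = 1.5),
                           training = TRUE) {
  reg_max <- model$cfg$reg_max
  nc <- model$cfg$nc
  anch <- anchor_grid(preds)
  A <- length(anch$x)
  N <- dim(ag_v(preds[[1]]$box))[4]
  stopifnot(length(targets) == N)
  # per-scale (A_s, C, N) nodes, concatenated later per image
  box_n <- lapply(preds, function(p) {
    ag_aperm(ag_reshape(p$box, c(4L * reg_max, p$h * p$w, N)), c(2, 1, 3))
  })
  cls_n <- lapply(preds, function(p) {
    ag_aperm(ag_reshape(p$cls, c(nc, p$h * p$w, N)), c(2, 1, 3))
  })
  total <- NULL
  box_sum <- 0; cls_sum <- 0; dfl_sum <- 0; n_fg <- 0L
  for (n in seq_len(N)) {
    p_box <- ag_rbind(lapply(box_n, ag_slab_n, n))
    p_cls <- ag_rbind(lapply(cls_n, ag_slab_n, n))
    scores <- stats::plogis(ag_v(p_cls))
    dec <- decode_boxes_num(ag_v(p_box), anch, reg_max)
    tg <- targets[[n]]
    gt_boxes <- if (is.null(tg) || is.null(tg$boxes) || nrow(tg$boxes) == 0L) NULL else tg$boxes
    gt_cls <- if (is.null(gt_boxes)) integer(0) else tg$cls
    asg <- assign_targets(scores, dec, anch, gt_boxes, gt_cls)
    norm <- max(sum(asg$target_scores), 1)
    l_cls <- ag_mul(ag_bce_sum(p_cls, asg$target_scores), 1 / norm)
    li <- ag_mul(l_cls, weights[["cls"]])
    cls_sum <- cls_sum + ag_v(l_cls)
    if (any(asg$fg)) {
      idx <- which(asg$fg)
      f <- length(idx)
      n_fg <- n_fg + f
      gt <- gt_boxes[asg$gt_idx[idx], , drop = FALSE]
      w_fg <- rowSums(asg$target_scores[idx, , drop = FALSE])
      st <- anch$stride[idx]
      axp <- anch$x[idx]; ayp <- anch$y[idx]
      # distribution expectation -> corner boxes (differentiable decode)
      b <- ag_rows(p_box, idx)                          # (f, 4*reg_max)
      b <- ag_reshape(b, c(f, reg_max, 4L))
      b <- ag_aperm(b, c(1, 3, 2))
      b <- ag_reshape(b, c(f * 4L, reg_max))            # rows: f fastest, side-major
      sm <- ag_softmax_rows(b)
      ex <- ag_reshape(ag_matvec(sm, seq_len(reg_max) - 1), c(f, 4L))
      dl <- ag_cells(ex, seq_len(f), rep(1L, f))
      dt <- ag_cells(ex, seq_len(f), rep(2L, f))
      dr <- ag_cells(ex, seq_len(f), rep(3L, f))
      db <- ag_cells(ex, seq_len(f), rep(4L, f))
      px1 <- ag_sub(axp, ag_mul(dl, st))
      py1 <- ag_sub(ayp, ag_mul(dt, st))
      px2 <- ag_add(axp, ag_mul(dr, st))
      py2 <- ag_add(ayp, ag_mul(db, st))
      wl_box <- wiou_loss_ag(px1, py1, px2, py2, gt, state, training = training)
      l_box <- ag_mul(ag_sum(ag_mul(wl_box, w_fg)), 1 / norm)
      # distribution-focal targets: true distances in stride units
      tdist <- cbind((axp - gt[, 1]) / st, (ayp - gt[, 2]) / st,
                     (gt[, 3] - axp) / st, (gt[, 4] - ayp) / st)
      tdist <- pmin(pmax(tdist, 0), reg_max - 1 - 1e-3)
      td <- as.numeric(tdist)                           # f fastest, side-major
      tl <- floor(td)
      wr <- td - tl
      wl <- 1 - wr
      l_dfl <- ag_mul(ag_dfl_ce(b, tl + 1L, pmin(tl + 2L, reg_max),
                                wl, wr, rep(w_fg, 4L) / 4),
                      1 / norm)
      li <- ag_add(li, ag_add(ag_mul(l_box, weights[["box"]]),
                              ag_mul(l_dfl, weights[["dfl"]])))
      box_sum <- box_sum + ag_v(l_box)
      dfl_sum <- dfl_sum + ag_v(l_dfl)
    }
    total <- if (is.null(total)) li else ag_add(total, li)
  }
  total <- ag_mul(total, 1 / N)
  list(total = total, box = box_sum / N, cls = cls_sum / N, dfl = dfl_sum / N,
       n_assigned = n_fg)
}

#' Stochastic gradient descent step with momentum and decoupled weight decay
#'
#' Weight decay applies to convolution kernels only (not to normalization
#' scale/shift or biases), the convention of this detector family.
#'
#' @param pars list of parameter environments (see [build_model()] internals).
#' @param lr learning rate.
#' @param momentum velocity retention.
#' @param weight_decay L2 coefficient for convolution kernels.
#' @param clip clip each parameter's gradient to this maximum absolute value
#'   (`Inf` to disable).
#' @keywords internal
sgd_step <- function(pars, lr, momentum = 0.937, weight_decay = 5e-4, clip = 10) {
  for (p in pars) {
    if (!p$trainable || is.null(p$grad)) next
    g <- p$grad
    if (is.finite(clip)) g <- pmax(pmin(g, clip), -clip)
    if (weight_decay > 0 && length(dim(p$value)) == 4L) {
      g <- g + weight_decay * p$value
    }
    v <- if (is.null(p$mom)) g else momentum * p$mom + g
    p$mom <- v
    p$value <- p$value - lr * v
    p$grad <- NULL
  }
  invisible(NULL)
}

#' Fit a detector on in-memory samples
#'
#' Full-precision SGD on one CPU.  One step consumes one minibatch; batches
#' cycle deterministically through a seeded permutation of the samples.
#' The learning rate warms up linearly over `warmup` steps, then decays
#' linearly from `lr0` (the family's default initial rate) to `lr0 * lrf`.
#'
#' @param model an `ev_model`.
#' @param samples list of samples: `list(image = H x W x 3 array in [0, 1],
#'   boxes = G x 4 corner matrix (pixels), cls = 0-based classes)`; see
#'   [sample_from_yolo()] for conversion from annotation rows.
#' @param steps number of optimizer steps.
#' @param batch minibatch size.
#' @param lr0 initial learning rate.
#' @param lrf final learning-rate fraction; the rate decays linearly from
#'   `lr0` to `lr0 * lrf` after warmup.
#' @param momentum,weight_decay SGD hyper-parameters.
#' @param warmup linear warmup steps.
#' @param loss_weights c(box, cls, dfl) weights.
#' @param wiou list of Wise-IoU hyper-parameters passed to [wiou_state()].
#' @param seed RNG seed controlling batch order (weights were seeded at
#'   [build_model()]).
#' @param log_every print a progress line every this many steps (0 = quiet).
#' @param log_file optional JSON-lines path; one record per step.
#' @return invisibly, a data frame history (step, loss, box, cls, dfl, lr).
#' @export
train_model <- function(model, samples, steps = 200, batch = 8, lr0 = 0.01,
                        lrf = 0.01, momentum = 0.937, weight_decay = 5e-4,
                        warmup = 10,
                        loss_weights = c(box = 7.5, cls = 0.5, dfl = 1.5),
                        wiou = list(), seed = 0, log_every = 0, log_file = NULL) {
  stopifnot(inherits(model, "ev_model"), length(samples) >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  state <- do.call(wiou_state, wiou)
  pars <- model_pars(model)
  hist <- vector("list", steps)
  order_pool <- integer(0)
  if (!is.null(log_file)) {
    con <- file(log_file, open = "wt")
    on.exit(close(con), add = TRUE)
  }
  for (step in seq_len(steps)) {
    while (length(order_pool) < batch) {
      order_pool <- c(order_pool, sample.int(length(samples)))
    }
    take <- order_pool[seq_len(batch)]
    order_pool <- order_pool[-seq_len(batch)]
    d1 <- dim(samples[[take[1]]]$image)
    x <- array(0, c(d1[1], d1[2], 3L, batch))
    for (j in seq_along(take)) x[, , , j] <- samples[[take[j]]]$image
    targets <- lapply(samples[take], function(s) list(boxes = s$boxes, cls = s$cls))
    preds <- forward_model(model, x, training = TRUE)
    zero_grads(pars)
    ls <- detection_loss(model, preds, targets, state, loss_weights, training = TRUE)
    ag_backward(ls$total)
    lr <- if (step <= warmup) {
      lr0 * step / warmup
    } else {
      frac <- (step - warmup) / max(steps - warmup, 1)
      lr0 * (1 - frac * (1 - lrf))
    }
    sgd_step(pars, lr, momentum, weight_decay)
    rec <- data.frame(step = step, loss = ag_v(ls$total), box = ls$box,
                      cls = ls$cls, dfl = ls$dfl, lr = lr,
                      n_assigned = ls$n_assigned)
    hist[[step]] <- rec
    if (!is.null(log_file)) {
      writeLines(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE, digits = NA), con)
    }
    if (log_every > 0 && (step %% log_every == 0 || step == 1L)) {
      message(sprintf("step %4d  loss %8.4f  box %7.4f  cls %7.4f  dfl %7.4f  lr %.4g",
                      step, rec$loss, rec$box, rec$cls, rec$dfl, lr))
    }
  }
  invisible(do.call(rbind, hist))
}

# ---------------------------------------------------------------------------
# Checkpoints: versioned single-file RDS with config and all arrays.

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding a format version, the
#' [model_config()] and every parameter/buffer array; loading rebuilds the
#' graph from the config and restores the arrays.
#'
#' @param model an `ev_model`.
#' @param path file path.
#' @param meta optional list stored alongside (epoch counters etc.).
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: a list
#'   `model`, `meta`.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  pars <- model_pars(model)
  saveRDS(list(version = 1L, cfg = unclass(model$cfg),
               values = lapply(pars, function(p) p$value),
               trainable = vapply(pars, function(p) p$trainable, logical(1)),
               meta = meta),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != 1L) {
    stop("unsupported checkpoint version: ", ck$version)
  }
  cfg <- do.call(model_config, ck$cfg[c("scale", "mgefa", "p6", "lska", "nc",
                                        "imgsz", "reg_max", "lska_k",
                                        "lse_grid", "lse_k", "seed")])
  model <- build_model(cfg)
  pars <- model_pars(model)
  stopifnot(length(pars) == length(ck$values))
  for (i in seq_along(pars)) {
    stopifnot(length(pars[[i]]$value) == length(ck$values[[i]]))
    pars[[i]]$value <- ck$values[[i]]
  }
  list(model = model, meta = ck$meta)
}
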