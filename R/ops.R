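# Differentiable array operations.
#
# Feature maps are arrays of dim (C, H, W, N) -- channels fastest.  With the
# channel axis first, per-channel affine maps (batch norm, biases, depthwise
# taps) are plain R vector recycling, and a k x k convolution is a loop over
# the k^2 kernel taps, each a single BLAS matmul of the (Cout, Cin) tap
# matrix against a shifted (Cin, H*W*N) slice of the padded input -- the same
# FLOPs as im2col without building or transposing the k^2-fold column matrix.
# Convolutions use "same" padding: stride 1 preserves H x W, stride 2 emits
# ceiling(H/2) x ceiling(W/2).

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- elementwise -----------------------------------------------------------

ag_add <- function(a, b) {
  av <- ag_v(a); bv <- ag_v(b)
  ag_op(av + bv, list(a, b), function(g) list(
    if (length(av) == 1L && length(g) > 1L) sum(g) else g,
    if (length(bv) == 1L && length(g) > 1L) sum(g) else g))
}

ag_sub <- function(a, b) {
  av <- ag_v(a); bv <- ag_v(b)
  ag_op(av - bv, list(a, b), function(g) list(
    if (length(av) == 1L && length(g) > 1L) sum(g) else g,
    if (length(bv) == 1L && length(g) > 1L) -sum(g) else -g))
}

ag_mul <- function(a, b) {
  av <- ag_v(a); bv <- ag_v(b)
  ag_op(av * bv, list(a, b), function(g) list(
    if (length(av) == 1L && length(g) > 1L) sum(g * bv) else g * bv,
    if (length(bv) == 1L && length(g) > 1L) sum(g * av) else g * av))
}

ag_div <- function(a, b) {
  av <- ag_v(a); bv <- ag_v(b)
  v <- av / bv
  ag_op(v, list(a, b), function(g) list(
    if (length(av) == 1L && length(g) > 1L) sum(g / bv) else g / bv,
    if (length(bv) == 1L && length(g) > 1L) sum(-g * v / bv) else -g * v / bv))
}

ag_neg <- function(a) ag_op(-ag_v(a), list(a), function(g) list(-g))

ag_exp <- function(a) {
  v <- exp(ag_v(a))
  ag_op(v, list(a), function(g) list(g * v))
}

ag_log <- function(a) {
  av <- ag_v(a)
  ag_op(log(av), list(a), function(g) list(g / av))
}

ag_sqrt <- function(a) {
  v <- sqrt(ag_v(a))
  ag_op(v, list(a), function(g) list(g / (2 * v)))
}

ag_sq <- function(a) {
  av <- ag_v(a)
  ag_op(av * av, list(a), function(g) list(2 * g * av))
}

ag_sigmoid <- function(a) {
  v <- stats::plogis(ag_v(a))
  ag_op(v, list(a), function(g) list(g * v * (1 - v)))
}

ag_silu <- function(a) {
  av <- ag_v(a)
  s <- stats::plogis(av)
  ag_op(av * s, list(a), function(g) list(g * s * (1 + av * (1 - s))))
}

ag_relu <- function(a) {
  av <- ag_v(a)
  v <- pmax(av, 0)
  ag_op(v, list(a), function(g) list(g * (av > 0)))
}

# elementwise max/min; ties route the gradient to the first argument
ag_pmax2 <- function(a, b) {
  av <- ag_v(a); bv <- ag_v(b)
  take_a <- av >= bv
  ag_op(pmax(av, bv), list(a, b), function(g) list(
    { ga <- g * take_a; if (length(av) == 1L) sum(ga) else ga },
    { gb <- g * !take_a; if (length(bv) == 1L) sum(gb) else gb }))
}

ag_pmin2 <- function(a, b) {
  av <- ag_v(a); bv <- ag_v(b)
  take_a <- av <= bv
  ag_op(pmin(av, bv), list(a, b), function(g) list(
    { ga <- g * take_a; if (length(av) == 1L) sum(ga) else ga },
    { gb <- g * !take_a; if (length(bv) == 1L) sum(gb) else gb }))
}

ag_sum <- function(a) {
  av <- ag_v(a)
  ag_op(sum(av), list(a), function(g) list(array(as.numeric(g), dim = dim(av) %||% length(av))))
}

ag_mean <- function(a) {
  av <- ag_v(a)
  n <- length(av)
  ag_op(sum(av) / n, list(a), function(g) list(array(as.numeric(g) / n, dim = dim(av) %||% n)))
}

# treat a value as a constant (block gradient flow); the detached running
# statistics of the Wise-IoU loss and the assigner inputs use this
ag_detach <- function(a) ag_new(ag_v(a))

# ---- shape ops -------------------------------------------------------------

ag_reshape <- function(a, dims) {
  av <- ag_v(a)
  od <- dim(av) %||% length(av)
  v <- av
  dim(v) <- dims
  ag_op(v, list(a), function(g) { dim(g) <- od; list(g) })
}

ag_aperm <- function(a, perm) {
  v <- aperm(ag_v(a), perm)
  inv <- order(perm)
  ag_op(v, list(a), function(g) list(aperm(g, inv)))
}

# gather rows of a matrix (duplicates allowed)
ag_rows <- function(a, idx) {
  av <- ag_v(a)
  idx <- as.integer(idx)
  ag_op(av[idx, , drop = FALSE], list(a), function(g) {
    d <- matrix(0, nrow(av), ncol(av))
    rs <- rowsum(g, idx)
    d[as.integer(rownames(rs)), ] <- rs
    list(d)
  })
}

# single cells of a matrix, x[cbind(rows, cols)]
ag_cells <- function(a, rows, cols) {
  av <- ag_v(a)
  ij <- cbind(as.integer(rows), as.integer(cols))
  ag_op(av[ij], list(a), function(g) {
    d <- matrix(0, nrow(av), ncol(av))
    lin <- (ij[, 2] - 1L) * nrow(av) + ij[, 1]
    rs <- rowsum(as.numeric(g), lin)
    d[as.integer(rownames(rs))] <- rs
    list(d)
  })
}

ag_rbind <- function(xs) {
  vs <- lapply(xs, ag_v)
  nr <- vapply(vs, nrow, integer(1))
  v <- do.call(rbind, vs)
  ends <- cumsum(nr)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ag_op(v, xs, function(g) {
    lapply(seq_along(xs), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

# fix the batch index of an (A, C, N) array -> (A, C) matrix
ag_slab_n <- function(a, n) {
  av <- ag_v(a)
  d <- dim(av)
  v <- av[, , n, drop = FALSE]
  dim(v) <- d[1:2]
  ag_op(v, list(a), function(g) {
    dz <- array(0, d)
    dz[, , n] <- g
    list(dz)
  })
}

# channel slice of a (C, H, W, N) array
ag_slice_c <- function(a, from, to) {
  av <- ag_v(a)
  d <- dim(av)
  ag_op(av[from:to, , , , drop = FALSE], list(a), function(g) {
    dz <- array(0, d)
    dz[from:to, , , ] <- g
    list(dz)
  })
}

ag_concat_c <- function(xs) {
  vs <- lapply(xs, ag_v)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[1], integer(1))
  v <- array(0, c(sum(cs), d1[2], d1[3], d1[4]))
  at <- 0L
  for (j in seq_along(vs)) {
    v[at + seq_len(cs[j]), , , ] <- vs[[j]]
    at <- at + cs[j]
  }
  ends <- cumsum(cs)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ag_op(v, xs, function(g) {
    lapply(seq_along(xs), function(j) g[starts[j]:ends[j], , , , drop = FALSE])
  })
}

# ---- padding helper --------------------------------------------------------

pad_chw <- function(x, ph, pw, fill = 0) {
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1], d[2] + 2L * ph, d[3] + 2L * pw, d[4]))
  xp[, ph + seq_len(d[2]), pw + seq_len(d[3]), ] <- x
  xp
}

unpad_chw <- function(xp, ph, pw, h, w) {
  if (ph == 0L && pw == 0L) return(xp)
  xp[, ph + seq_len(h), pw + seq_len(w), , drop = FALSE]
}

# ---- convolutions ----------------------------------------------------------

# Dense convolution, groups = 1.  w: (Cout, Cin, kh, kw); x: (Cin, H, W, N).
ag_conv_dense <- function(x, w, stride = 1L, dil = 1L) {
  xv <- ag_v(x); wv <- ag_v(w)
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  kd <- dim(wv)
  cout <- kd[1]; kh <- kd[3]; kw <- kd[4]
  stopifnot(C == kd[2])
  if (kh == 1L && kw == 1L && stride == 1L) return(ag_conv_point(x, w))
  ph <- (dil * (kh - 1L)) %/% 2L
  pw <- (dil * (kw - 1L)) %/% 2L
  Ho <- as.integer(ceiling(H / stride)); Wo <- as.integer(ceiling(W / stride))
  xp <- pad_chw(xv, ph, pw)
  m <- Ho * Wo * N
  om <- matrix(0, cout, m)
  for (th in seq_len(kh)) {
    ri <- seq.int((th - 1L) * dil + 1L, by = stride, length.out = Ho)
    for (tw in seq_len(kw)) {
      ci <- seq.int((tw - 1L) * dil + 1L, by = stride, length.out = Wo)
      sl <- xp[, ri, ci, , drop = FALSE]
      dim(sl) <- c(C, m)
      om <- om + wv[, , th, tw] %*% sl
    }
  }
  dim(om) <- c(cout, Ho, Wo, N)
  ag_op(om, list(x, w), function(g) {
    gm <- g
    dim(gm) <- c(cout, m)
    need_x <- is_ag(x) && x$rq
    need_w <- is_ag(w) && w$rq
    gw <- if (need_w) array(0, kd) else NULL
    dxp <- if (need_x) array(0, dim(xp)) else NULL
    for (th in seq_len(kh)) {
      ri <- seq.int((th - 1L) * dil + 1L, by = stride, length.out = Ho)
      for (tw in seq_len(kw)) {
        ci <- seq.int((tw - 1L) * dil + 1L, by = stride, length.out = Wo)
        if (need_w) {
          sl <- xp[, ri, ci, , drop = FALSE]
          dim(sl) <- c(C, m)
          gw[, , th, tw] <- tcrossprod(gm, sl)
        }
        if (need_x) {
          ds <- crossprod(wv[, , th, tw], gm)
          dim(ds) <- c(C, Ho, Wo, N)
          dxp[, ri, ci, ] <- dxp[, ri, ci, , drop = FALSE] + ds
        }
      }
    }
    gx <- if (need_x) unpad_chw(dxp, ph, pw, H, W) else NULL
    list(gx, gw)
  })
}

# Pointwise (1x1, stride 1) convolution.
ag_conv_point <- function(x, w) {
  xv <- ag_v(x); wv <- ag_v(w)
  d <- dim(xv)
  C <- d[1]
  m <- d[2] * d[3] * d[4]
  cout <- dim(wv)[1]
  wm <- wv
  dim(wm) <- c(cout, C)
  xm <- xv
  dim(xm) <- c(C, m)
  om <- wm %*% xm
  dim(om) <- c(cout, d[2], d[3], d[4])
  ag_op(om, list(x, w), function(g) {
    gm <- g
    dim(gm) <- c(cout, m)
    gx <- NULL; gw <- NULL
    if (is_ag(w) && w$rq) {
      gw <- tcrossprod(gm, xm)
      dim(gw) <- c(cout, C, 1L, 1L)
    }
    if (is_ag(x) && x$rq) {
      gx <- crossprod(wm, gm)
      dim(gx) <- d
    }
    list(gx, gw)
  })
}

# Depthwise convolution (groups = channels), stride 1, optional dilation.
# w: (C, 1, kh, kw).  Channel-first layout makes the per-channel tap weight
# a plain recycled vector multiply.
ag_conv_dw <- function(x, w, dil = 1L) {
  xv <- ag_v(x); wv <- ag_v(w)
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]
  kd <- dim(wv)
  kh <- kd[3]; kw <- kd[4]
  stopifnot(kd[1] == C, kd[2] == 1L)
  ph <- (dil * (kh - 1L)) %/% 2L
  pw <- (dil * (kw - 1L)) %/% 2L
  xp <- pad_chw(xv, ph, pw)
  out <- array(0, d)
  for (th in seq_len(kh)) {
    ri <- (th - 1L) * dil + seq_len(H)
    for (tw in seq_len(kw)) {
      ci <- (tw - 1L) * dil + seq_len(W)
      out <- out + xp[, ri, ci, , drop = FALSE] * as.numeric(wv[, 1L, th, tw])
    }
  }
  ag_op(out, list(x, w), function(g) {
    need_x <- is_ag(x) && x$rq
    need_w <- is_ag(w) && w$rq
    gw <- if (need_w) array(0, kd) else NULL
    dxp <- if (need_x) array(0, dim(xp)) else NULL
    for (th in seq_len(kh)) {
      ri <- (th - 1L) * dil + seq_len(H)
      for (tw in seq_len(kw)) {
        ci <- (tw - 1L) * dil + seq_len(W)
        if (need_w) {
          s <- g * xp[, ri, ci, , drop = FALSE]
          dim(s) <- c(C, length(s) %/% C)
          gw[, 1L, th, tw] <- rowSums(s)
        }
        if (need_x) {
          dxp[, ri, ci, ] <- dxp[, ri, ci, , drop = FALSE] +
            g * as.numeric(wv[, 1L, th, tw])
        }
      }
    }
    gx <- if (need_x) unpad_chw(dxp, ph, pw, H, W) else NULL
    list(gx, gw)
  })
}

# General grouped convolution: split channels, run dense per group.
ag_conv_grouped <- function(x, w, groups, stride = 1L, dil = 1L) {
  xv <- ag_v(x)
  C <- dim(xv)[1]
  kd <- dim(ag_v(w))
  cout <- kd[1]
  if (groups == 1L) return(ag_conv_dense(x, w, stride, dil))
  if (groups == C && cout == C && stride == 1L) return(ag_conv_dw(x, w, dil))
  cpg_in <- C %/% groups
  cpg_out <- cout %/% groups
  outs <- lapply(seq_len(groups), function(gi) {
    xs <- ag_slice_c(x, (gi - 1L) * cpg_in + 1L, gi * cpg_in)
    ws <- ag_wslice(w, (gi - 1L) * cpg_out + 1L, gi * cpg_out)
    ag_conv_dense(xs, ws, stride, dil)
  })
  ag_concat_c(outs)
}

# slice output-channel block of a weight array
ag_wslice <- function(w, from, to) {
  wv <- ag_v(w)
  d <- dim(wv)
  ag_op(wv[from:to, , , , drop = FALSE], list(w), function(g) {
    dz <- array(0, d)
    dz[from:to, , , ] <- g
    list(dz)
  })
}

# per-channel bias over (C, H, W, N): plain vector recycling
ag_bias_c <- function(x, b) {
  xv <- ag_v(x); bv <- as.numeric(ag_v(b))
  d <- dim(xv)
  C <- d[1]
  ag_op(xv + bv, list(x, b), function(g) {
    gb <- NULL
    if (is_ag(b) && b$rq) {
      gm <- g
      dim(gm) <- c(C, length(g) %/% C)
      gb <- rowSums(gm)
    }
    list(g, gb)
  })
}

# ---- batch normalization ---------------------------------------------------

# Training mode normalizes with batch statistics over (H, W, N) per channel
# and updates the running buffers in place; eval mode uses the buffers.
ag_batchnorm <- function(x, gamma, beta, rm, rv, training = FALSE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ag_v(x)
  d <- dim(xv)
  C <- d[1]
  m <- length(xv) %/% C
  gv <- as.numeric(ag_v(gamma)); bv <- as.numeric(ag_v(beta))
  xm <- xv
  dim(xm) <- c(C, m)
  if (training) {
    mu <- rowSums(xm) / m
    xc <- xv - mu
    xcm <- xc
    dim(xcm) <- c(C, m)
    va <- rowSums(xcm * xcm) / m
    rm$value <- (1 - momentum) * rm$value + momentum * mu
    rv$value <- (1 - momentum) * rv$value + momentum * va * m / max(m - 1, 1)
  } else {
    mu <- as.numeric(rm$value)
    va <- as.numeric(rv$value)
    xc <- xv - mu
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  v <- gv * xhat + bv
  ag_op(v, list(x, gamma, beta), function(g) {
    per_c <- function(a) { dim(a) <- c(C, m); rowSums(a) }
    dgamma <- per_c(g * xhat)
    dbeta <- per_c(g)
    gx <- NULL
    if (is_ag(x) && x$rq) {
      if (training) {
        gx <- (gv * istd) * (g - dbeta / m - xhat * (dgamma / m))
      } else {
        gx <- (gv * istd) * g
      }
    }
    list(gx, dgamma, dbeta)
  })
}

# ---- pooling / resampling --------------------------------------------------

# k x k max pool, stride 1, same padding
ag_maxpool_same <- function(x, k) {
  xv <- ag_v(x)
  d <- dim(xv)
  H <- d[2]; W <- d[3]
  p <- (k - 1L) %/% 2L
  xp <- pad_chw(xv, p, p, fill = -Inf)
  out <- array(-Inf, d)
  for (th in seq_len(k)) {
    ri <- (th - 1L) + seq_len(H)
    for (tw in seq_len(k)) {
      ci <- (tw - 1L) + seq_len(W)
      out <- pmax(out, xp[, ri, ci, , drop = FALSE])
    }
  }
  ag_op(out, list(x), function(g) {
    dxp <- array(0, dim(xp))
    for (th in seq_len(k)) {
      ri <- (th - 1L) + seq_len(H)
      for (tw in seq_len(k)) {
        ci <- (tw - 1L) + seq_len(W)
        sl <- xp[, ri, ci, , drop = FALSE]
        dxp[, ri, ci, ] <- dxp[, ri, ci, , drop = FALSE] + g * (sl == out)
      }
    }
    list(unpad_chw(dxp, p, p, H, W))
  })
}

# adaptive average pool to a g x g grid (clamped to the input size)
ag_avgpool_adaptive <- function(x, g) {
  xv <- ag_v(x)
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  g <- min(g, H, W)
  rs <- floor((seq_len(g) - 1L) * H / g) + 1L
  re <- ceiling(seq_len(g) * H / g)
  cs <- floor((seq_len(g) - 1L) * W / g) + 1L
  ce <- ceiling(seq_len(g) * W / g)
  out <- array(0, c(C, g, g, N))
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      sl <- xv[, rs[i]:re[i], cs[j]:ce[j], , drop = FALSE]
      nb <- (re[i] - rs[i] + 1L) * (ce[j] - cs[j] + 1L)
      dim(sl) <- c(C * nb, N)
      acc <- matrix(0, C, N)
      for (b in seq_len(nb)) acc <- acc + sl[(b - 1L) * C + seq_len(C), , drop = FALSE]
      out[, i, j, ] <- acc / nb
    }
  }
  ag_op(out, list(x), function(gr) {
    dx <- array(0, d)
    for (i in seq_len(g)) {
      for (j in seq_len(g)) {
        nb <- (re[i] - rs[i] + 1L) * (ce[j] - cs[j] + 1L)
        gij <- gr[, i, j, ] / nb               # (C, N)
        nr <- re[i] - rs[i] + 1L; ncl <- ce[j] - cs[j] + 1L
        add <- array(0, c(C, nr, ncl, N))
        for (n in seq_len(N)) add[, , , n] <- gij[, n]
        dx[, rs[i]:re[i], cs[j]:ce[j], ] <-
          dx[, rs[i]:re[i], cs[j]:ce[j], , drop = FALSE] + add
      }
    }
    list(dx)
  })
}

# nearest-neighbour 2x upsampling
ag_upsample2 <- function(x) {
  xv <- ag_v(x)
  d <- dim(xv)
  H <- d[2]; W <- d[3]
  ri <- rep(seq_len(H), each = 2L)
  ci <- rep(seq_len(W), each = 2L)
  out <- xv[, ri, ci, , drop = FALSE]
  ag_op(out, list(x), function(g) {
    o1 <- seq(1L, 2L * H, by = 2L); o2 <- o1 + 1L
    e1 <- seq(1L, 2L * W, by = 2L); e2 <- e1 + 1L
    list(g[, o1, e1, , drop = FALSE] + g[, o2, e1, , drop = FALSE] +
           g[, o1, e2, , drop = FALSE] + g[, o2, e2, , drop = FALSE])
  })
}

# broadcast a (C, g, g, N) gate to (C, H, W, N) by nearest-neighbour mapping
ag_gate_upsample <- function(gate, H, W) {
  gv <- ag_v(gate)
  d <- dim(gv)
  g1 <- d[2]; g2 <- d[3]
  ri <- floor((seq_len(H) - 1L) * g1 / H) + 1L
  ci <- floor((seq_len(W) - 1L) * g2 / W) + 1L
  out <- gv[, ri, ci, , drop = FALSE]
  ag_op(out, list(gate), function(gr) {
    dg <- array(0, d)
    for (i in seq_len(g1)) {
      for (j in seq_len(g2)) {
        rows <- which(ri == i); cols <- which(ci == j)
        sl <- gr[, rows, cols, , drop = FALSE]
        nb <- length(rows) * length(cols)
        dim(sl) <- c(d[1] * nb, d[4])
        acc <- matrix(0, d[1], d[4])
        for (b in seq_len(nb)) acc <- acc + sl[(b - 1L) * d[1] + seq_len(d[1]), , drop = FALSE]
        dg[, i, j, ] <- acc
      }
    }
    list(dg)
  })
}

# 1-D convolution across the channel axis of a pooled (C, g, g, N) block,
# zero padding, single filter `w` of odd length k plus scalar bias.
ag_chan_conv1d <- function(p, w, b) {
  pv <- ag_v(p); wv <- as.numeric(ag_v(w)); bv <- as.numeric(ag_v(b))
  d <- dim(pv)
  C <- d[1]
  k <- length(wv)
  off <- (k - 1L) %/% 2L
  out <- array(bv, d)
  for (j in seq_len(k)) {
    sh <- j - 1L - off                        # channel shift
    src <- seq_len(C) + sh
    ok <- src >= 1L & src <= C
    out[which(ok), , , ] <- out[which(ok), , , , drop = FALSE] +
      wv[j] * pv[src[ok], , , , drop = FALSE]
  }
  ag_op(out, list(p, w, b), function(g) {
    gp <- NULL
    gw <- numeric(k)
    for (j in seq_len(k)) {
      sh <- j - 1L - off
      src <- seq_len(C) + sh
      ok <- src >= 1L & src <= C
      gw[j] <- sum(g[which(ok), , , , drop = FALSE] * pv[src[ok], , , , drop = FALSE])
    }
    if (is_ag(p) && p$rq) {
      gp <- array(0, d)
      for (j in seq_len(k)) {
        sh <- j - 1L - off
        src <- seq_len(C) + sh
        ok <- src >= 1L & src <= C
        gp[src[ok], , , ] <- gp[src[ok], , , , drop = FALSE] +
          wv[j] * g[which(ok), , , , drop = FALSE]
      }
    }
    list(gp, gw, sum(g))
  })
}

# ---- head / loss helpers ---------------------------------------------------

ag_softmax_rows <- function(x) {
  xv <- ag_v(x)
  mx <- xv[cbind(seq_len(nrow(xv)), max.col(xv, ties.method = "first"))]
  e <- exp(xv - mx)
  s <- e / rowSums(e)
  ag_op(s, list(x), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

# rows of x (n x k) dotted with a fixed vector v -> length-n vector
ag_matvec <- function(x, v) {
  xv <- ag_v(x)
  vv <- as.numeric(ag_v(v))
  ag_op(as.numeric(xv %*% vv), list(x), function(g) {
    list(outer(as.numeric(g), vv))
  })
}

# weighted sum of binary cross-entropies with logits; `t`, `w` constants
ag_bce_sum <- function(x, t, w = 1) {
  xv <- ag_v(x); tv <- ag_v(t); wv <- ag_v(w)
  l <- pmax(xv, 0) - xv * tv + log1p(exp(-abs(xv)))
  ag_op(sum(wv * l), list(x), function(g) {
    list(as.numeric(g) * wv * (stats::plogis(xv) - tv))
  })
}

# Distribution-focal cross-entropy: softmax over reg_max bins per row, target
# spread over the two bins bracketing the continuous distance.  `tl`/`tr` are
# 1-based bin columns, `wl`/`wr` their weights, `w_row` per-row loss weights.
ag_dfl_ce <- function(x, tl, tr, wl, wr, w_row) {
  xv <- ag_v(x)
  n <- nrow(xv)
  mx <- xv[cbind(seq_len(n), max.col(xv, ties.method = "first"))]
  e <- exp(xv - mx)
  s <- e / rowSums(e)
  eps <- 1e-12
  v <- sum(w_row * (-wl * log(s[cbind(seq_len(n), tl)] + eps) -
                      wr * log(s[cbind(seq_len(n), tr)] + eps)))
  ag_op(v, list(x), function(g) {
    tgt <- matrix(0, n, ncol(xv))
    tgt[cbind(seq_len(n), tl)] <- tgt[cbind(seq_len(n), tl)] + wl
    tgt[cbind(seq_len(n), tr)] <- tgt[cbind(seq_len(n), tr)] + wr
    list(as.numeric(g) * w_row * (s - tgt))
  })
}
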