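# Independent closed-form parameter accounting, written directly from the
# block definitions (never from the package's counters).  Convention:
# convolutions are bias-free with a trainable scale+shift normalization pair
# per output channel unless stated otherwise.

o_conv <- function(cin, cout, k = 1, g = 1, norm = TRUE, bias = !norm) {
  k <- if (length(k) == 1L) c(k, k) else k
  n <- cin / g * cout * k[1] * k[2]
  if (norm) n <- n + 2 * cout
  if (bias) n <- n + cout
  n
}

o_bottleneck <- function(c1, c2, e = 1) {
  ch <- round(c2 * e)
  o_conv(c1, ch, 3) + o_conv(ch, c2, 3)
}

o_c2f <- function(c1, c2, n) {
  c <- c2 %/% 2
  o_conv(c1, 2 * c, 1) + n * o_bottleneck(c, c) + o_conv((2 + n) * c, c2, 1)
}

o_c2 <- function(c1, c2, n) {
  c <- c2 %/% 2
  o_conv(c1, 2 * c, 1) + n * o_bottleneck(c, c) + o_conv(2 * c, c2, 1)
}

o_sppf <- function(c1, c2) {
  ch <- c1 %/% 2
  o_conv(c1, ch, 1) + o_conv(4 * ch, c2, 1)
}

o_lse <- function(k = 3) k + 1

# bias-free separable large-kernel attention (local 3-taps, dilated 5-taps,
# pointwise mix)
o_lska <- function(dim, local_k = 3, dil_k = 5) {
  2 * dim * local_k + 2 * dim * dil_k + dim * dim
}

o_sppf_lska <- function(c1, c2) {
  ch <- c1 %/% 2
  o_conv(c1, ch, 1) + o_lska(4 * ch) + o_conv(4 * ch, c2, 1)
}

# default MGEFA: 1x1 depthwise branch + 3x3 depthwise branch, each with
# norm + LSE gate
o_mgefa <- function(c, lse_k = 3) {
  (o_conv(c, c, 1, g = c) + o_lse(lse_k)) + (o_conv(c, c, 3, g = c) + o_lse(lse_k))
}

o_detect_branch <- function(cin, cmid, cfinal) {
  o_conv(cin, cmid, 3) + o_conv(cmid, cmid, 3) +
    o_conv(cmid, cfinal, 1, norm = FALSE, bias = TRUE)
}

o_detect <- function(nc, ch, reg_max = 16) {
  c2 <- max(16, ch[1] %/% 4, 4 * reg_max)
  c3 <- max(ch[1], min(nc, 100))
  sum(vapply(ch, function(ci) {
    o_detect_branch(ci, c2, 4 * reg_max) + o_detect_branch(ci, c3, nc)
  }, numeric(1)))
}

# full-model oracle: walk the graph but price every node from the closed
# forms above using only its hyper-parameters
o_model_params <- function(model) {
  price <- function(m) {
    if (inherits(m, "ev_conv")) {
      o_conv(m$cin, m$cout, m$k, m$g, norm = m$norm, bias = m$bias)
    } else if (inherits(m, "ev_c2f")) {
      o_c2f(m$c1, m$c2, m$n)
    } else if (inherits(m, "ev_c2")) {
      o_c2(m$c1, m$c2, m$n)
    } else if (inherits(m, "ev_sppf")) {
      o_sppf(m$c1, m$c2)
    } else if (inherits(m, "ev_sppf_lska")) {
      o_sppf_lska(m$c1, m$c2)
    } else if (inherits(m, "ev_mgefac2f")) {
      o_c2f(m$c1, m$c2, m$c2f$n) + o_mgefa(m$c2)
    } else if (inherits(m, "ev_detect")) {
      o_detect(m$nc, m$ch, m$reg_max)
    } else if (inherits(m, "ev_upsample") || inherits(m, "ev_concat")) {
      0
    } else {
      stop("oracle cannot price module of class ", class(m)[1])
    }
  }
  sum(vapply(model$nodes, function(nd) price(nd$m), numeric(1)))
}
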