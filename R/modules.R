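# Network building blocks.
#
# Modules are plain lists (class c("ev_<kind>", "ev_module")) holding their
# hyper-parameters and `ev_par` environments for every learnable array.
# Three generic surfaces are defined over the same structure:
#   * construction (this file)       -- allocates and initializes weights,
#   * ev_flops()   (this file)       -- closed-form FLOP accounting,
#   * ev_forward() (R/forward.R)     -- the numeric forward pass.
# Trainable-parameter counting is not per-module arithmetic: it walks the
# allocated arrays (see count_parameters), so tests can check it against an
# independent closed-form summation.

new_module <- function(kind, fields) {
  structure(fields, class = c(paste0("ev_", kind), "ev_module"))
}

#' @export
print.ev_module <- function(x, ...) {
  cat("<", class(x)[1], ": ", format(n_trainable(collect_pars(x)), big.mark = ","),
      " trainable parameters>\n", sep = "")
  invisible(x)
}

norm_kernel <- function(k) {
  if (length(k) == 1L) c(k, k) else as.integer(k)
}

#' Convolution block (conv + batch norm + activation)
#'
#' The basic unit all larger blocks are assembled from: a bias-free 2-D
#' convolution with "same" padding, per-channel batch normalization
#' (scale and shift are trainable; running statistics are buffers) and a
#' pointwise activation.  Stride 1 preserves spatial dimensions exactly;
#' stride 2 halves them (ceiling division for odd inputs).
#'
#' @param cin,cout input/output channel counts.
#' @param k kernel size, a scalar odd integer or a `(kh, kw)` pair.
#' @param s stride, 1 or 2.
#' @param g group count; must divide both `cin` and `cout`.
#' @param d dilation.
#' @param act one of `"silu"`, `"relu"`, `"none"`.
#' @param norm include batch normalization (TRUE for all backbone/neck convs;
#'   FALSE for the raw prediction convolutions in the head and the attention
#'   projections, which carry a bias instead).
#' @param bias include an additive bias (default: only when `norm` is FALSE).
#' @return an `ev_module`.
#' @keywords internal
ev_conv <- function(cin, cout, k = 1, s = 1, g = 1, d = 1,
                    act = "silu", norm = TRUE, bias = !norm) {
  k <- norm_kernel(k)
  if (cin %% g != 0 || cout %% g != 0) {
    stop(sprintf("groups (%d) must divide both cin (%d) and cout (%d)", g, cin, cout))
  }
  if (!s %in% c(1L, 2L)) stop("stride must be 1 or 2")
  if (any(k %% 2 == 0)) stop("kernels must be odd for same padding")
  if (!act %in% c("silu", "relu", "none")) stop("unknown activation: ", act)
  fan_in <- (cin / g) * prod(k)
  pars <- list(w = par_kaiming(c(cout, cin / g, k[1], k[2]), fan_in))
  if (norm) {
    pars$bn_g <- par_new(cout, array(1, cout))
    pars$bn_b <- par_new(cout, array(0, cout))
    pars$bn_rm <- par_new(cout, array(0, cout), trainable = FALSE)
    pars$bn_rv <- par_new(cout, array(1, cout), trainable = FALSE)
  }
  if (bias) pars$b <- par_new(cout, array(0, cout))
  new_module("conv", list(cin = cin, cout = cout, k = k, s = s, g = g, d = d,
                          act = act, norm = norm, bias = bias, pars = pars))
}

#' Residual bottleneck: two 3x3 convolutions with optional identity skip.
#' Hidden width is `round(c2 * e)`; the split-concat blocks use e = 1.
#' @keywords internal
ev_bottleneck <- function(c1, c2, shortcut = TRUE, e = 1.0) {
  ch <- as.integer(round(c2 * e))
  new_module("bottleneck", list(
    c1 = c1, c2 = c2, add = shortcut && c1 == c2,
    cv1 = ev_conv(c1, ch, 3), cv2 = ev_conv(ch, c2, 3)))
}

#' C2f block: split-transform-concat with dense intermediate reuse
#'
#' A 1x1 convolution expands to `2c` hidden channels (`c = c2 %/% 2`), the
#' halves are split, `n` bottlenecks are chained on the second half, and the
#' split plus every intermediate output (`(2+n)c` channels) are concatenated
#' before a final 1x1 fusion to `c2` channels.
#' @keywords internal
ev_c2f <- function(c1, c2, n = 1, shortcut = FALSE) {
  if (n < 1) stop("c2f requires n >= 1 bottlenecks")
  c <- c2 %/% 2L
  new_module("c2f", list(
    c1 = c1, c2 = c2, c = c, n = n,
    cv1 = ev_conv(c1, 2L * c, 1),
    m = lapply(seq_len(n), function(i) ev_bottleneck(c, c, shortcut, e = 1.0)),
    cv2 = ev_conv((2L + n) * c, c2, 1)))
}

#' C2 block: the cheaper split-transform-concat variant
#'
#' Identical split and bottleneck chain, but only the two halves (the
#' untouched split and the final bottleneck output) are concatenated, so the
#' fusion convolution sees `2c` channels regardless of `n`.  Used in the
#' four-level neck, where feature maps are deep but coarse.
#' @keywords internal
ev_c2 <- function(c1, c2, n = 1, shortcut = FALSE) {
  if (n < 1) stop("c2 requires n >= 1 bottlenecks")
  c <- c2 %/% 2L
  new_module("c2", list(
    c1 = c1, c2 = c2, c = c, n = n,
    cv1 = ev_conv(c1, 2L * c, 1),
    m = lapply(seq_len(n), function(i) ev_bottleneck(c, c, shortcut, e = 1.0)),
    cv2 = ev_conv(2L * c, c2, 1)))
}

#' SPPF: spatial pyramid pooling (fast)
#'
#' Three cascaded k x k stride-1 max pools; concatenating the pre-pool hidden
#' map with the three pooled maps is equivalent to pooling with kernels
#' k, 2k-1, 3k-2 directly (5, 9, 13 for the default k = 5).
#' @keywords internal
ev_sppf <- function(c1, c2, k = 5) {
  if (k %% 2 == 0) stop("sppf pool kernel must be odd")
  ch <- c1 %/% 2L
  new_module("sppf", list(
    c1 = c1, c2 = c2, ch = ch, pool_k = as.integer(k),
    cv1 = ev_conv(c1, ch, 1),
    cv2 = ev_conv(4L * ch, c2, 1)))
}

#' LSE: localized spatial-channel attention gate
#'
#' Pools the map to a coarse `g x g` grid, runs a 1-D convolution of span `k`
#' along the channel axis of each pooled cell, squashes through a sigmoid and
#' rescales the input by the (nearest-neighbour upsampled) gate.
#' @keywords internal
ev_lse <- function(channels, pool_grid = 4, channel_kernel = 3) {
  if (channel_kernel %% 2 == 0) stop("LSE channel kernel must be odd")
  if (pool_grid < 1) stop("LSE pool grid must be >= 1")
  if (channels < channel_kernel) {
    stop(sprintf("LSE needs channels (%d) >= channel kernel (%d)", channels, channel_kernel))
  }
  new_module("lse", list(
    channels = channels, g = as.integer(pool_grid), k = as.integer(channel_kernel),
    pars = list(w = par_new(channel_kernel, array(0, channel_kernel)),
                b = par_new(1, array(0, 1)))))
}

#' MGEFA: multi-branch group-enhanced fusion attention
#'
#' Parallel channel-preserving branches (by default a pointwise grouped
#' convolution and a 3x3 depthwise convolution, each with batch norm + ReLU),
#' each gated by an LSE attention block; branch outputs are summed and fused
#' with the input through a residual connection, so zeroed branch weights
#' reduce the block to the identity.
#'
#' @param channels channel count (preserved).
#' @param branch_specs list of lists with fields `k` (kernel) and `g` (groups);
#'   defaults to a pointwise per-channel branch and a 3x3 depthwise branch.
#' @param pool_grid,channel_kernel LSE configuration.
#' @keywords internal
ev_mgefa <- function(channels, branch_specs = NULL, pool_grid = 4, channel_kernel = 3) {
  if (is.null(branch_specs)) {
    branch_specs <- list(list(k = 1, g = channels), list(k = 3, g = channels))
  }
  if (length(branch_specs) < 2) stop("MGEFA requires at least two branches")
  branches <- lapply(branch_specs, function(sp) {
    g <- if (is.null(sp$g)) channels else min(sp$g, channels)
    list(conv = ev_conv(channels, channels, k = sp$k, g = g, act = "relu"),
         lse = ev_lse(channels, pool_grid, channel_kernel))
  })
  new_module("mgefa", list(channels = channels, branches = branches))
}

#' MGEFAC2f: C2f followed by MGEFA attention over its output.
#' @keywords internal
ev_mgefac2f <- function(c1, c2, n = 1, shortcut = FALSE, ...) {
  new_module("mgefac2f", list(
    c1 = c1, c2 = c2,
    c2f = ev_c2f(c1, c2, n, shortcut),
    mgefa = ev_mgefa(c2, ...)))
}

#' LSKA: large separable kernel attention
#'
#' A large 2-D depthwise kernel (effective receptive field `K`) factored into
#' sequential horizontal and vertical 1-D depthwise convolutions -- a local
#' pair of span `local_k` and a dilated pair of span `dil_k` with dilation
#' `dilation` -- followed by a 1x1 channel-mixing convolution.  The result is
#' used as a multiplicative attention map over the input.  All projections
#' are bias-free: constant offsets in an attention map are absorbed by the
#' normalization of the fusion convolution that follows the gate.
#' @keywords internal
ev_lska <- function(dim, K = 11, local_k = 3, dil_k = 5, dilation = 2) {
  eff <- local_k + dilation * (dil_k - 1)
  if (eff < K) {
    stop(sprintf("LSKA decomposition covers %d < requested field %d", eff, K))
  }
  mk <- function(kh, kw, d) ev_conv(dim, dim, k = c(kh, kw), g = dim, d = d,
                                    act = "none", norm = FALSE, bias = FALSE)
  new_module("lska", list(
    dim = dim, K = K, local_k = local_k, dil_k = dil_k, dilation = dilation,
    conv0h = mk(1, local_k, 1), conv0v = mk(local_k, 1, 1),
    convsh = mk(1, dil_k, dilation), convsv = mk(dil_k, 1, dilation),
    conv1 = ev_conv(dim, dim, 1, act = "none", norm = FALSE, bias = FALSE)))
}

#' SPPF with LSKA attention over the concatenated pyramid
#'
#' Identical to [ev_sppf()] except the 4-way concatenated hidden map passes
#' through an LSKA attention block before the final 1x1 fusion.
#' @keywords internal
ev_sppf_lska <- function(c1, c2, k = 5, K = 11) {
  if (k %% 2 == 0) stop("sppf pool kernel must be odd")
  ch <- c1 %/% 2L
  new_module("sppf_lska", list(
    c1 = c1, c2 = c2, ch = ch, pool_k = as.integer(k),
    cv1 = ev_conv(c1, ch, 1),
    lska = ev_lska(4L * ch, K = K),
    cv2 = ev_conv(4L * ch, c2, 1)))
}

#' Nearest-neighbour 2x upsampling (no parameters).
#' @keywords internal
ev_upsample <- function() new_module("upsample", list())

#' Channel concatenation (no parameters).
#' @keywords internal
ev_concat <- function() new_module("concat", list())

#' Decoupled anchor-free detection head
#'
#' Per pyramid level, two independent 3x3-3x3-1x1 convolution stacks emit
#' class logits (`nc` channels) and discretized box-distribution logits
#' (`4 * reg_max` channels).  Box decoding takes the expectation of the
#' softmaxed distribution over bin offsets 0..reg_max-1 (a fixed,
#' non-trainable projection), giving left/top/right/bottom distances from the
#' anchor point in stride units.
#' @keywords internal
ev_detect <- function(nc, ch, strides, reg_max = 16) {
  if (anyDuplicated(strides)) stop("detection strides must be distinct")
  if (is.unsorted(strides)) stop("detection inputs must be ordered by increasing stride")
  c2 <- max(16L, ch[1] %/% 4L, 4L * reg_max)
  c3 <- max(ch[1], min(nc, 100L))
  mk_branch <- function(cin, cmid, cfinal) list(
    ev_conv(cin, cmid, 3),
    ev_conv(cmid, cmid, 3),
    ev_conv(cmid, cfinal, 1, act = "none", norm = FALSE, bias = TRUE))
  box <- lapply(ch, function(ci) mk_branch(ci, c2, 4L * reg_max))
  cls <- lapply(ch, function(ci) mk_branch(ci, c3, nc))
  # classification priors: start detections sparse so early training is stable
  for (br in cls) br[[3]]$pars$b$value[] <- stats::qlogis(0.01)
  for (br in box) br[[3]]$pars$b$value[] <- 1
  new_module("detect", list(
    nc = nc, ch = ch, strides = strides, reg_max = reg_max, c2 = c2, c3 = c3,
    box = box, cls = cls,
    proj = par_new(reg_max, array(seq_len(reg_max) - 1, reg_max), trainable = FALSE)))
}

# ---------------------------------------------------------------------------
# FLOP accounting.
#
# Convention (the one under which the family's printed baseline numbers are
# reproducible): 2 FLOPs per convolution multiply-accumulate, batch norm
# fused into the convolution, batch 1.  Pooling, activations and elementwise
# arithmetic are counted at 1 FLOP per produced element (k^2 per element for
# max pools); these terms are two orders of magnitude below the convolution
# term.  Spatial bookkeeping: stride-2 convs emit ceil(h/2) x ceil(w/2).

ev_flops <- function(m, h, w, ...) UseMethod("ev_flops")

fl_out <- function(fl, h, w) list(fl = fl, h = h, w = w)

#' @export
ev_flops.ev_conv <- function(m, h, w, ...) {
  ho <- ceiling(h / m$s); wo <- ceiling(w / m$s)
  fl <- 2 * prod(m$k) * (m$cin / m$g) * m$cout * ho * wo
  if (m$bias) fl <- fl + m$cout * ho * wo
  if (m$act != "none") fl <- fl + m$cout * ho * wo
  fl_out(fl, ho, wo)
}

#' @export
ev_flops.ev_bottleneck <- function(m, h, w, ...) {
  fl <- ev_flops(m$cv1, h, w)$fl + ev_flops(m$cv2, h, w)$fl
  if (m$add) fl <- fl + m$c2 * h * w
  fl_out(fl, h, w)
}

#' @export
ev_flops.ev_c2f <- function(m, h, w, ...) {
  fl <- ev_flops(m$cv1, h, w)$fl + ev_flops(m$cv2, h, w)$fl +
    sum(vapply(m$m, function(b) ev_flops(b, h, w)$fl, numeric(1)))
  fl_out(fl, h, w)
}

#' @export
ev_flops.ev_c2 <- ev_flops.ev_c2f

#' @export
ev_flops.ev_sppf <- function(m, h, w, ...) {
  fl <- ev_flops(m$cv1, h, w)$fl + ev_flops(m$cv2, h, w)$fl +
    3 * m$pool_k^2 * m$ch * h * w
  fl_out(fl, h, w)
}

#' @export
ev_flops.ev_lse <- function(m, h, w, ...) {
  g <- min(m$g, h, w)
  fl <- m$channels * h * w +                 # adaptive average pool (adds)
    2 * m$k * m$channels * g * g +           # 1-D conv across channels
    2 * m$channels * g * g +                 # bias + sigmoid
    m$channels * h * w                       # gating multiply
  fl_out(fl, h, w)
}

#' @export
ev_flops.ev_mgefa <- function(m, h, w, ...) {
  fl <- 0
  for (br in m$branches) {
    fl <- fl + ev_flops(br$conv, h, w)$fl + ev_flops(br$lse, h, w)$fl +
      m$channels * h * w                     # running sum of branch outputs
  }
  fl <- fl + m$channels * h * w              # residual add
  fl_out(fl, h, w)
}

#' @export
ev_flops.ev_mgefac2f <- function(m, h, w, ...) {
  fl_out(ev_flops(m$c2f, h, w)$fl + ev_flops(m$mgefa, h, w)$fl, h, w)
}

#' @export
ev_flops.ev_lska <- function(m, h, w, ...) {
  fl <- ev_flops(m$conv0h, h, w)$fl + ev_flops(m$conv0v, h, w)$fl +
    ev_flops(m$convsh, h, w)$fl + ev_flops(m$convsv, h, w)$fl +
    ev_flops(m$conv1, h, w)$fl +
    m$dim * h * w                            # attention multiply
  fl_out(fl, h, w)
}

#' @export
ev_flops.ev_sppf_lska <- function(m, h, w, ...) {
  fl <- ev_flops(m$cv1, h, w)$fl + ev_flops(m$cv2, h, w)$fl +
    3 * m$pool_k^2 * m$ch * h * w + ev_flops(m$lska, h, w)$fl
  fl_out(fl, h, w)
}

#' @export
ev_flops.ev_upsample <- function(m, h, w, ...) fl_out(0, 2L * h, 2L * w)

#' @export
ev_flops.ev_concat <- function(m, h, w, ...) fl_out(0, h, w)

# detect: `hw` is a list of (h, w) pairs, one per pyramid level.
#' @export
ev_flops.ev_detect <- function(m, h, w, hw = NULL, ...) {
  stopifnot(!is.null(hw))
  fl <- 0
  for (i in seq_along(m$ch)) {
    for (cv in c(m$box[[i]], m$cls[[i]])) {
      fl <- fl + ev_flops(cv, hw[[i]][1], hw[[i]][2])$fl
    }
  }
  fl_out(fl, h, w)
}
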