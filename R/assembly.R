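# Model assembly and structural profiling.
#
# A model is a flat graph of nodes (module + indices of its inputs), the same
# layout convention the YOLO family uses: a backbone chain, then a top-down /
# bottom-up path-aggregation neck whose concat nodes reach back into saved
# backbone features, then a multi-scale detection head.

#' Model configuration
#'
#' Describes one member of the detector family: the compound scale (depth /
#' width multiples), the three architectural toggles and the class count.
#'
#' @param scale one of `"n"`, `"s"`, `"m"` (depth/width multiples
#'   0.33/0.25, 0.33/0.50 and 0.67/0.75; the m scale caps widths at 768
#'   channels, n and s at 1024).
#' @param mgefa replace the backbone C2f stages with MGEFAC2f.
#' @param p6 add the stride-64 pyramid level: one extra backbone stage and a
#'   four-level neck built from C2 blocks, with a fourth detection scale.
#' @param lska replace SPPF with SPPF_LSKA (attention over the concatenated
#'   pooling pyramid, effective kernel `lska_k`).
#' @param nc number of object classes.
#' @param imgsz input image edge in pixels; must be divisible by the largest
#'   stride (32, or 64 when `p6`).
#' @param reg_max number of bins of the discretized box regression.
#' @param lska_k effective LSKA receptive field (odd).
#' @param lse_grid,lse_k LSE pooling grid and channel-kernel span used inside
#'   MGEFA.
#' @param seed integer seed used for weight initialization in [build_model()].
#' @return an object of class `ev_config`.
#' @export
#' @examples
#' cfg <- model_config("s", nc = 20)
#' cfg
model_config <- function(scale = c("s", "n", "m"), mgefa = FALSE, p6 = FALSE,
                         lska = FALSE, nc = 20, imgsz = 640, reg_max = 16,
                         lska_k = 11, lse_grid = 4, lse_k = 3, seed = 0) {
  scale <- match.arg(scale)
  mult <- switch(scale,
                 n = list(depth = 0.33, width = 0.25, max_ch = 1024L),
                 s = list(depth = 0.33, width = 0.50, max_ch = 1024L),
                 m = list(depth = 0.67, width = 0.75, max_ch = 768L))
  strides <- if (p6) c(8L, 16L, 32L, 64L) else c(8L, 16L, 32L)
  if (imgsz %% max(strides) != 0) {
    stop(sprintf("imgsz (%d) must be divisible by the largest stride (%d)",
                 imgsz, max(strides)))
  }
  if (nc < 1) stop("nc must be >= 1")
  structure(list(scale = scale, mgefa = isTRUE(mgefa), p6 = isTRUE(p6),
                 lska = isTRUE(lska), nc = as.integer(nc),
                 imgsz = as.integer(imgsz), reg_max = as.integer(reg_max),
                 depth_mult = mult$depth, width_mult = mult$width,
                 max_channels = mult$max_ch, strides = strides,
                 lska_k = as.integer(lska_k), lse_grid = as.integer(lse_grid),
                 lse_k = as.integer(lse_k), seed = as.integer(seed)),
            class = "ev_config")
}

#' @export
print.ev_config <- function(x, ...) {
  togs <- c(if (x$mgefa) "MGEFA", if (x$p6) "P6", if (x$lska) "LSKA")
  cat(sprintf("<ev_config scale=%s nc=%d imgsz=%d toggles=[%s]>\n",
              x$scale, x$nc, x$imgsz,
              if (length(togs)) paste(togs, collapse = ",") else "none"))
  invisible(x)
}

make_div <- function(x, div = 8L) as.integer(ceiling(x / div) * div)

cfg_width <- function(cfg, base) make_div(min(base, cfg$max_channels) * cfg$width_mult)
cfg_depth <- function(cfg, n) max(as.integer(round(n * cfg$depth_mult)), 1L)

#' Assemble a detector
#'
#' Builds the full network graph for a [model_config()]: backbone (stem +
#' stride-2 stages ending in the pooling block), path-aggregation neck and
#' decoupled detection head, with weights initialized from `cfg$seed`
#' (Kaiming-normal convolutions, unit-scale/zero-shift normalization).
#'
#' @param cfg an `ev_config`.
#' @return an object of class `ev_model`: `$cfg`, `$nodes` (graph),
#'   `$out_idx` (indices of the per-scale feature nodes feeding the head).
#' @export
#' @examples
#' m <- build_model(model_config("n", nc = 3, imgsz = 64))
#' count_parameters(m)
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "ev_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  nodes <- list()
  add <- function(module, from) {
    nodes[[length(nodes) + 1L]] <<- list(i = length(nodes) + 1L,
                                         from = as.integer(from), m = module)
    length(nodes)
  }
  # MGEFA placement rule: every backbone stage that exports a pyramid feature
  # to the neck, except the deepest one -- that stage feeds the (optionally
  # LSKA-augmented) pooling block, which already supplies attention for the
  # coarsest scale.  P3/P4 in the three-level model, P3/P4/P5 with P6 on.
  stage_block <- function(c1, c2, n, from, attn = FALSE) {
    if (cfg$mgefa && attn) {
      add(ev_mgefac2f(c1, c2, n, shortcut = TRUE,
                      pool_grid = cfg$lse_grid, channel_kernel = cfg$lse_k), from)
    } else {
      add(ev_c2f(c1, c2, n, shortcut = TRUE), from)
    }
  }
  pool_block <- function(ch, from) {
    if (cfg$lska) add(ev_sppf_lska(ch, ch, K = cfg$lska_k), from)
    else add(ev_sppf(ch, ch), from)
  }

  w <- vapply(c(64, 128, 256, 512), function(b) cfg_width(cfg, b), integer(1))
  n1 <- cfg_depth(cfg, 3); n2 <- cfg_depth(cfg, 6)

  if (!cfg$p6) {
    w5 <- cfg_width(cfg, 1024)
    i0 <- add(ev_conv(3, w[1], 3, 2), 0)                    # P1/2
    i1 <- add(ev_conv(w[1], w[2], 3, 2), i0)                # P2/4
    i2 <- stage_block(w[2], w[2], n1, i1)
    i3 <- add(ev_conv(w[2], w[3], 3, 2), i2)                # P3/8
    i4 <- stage_block(w[3], w[3], n2, i3, attn = TRUE)
    i5 <- add(ev_conv(w[3], w[4], 3, 2), i4)                # P4/16
    i6 <- stage_block(w[4], w[4], n2, i5, attn = TRUE)
    i7 <- add(ev_conv(w[4], w5, 3, 2), i6)                  # P5/32
    i8 <- stage_block(w5, w5, n1, i7)
    i9 <- pool_block(w5, i8)
    # top-down
    i10 <- add(ev_upsample(), i9)
    i11 <- add(ev_concat(), c(i10, i6))
    i12 <- add(ev_c2f(w5 + w[4], w[4], n1, FALSE), i11)
    i13 <- add(ev_upsample(), i12)
    i14 <- add(ev_concat(), c(i13, i4))
    i15 <- add(ev_c2f(w[4] + w[3], w[3], n1, FALSE), i14)   # out P3
    # bottom-up
    i16 <- add(ev_conv(w[3], w[3], 3, 2), i15)
    i17 <- add(ev_concat(), c(i16, i12))
    i18 <- add(ev_c2f(w[3] + w[4], w[4], n1, FALSE), i17)   # out P4
    i19 <- add(ev_conv(w[4], w[4], 3, 2), i18)
    i20 <- add(ev_concat(), c(i19, i9))
    i21 <- add(ev_c2f(w[4] + w5, w5, n1, FALSE), i20)       # out P5
    out_idx <- c(i15, i18, i21)
    ch_out <- c(w[3], w[4], w5)
  } else {
    w5 <- cfg_width(cfg, 768)                               # P5 stage width
    w6 <- cfg_width(cfg, 1024)                              # P6 stage width
    i0 <- add(ev_conv(3, w[1], 3, 2), 0)
    i1 <- add(ev_conv(w[1], w[2], 3, 2), i0)
    i2 <- stage_block(w[2], w[2], n1, i1)
    i3 <- add(ev_conv(w[2], w[3], 3, 2), i2)
    i4 <- stage_block(w[3], w[3], n2, i3, attn = TRUE)      # P3/8
    i5 <- add(ev_conv(w[3], w[4], 3, 2), i4)
    i6 <- stage_block(w[4], w[4], n2, i5, attn = TRUE)      # P4/16
    i7 <- add(ev_conv(w[4], w5, 3, 2), i6)
    i8 <- stage_block(w5, w5, n1, i7, attn = TRUE)          # P5/32
    i9 <- add(ev_conv(w5, w6, 3, 2), i8)
    i10 <- stage_block(w6, w6, n1, i9)                      # P6/64
    i11 <- pool_block(w6, i10)
    # top-down (C2 blocks in the four-level neck)
    i12 <- add(ev_upsample(), i11)
    i13 <- add(ev_concat(), c(i12, i8))
    i14 <- add(ev_c2(w6 + w5, w5, n1, FALSE), i13)
    i15 <- add(ev_upsample(), i14)
    i16 <- add(ev_concat(), c(i15, i6))
    i17 <- add(ev_c2(w5 + w[4], w[4], n1, FALSE), i16)
    i18 <- add(ev_upsample(), i17)
    i19 <- add(ev_concat(), c(i18, i4))
    i20 <- add(ev_c2(w[4] + w[3], w[3], n1, FALSE), i19)    # out P3
    # bottom-up
    i21 <- add(ev_conv(w[3], w[3], 3, 2), i20)
    i22 <- add(ev_concat(), c(i21, i17))
    i23 <- add(ev_c2(w[3] + w[4], w[4], n1, FALSE), i22)    # out P4
    i24 <- add(ev_conv(w[4], w[4], 3, 2), i23)
    i25 <- add(ev_concat(), c(i24, i14))
    i26 <- add(ev_c2(w[4] + w5, w5, n1, FALSE), i25)        # out P5
    i27 <- add(ev_conv(w5, w5, 3, 2), i26)
    i28 <- add(ev_concat(), c(i27, i11))
    i29 <- add(ev_c2(w5 + w6, w6, n1, FALSE), i28)          # out P6
    out_idx <- c(i20, i23, i26, i29)
    ch_out <- c(w[3], w[4], w5, w6)
  }
  ih <- add(ev_detect(cfg$nc, ch_out, cfg$strides, cfg$reg_max), out_idx)

  structure(list(cfg = cfg, nodes = nodes, out_idx = out_idx,
                 head_idx = ih, ch_out = ch_out),
            class = "ev_model")
}

#' @export
print.ev_model <- function(x, ...) {
  cat(sprintf("<ev_model %s: %d nodes, %s trainable parameters (%.1f M)>\n",
              x$cfg$scale, length(x$nodes),
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

model_pars <- function(model) {
  do.call(c, lapply(model$nodes, function(nd) collect_pars(nd$m)))
}

#' Count trainable parameters
#'
#' Walks every allocated weight array of the assembled model and sums the
#' lengths of the trainable ones (convolution kernels, biases, normalization
#' scale/shift).  Buffers (running statistics, the fixed box-bin projection)
#' are excluded.
#'
#' @param model an `ev_model`.
#' @return exact integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ev_model"))
  n_trainable(model_pars(model))
}

#' Count inference FLOPs
#'
#' Closed-form FLOP count for a single image at `imgsz` x `imgsz`:
#' 2 FLOPs per convolution multiply-accumulate with normalization fused,
#' plus the (small) pooling and elementwise terms.
#'
#' @param model an `ev_model`.
#' @param imgsz input edge in pixels (defaults to the configured size).
#' @return FLOPs in units of 1e9 (GFLOPs).
#' @export
count_flops <- function(model, imgsz = model$cfg$imgsz) {
  stopifnot(inherits(model, "ev_model"))
  if (imgsz %% max(model$cfg$strides) != 0) {
    stop(sprintf("imgsz (%d) must be divisible by the largest stride (%d)",
                 imgsz, max(model$cfg$strides)))
  }
  hw <- vector("list", length(model$nodes))
  total <- 0
  for (nd in model$nodes) {
    if (inherits(nd$m, "ev_detect")) {
      r <- ev_flops(nd$m, 0, 0, hw = hw[nd$from])
    } else if (inherits(nd$m, "ev_concat")) {
      r <- do.call(fl_out, c(list(0), as.list(hw[[nd$from[1]]])))
    } else {
      at <- if (nd$from[1] == 0L) c(imgsz, imgsz) else hw[[nd$from[1]]]
      r <- ev_flops(nd$m, at[1], at[2])
    }
    hw[[nd$i]] <- c(r$h, r$w)
    total <- total + r$fl
  }
  total / 1e9
}

#' Structural profile of one configuration
#'
#' @param cfg an `ev_config` (or an already built `ev_model`).
#' @param imgsz profiling input edge.
#' @return an `ev_profile`: exact parameter count, parameters in millions at
#'   one-decimal rounding, GFLOPs at one decimal, and a per-node breakdown.
#' @export
#' @examples
#' profile_model(model_config("n", nc = 20, imgsz = 64), imgsz = 64)
profile_model <- function(cfg, imgsz = NULL) {
  model <- if (inherits(cfg, "ev_model")) cfg else build_model(cfg)
  if (is.null(imgsz)) imgsz <- model$cfg$imgsz
  params <- count_parameters(model)
  gflops <- count_flops(model, imgsz)
  breakdown <- data.frame(
    node = vapply(model$nodes, function(nd) nd$i, integer(1)),
    kind = vapply(model$nodes, function(nd) sub("^ev_", "", class(nd$m)[1]), character(1)),
    params = vapply(model$nodes, function(nd) n_trainable(collect_pars(nd$m)), numeric(1)))
  stopifnot(sum(breakdown$params) == params)
  structure(list(cfg = model$cfg, params = params,
                 params_M = round(params / 1e6, 1),
                 gflops = round(gflops, 1), gflops_raw = gflops,
                 imgsz = imgsz, per_module = breakdown),
            class = "ev_profile")
}

#' @export
print.ev_profile <- function(x, ...) {
  togs <- c(if (x$cfg$mgefa) "MGEFA", if (x$cfg$p6) "P6", if (x$cfg$lska) "LSKA")
  cat(sprintf("%-28s %10s params  %5.1f M  %6.1f GFLOPs @ %d\n",
              sprintf("scale=%s [%s] nc=%d", x$cfg$scale,
                      if (length(togs)) paste(togs, collapse = "+") else "base", x$cfg$nc),
              format(x$params, big.mark = ","), x$params_M, x$gflops, x$imgsz))
  invisible(x)
}

#' Profile a grid of toggle combinations
#'
#' Builds one model per row and reports the structural numbers side by side,
#' mirroring an ablation table.
#'
#' @param rows a data frame with logical columns `mgefa`, `p6`, `lska`
#'   (missing columns default to FALSE) and optionally `scale`.
#' @param scale,nc,imgsz shared configuration for all rows.
#' @return a data frame with columns scale, mgefa, p6, lska, params,
#'   params_M, gflops.
#' @export
profile_grid <- function(rows, scale = "s", nc = 20, imgsz = 640) {
  rows <- as.data.frame(rows)
  for (col in c("mgefa", "p6", "lska")) if (is.null(rows[[col]])) rows[[col]] <- FALSE
  if (is.null(rows$scale)) rows$scale <- scale
  out <- lapply(seq_len(nrow(rows)), function(i) {
    pr <- profile_model(model_config(rows$scale[i], mgefa = rows$mgefa[i],
                                     p6 = rows$p6[i], lska = rows$lska[i],
                                     nc = nc, imgsz = imgsz))
    data.frame(scale = rows$scale[i], mgefa = rows$mgefa[i], p6 = rows$p6[i],
               lska = rows$lska[i], params = pr$params, params_M = pr$params_M,
               gflops = pr$gflops)
  })
  do.call(rbind, out)
}
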