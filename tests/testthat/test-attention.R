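# Attention blocks: LSE gating, MGEFA residual fusion, LSKA separable
# kernels and the LSKA-augmented pooling block.

test_that("LSE preserves shape and zeroed weights give the 0.5 gate", {
  m <- yoloev:::ev_lse(64, pool_grid = 4, channel_kernel = 3)
  x <- rnd_x(64, 32, 32)
  out <- fwd(m, x)
  expect_equal(dim(out), dim(x))
  # weights and bias are zero-initialized -> sigmoid(0) = 0.5 everywhere
  expect_equal(out, 0.5 * x, tolerance = 1e-12)
})

test_that("LSE gates are strictly inside (0, 1) so |output| <= |input|", {
  m <- yoloev:::ev_lse(16, 4, 3)
  set.seed(2)
  m$pars$w$value[] <- rnorm(3)
  m$pars$b$value[] <- rnorm(1)
  for (seed in 1:5) {
    x <- rnd_x(16, 9, 7, seed = seed)
    out <- fwd(m, x)
    expect_true(all(abs(out) <= abs(x)))
    gate <- out / ifelse(x == 0, 1, x)
    expect_true(all(gate[x != 0] > 0 & gate[x != 0] < 1))
  }
})

test_that("LSE clamps an oversized pooling grid with a warning", {
  m <- yoloev:::ev_lse(8, pool_grid = 4, channel_kernel = 3)
  expect_warning(fwd(m, rnd_x(8, 2, 2)), "clamp")
})

test_that("LSE validates its configuration", {
  expect_error(yoloev:::ev_lse(8, channel_kernel = 4), "odd")
  expect_error(yoloev:::ev_lse(2, channel_kernel = 3), "channels")
  expect_error(yoloev:::ev_lse(8, pool_grid = 0), "grid")
})

test_that("MGEFA is shape-preserving and reduces to the identity with zeroed branches", {
  m <- yoloev:::ev_mgefa(32)
  x <- rnd_x(32, 16, 16)
  expect_equal(dim(fwd(m, x)), dim(x))
  for (br in m$branches) zero_module(br$conv)
  # zero branch convs -> batchnorm of zeros is zero -> ReLU(0) = 0 ->
  # gated zeros are zero -> residual returns x exactly
  expect_equal(fwd(m, x), x, tolerance = 1e-12)
})

test_that("MGEFA demands channel-preserving branches and >= 2 of them", {
  expect_error(yoloev:::ev_mgefa(16, branch_specs = list(list(k = 1))), "two branches")
})

test_that("MGEFA parameter cost follows its closed form and stays tiny", {
  for (c in c(64, 128, 256)) {
    m <- yoloev:::ev_mgefa(c)
    expect_identical(yoloev:::n_trainable(yoloev:::collect_pars(m)), o_mgefa(c))
  }
  # the budget that keeps the s-scale integration below 0.05 M
  expect_lt(o_mgefa(64) + o_mgefa(128) + o_mgefa(256) + o_mgefa(512), 5e4)
})

test_that("MGEFAC2f composes C2f with MGEFA and the parameter delta is exactly MGEFA", {
  m <- yoloev:::ev_mgefac2f(64, 64, 1, shortcut = TRUE)
  x <- rnd_x(64, 32, 32)
  expect_equal(dim(fwd(m, x)), c(64L, 32L, 32L, 1L))
  p_all <- yoloev:::n_trainable(yoloev:::collect_pars(m))
  p_c2f <- yoloev:::n_trainable(yoloev:::collect_pars(m$c2f))
  p_mg <- yoloev:::n_trainable(yoloev:::collect_pars(m$mgefa))
  expect_identical(p_all - p_c2f, p_mg)
  # with MGEFA branches zeroed the block equals its plain C2f
  for (br in m$mgefa$branches) zero_module(br$conv)
  expect_equal(fwd(m, x), fwd(m$c2f, x), tolerance = 1e-12)
})

test_that("a horizontal+vertical 1-D depthwise pair equals the dense outer-product kernel", {
  # dense 2-D depthwise oracle: direct double loop with zero padding
  dw2d_oracle <- function(x, ker) {
    d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
    kh <- nrow(ker[[1]]); kw <- ncol(ker[[1]])
    oh <- (kh - 1) %/% 2; ow <- (kw - 1) %/% 2
    out <- array(0, d)
    for (c in seq_len(C)) {
      for (i in seq_len(H)) {
        for (j in seq_len(W)) {
          acc <- 0
          for (di in seq_len(kh)) {
            for (dj in seq_len(kw)) {
              ii <- i + di - 1 - oh; jj <- j + dj - 1 - ow
              if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
                acc <- acc + ker[[c]][di, dj] * x[c, ii, jj, 1]
              }
            }
          }
          out[c, i, j, 1] <- acc
        }
      }
    }
    out
  }
  k <- 3L; C <- 4L
  worst <- 0
  for (trial in 1:100) {
    set.seed(trial)
    x <- array(rnorm(C * 8 * 8), c(C, 8, 8, 1))
    wh <- matrix(rnorm(C * k), C)                   # per-channel horizontal taps
    wv <- matrix(rnorm(C * k), C)                   # per-channel vertical taps
    mh <- yoloev:::ev_conv(C, C, c(1, k), g = C, act = "none", norm = FALSE, bias = FALSE)
    mv <- yoloev:::ev_conv(C, C, c(k, 1), g = C, act = "none", norm = FALSE, bias = FALSE)
    for (c in seq_len(C)) mh$pars$w$value[c, 1, 1, ] <- wh[c, ]
    for (c in seq_len(C)) mv$pars$w$value[c, 1, , 1] <- wv[c, ]
    got <- fwd(mv, fwd(mh, x))
    ker <- lapply(seq_len(C), function(c) outer(wv[c, ], wh[c, ]))
    want <- dw2d_oracle(x, ker)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-5)
})

test_that("LSKA preserves shape and its parameter count matches the closed form", {
  m <- yoloev:::ev_lska(64, K = 11)
  x <- rnd_x(64, 20, 20)
  expect_equal(dim(fwd(m, x)), dim(x))
  # local 3-taps + dilated 5-taps (both orientations) + 1x1 mix, bias-free
  expect_identical(yoloev:::n_trainable(yoloev:::collect_pars(m)),
                   64 * (3 + 3 + 5 + 5) + 64 * 64)
  expect_identical(o_lska(64), 5120)
  expect_error(yoloev:::ev_lska(16, K = 21, local_k = 3, dil_k = 5, dilation = 2),
               "covers")
})

test_that("delta-kernel LSKA gates the input with itself; zeroed LSKA gates everything off", {
  # depthwise kernels = centered delta, 1x1 mix = identity: the attention
  # map reproduces its input exactly, so the gated output is x^2
  lk <- yoloev:::ev_lska(8)
  lk$conv0h$pars$w$value[] <- 0; lk$conv0h$pars$w$value[, 1, 1, 2] <- 1
  lk$conv0v$pars$w$value[] <- 0; lk$conv0v$pars$w$value[, 1, 2, 1] <- 1
  lk$convsh$pars$w$value[] <- 0; lk$convsh$pars$w$value[, 1, 1, 3] <- 1
  lk$convsv$pars$w$value[] <- 0; lk$convsv$pars$w$value[, 1, 3, 1] <- 1
  lk$conv1$pars$w$value[] <- 0
  for (c in 1:8) lk$conv1$pars$w$value[c, c, 1, 1] <- 1
  x <- rnd_x(8, 10, 10, seed = 9)
  expect_equal(fwd(lk, x), x * x, tolerance = 1e-10)
  # zero weights -> zero attention map -> fully closed gate
  lk0 <- zero_module(yoloev:::ev_lska(8))
  expect_equal(fwd(lk0, x), 0 * x, tolerance = 1e-12)
  # and a zero-gated pooling block collapses to zero output
  m <- yoloev:::ev_sppf_lska(16, 16)
  zero_module(m$lska)
  out <- fwd(m, rnd_x(16, 6, 6, seed = 2))
  expect_equal(max(abs(out)), 0, tolerance = 1e-12)
})

test_that("SPPF_LSKA output shape and parameter delta over SPPF", {
  m <- yoloev:::ev_sppf_lska(64, 64)
  expect_equal(dim(fwd(m, rnd_x(64, 12, 12))), c(64L, 12L, 12L, 1L))
  d <- yoloev:::n_trainable(yoloev:::collect_pars(m)) -
    yoloev:::n_trainable(yoloev:::collect_pars(yoloev:::ev_sppf(64, 64)))
  expect_identical(d, o_lska(4 * 32))
})

test_that("attention blocks preserve batch size and finiteness", {
  blocks <- list(yoloev:::ev_lse(8, 2, 3), yoloev:::ev_mgefa(8),
                 yoloev:::ev_lska(8), yoloev:::ev_sppf_lska(8, 8))
  for (seed in 1:3) {
    x <- rnd_x(8, 8, 8, n = 2, seed = seed)
    for (m in blocks) {
      out <- fwd(m, x)
      expect_equal(dim(out), dim(x))
      expect_true(all(is.finite(out)))
    }
  }
})
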