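# Window partitioning, windowed attention and the STL/RSTB blocks.

test_that("window_partition follows raster order and roundtrips", {
  # 4x4 map holding 0..15 row-major, m = 2: first window reads 0, 1, 4, 5
  vals <- matrix(0:15, 4, 4, byrow = TRUE)
  f <- array(0, c(1, 4, 4, 1))
  f[1, , , 1] <- vals
  w <- window_partition(f, 2)
  expect_identical(dim(w), c(1L, 4L, 4L, 1L))
  expect_equal(as.numeric(w[1, , 1, 1]), c(0, 1, 4, 5))

  # 8x8 with m = 4 gives (8/4)^2 = 4 windows of 16 tokens
  f8 <- array(rnorm(2 * 8 * 8 * 1), c(2, 8, 8, 1))
  w8 <- window_partition(f8, 4)
  expect_identical(dim(w8)[2:3], c(16L, 4L))

  # exact inverse over random shapes (multiples of m)
  set.seed(42)
  for (i in 1:50) {
    m <- sample(c(2L, 4L), 1)
    H <- m * sample(1:4, 1)
    W <- m * sample(1:4, 1)
    C <- sample(1:3, 1)
    B <- sample(1:2, 1)
    x <- array(rnorm(C * H * W * B), c(C, H, W, B))
    expect_identical(window_reverse(window_partition(x, m), m, H, W), x)
  }
})

test_that("permuted windows do not reverse to the original", {
  set.seed(7)
  x <- array(rnorm(1 * 8 * 8), c(1, 8, 8, 1))
  w <- window_partition(x, 4)
  wp <- w[, , c(2, 1, 4, 3), , drop = FALSE]
  expect_gt(max(abs(window_reverse(wp, 4, 8, 8) - x)), 0)
})

test_that("partition errors on invalid window sizes", {
  x <- array(rnorm(64), c(1, 8, 8, 1))
  expect_error(window_partition(x, 0), class = "swinreg_config_error")
  expect_error(window_partition(x, 16), class = "swinreg_config_error")
})

test_that("relative position index enumerates all 2D offsets", {
  for (m in c(2L, 3L, 4L)) {
    idx <- rel_pos_index(m)
    expect_identical(dim(idx), as.integer(c(m^2, m^2)))
    expect_identical(sort(unique(as.vector(idx))), seq_len((2 * m - 1)^2))
    expect_true(all(idx >= 1 & idx <= (2 * m - 1)^2))
  }
})

test_that("window_attention matches the dense oracle", {
  set.seed(11)
  for (m in c(2L, 4L)) for (h in c(1L, 2L)) {
    cfg <- swin_config(window = m, embed_dim = 4L * h, num_heads = h)
    p <- init_stl(cfg)
    p$bias[] <- rnorm(length(p$bias), 0, 0.5) # exercise the bias path
    f <- array(rnorm(cfg$embed_dim * (2 * m)^2 * 2),
               c(cfg$embed_dim, 2 * m, 2 * m, 2))
    w <- window_partition(f, m)
    expect_lt(max(abs(window_attention(w, p, cfg) -
                        dense_attention_oracle(w, p, cfg))), 1e-5)
  }
})

test_that("identical value rows pass through attention unchanged", {
  # every V row equal to v => each pre-projection output row is v, so the
  # final output is proj(v) broadcast over tokens
  cfg <- swin_config(window = 2L, embed_dim = 4L, num_heads = 1L)
  p <- init_stl(cfg)
  set.seed(12)
  x_tok <- rnorm(4) # one token vector repeated
  w <- array(rep(x_tok, each = 1), c(4, 4, 1, 1))
  for (t in 1:4) w[, t, 1, 1] <- x_tok
  out <- window_attention(w, p, cfg)
  v_row <- (p$qkv_w %*% x_tok + p$qkv_b)[9:12]
  want <- p$proj_w %*% v_row + p$proj_b
  for (t in 1:4) expect_equal(as.numeric(out[, t, 1, 1]),
                              as.numeric(want), tolerance = 1e-10)
})

test_that("attention rows are a probability distribution and masks kill pairs", {
  cfg <- swin_config(window = 2L, embed_dim = 4L, num_heads = 1L)
  p <- init_stl(cfg)
  set.seed(13)
  w <- array(rnorm(16), c(4, 4, 1, 1))
  # recompute softmax probabilities via the oracle formula
  X <- t(w[, , 1, 1])
  QKV <- X %*% t(p$qkv_w) + matrix(p$qkv_b, 4, 12, byrow = TRUE)
  S <- QKV[, 1:4] %*% t(QKV[, 5:8]) / 2 +
    matrix(p$bias[rel_pos_index(2), 1], 4, 4)
  P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-6)
  # a -1e9 mask entry suppresses the pair below 1e-8
  Sm <- S
  Sm[1, 2] <- Sm[1, 2] - 1e9
  Pm <- exp(Sm - apply(Sm, 1, max)); Pm <- Pm / rowSums(Pm)
  expect_lt(Pm[1, 2], 1e-8)
  # and through the public interface a masked window still normalises
  mask <- array(0, c(4, 4, 1))
  out_masked <- window_attention(w, p, cfg, mask = mask)
  expect_equal(out_masked, window_attention(w, p, cfg), tolerance = 1e-12)
})

test_that("STL preserves shape; zero shift equals the plain W-MSA path", {
  set.seed(14)
  for (trial in 1:3) {
    H <- sample(c(8L, 12L), 1)
    W <- sample(c(8L, 16L), 1)
    cfg <- tiny_swin()
    p <- init_stl(cfg)
    x <- array(rnorm(cfg$embed_dim * H * W * 2), c(cfg$embed_dim, H, W, 2))
    out <- swin_layer_forward(x, cfg, p)
    expect_identical(dim(out), dim(x))
  }
  cfg0 <- tiny_swin(shift = 0L)
  p <- init_stl(cfg0)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  expect_identical(swin_layer_forward(x, cfg0, p),
                   swin_layer_forward(x, cfg0, p))
})

test_that("shifted attention equals the region-wise dense oracle", {
  # 2m x 2m map, s = m/2: roll by (-s, -s), then attention must stay within
  # the contiguous pre-shift regions; oracle computes dense masked softmax
  # per window using region bookkeeping only.
  m <- 4L; s <- 2L; H <- 2L * m
  cfg <- swin_config(window = m, embed_dim = 8L, num_heads = 2L, shift = s)
  p <- init_stl(cfg)
  # isolate the attention sub-path: zero the MLP and disable both norms
  p$fc1_w[] <- 0; p$fc2_w[] <- 0
  p$ln1_g[] <- 1; p$ln1_b[] <- 0
  set.seed(15)
  x <- array(rnorm(8 * H * H), c(8, H, H, 1))
  got <- swin_layer_forward(x, cfg, p)

  # oracle
  ln <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  xn <- x
  for (r in 1:H) for (cc in 1:H) xn[, r, cc, 1] <- ln(x[, r, cc, 1])
  seg_id <- function(n) c(rep(0L, n - m), rep(1L, m - s), rep(2L, s))
  hid <- seg_id(H)
  region <- outer(hid, hid, function(a, b) a * 3L + b)
  rolled <- xn[, c((1 + s):H, 1:s), c((1 + s):H, 1:s), 1, drop = FALSE]
  regr <- region[c((1 + s):H, 1:s), c((1 + s):H, 1:s)]
  w <- window_partition(rolled, m)
  rpi <- rel_pos_index(m)
  attn_out <- array(0, dim(w))
  for (wi in seq_len(dim(w)[3])) {
    wr <- (wi - 1) %/% 2L
    wc <- (wi - 1) %% 2L
    tok_reg <- as.vector(t(regr[wr * m + 1:m, wc * m + 1:m]))
    X <- t(w[, , wi, 1])
    QKV <- X %*% t(p$qkv_w) + matrix(p$qkv_b, m^2, 24, byrow = TRUE)
    O <- matrix(0, m^2, 8)
    for (hh in 1:2) {
      cols <- ((hh - 1) * 4 + 1):(hh * 4)
      Q <- QKV[, cols]; K <- QKV[, 8 + cols]; V <- QKV[, 16 + cols]
      S <- Q %*% t(K) / 2 + matrix(p$bias[rpi, hh], m^2, m^2)
      S[outer(tok_reg, tok_reg, "!=")] <- -Inf
      P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
      O[, cols] <- P %*% V
    }
    attn_out[, , wi, 1] <- t(O %*% t(p$proj_w) +
                               matrix(p$proj_b, m^2, 8, byrow = TRUE))
  }
  back <- window_reverse(attn_out, m, H, H)
  unrolled <- back[, c((H - s + 1):H, 1:(H - s)),
                   c((H - s + 1):H, 1:(H - s)), 1, drop = FALSE]
  want <- x + unrolled # attention residual only (MLP is zeroed)
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("RSTB is residual and composes its sub-operations", {
  cfg <- tiny_swin()
  p <- init_rstb(cfg, n_stl = 2L)
  set.seed(16)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))

  # zero conv => exact identity (Conv(F) + T_IN with Conv = 0)
  p0 <- p
  p0$conv_w[] <- 0
  p0$conv_b[] <- 0
  expect_identical(rstb_forward(x, p0), x)

  # manual composition: conv(stl2(stl1(x))) + x
  s1 <- swinreg:::sub_par(p, "stl1")
  s2 <- swinreg:::sub_par(p, "stl2")
  cfg_s <- cfg
  t1 <- swin_layer_forward(x, cfg_s, s1)
  cfg_s$shift <- cfg$window %/% 2L
  t2 <- swin_layer_forward(t1, cfg_s, s2)
  swinreg:::tape_reset()
  cv <- swinreg:::ad_conv2d(swinreg:::ad_const(t2),
                            swinreg:::ad_const(p$conv_w),
                            swinreg:::ad_const(p$conv_b))$v
  expect_lt(max(abs(rstb_forward(x, p) - (cv + x))), 1e-6)
})

test_that("default RSTB parameter budget is 6 STLs plus one conv", {
  cfg <- tiny_swin()
  p6 <- init_rstb(cfg)
  p1 <- init_stl(cfg)
  stl_count <- sum(startsWith(names(p6), "stl"))
  expect_identical(stl_count, 6L * length(p1))
  expect_identical(sum(!startsWith(names(p6), "stl")), 2L) # conv w + b
  n_params <- function(lst) sum(vapply(lst, length, 1L))
  expect_identical(n_params(p6), 6L * n_params(p1) +
                     length(p6$conv_w) + length(p6$conv_b))
})
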