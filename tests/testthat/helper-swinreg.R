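# Shared fixtures: small network configurations sized for second-scale
# tests, plus a central-difference gradient checker.

tiny_swin <- function(m = 4L, C = 8L, h = 2L, shift = 0L) {
  swin_config(window = m, embed_dim = C, num_heads = h, shift = shift)
}

tiny_stg <- function(use_swin = TRUE) {
  stg_config(n_rstb = 2L, n_stl_per_rstb = 2L, swin = tiny_swin(),
             use_swin = use_swin)
}

tiny_str <- function(use_swin = TRUE) {
  str_config(levels = 2L, base_channels = 4L, n_stl_encoder = 1L,
             use_swin = use_swin, window = 4L)
}

tiny_disc <- function() disc_config(n_layers = 3L, base_channels = 8L)

tiny_train_cfg <- function(scenario = "mmtrans", epochs = 2L, seed = 1L,
                           mode = "aligned", weights = loss_weights()) {
  train_config(epochs = epochs, batch_size = 4L, seed = seed,
               scenario = scenario, mode = mode, weights = weights,
               generator = tiny_stg(), registration = tiny_str(),
               discriminator = tiny_disc())
}

num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rand_image_batch <- function(H, W, B, seed = 1) {
  set.seed(seed)
  array(runif(H * W * B), c(H, W, B))
}

images_to_array <- function(lst) {
  a <- array(0, c(dim(lst[[1]]), length(lst)))
  for (i in seq_along(lst)) a[, , i] <- lst[[i]]
  a
}

# Mean endpoint error between predicted and true displacement fields.
mean_epe <- function(pred, true) {
  d <- pred - true
  mean(sqrt(colSums(array(d * d, c(2, length(d) %/% 2)))))
}

# Dense per-window multi-head attention oracle (independent of the
# batched/cube implementation path).
dense_attention_oracle <- function(windows, p, cfg) {
  d <- dim(windows)
  C <- d[1]; m2 <- d[2]; h <- cfg$num_heads; dh <- C / h
  rpi <- rel_pos_index(cfg$window)
  out <- array(0, d)
  for (b in seq_len(d[4])) for (wi in seq_len(d[3])) {
    X <- t(windows[, , wi, b])
    QKV <- X %*% t(p$qkv_w) + matrix(p$qkv_b, m2, 3 * C, byrow = TRUE)
    O <- matrix(0, m2, C)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      Q <- QKV[, cols]; K <- QKV[, C + cols]; V <- QKV[, 2 * C + cols]
      S <- Q %*% t(K) / sqrt(dh) + matrix(p$bias[rpi, hh], m2, m2)
      P <- exp(S - apply(S, 1, max))
      P <- P / rowSums(P)
      O[, cols] <- P %*% V
    }
    out[, , wi, b] <- t(O %*% t(p$proj_w) +
                          matrix(p$proj_b, m2, C, byrow = TRUE))
  }
  out
}

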