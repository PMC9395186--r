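# Shifted-window self-attention core: window partitioning, windowed
# multi-head attention with relative position bias, the Swin transformer
# layer (STL) and the residual Swin transformer block (RSTB).
#
# Feature maps are (C, H, W, B) arrays. Token windows are (C, m^2, nW, B)
# arrays: tokens are ordered row-major within each m x m window and windows
# are ordered raster (left-to-right, top-to-bottom).

#' Configuration for shifted-window attention layers
#'
#' @param window Window side length `m` in pixels; each window holds `m^2`
#'   tokens. Must be at least 2.
#' @param embed_dim Channel count `C` of the token embeddings; must be
#'   divisible by `num_heads`.
#' @param num_heads Number of attention heads `h`; each head works in
#'   dimension `d = C / h`.
#' @param shift Cyclic shift `s` applied before windowing (`0 <= s < m`).
#'   Consecutive layers alternate `s = 0` and `s = floor(m/2)`.
#' @param mlp_ratio Hidden-width multiplier of the two-layer MLP.
#' @return An object of class `swin_config`.
#' @export
swin_config <- function(window = 8L, embed_dim = 60L, num_heads = 6L,
                        shift = 0L, mlp_ratio = 2) {
  window <- as.integer(window)
  embed_dim <- as.integer(embed_dim)
  num_heads <- as.integer(num_heads)
  shift <- as.integer(shift)
  if (window < 2L) err_config("window size must be >= 2")
  if (embed_dim < 1L || num_heads < 1L) err_config("dims must be positive")
  if (embed_dim %% num_heads != 0L)
    err_config("embed_dim must be divisible by num_heads")
  if (shift < 0L || shift >= window)
    err_config("shift must satisfy 0 <= shift < window")
  if (mlp_ratio <= 0) err_config("mlp_ratio must be positive")
  structure(list(window = window, embed_dim = embed_dim,
                 num_heads = num_heads, shift = shift,
                 mlp_ratio = mlp_ratio),
            class = "swin_config")
}

#' Relative-position index for a square attention window
#'
#' Maps each (query, key) token pair inside an `m x m` window to one of the
#' `(2m-1)^2` distinct 2D offsets. Entry `[i, j]` indexes the bias-table row
#' for query token `i` and key token `j` (row-major token order).
#'
#' @param m Window side length.
#' @return An `m^2 x m^2` integer matrix with values in `1..(2m-1)^2`.
#' @export
rel_pos_index <- function(m) {
  m <- as.integer(m)
  if (m < 2L) err_config("window size must be >= 2")
  t <- 0:(m * m - 1L)
  tr <- t %/% m
  tc <- t %% m
  dr <- outer(tr, tr, "-") # row offset query - key
  dc <- outer(tc, tc, "-")
  idx <- (dr + m - 1L) * (2L * m - 1L) + (dc + m - 1L) + 1L
  storage.mode(idx) <- "integer"
  idx
}

# --- cached index builders ---------------------------------------------------

# Window partition as a pure permutation: maps a (C, H, W, B) array (H, W
# multiples of m) to (C, m^2, nW, B).
win_part_idx <- function(C, H, W, B, m) {
  key <- paste("wp", C, H, W, B, m, sep = "_")
  cache_get(key, function() {
    nWr <- H %/% m
    nWc <- W %/% m
    nW <- nWr * nWc
    t <- 0:(m * m - 1L)
    tr <- t %/% m
    tc <- t %% m
    w <- 0:(nW - 1L)
    wr <- w %/% nWc
    wc <- w %% nWc
    r <- outer(tr, wr * m, "+") # (m^2, nW)
    s <- outer(tc, wc * m, "+")
    pix <- r + H * s
    i1 <- 1 + outer(0:(C - 1L), as.vector(pix) * C, "+") # (C, m^2*nW)
    idx <- outer(as.vector(i1), (0:(B - 1L)) * C * H * W, "+")
    storage.mode(idx) <- "integer"
    dim(idx) <- NULL
    idx
  })
}

win_rev_idx <- function(C, H, W, B, m) {
  key <- paste("wr", C, H, W, B, m, sep = "_")
  cache_get(key, function() {
    fwd <- win_part_idx(C, H, W, B, m)
    inv <- integer(length(fwd))
    inv[fwd] <- seq_along(fwd)
    inv
  })
}

# Cyclic roll of the (H, W) grid: out(r, c) = in(r + sr, c + sc) (mod size).
roll_idx <- function(C, H, W, B, sr, sc = sr) {
  key <- paste("roll", C, H, W, B, sr, sc, sep = "_")
  cache_get(key, function() {
    r <- (0:(H - 1L) + sr) %% H
    cix <- (0:(W - 1L) + sc) %% W
    pix <- outer(r, cix * H, "+") # target (r, c) -> source pixel
    i1 <- 1 + outer(0:(C - 1L), as.vector(pix) * C, "+")
    idx <- outer(as.vector(i1), (0:(B - 1L)) * C * H * W, "+")
    storage.mode(idx) <- "integer"
    dim(idx) <- NULL
    idx
  })
}

# Reflect padding (no edge repeat) on bottom/right to (Hp, Wp).
pad_reflect_idx <- function(C, H, W, B, Hp, Wp) {
  key <- paste("pad", C, H, W, B, Hp, Wp, sep = "_")
  cache_get(key, function() {
    if (Hp - H > H - 1L || Wp - W > W - 1L)
      err_config("map too small for reflect padding to window multiple")
    refl <- function(i, n) ifelse(i < n, i, 2L * n - i - 2L)
    r <- refl(0:(Hp - 1L), H)
    s <- refl(0:(Wp - 1L), W)
    pix <- outer(r, s * H, "+")
    i1 <- 1 + outer(0:(C - 1L), as.vector(pix) * C, "+")
    idx <- outer(as.vector(i1), (0:(B - 1L)) * C * H * W, "+")
    storage.mode(idx) <- "integer"
    dim(idx) <- NULL
    idx
  })
}

# Crop the padded (C, Hp, Wp, B) array back to (C, H, W, B).
crop_idx <- function(C, Hp, Wp, B, H, W) {
  key <- paste("crop", C, Hp, Wp, B, H, W, sep = "_")
  cache_get(key, function() {
    pix <- outer(0:(H - 1L), (0:(W - 1L)) * Hp, "+")
    i1 <- 1 + outer(0:(C - 1L), as.vector(pix) * C, "+")
    idx <- outer(as.vector(i1), (0:(B - 1L)) * C * Hp * Wp, "+")
    storage.mode(idx) <- "integer"
    dim(idx) <- NULL
    idx
  })
}

# Additive attention mask for shifted windows: entry 0 where query and key
# tokens come from the same pre-shift region, -1e9 otherwise. (m^2, m^2, nW).
attn_mask <- function(H, W, m, s) {
  key <- paste("mask", H, W, m, s, sep = "_")
  cache_get(key, function() {
    seg <- function(n) {
      id <- integer(n)
      if (n > m) {
        id[] <- 0L
        id[(n - m + 1L):n] <- 1L
        id[(n - s + 1L):n] <- 2L
      }
      id
    }
    hid <- seg(H)
    wid <- seg(W)
    region <- outer(hid, wid, function(a, b) a * 3L + b) # (H, W)
    # roll then partition with the same conventions as the feature path
    rolled <- region[((0:(H - 1L) + s) %% H) + 1L, ((0:(W - 1L) + s) %% W) + 1L]
    arr <- array(as.numeric(rolled), c(1L, H, W, 1L))
    tok <- arr[win_part_idx(1L, H, W, 1L, m)]
    nW <- (H %/% m) * (W %/% m)
    dim(tok) <- c(m * m, nW)
    mask <- array(0, c(m * m, m * m, nW))
    for (w in seq_len(nW)) {
      same <- outer(tok[, w], tok[, w], "==")
      mask[, , w] <- ifelse(same, 0, -1e9)
    }
    mask
  })
}

# --- parameter initialisation ------------------------------------------------

#' Initialise parameters for one Swin transformer layer
#'
#' Attention/MLP weights are truncated-normal (sd 0.02), biases zero,
#' layer-norm affine (1, 0). The relative-position bias table has
#' `(2m-1)^2` rows (one per distinct 2D offset) and one column per head.
#'
#' @param cfg A [swin_config()].
#' @return Flat named list of parameter arrays (`ln1_*`, `qkv_*`, `bias`,
#'   `proj_*`, `ln2_*`, `fc1_*`, `fc2_*`).
#' @export
init_stl <- function(cfg) {
  C <- cfg$embed_dim
  h <- cfg$num_heads
  m <- cfg$window
  hid <- as.integer(round(cfg$mlp_ratio * C))
  list(
    ln1_g = rep(1, C), ln1_b = rep(0, C),
    qkv_w = matrix(trunc_normal(3 * C * C), 3 * C, C),
    qkv_b = rep(0, 3 * C),
    bias = matrix(trunc_normal((2 * m - 1)^2 * h), (2 * m - 1)^2, h),
    proj_w = matrix(trunc_normal(C * C), C, C),
    proj_b = rep(0, C),
    ln2_g = rep(1, C), ln2_b = rep(0, C),
    fc1_w = matrix(trunc_normal(hid * C), hid, C),
    fc1_b = rep(0, hid),
    fc2_w = matrix(trunc_normal(C * hid), C, hid),
    fc2_b = rep(0, C)
  )
}

# Prefix a flat parameter list.
pfx <- function(prefix, lst) {
  names(lst) <- paste0(prefix, ".", names(lst))
  lst
}

# Extract the sub-list with a given prefix (prefix stripped).
sub_par <- function(P, prefix) {
  pre <- paste0(prefix, ".")
  hit <- startsWith(names(P), pre)
  out <- P[hit]
  names(out) <- substring(names(out), nchar(pre) + 1L)
  out
}

#' Parameters for one residual Swin transformer block
#'
#' An RSTB is `n_stl` Swin transformer layers (alternating unshifted and
#' shifted windows) followed by a 3x3 convolution, added residually to the
#' block input. The swin configuration used at init is attached as the
#' `"cfg"` attribute.
#'
#' @param cfg A [swin_config()].
#' @param n_stl Number of STLs in the block (default 6).
#' @return Flat named list of parameter arrays.
#' @export
init_rstb <- function(cfg, n_stl = 6L) {
  C <- cfg$embed_dim
  out <- list()
  for (i in seq_len(n_stl)) {
    out <- c(out, pfx(paste0("stl", i), init_stl(cfg)))
  }
  out$conv_w <- matrix(trunc_normal(C * C * 9), C, C * 9)
  out$conv_b <- rep(0, C)
  attr(out, "cfg") <- cfg
  attr(out, "n_stl") <- as.integer(n_stl)
  out
}

# --- forward passes (tape nodes) ---------------------------------------------

# Windowed multi-head attention on a token node X (C, m^2, nWB). `p` holds
# qkv_w/qkv_b/bias/proj_w/proj_b nodes. Returns same-shape node. If
# `capture` is an environment, the softmaxed attention (m^2 keys, m^2
# queries, h*nWB slices) is stored in capture$attn.
fwd_window_attention <- function(X, p, cfg, mask_big = NULL, capture = NULL) {
  d3 <- dim(X$v)
  C <- d3[1]; m2 <- d3[2]; nWB <- d3[3]
  h <- cfg$num_heads
  dh <- C %/% h
  if (any(!is.finite(X$v))) err_numeric("non-finite attention input")
  Xm <- ad_reshape(X, c(C, m2 * nWB))
  qkv <- ad_linear(p$qkv_w, Xm, p$qkv_b) # (3C, m2*nWB)
  to_heads <- function(t) {
    t3 <- ad_reshape(t, c(C, m2, nWB))
    ad_reshape(ad_aperm(t3, c(2, 1, 3)), c(m2, dh, h * nWB))
  }
  Q <- to_heads(ad_rows(qkv, 1L, C))
  K <- to_heads(ad_rows(qkv, C + 1L, 2L * C))
  V <- to_heads(ad_rows(qkv, 2L * C + 1L, 3L * C))
  Qs <- ad_smul(Q, 1 / sqrt(dh))
  # S[j, i, slice] = <K_j, Q_i> / sqrt(d): keys along dim 1
  S <- ad_bmm(K, Qs, transB = TRUE)
  # relative position bias: S[j, i] gets table[rpi[i, j], head]
  m <- cfg$window
  bkey <- paste("bidx", m, h, nWB, sep = "_")
  bidx <- cache_get(bkey, function() {
    rpi_t <- t(rel_pos_index(m)) # entry [j, i]
    per_head <- outer(as.vector(rpi_t), ((1:h) - 1L) * (2L * m - 1L)^2, "+")
    idx <- rep(as.vector(per_head), times = nWB)
    storage.mode(idx) <- "integer"
    idx
  })
  S <- ad_add(S, ad_gather(p$bias, bidx, c(m2, m2, h * nWB)))
  if (!is.null(mask_big)) S <- ad_addc(S, mask_big)
  P <- ad_softmax1(S) # softmax over keys (dim 1)
  if (!is.null(capture)) capture$attn <- P$v
  O <- ad_bmm(P, V, transA = TRUE) # (m2, dh, h*nWB)
  Oc <- ad_aperm(ad_reshape(O, c(m2, C, nWB)), c(2, 1, 3))
  Om <- ad_reshape(Oc, c(C, m2 * nWB))
  out <- ad_linear(p$proj_w, Om, p$proj_b)
  ad_reshape(out, c(C, m2, nWB))
}

# One Swin transformer layer on a (C, H, W, B) node.
fwd_stl <- function(x, p, cfg, capture = NULL) {
  d <- dim(x$v)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  m <- cfg$window
  s <- cfg$shift
  if (m > min(H, W)) {
    # pad below, but padding cannot exceed size - 1
    if (m - H > H - 1L || m - W > W - 1L)
      err_config("feature map too small for window size")
  }
  shortcut <- x
  xm <- ad_reshape(x, c(C, H * W * B))
  xn <- ad_layernorm(xm, p$ln1_g, p$ln1_b)
  t <- ad_reshape(xn, d)
  Hp <- ceiling(H / m) * m
  Wp <- ceiling(W / m) * m
  if (Hp != H || Wp != W) {
    t <- ad_gather(t, pad_reflect_idx(C, H, W, B, Hp, Wp), c(C, Hp, Wp, B))
  }
  if (s > 0L) t <- ad_gather(t, roll_idx(C, Hp, Wp, B, s), c(C, Hp, Wp, B))
  nW <- (Hp %/% m) * (Wp %/% m)
  t <- ad_gather(t, win_part_idx(C, Hp, Wp, B, m), c(C, m * m, nW * B))
  mask_big <- NULL
  if (s > 0L) {
    mk <- attn_mask(Hp, Wp, m, s)
    mask_big <- mk[, , rep(rep(seq_len(nW), each = cfg$num_heads), times = B),
                   drop = FALSE]
  }
  t <- fwd_window_attention(t, p, cfg, mask_big, capture)
  t <- ad_reshape(t, c(C, m * m, nW, B))
  t <- ad_gather(ad_reshape(t, c(C, m * m, nW * B)),
                 win_rev_idx(C, Hp, Wp, B, m), c(C, Hp, Wp, B))
  if (s > 0L) {
    t <- ad_gather(t, roll_idx(C, Hp, Wp, B, (-s) %% Hp, (-s) %% Wp),
                   c(C, Hp, Wp, B))
  }
  if (Hp != H || Wp != W) {
    t <- ad_gather(t, crop_idx(C, Hp, Wp, B, H, W), c(C, H, W, B))
  }
  x1 <- ad_add(shortcut, t)
  # MLP branch
  xm2 <- ad_reshape(x1, c(C, H * W * B))
  xn2 <- ad_layernorm(xm2, p$ln2_g, p$ln2_b)
  hdn <- ad_gelu(ad_linear(p$fc1_w, xn2, p$fc1_b))
  mlp <- ad_linear(p$fc2_w, hdn, p$fc2_b)
  ad_add(x1, ad_reshape(mlp, d))
}

# One RSTB: STL stack (alternating shift 0 / floor(m/2)) + 3x3 conv, with
# the block input added back (residual).
fwd_rstb <- function(x, P, cfg, n_stl, capture_list = NULL) {
  t <- x
  for (i in seq_len(n_stl)) {
    s <- if (i %% 2L == 1L) 0L else cfg$window %/% 2L
    cfg_i <- cfg
    cfg_i$shift <- s
    cap <- if (!is.null(capture_list)) capture_list[[i]] else NULL
    t <- fwd_stl(t, sub_par(P, paste0("stl", i)), cfg_i, cap)
  }
  t <- ad_conv2d(t, P$conv_w, P$conv_b)
  ad_add(t, x)
}

# --- user-facing wrappers on plain arrays ------------------------------------

as_fmap <- function(fmap) {
  if (is.matrix(fmap)) fmap <- array(fmap, c(1L, dim(fmap), 1L))
  if (length(dim(fmap)) != 4L)
    err_dim("feature map must be a (C, H, W, B) array")
  if (any(!is.finite(fmap))) err_numeric("non-finite feature map")
  fmap
}

#' Partition a feature map into non-overlapping square windows
#'
#' Pads the map on the bottom/right by reflection when `H` or `W` is not a
#' multiple of `m`, then cuts it into `m x m` windows in raster order,
#' flattening each to `m^2` row-major tokens.
#'
#' @param fmap A (C, H, W, B) array (a plain `H x W` matrix is promoted).
#' @param m Window side length.
#' @return A (C, m^2, nW, B) array with attributes `H`, `W` recording the
#'   unpadded spatial size.
#' @export
window_partition <- function(fmap, m) {
  fmap <- as_fmap(fmap)
  m <- as.integer(m)
  d <- dim(fmap)
  if (m <= 0L) err_config("window size must be positive")
  Hp <- ceiling(d[2] / m) * m
  Wp <- ceiling(d[3] / m) * m
  if (m > min(Hp, Wp)) err_config("window larger than padded map")
  x <- fmap
  if (Hp != d[2] || Wp != d[3]) {
    x <- x[pad_reflect_idx(d[1], d[2], d[3], d[4], Hp, Wp)]
    dim(x) <- c(d[1], Hp, Wp, d[4])
  }
  nW <- (Hp %/% m) * (Wp %/% m)
  out <- x[win_part_idx(d[1], Hp, Wp, d[4], m)]
  dim(out) <- c(d[1], m * m, nW, d[4])
  attr(out, "H") <- d[2]
  attr(out, "W") <- d[3]
  out
}

#' Reassemble a feature map from token windows
#'
#' Exact inverse of [window_partition()] on the padded extent; any padding
#' is cropped so the result has spatial size `H x W`.
#'
#' @param windows A (C, m^2, nW, B) array.
#' @param m Window side length.
#' @param H,W Target (unpadded) spatial size.
#' @return A (C, H, W, B) array.
#' @export
window_reverse <- function(windows, m, H, W) {
  d <- dim(windows)
  if (length(d) != 4L) err_dim("windows must be a (C, m^2, nW, B) array")
  m <- as.integer(m)
  if (d[2] != m * m) err_dim("token count does not match window size")
  Hp <- ceiling(H / m) * m
  Wp <- ceiling(W / m) * m
  if (d[3] != (Hp %/% m) * (Wp %/% m))
    err_dim("window count inconsistent with H, W, m")
  x <- windows
  dim(x) <- c(d[1], m * m * d[3], d[4])
  out <- as.vector(x)[win_rev_idx(d[1], Hp, Wp, d[4], m)]
  dim(out) <- c(d[1], Hp, Wp, d[4])
  if (Hp != H || Wp != W) {
    out <- out[crop_idx(d[1], Hp, Wp, d[4], H, W)]
    dim(out) <- c(d[1], H, W, d[4])
  }
  out
}

#' Windowed multi-head self-attention over token windows
#'
#' Computes `softmax(Q K' / sqrt(d) + B + mask) V` per window and head with
#' a learnable relative-position bias `B`, concatenates heads and applies
#' the output projection.
#'
#' @param windows A (C, m^2, nW, B) token array from [window_partition()].
#' @param params List with `qkv_w` (3C x C), `qkv_b`, `bias`
#'   ((2m-1)^2 x h), `proj_w` (C x C), `proj_b`.
#' @param cfg A [swin_config()] (supplies `num_heads` and `window`).
#' @param mask Optional additive mask, (m^2, m^2, nW) with entries in
#'   \{0, -1e9\}; `NULL` means unmasked.
#' @return Array with the same shape as `windows`.
#' @export
window_attention <- function(windows, params, cfg, mask = NULL) {
  d <- dim(windows)
  if (length(d) != 4L) err_dim("windows must be a (C, m^2, nW, B) array")
  if (d[1] %% cfg$num_heads != 0L)
    err_config("channels not divisible by num_heads")
  if (any(!is.finite(windows))) err_numeric("non-finite attention input")
  mask_big <- NULL
  if (!is.null(mask)) {
    mask_big <- mask[, , rep(rep(seq_len(d[3]), each = cfg$num_heads),
                             times = d[4]), drop = FALSE]
  }
  tape_reset()
  X <- ad_const(array(windows, c(d[1], d[2], d[3] * d[4])))
  p <- const_params(params)
  out <- fwd_window_attention(X, p, cfg, mask_big)
  v <- out$v
  dim(v) <- d
  tape_reset()
  v
}

#' Apply one Swin transformer layer to a feature map
#'
#' Pre-norm layout: layer norm, (optionally shifted) windowed attention with
#' a residual connection, then layer norm and a GELU MLP with a second
#' residual. Shape is preserved.
#'
#' @param fmap A (C, H, W, B) array.
#' @param cfg A [swin_config()]; `cfg$shift` selects W-MSA (0) or SW-MSA.
#' @param params Flat list from `init_stl`-style initialisation (fields
#'   `ln1_*`, `qkv_*`, `bias`, `proj_*`, `ln2_*`, `fc1_*`, `fc2_*`).
#' @return Array with the same shape as `fmap`.
#' @export
swin_layer_forward <- function(fmap, cfg, params) {
  fmap <- as_fmap(fmap)
  if (dim(fmap)[1] != cfg$embed_dim)
    err_config("channel count does not match embed_dim")
  tape_reset()
  out <- fwd_stl(ad_const(fmap), const_params(params), cfg)
  v <- out$v
  tape_reset()
  v
}

#' Apply one residual Swin transformer block
#'
#' Runs the STL stack (shift alternating 0 and `m/2`), a 3x3 convolution,
#' and adds the block input: `Conv(STL_n(...STL_1(x))) + x`.
#'
#' @param fmap A (C, H, W, B) array.
#' @param params Parameters from [init_rstb()] (carries its `swin_config`
#'   as attribute `"cfg"`).
#' @return Array with the same shape as `fmap`.
#' @export
rstb_forward <- function(fmap, params) {
  fmap <- as_fmap(fmap)
  cfg <- attr(params, "cfg")
  n_stl <- attr(params, "n_stl")
  tape_reset()
  out <- fwd_rstb(ad_const(fmap), const_params(params), cfg, n_stl)
  v <- out$v
  tape_reset()
  v
}
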