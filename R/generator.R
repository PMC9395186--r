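# Swin transformer generator (STG): shallow 3x3 conv embedding, a stack of
# RSTBs for deep feature extraction, a post-body conv, a long skip carrying
# the shallow (low-frequency) features straight to the recovery head, and a
# 3x3 conv + sigmoid recovery producing the translated image in [0, 1].

#' Generator configuration
#'
#' @param n_rstb Number of residual Swin transformer blocks (default 4).
#' @param n_stl_per_rstb STLs per block (default 6).
#' @param swin A [swin_config()] shared by all STLs.
#' @param in_channels,out_channels Image channel counts (default 1).
#' @param use_swin If `FALSE`, each STL is replaced by a 3x3 conv + GELU
#'   block of the same width (the convolution-only ablation generator).
#' @param recovery Either `"conv"` (3x3 conv to the output channels) or
#'   `"subpixel"` (conv to `out_channels * r^2` channels followed by a
#'   pixel shuffle with `r = 1`, i.e. numerically a plain conv; kept as a
#'   flag because translation is same-resolution).
#' @return Object of class `stg_config`.
#' @export
stg_config <- function(n_rstb = 4L, n_stl_per_rstb = 6L,
                       swin = swin_config(), in_channels = 1L,
                       out_channels = 1L, use_swin = TRUE,
                       recovery = c("conv", "subpixel")) {
  recovery <- match.arg(recovery)
  n_rstb <- as.integer(n_rstb)
  n_stl_per_rstb <- as.integer(n_stl_per_rstb)
  if (n_rstb < 1L || n_stl_per_rstb < 1L)
    err_config("block counts must be positive")
  if (in_channels < 1L || out_channels < 1L)
    err_config("channel counts must be positive")
  structure(list(n_rstb = n_rstb, n_stl_per_rstb = n_stl_per_rstb,
                 swin = swin, in_channels = in_channels,
                 out_channels = out_channels, use_swin = use_swin,
                 recovery = recovery),
            class = "stg_config")
}

#' Initialise generator parameters
#'
#' @param cfg An [stg_config()].
#' @return Flat named list of arrays; deterministic given the RNG state.
#' @export
init_stg <- function(cfg) {
  C <- cfg$swin$embed_dim
  P <- list()
  P$shallow.w <- matrix(trunc_normal(C * cfg$in_channels * 9), C,
                        cfg$in_channels * 9)
  P$shallow.b <- rep(0, C)
  for (r in seq_len(cfg$n_rstb)) {
    if (cfg$use_swin) {
      P <- c(P, pfx(paste0("rstb", r), init_rstb(cfg$swin,
                                                 cfg$n_stl_per_rstb)))
    } else {
      blk <- list()
      for (i in seq_len(cfg$n_stl_per_rstb)) {
        blk[[paste0("cblk", i, ".w")]] <- matrix(trunc_normal(C * C * 9),
                                                 C, C * 9)
        blk[[paste0("cblk", i, ".b")]] <- rep(0, C)
      }
      blk$conv_w <- matrix(trunc_normal(C * C * 9), C, C * 9)
      blk$conv_b <- rep(0, C)
      P <- c(P, pfx(paste0("rstb", r), blk))
    }
  }
  P$body.w <- matrix(trunc_normal(C * C * 9), C, C * 9)
  P$body.b <- rep(0, C)
  P$rec.w <- matrix(trunc_normal(cfg$out_channels * C * 9),
                    cfg$out_channels, C * 9)
  P$rec.b <- rep(0, cfg$out_channels)
  P
}

# Conv-only stand-in for an RSTB (ablation scenarios): conv+GELU blocks
# followed by the block conv, residual to the input.
fwd_conv_block_stack <- function(x, P, n_blk) {
  t <- x
  for (i in seq_len(n_blk)) {
    t <- ad_gelu(ad_conv2d(t, P[[paste0("cblk", i, ".w")]],
                           P[[paste0("cblk", i, ".b")]]))
  }
  t <- ad_conv2d(t, P$conv_w, P$conv_b)
  ad_add(t, x)
}

# Generator forward on tape nodes. x: (Cin, H, W, B) node in [0, 1].
# capture: optional list of environments, one per global STL index.
fwd_stg <- function(x, P, cfg, capture = NULL) {
  t <- ad_conv2d(x, P$shallow.w, P$shallow.b)
  f0 <- t
  gi <- 0L
  for (r in seq_len(cfg$n_rstb)) {
    Pr <- sub_par(P, paste0("rstb", r))
    if (cfg$use_swin) {
      caps <- NULL
      if (!is.null(capture)) {
        caps <- lapply(seq_len(cfg$n_stl_per_rstb), function(i) {
          capture[[gi + i]]
        })
      }
      t <- fwd_rstb(t, Pr, cfg$swin, cfg$n_stl_per_rstb, caps)
    } else {
      t <- fwd_conv_block_stack(t, Pr, cfg$n_stl_per_rstb)
    }
    gi <- gi + cfg$n_stl_per_rstb
  }
  t <- ad_conv2d(t, P$body.w, P$body.b)
  t <- ad_add(t, f0) # long skip: shallow features feed the recovery head
  y <- ad_conv2d(t, P$rec.w, P$rec.b)
  ad_sigmoid(y)
}

check_image_batch <- function(x, what = "input") {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L)
    err_dim(sprintf("%s must be an (H, W, B) array or H x W matrix", what))
  if (any(!is.finite(x))) err_numeric(sprintf("non-finite %s", what))
  if (min(x) < 0 || max(x) > 1) {
    warning(sprintf("%s outside [0, 1]; clamping", what), call. = FALSE)
    x[x < 0] <- 0
    x[x > 1] <- 1
  }
  x
}

# (H, W, B) -> (1, H, W, B)
ib_to_chw <- function(x) {
  d <- dim(x)
  array(x, c(1L, d[1], d[2], d[3]))
}
chw_to_ib <- function(x) {
  d <- dim(x)
  array(x, c(d[2], d[3], d[4]))
}

#' Translate an image batch with the Swin transformer generator
#'
#' @param x An (H, W, B) array (or single H x W matrix) with values in
#'   `[0, 1]`; values outside the range are clamped with a warning.
#' @param cfg An [stg_config()].
#' @param params Parameters from [init_stg()].
#' @return An (H, W, B) array in `[0, 1]` of the same spatial size.
#' @export
stg_forward <- function(x, cfg, params) {
  x <- check_image_batch(x)
  d <- dim(x)
  if (min(d[1], d[2]) < cfg$swin$window)
    err_input("spatial size below window size")
  tape_reset()
  out <- fwd_stg(ad_const(ib_to_chw(x)), const_params(params), cfg)
  v <- chw_to_ib(out$v)
  tape_reset()
  v
}

#' Mean received attention per pixel for one STL
#'
#' Runs the generator forward, captures the softmaxed attention of the
#' STL with global index `layer_index` (counting across RSTBs), and for
#' each key token averages the attention it receives over all queries and
#' heads in its window. Token values are scattered back to pixel positions
#' and scaled by the per-image maximum, so a uniform attention pattern maps
#' to values near 1 everywhere rather than being stretched to full range.
#'
#' @param x An (H, W, B) image batch in `[0, 1]`.
#' @param cfg An [stg_config()] with `use_swin = TRUE`.
#' @param params Parameters from [init_stg()].
#' @param layer_index Global STL index in `1..(n_rstb * n_stl_per_rstb)`.
#' @return An (H, W, B) array with values in `[0, 1]`.
#' @export
extract_attention_maps <- function(x, cfg, params, layer_index) {
  if (!cfg$use_swin) err_config("attention maps need a swin generator")
  n_stl <- cfg$n_rstb * cfg$n_stl_per_rstb
  layer_index <- as.integer(layer_index)
  if (layer_index < 1L || layer_index > n_stl)
    err_config("layer_index out of range")
  x <- check_image_batch(x)
  d <- dim(x)
  H <- d[1]; W <- d[2]; B <- d[3]
  caps <- vector("list", n_stl)
  caps[[layer_index]] <- new.env(parent = emptyenv())
  tape_reset()
  invisible(fwd_stg(ad_const(ib_to_chw(x)), const_params(params), cfg, caps))
  A <- caps[[layer_index]]$attn # (m2 keys, m2 queries, h * nW * B)
  tape_reset()
  m <- cfg$swin$window
  h <- cfg$swin$num_heads
  m2 <- m * m
  Hp <- ceiling(H / m) * m
  Wp <- ceiling(W / m) * m
  nW <- (Hp %/% m) * (Wp %/% m)
  # received attention per key token: average over queries and heads
  recv <- with_dim(rowMeans(aperm(with_dim(A, c(m2, m2, h, nW, B)),
                                  c(1, 4, 5, 2, 3)), dims = 3),
                   c(1L, m2, nW, B))
  # reassemble on the padded extent, undo the cyclic shift of shifted
  # layers, then crop back to H x W
  i_in_block <- ((layer_index - 1L) %% cfg$n_stl_per_rstb) + 1L
  s <- if (i_in_block %% 2L == 0L) m %/% 2L else 0L
  maps <- as.vector(recv)[win_rev_idx(1L, Hp, Wp, B, m)]
  dim(maps) <- c(1L, Hp, Wp, B)
  if (s > 0L) {
    maps <- maps[roll_idx(1L, Hp, Wp, B, (-s) %% Hp, (-s) %% Wp)]
    dim(maps) <- c(1L, Hp, Wp, B)
  }
  if (Hp != H || Wp != W) {
    maps <- maps[crop_idx(1L, Hp, Wp, B, H, W)]
    dim(maps) <- c(1L, H, W, B)
  }
  maps <- chw_to_ib(maps)
  for (b in seq_len(B)) {
    mx <- max(maps[, , b])
    if (mx > 0) maps[, , b] <- maps[, , b] / mx
  }
  maps
}
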