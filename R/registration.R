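# Swin transformer registration network (STR): a U-shaped encoder-decoder
# that takes the moving image (the generator output) and the fixed image
# (the observed target) and predicts a dense displacement vector field
# (DVF) in pixel units, plus the bilinear resampling operator and the
# displacement smoothness penalty.
#
# DVFs are (2, H, W, B) arrays: component 1 is the row displacement,
# component 2 the column displacement, added to the identity sampling grid.

#' Registration network configuration
#'
#' @param levels Number of stride-2 encoder stages (default 4). Each stage
#'   halves the spatial size and doubles the channel count (capped at
#'   `8 * base_channels`).
#' @param base_channels Channels after the full-resolution stem (default 16).
#' @param leaky_slope Negative slope of the LeakyReLU activations (0.2).
#' @param n_stl_encoder Swin transformer layers appended to each encoder
#'   stage (default 2); ignored when `use_swin = FALSE`.
#' @param use_swin If `FALSE` the encoder is convolution-only (the ablation
#'   registration network).
#' @param window Window size of the encoder STLs (default 4). Stages whose
#'   spatial size is below the window skip their STLs.
#' @param num_heads Attention heads of the encoder STLs.
#' @return Object of class `str_config`.
#' @export
str_config <- function(levels = 4L, base_channels = 16L, leaky_slope = 0.2,
                       n_stl_encoder = 2L, use_swin = TRUE, window = 4L,
                       num_heads = 2L) {
  levels <- as.integer(levels)
  base_channels <- as.integer(base_channels)
  if (levels < 1L) err_config("levels must be >= 1")
  if (base_channels < 1L) err_config("base_channels must be positive")
  structure(list(levels = levels, base_channels = base_channels,
                 leaky_slope = leaky_slope,
                 n_stl_encoder = as.integer(n_stl_encoder),
                 use_swin = use_swin, window = as.integer(window),
                 num_heads = as.integer(num_heads)),
            class = "str_config")
}

str_channels <- function(cfg) {
  pmin(cfg$base_channels * 2^(seq_len(cfg$levels)), 8L * cfg$base_channels)
}

#' Initialise registration network parameters
#'
#' The flow head is zero-initialised so training starts from the identity
#' warp.
#'
#' @param cfg An [str_config()].
#' @param in_channels Channels of the concatenated (moving, fixed) input
#'   (default 2).
#' @return Flat named list of arrays.
#' @export
init_str <- function(cfg, in_channels = 2L) {
  ch <- str_channels(cfg)
  b0 <- cfg$base_channels
  P <- list()
  P$stem.w <- matrix(trunc_normal(b0 * in_channels * 9), b0, in_channels * 9)
  P$stem.b <- rep(0, b0)
  cin <- b0
  for (l in seq_len(cfg$levels)) {
    P[[paste0("enc", l, ".w")]] <- matrix(trunc_normal(ch[l] * cin * 9),
                                          ch[l], cin * 9)
    P[[paste0("enc", l, ".b")]] <- rep(0, ch[l])
    if (cfg$use_swin) {
      scfg <- swin_config(window = cfg$window, embed_dim = ch[l],
                          num_heads = cfg$num_heads)
      for (i in seq_len(cfg$n_stl_encoder)) {
        P <- c(P, pfx(paste0("enc", l, ".stl", i), init_stl(scfg)))
      }
    }
    cin <- ch[l]
  }
  for (l in rev(seq_len(cfg$levels))) {
    skip_ch <- if (l == 1L) b0 else ch[l - 1L]
    out_ch <- skip_ch
    P[[paste0("dec", l, ".w")]] <- matrix(
      trunc_normal(out_ch * (ch[l] + skip_ch) * 9), out_ch,
      (ch[l] + skip_ch) * 9)
    P[[paste0("dec", l, ".b")]] <- rep(0, out_ch)
    ch[l] <- out_ch # channels entering the next (shallower) decoder stage
  }
  P$refine1.w <- matrix(trunc_normal(b0 * b0 * 9), b0, b0 * 9)
  P$refine1.b <- rep(0, b0)
  P$refine2.w <- matrix(trunc_normal(b0 * b0 * 9), b0, b0 * 9)
  P$refine2.b <- rep(0, b0)
  P$flow.w <- matrix(0, 2, b0 * 9)
  P$flow.b <- rep(0, 2)
  P
}

# STR forward on tape nodes. moving, fixed: (1, H, W, B). Returns a
# (2, H, W, B) DVF node.
fwd_str <- function(moving, fixed, P, cfg) {
  sl <- cfg$leaky_slope
  x <- ad_concat1(moving, fixed)
  x <- ad_leakyrelu(ad_conv2d(x, P$stem.w, P$stem.b), sl)
  skips <- list(x)
  ch <- str_channels(cfg)
  for (l in seq_len(cfg$levels)) {
    x <- ad_leakyrelu(ad_conv2d(x, P[[paste0("enc", l, ".w")]],
                                P[[paste0("enc", l, ".b")]],
                                stride = 2L, pad = 1L), sl)
    sz <- dim(x$v)[2:3]
    if (cfg$use_swin && min(sz) >= cfg$window) {
      scfg <- swin_config(window = cfg$window, embed_dim = ch[l],
                          num_heads = cfg$num_heads)
      for (i in seq_len(cfg$n_stl_encoder)) {
        scfg$shift <- if (i %% 2L == 1L) 0L else cfg$window %/% 2L
        x <- fwd_stl(x, sub_par(P, paste0("enc", l, ".stl", i)), scfg)
      }
    }
    skips[[l + 1L]] <- x
  }
  for (l in rev(seq_len(cfg$levels))) {
    x <- ad_upsample(x, 2L)
    x <- ad_concat1(x, skips[[l]])
    x <- ad_leakyrelu(ad_conv2d(x, P[[paste0("dec", l, ".w")]],
                                P[[paste0("dec", l, ".b")]]), sl)
  }
  x <- ad_leakyrelu(ad_conv2d(x, P$refine1.w, P$refine1.b), sl)
  x <- ad_leakyrelu(ad_conv2d(x, P$refine2.w, P$refine2.b), sl)
  ad_conv2d(x, P$flow.w, P$flow.b)
}

as_dvf <- function(dvf, B = NULL) {
  d <- dim(dvf)
  if (length(d) == 3L) {
    if (d[1] != 2L) err_dim("DVF must have 2 components in dim 1")
    dvf <- array(dvf, c(d, 1L))
  } else if (length(d) != 4L || d[1] != 2L) {
    err_dim("DVF must be a (2, H, W, B) array")
  }
  if (any(!is.finite(dvf))) err_numeric("non-finite displacement field")
  dvf
}

#' Predict a displacement field registering a moving to a fixed image
#'
#' Concatenates the two images on the channel axis and runs the U-shaped
#' encoder-decoder: stride-2 3x3 convolutions with LeakyReLU(0.2)
#' interleaved with Swin transformer layers on the way down, nearest-
#' neighbour upsampling + 3x3 convolutions with encoder skip connections on
#' the way up, two full-resolution refinement convolutions, and a
#' zero-initialised flow head.
#'
#' @param moving,fixed (H, W, B) arrays (or H x W matrices) in `[0, 1]`.
#' @param cfg An [str_config()].
#' @param params Parameters from [init_str()].
#' @return A (2, H, W, B) displacement field in pixel units.
#' @export
str_forward <- function(moving, fixed, cfg, params) {
  moving <- check_image_batch(moving, "moving image")
  fixed <- check_image_batch(fixed, "fixed image")
  if (!identical(dim(moving), dim(fixed)))
    err_dim("moving and fixed images must have the same shape")
  tape_reset()
  out <- fwd_str(ad_const(ib_to_chw(moving)), ad_const(ib_to_chw(fixed)),
                 const_params(params), cfg)
  v <- out$v
  tape_reset()
  v
}

#' Resample an image along a displacement field
#'
#' `output(p) = image(p + dvf(p))` with bilinear interpolation;
#' out-of-bounds sample coordinates are clamped to the image border. A zero
#' field reproduces the input exactly.
#'
#' @param image (H, W, B) array, H x W matrix, or (C, H, W, B) array.
#' @param dvf (2, H, W, B) (or (2, H, W) for a single image) displacement
#'   field in pixels, components (row, col).
#' @return Warped image with the shape of `image`.
#' @export
spatial_resample <- function(image, dvf) {
  was_mat <- is.matrix(image)
  chw <- length(dim(image)) == 4L
  x <- if (chw) image else ib_to_chw(check_image_batch(image, "image"))
  dvf <- as_dvf(dvf)
  d <- dim(x)
  if (!identical(as.integer(dim(dvf)[2:4]), as.integer(d[2:4])))
    err_dim("image and DVF spatial shapes disagree")
  v <- warp_fwd_cpp(as.numeric(x), as.numeric(dvf), d[1], d[2], d[3], d[4])
  dim(v) <- d
  if (chw) return(v)
  v <- chw_to_ib(v)
  if (was_mat) v[, , 1] else v
}

#' Smoothness penalty of a displacement field
#'
#' Mean squared forward finite difference of the displacement, i.e. the
#' mean over pixels, components and batch of the squared spatial gradient
#' magnitude summed over the two directions:
#' `mean(drow^2) + mean(dcol^2)`. A constant field scores 0 and the penalty
#' is quadratically homogeneous.
#'
#' @param dvf (2, H, W, B) or (2, H, W) displacement field.
#' @return Non-negative scalar.
#' @export
smoothness_loss <- function(dvf) {
  dvf <- as_dvf(dvf)
  d <- dim(dvf)
  dr <- dvf[, -1, , , drop = FALSE] - dvf[, -d[2], , , drop = FALSE]
  dc <- dvf[, , -1, , drop = FALSE] - dvf[, , -d[3], , drop = FALSE]
  mean(dr * dr) + mean(dc * dc)
}

# Tape version of the smoothness penalty via shifted-slice gathers.
smooth_diff_idx <- function(d, axis) {
  key <- paste("sdiff", paste(d, collapse = "x"), axis, sep = "_")
  cache_get(key, function() {
    C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
    if (axis == 1L) {
      hi <- 1:(H - 1L)
      a <- outer(outer(1 + 0:(C - 1L), (hi) * C, "+"),
                 (0:(W - 1L)) * C * H, "+") # shifted rows (r+1)
      b <- outer(outer(1 + 0:(C - 1L), (hi - 1L) * C, "+"),
                 (0:(W - 1L)) * C * H, "+")
    } else {
      wi <- 1:(W - 1L)
      a <- outer(outer(1 + 0:(C - 1L), (0:(H - 1L)) * C, "+"),
                 wi * C * H, "+")
      b <- outer(outer(1 + 0:(C - 1L), (0:(H - 1L)) * C, "+"),
                 (wi - 1L) * C * H, "+")
    }
    off <- (0:(B - 1L)) * C * H * W
    ia <- outer(as.vector(a), off, "+")
    ib <- outer(as.vector(b), off, "+")
    storage.mode(ia) <- "integer"
    storage.mode(ib) <- "integer"
    list(a = as.vector(ia), b = as.vector(ib),
         n = length(ia))
  })
}

ad_smoothness <- function(dvf) {
  d <- dim(dvf$v)
  ir <- smooth_diff_idx(d, 1L)
  ic <- smooth_diff_idx(d, 2L)
  dr <- ad_sub(ad_gather(dvf, ir$a, ir$n), ad_gather(dvf, ir$b, ir$n))
  dc <- ad_sub(ad_gather(dvf, ic$a, ic$n), ad_gather(dvf, ic$b, ic$n))
  ad_add(ad_mean(ad_sq(dr)), ad_mean(ad_sq(dc)))
}

#' Fit the registration network alone on image pairs
#'
#' Optimises `L1(fixed, moving o DVF) + mu * smoothness(DVF)` with Adam,
#' leaving generator and discriminator out entirely. Useful for
#' registration-only experiments and for validating displacement recovery
#' against synthetic ground truth.
#'
#' @param moving,fixed (H, W, B) arrays (or lists of matrices) in `[0, 1]`;
#'   the network learns to warp `moving` onto `fixed`.
#' @param cfg An [str_config()].
#' @param epochs Passes over the pairs (default 10).
#' @param batch_size Pairs per step (default 4).
#' @param lr Adam learning rate. Registration-only fitting converges much
#'   faster than GAN training; the default 1e-3 suits the small encoder.
#' @param lambda,mu Correction and smoothness weights (defaults 20 and 10,
#'   the published operating point; what matters here is their ratio).
#' @param seed Seed controlling initialisation and batch order.
#' @return List with `params`, `cfg`, and `history` (per-epoch mean L1 and
#'   smoothness).
#' @export
fit_registration <- function(moving, fixed, cfg = str_config(),
                             epochs = 10L, batch_size = 4L, lr = 1e-3,
                             lambda = 20, mu = 10, seed = 1L) {
  as_arr <- function(x) {
    if (is.list(x)) {
      a <- array(0, c(dim(x[[1]]), length(x)))
      for (i in seq_along(x)) a[, , i] <- x[[i]]
      a
    } else if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
  }
  moving <- as_arr(moving)
  fixed <- as_arr(fixed)
  if (!identical(dim(moving), dim(fixed)))
    err_dim("moving and fixed shapes disagree")
  n <- dim(moving)[3]
  set.seed(derive_seed(seed, 7L))
  P <- init_str(cfg)
  # non-adversarial objective: standard Adam momentum
  opt <- adam_new(P, lr = lr, beta1 = 0.9)
  hist <- matrix(0, epochs, 2L,
                 dimnames = list(NULL, c("l1", "smooth")))
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(seed, 7000L + ep))
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    comp <- matrix(0, length(batches), 2L)
    for (bi in seq_along(batches)) {
      ix <- batches[[bi]]
      mv <- array(moving[, , ix], c(1L, dim(moving)[1:2], length(ix)))
      fx <- array(fixed[, , ix], c(1L, dim(fixed)[1:2], length(ix)))
      tape_reset()
      Pn <- wrap_params(P)
      dvf <- fwd_str(ad_const(mv), ad_const(fx), Pn, cfg)
      warped <- ad_warp(ad_const(mv), dvf)
      l1 <- ad_mean(ad_abs(ad_sub(ad_const(fx), warped)))
      sm <- ad_smoothness(dvf)
      loss <- ad_add(ad_smul(l1, lambda), ad_smul(sm, mu))
      if (!is.finite(loss$v)) err_numeric("NaN/Inf registration loss")
      ad_backward(loss)
      up <- adam_step(P, collect_grads(Pn), opt)
      P <- up$params
      opt <- up$st
      comp[bi, ] <- c(l1$v, sm$v)
    }
    hist[ep, ] <- colMeans(comp)
  }
  tape_reset()
  list(params = P, cfg = cfg, history = as.data.frame(cbind(
    epoch = seq_len(epochs), hist)))
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the inverse warp: `v(p) = -u(p + v(p))`,
#' starting from `v = -u`. Accurate for smooth, moderate-amplitude fields.
#'
#' @param dvf (2, H, W, B) or (2, H, W) displacement field.
#' @param iters Fixed-point iterations (default 8).
#' @return Field of the same shape such that warping by it approximately
#'   undoes warping by `dvf`.
#' @export
invert_dvf <- function(dvf, iters = 8L) {
  was3 <- length(dim(dvf)) == 3L
  u <- as_dvf(dvf)
  v <- -u
  for (k in seq_len(iters)) {
    # sample u at p + v(p) and negate
    d <- dim(u)
    smp <- warp_fwd_cpp(u, v, d[1], d[2], d[3], d[4])
    v <- -with_dim(smp, d)
  }
  if (was3) with_dim(v, dim(dvf)) else v
}
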