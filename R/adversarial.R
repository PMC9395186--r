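# Convolutional patch discriminator and the three training losses:
# adversarial (logit-space binary cross-entropy), registration-corrected L1
# correction loss, and displacement smoothness, combined with weights
# (kappa, lambda, mu).

#' Loss weights for the total objective
#'
#' The total loss is `kappa * L_adv + lambda * L_corr + mu * L_smooth`.
#' Defaults are the published operating point (kappa = 1, lambda = 20,
#' mu = 10).
#'
#' @param kappa Weight of the adversarial term (non-negative).
#' @param lambda Weight of the correction (registered L1) term.
#' @param mu Weight of the smoothness term.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(kappa = 1, lambda = 20, mu = 10) {
  if (kappa < 0 || lambda < 0 || mu < 0)
    err_config("loss weights must be non-negative")
  structure(list(kappa = kappa, lambda = lambda, mu = mu),
            class = "loss_weights")
}

#' Patch discriminator configuration
#'
#' A pix2pix-style patch classifier: `n_layers` stride-2 3x3 convolutions
#' with LeakyReLU(0.2) and instance normalisation from the second block,
#' then a stride-1 convolution to a single logit channel. Each output logit
#' covers one local receptive field.
#'
#' @param n_layers Number of stride-2 blocks (default 3).
#' @param base_channels Channels of the first block (default 64).
#' @return Object of class `disc_config`.
#' @export
disc_config <- function(n_layers = 3L, base_channels = 64L) {
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) err_config("n_layers must be >= 1")
  structure(list(n_layers = n_layers,
                 base_channels = as.integer(base_channels)),
            class = "disc_config")
}

#' Initialise discriminator parameters
#' @param cfg A [disc_config()].
#' @param in_channels Image channels (default 1).
#' @return Flat named list of arrays.
#' @export
init_disc <- function(cfg, in_channels = 1L) {
  ch <- pmin(cfg$base_channels * 2^(seq_len(cfg$n_layers) - 1L),
             8L * cfg$base_channels)
  P <- list()
  cin <- in_channels
  for (l in seq_len(cfg$n_layers)) {
    P[[paste0("conv", l, ".w")]] <- matrix(trunc_normal(ch[l] * cin * 9),
                                           ch[l], cin * 9)
    P[[paste0("conv", l, ".b")]] <- rep(0, ch[l])
    if (l >= 2L) {
      P[[paste0("in", l, ".g")]] <- rep(1, ch[l])
      P[[paste0("in", l, ".b")]] <- rep(0, ch[l])
    }
    cin <- ch[l]
  }
  P$final.w <- matrix(trunc_normal(cin * 9), 1, cin * 9)
  P$final.b <- 0
  P
}

fwd_disc <- function(x, P, cfg) {
  t <- x
  for (l in seq_len(cfg$n_layers)) {
    t <- ad_conv2d(t, P[[paste0("conv", l, ".w")]],
                   P[[paste0("conv", l, ".b")]], stride = 2L, pad = 1L)
    if (l >= 2L) {
      t <- ad_instnorm(t, P[[paste0("in", l, ".g")]],
                       P[[paste0("in", l, ".b")]])
    }
    t <- ad_leakyrelu(t, 0.2)
  }
  ad_conv2d(t, P$final.w, P$final.b)
}

#' Patch logits for an image batch
#'
#' @param img (H, W, B) array (or H x W matrix) in `[0, 1]`.
#' @param cfg A [disc_config()].
#' @param params Parameters from [init_disc()].
#' @return A (1, H', W', B) grid of real-valued logits, `H' = H / 2^n_layers`
#'   (no final sigmoid; the losses work on logits).
#' @export
discriminator_forward <- function(img, cfg, params) {
  img <- check_image_batch(img, "discriminator input")
  d <- dim(img)
  if (min(d[1], d[2]) < 2^cfg$n_layers)
    err_config("image too small for the stride-2 stack")
  tape_reset()
  out <- fwd_disc(ad_const(ib_to_chw(img)), const_params(params), cfg)
  v <- out$v
  tape_reset()
  v
}

# Tape-level adversarial losses (logit space, numerically stable).
ad_adv_loss_d <- function(real_logits, fake_logits) {
  ad_add(ad_smul(ad_mean(ad_logsigmoid(real_logits)), -1),
         ad_smul(ad_mean(ad_logsigmoid(ad_smul(fake_logits, -1))), -1))
}

ad_adv_loss_g <- function(fake_logits) {
  ad_smul(ad_mean(ad_logsigmoid(fake_logits)), -1)
}

#' Adversarial loss on patch logits
#'
#' For `role = "discriminator"` the minimised objective is
#' `-E[log sigmoid(D(y))] - E[log(1 - sigmoid(D(G(x))))]` (the negative of
#' the inner GAN value); at all-zero logits it equals `2 log 2`. For
#' `role = "generator"` the non-saturating form
#' `-E[log sigmoid(D(G(x)))]` is used (`log 2` at zero logits); its
#' gradient direction matches the saturating minimax term.
#'
#' @param real_logits Logit array for real targets (unused for the
#'   generator role; pass `NULL`).
#' @param fake_logits Logit array for generated images.
#' @param role `"discriminator"` or `"generator"`.
#' @return Scalar loss.
#' @export
adversarial_loss <- function(real_logits, fake_logits,
                             role = c("discriminator", "generator")) {
  role <- match.arg(role)
  if (!is.null(real_logits) && any(!is.finite(real_logits)))
    err_numeric("non-finite logits")
  if (any(!is.finite(fake_logits))) err_numeric("non-finite logits")
  logsig <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))
  if (role == "discriminator") {
    if (is.null(real_logits)) err_input("discriminator role needs real logits")
    -mean(logsig(real_logits)) - mean(logsig(-fake_logits))
  } else {
    -mean(logsig(fake_logits))
  }
}

#' Registration-corrected L1 correction loss
#'
#' Mean absolute error between the observed target `y` and the generated
#' image warped by the predicted displacement field:
#' `E[| y - G(x) o R(G(x), y) |]`. With a zero field this reduces to plain
#' L1.
#'
#' @param y Observed target, (H, W, B) array or H x W matrix.
#' @param g_x Generated image, same shape as `y`.
#' @param dvf (2, H, W, B) displacement field (or (2, H, W)).
#' @return Non-negative scalar.
#' @export
correction_loss <- function(y, g_x, dvf) {
  y <- check_image_batch(y, "target")
  g_x <- check_image_batch(g_x, "generated image")
  if (!identical(dim(y), dim(g_x)))
    err_dim("target and generated image shapes disagree")
  warped <- spatial_resample(g_x, dvf)
  mean(abs(y - warped))
}

#' Weighted total training loss
#'
#' `kappa * adv + lambda * corr + mu * smooth`.
#'
#' @param adv,corr,smooth Scalar loss components.
#' @param w A [loss_weights()].
#' @return Scalar.
#' @export
total_loss <- function(adv, corr, smooth, w = loss_weights()) {
  if (!all(is.finite(c(adv, corr, smooth))))
    err_numeric("non-finite loss component")
  w$kappa * adv + w$lambda * corr + w$mu * smooth
}
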