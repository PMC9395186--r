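# Image-fidelity metrics on the [0, 1] intensity scale: PSNR (data range
# fixed at 1, capped at 100 dB), MAE, and SSIM (11x11 Gaussian window,
# sd 1.5, Wang et al. constants), reported per image and as mean +/- sd.

as_image_list <- function(x) {
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[3]), function(b) x[, , b]))
  }
  if (is.list(x)) return(x)
  err_dim("expected a matrix, (H, W, B) array, or list of matrices")
}

# SSIM between two matrices; 'valid'-region mean of the SSIM map computed
# with a normalized Gaussian window (no sample-covariance correction).
ssim_pair <- function(a, b, win = 11L, sigma = 1.5, data_range = 1) {
  if (min(dim(a)) < win) err_dim("image smaller than the SSIM window")
  k <- dnorm(seq_len(win) - (win + 1) / 2, sd = sigma)
  k <- k / sum(k)
  fil1 <- function(x) { # valid separable filtering
    H <- nrow(x); W <- ncol(x)
    y <- matrix(0, H - win + 1L, W)
    for (i in seq_len(win)) y <- y + k[i] * x[i:(i + H - win), , drop = FALSE]
    z <- matrix(0, H - win + 1L, W - win + 1L)
    for (i in seq_len(win)) z <- z + k[i] * y[, i:(i + W - win), drop = FALSE]
    z
  }
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu1 <- fil1(a)
  mu2 <- fil1(b)
  s11 <- fil1(a * a) - mu1 * mu1
  s22 <- fil1(b * b) - mu2 * mu2
  s12 <- fil1(a * b) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1 * mu1 + mu2 * mu2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Compute PSNR, MAE and SSIM for a batch of image pairs
#'
#' Definitions (data range fixed at 1.0, per the [0, 1] normalisation):
#' `PSNR = 10 log10(1 / MSE)` capped at 100 dB when `MSE < 1e-10`;
#' `MAE = mean |pred - truth|`; SSIM with an 11x11 Gaussian window of
#' sd 1.5 and constants `C1 = 0.01^2`, `C2 = 0.03^2`.
#'
#' @param pred,truth Matching matrices, (H, W, B) arrays, or lists of
#'   matrices with values in `[0, 1]`.
#' @return Object of class `metrics_record`: per-image vectors `psnr`,
#'   `mae`, `ssim` plus a `summary` data frame of mean and sd.
#' @export
compute_metrics <- function(pred, truth) {
  p <- as_image_list(pred)
  t <- as_image_list(truth)
  if (length(p) != length(t)) err_dim("batch sizes disagree")
  n <- length(p)
  psnr <- mae <- ssim <- numeric(n)
  for (i in seq_len(n)) {
    if (!identical(dim(p[[i]]), dim(t[[i]])))
      err_dim("image shapes disagree")
    d <- p[[i]] - t[[i]]
    mse <- mean(d * d)
    psnr[i] <- if (mse < 1e-10) 100 else 10 * log10(1 / mse)
    mae[i] <- mean(abs(d))
    ssim[i] <- ssim_pair(p[[i]], t[[i]])
  }
  structure(list(
    psnr = psnr, mae = mae, ssim = ssim,
    summary = data.frame(
      metric = c("psnr", "mae", "ssim"),
      mean = c(mean(psnr), mean(mae), mean(ssim)),
      sd = c(if (n > 1) sd(psnr) else 0, if (n > 1) sd(mae) else 0,
             if (n > 1) sd(ssim) else 0))),
    class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("metrics over %d image(s):\n", length(x$psnr)))
  cat(sprintf("  PSNR  %6.2f +/- %.2f dB\n", x$summary$mean[1],
              x$summary$sd[1]))
  # MAE shown x100 to match the conventional 10^-2 display scale
  cat(sprintf("  MAE   %6.2f +/- %.2f (x 10^-2)\n",
              100 * x$summary$mean[2], 100 * x$summary$sd[2]))
  cat(sprintf("  SSIM  %6.4f +/- %.4f\n", x$summary$mean[3],
              x$summary$sd[3]))
  invisible(x)
}

#' Per-pixel absolute error map
#'
#' @param pred,truth Matching matrices or (H, W, B) arrays in `[0, 1]`.
#' @return `|pred - truth|`, same shape; its mean equals the MAE.
#' @export
error_map <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) err_dim("shapes disagree")
  abs(pred - truth)
}
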