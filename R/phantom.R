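# Synthetic multi-modal phantom generator: shared elliptical "anatomy"
# rendered under two monotone, mutually inverted intensity lookup tables
# (emulating T1-vs-T2 contrast), with optional known smooth misalignment of
# the target modality and an unpaired sampling mode. Replaces real MRI
# datasets for desk-scale experiments and ground-truth checks.

#' Phantom dataset configuration
#'
#' @param image_size Square image side in pixels (>= 16, default 32).
#' @param n_samples Number of samples to generate.
#' @param n_shapes Integer range (length-2 vector) of interior ellipses per
#'   phantom; default 3 to 6.
#' @param noise_sd Gaussian intensity noise standard deviation (default
#'   0.01 on the [0, 1] scale).
#' @param blur_sd Gaussian blur sd in pixels applied after noise (default
#'   0.5; 0 disables blurring).
#' @param deform_amplitude Maximum displacement magnitude in pixels of the
#'   misalignment field (default 2).
#' @param deform_smoothness Gaussian kernel sd (pixels) of the deformation
#'   smoothing (default 4).
#' @param mode One of `"aligned"`, `"misaligned"`, `"unpaired"`.
#' @param seed Integer master seed; the full dataset is a deterministic
#'   function of the configuration.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 32L, n_samples = 16L,
                           n_shapes = c(3L, 6L), noise_sd = 0.01,
                           blur_sd = 0.5, deform_amplitude = 2.0,
                           deform_smoothness = 4.0,
                           mode = c("aligned", "misaligned", "unpaired"),
                           seed = 1L) {
  mode <- match.arg(mode)
  image_size <- as.integer(image_size)
  if (image_size < 16L) err_config("image_size must be >= 16")
  if (noise_sd < 0 || deform_amplitude < 0)
    err_config("noise_sd and deform_amplitude must be non-negative")
  if (deform_smoothness <= 0) err_config("deform_smoothness must be positive")
  n_samples <- as.integer(n_samples)
  if (mode == "unpaired" && n_samples < 2L)
    err_config("unpaired mode needs at least 2 samples (derangement)")
  structure(list(image_size = image_size, n_samples = n_samples,
                 n_shapes = as.integer(range(n_shapes)), noise_sd = noise_sd,
                 blur_sd = blur_sd, deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness, mode = mode,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Separable Gaussian blur of a matrix, reflect boundary.
gaussian_blur <- function(x, sd) {
  if (sd <= 0) return(x)
  r <- max(1L, ceiling(3 * sd))
  k <- dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  pad_ref <- function(n, r) {
    idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    idx
  }
  H <- nrow(x); W <- ncol(x)
  xp <- x[pad_ref(H, r), , drop = FALSE]
  y <- matrix(0, H, W)
  for (i in seq_along(k)) y <- y + k[i] * xp[i:(i + H - 1L), , drop = FALSE]
  yp <- y[, pad_ref(W, r), drop = FALSE]
  z <- matrix(0, H, W)
  for (i in seq_along(k)) z <- z + k[i] * yp[, i:(i + W - 1L), drop = FALSE]
  z
}

#' Render a random labelled tissue map
#'
#' A head-like outer ellipse (label 1) inscribed with a margin, plus
#' `n_shapes` random interior ellipses with labels `2..n_shapes+1` (later
#' shapes overdraw earlier ones). Background is label 0.
#'
#' @param seed Integer seed; the map is deterministic given it.
#' @param size Image side in pixels (>= 16).
#' @param n_shapes Length-2 integer range for the number of interior
#'   ellipses.
#' @return A `size x size` integer matrix of labels with attribute
#'   `n_labels` (the number of distinct non-background labels used).
#' @export
make_anatomy <- function(seed, size = 32L, n_shapes = c(3L, 6L)) {
  size <- as.integer(size)
  if (size < 16L) err_config("size must be >= 16")
  set.seed(seed)
  n_shapes <- as.integer(range(n_shapes))
  n <- if (n_shapes[1] == n_shapes[2]) n_shapes[1] else
    sample(n_shapes[1]:n_shapes[2], 1L)
  cx <- (size + 1) / 2 + runif(1, -0.02, 0.02) * size
  cy <- (size + 1) / 2 + runif(1, -0.02, 0.02) * size
  a0 <- runif(1, 0.34, 0.42) * size
  b0 <- runif(1, 0.34, 0.42) * size
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  lab <- matrix(0L, size, size)
  inside0 <- ((rr - cx) / a0)^2 + ((cc - cy) / b0)^2 <= 1
  lab[inside0] <- 1L
  for (k in seq_len(n)) {
    repeat {
      ex <- runif(1, 0.25, 0.75) * size
      ey <- runif(1, 0.25, 0.75) * size
      if (((ex - cx) / a0)^2 + ((ey - cy) / b0)^2 <= 0.55) break
    }
    ea <- runif(1, 0.05, 0.18) * size
    eb <- runif(1, 0.05, 0.18) * size
    th <- runif(1, 0, pi)
    dx <- rr - ex
    dy <- cc - ey
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / ea)^2 + (v / eb)^2 <= 1
    lab[inside & inside0] <- k + 1L
  }
  attr(lab, "n_labels") <- n + 1L
  lab
}

# Modality lookup tables: monotone increasing intensities for modality A;
# modality B reverses the ordering of the non-background tissues
# (contrast inversion). Background sits at 0.05 in both.
modality_lut <- function(n_labels, modality) {
  tiss <- seq(0.30, 0.95, length.out = n_labels)
  if (modality == "B") tiss <- rev(tiss)
  c(0.05, tiss) # index by label + 1
}

#' Render a tissue map under one modality's intensity mapping
#'
#' Maps labels through the modality lookup table, adds Gaussian noise,
#' blurs mildly, and clamps to `[0, 1]` (noise before blur, clamp last).
#'
#' @param anatomy Labelled matrix from [make_anatomy()].
#' @param modality `"A"` (bright tissues ordered by label) or `"B"`
#'   (reversed tissue ordering, emulating T1/T2 contrast inversion).
#' @param noise_sd Gaussian noise sd.
#' @param seed Seed for the noise draw.
#' @param blur_sd Gaussian blur sd in pixels (0 = no blur).
#' @return Matrix of intensities in `[0, 1]`, same size as `anatomy`.
#' @export
modality_transform <- function(anatomy, modality = c("A", "B"),
                               noise_sd = 0.01, seed = 1L, blur_sd = 0.5) {
  modality <- match.arg(modality)
  n_labels <- attr(anatomy, "n_labels") %||% max(anatomy)
  lut <- modality_lut(n_labels, modality)
  img <- matrix(lut[anatomy + 1L], nrow(anatomy), ncol(anatomy))
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
  }
  img <- gaussian_blur(img, blur_sd)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Draw a random smooth displacement field
#'
#' Gaussian-smoothed white noise per component, rescaled so the maximum
#' displacement magnitude over pixels equals `amplitude` exactly
#' (`amplitude = 0` gives the zero field).
#'
#' @param seed Integer seed.
#' @param size Image side in pixels.
#' @param amplitude Maximum displacement magnitude in pixels.
#' @param smoothness Gaussian kernel sd in pixels.
#' @return A (2, size, size) displacement array.
#' @export
random_smooth_dvf <- function(seed, size, amplitude = 2.0, smoothness = 4.0) {
  size <- as.integer(size)
  out <- array(0, c(2L, size, size))
  if (amplitude <= 0) return(out)
  set.seed(seed)
  u <- gaussian_blur(matrix(rnorm(size * size), size), smoothness)
  v <- gaussian_blur(matrix(rnorm(size * size), size), smoothness)
  mx <- max(sqrt(u * u + v * v))
  if (mx == 0) return(out)
  out[1, , ] <- u * (amplitude / mx)
  out[2, , ] <- v * (amplitude / mx)
  out
}

#' Generate a phantom dataset
#'
#' Each sample shares one anatomy rendered under both modality mappings.
#' In `aligned` mode the observed target equals the aligned target and the
#' true field is zero; in `misaligned` mode the observed target is the
#' aligned target warped by a fresh [random_smooth_dvf()] whose ground
#' truth is stored; in `unpaired` mode the observed target is another
#' sample's aligned target chosen by a random derangement (no sample is
#' paired with itself) and no true field exists.
#'
#' @param cfg A [phantom_config()].
#' @return A list of class `phantom_dataset`; each element has fields
#'   `x`, `y_aligned`, `y_observed` (`size x size` matrices in `[0, 1]`),
#'   `true_dvf` ((2, size, size) or `NULL`) and `mode`.
#' @export
make_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  n <- cfg$n_samples
  set.seed(cfg$seed)
  sub <- matrix(sample.int(2^30, 4L * n), ncol = 4L)
  perm <- NULL
  if (cfg$mode == "unpaired") {
    repeat {
      perm <- sample.int(n)
      if (all(perm != seq_len(n))) break
    }
  }
  base <- vector("list", n)
  for (i in seq_len(n)) {
    anat <- make_anatomy(sub[i, 1], cfg$image_size, cfg$n_shapes)
    x <- modality_transform(anat, "A", cfg$noise_sd, sub[i, 2], cfg$blur_sd)
    y <- modality_transform(anat, "B", cfg$noise_sd, sub[i, 3], cfg$blur_sd)
    base[[i]] <- list(x = x, y_aligned = y)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- base[[i]]
    if (cfg$mode == "aligned") {
      s$y_observed <- s$y_aligned
      s$true_dvf <- array(0, c(2L, cfg$image_size, cfg$image_size))
    } else if (cfg$mode == "misaligned") {
      dvf <- random_smooth_dvf(sub[i, 4], cfg$image_size,
                               cfg$deform_amplitude, cfg$deform_smoothness)
      s$y_observed <- spatial_resample(s$y_aligned, dvf)
      s$true_dvf <- dvf
    } else {
      s$y_observed <- base[[perm[i]]]$y_aligned
      s$true_dvf <- NULL
    }
    s$mode <- cfg$mode
    class(s) <- "phantom_sample"
    out[[i]] <- s
  }
  structure(out, class = "phantom_dataset", cfg = cfg)
}

#' Split a dataset into train and held-out parts
#' @param dataset A `phantom_dataset`.
#' @param holdout Fraction held out (0 < holdout < 1).
#' @param seed Seed for the split.
#' @return `list(train = ..., holdout = ...)`, both `phantom_dataset`s.
#' @export
split_dataset <- function(dataset, holdout = 0.2, seed = 1L) {
  n <- length(dataset)
  set.seed(seed)
  k <- max(1L, round(holdout * n))
  hi <- sort(sample.int(n, k))
  mk <- function(idx) structure(dataset[idx], class = "phantom_dataset",
                                cfg = attr(dataset, "cfg"))
  list(train = mk(setdiff(seq_len(n), hi)), holdout = mk(hi))
}
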