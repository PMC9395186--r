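# Training loop (alternating discriminator and generator+registration
# updates), inference, evaluation, the four-scenario ablation matrix and
# the greedy one-at-a-time hyperparameter sweep.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param reg_learning_rate Learning rate for the registration network
#'   (default: `learning_rate`). The registration branch minimises a
#'   purely non-adversarial objective and tolerates — and at desk scale
#'   needs — a larger rate than the GAN pair; see the methods vignette.
#' @param disc_learning_rate Learning rate for the discriminator
#'   (default: `learning_rate`). Lowering it relative to the generator is
#'   the standard remedy when the discriminator wins the adversarial game
#'   outright at small scale.
#' @param epochs Training epochs (published setting: 80; desk-scale tests
#'   use far fewer).
#' @param batch_size Images per batch (default 4).
#' @param weights A [loss_weights()] (defaults kappa 1, lambda 20, mu 10).
#' @param seed Master seed; data order, initialisation and therefore the
#'   whole checkpoint are deterministic functions of it.
#' @param scenario One of `"baseline_gan"` (conv G, conv R),
#'   `"swin_g"` (swin G, no registration), `"swin_g_plus_r"` (swin G,
#'   conv R), `"mmtrans"` (swin G and swin R).
#' @param mode Data sampling mode the config expects
#'   (`"aligned"`, `"misaligned"`, `"unpaired"`); informational, the
#'   dataset defines the actual pairing.
#' @param generator,registration,discriminator Network configurations
#'   ([stg_config()], [str_config()], [disc_config()]); the scenario
#'   overrides their `use_swin` flags and whether registration exists.
#' @param disc_on_registered If `TRUE` the discriminator sees the
#'   registered (warped) generator output instead of the raw one
#'   (ablation flag; default `FALSE`, matching the adversarial loss which
#'   is written on `G(x)`).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4,
                         reg_learning_rate = learning_rate,
                         disc_learning_rate = learning_rate,
                         epochs = 80L, batch_size = 4L,
                         weights = loss_weights(), seed = 1L,
                         scenario = c("mmtrans", "baseline_gan", "swin_g",
                                      "swin_g_plus_r"),
                         mode = c("aligned", "misaligned", "unpaired"),
                         generator = stg_config(),
                         registration = str_config(),
                         discriminator = disc_config(),
                         disc_on_registered = FALSE) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  if (learning_rate <= 0) err_config("learning_rate must be positive")
  epochs <- as.integer(epochs)
  if (epochs < 1L) err_config("epochs must be >= 1")
  generator$use_swin <- scenario != "baseline_gan"
  registration$use_swin <- scenario == "mmtrans"
  has_r <- scenario != "swin_g"
  structure(list(learning_rate = learning_rate,
                 reg_learning_rate = reg_learning_rate,
                 disc_learning_rate = disc_learning_rate, epochs = epochs,
                 batch_size = as.integer(batch_size), weights = weights,
                 seed = as.integer(seed), scenario = scenario, mode = mode,
                 generator = generator, registration = registration,
                 discriminator = discriminator, has_registration = has_r,
                 disc_on_registered = disc_on_registered),
            class = "train_config")
}

batch_arrays <- function(dataset, idx) {
  H <- nrow(dataset[[1]]$x)
  W <- ncol(dataset[[1]]$x)
  B <- length(idx)
  x <- array(0, c(1L, H, W, B))
  y <- array(0, c(1L, H, W, B))
  for (j in seq_along(idx)) {
    x[1, , , j] <- dataset[[idx[j]]]$x
    y[1, , , j] <- dataset[[idx[j]]]$y_observed
  }
  list(x = x, y = y)
}

#' Train the translation GAN
#'
#' Per batch: (1) the discriminator is updated on the logit-space
#' adversarial loss with the generator output detached; (2) the generator
#' and (when present) the registration network are updated jointly on
#' `kappa * L_adv + lambda * L_corr + mu * L_smooth`, where `L_corr` is the
#' L1 between the observed target and the generated image warped by the
#' predicted displacement field (plain L1 when no registration network
#' exists, with the smoothness term absent). Adam with betas (0.5, 0.999).
#'
#' @param cfg A [train_config()].
#' @param dataset A `phantom_dataset` (or any list of samples with `x` and
#'   `y_observed` matrices in `[0, 1]`).
#' @return Object of class `swinreg_checkpoint`: parameters, optimizer
#'   state, configs, seed and the per-epoch / per-step loss history.
#' @export
train <- function(cfg, dataset) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(dataset) == 0L) err_input("empty dataset")
  set.seed(derive_seed(cfg$seed, 1L))
  g <- init_stg(cfg$generator)
  r <- if (cfg$has_registration) init_str(cfg$registration) else NULL
  d <- init_disc(cfg$discriminator)
  opt_d <- adam_new(d, lr = cfg$disc_learning_rate)
  opt_g <- adam_new(g, lr = cfg$learning_rate)
  opt_r <- if (!is.null(r)) adam_new(r, lr = cfg$reg_learning_rate)
  w <- cfg$weights
  n <- length(dataset)
  steps <- list()
  epochs_log <- list()
  si <- 0L
  for (ep in seq_len(cfg$epochs)) {
    set.seed(derive_seed(cfg$seed, 1000L + ep))
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    comp <- matrix(0, length(batches), 5L)
    for (bi in seq_along(batches)) {
      ba <- batch_arrays(dataset, batches[[bi]])
      # --- discriminator step (generator detached) ---
      tape_reset()
      fake_v <- fwd_stg(ad_const(ba$x), const_params(g), cfg$generator)$v
      d_in_fake <- fake_v
      if (cfg$disc_on_registered && !is.null(r)) {
        dvf_v <- fwd_str(ad_const(fake_v), ad_const(ba$y),
                         const_params(r), cfg$registration)$v
        d_in_fake <- warp_fwd_cpp(as.numeric(fake_v), as.numeric(dvf_v),
                                  1L, dim(fake_v)[2], dim(fake_v)[3],
                                  dim(fake_v)[4])
        dim(d_in_fake) <- dim(fake_v)
      }
      tape_reset()
      Pd <- wrap_params(d)
      rl <- fwd_disc(ad_const(ba$y), Pd, cfg$discriminator)
      fl <- fwd_disc(ad_const(d_in_fake), Pd, cfg$discriminator)
      dl <- ad_adv_loss_d(rl, fl)
      ad_backward(dl)
      up <- adam_step(d, collect_grads(Pd), opt_d)
      d <- up$params
      opt_d <- up$st
      adv_d <- dl$v
      # --- joint generator (+ registration) step ---
      tape_reset()
      Pg <- wrap_params(g)
      Pr <- if (!is.null(r)) wrap_params(r)
      fake <- fwd_stg(ad_const(ba$x), Pg, cfg$generator)
      flog <- fwd_disc(fake, const_params(d), cfg$discriminator)
      adv <- ad_adv_loss_g(flog)
      if (!is.null(r)) {
        dvf <- fwd_str(fake, ad_const(ba$y), Pr, cfg$registration)
        warped <- ad_warp(fake, dvf)
        corr <- ad_mean(ad_abs(ad_sub(ad_const(ba$y), warped)))
        smooth <- ad_smoothness(dvf)
      } else {
        corr <- ad_mean(ad_abs(ad_sub(ad_const(ba$y), fake)))
        smooth <- NULL
      }
      tot <- ad_add(ad_smul(adv, w$kappa), ad_smul(corr, w$lambda))
      if (!is.null(smooth)) tot <- ad_add(tot, ad_smul(smooth, w$mu))
      if (!is.finite(tot$v)) {
        err_numeric(sprintf(
          "NaN/Inf loss at epoch %d step %d (adv %.4g corr %.4g smooth %.4g)",
          ep, bi, adv$v, corr$v, if (is.null(smooth)) 0 else smooth$v))
      }
      ad_backward(tot)
      up <- adam_step(g, collect_grads(Pg), opt_g)
      g <- up$params
      opt_g <- up$st
      if (!is.null(r)) {
        upr <- adam_step(r, collect_grads(Pr), opt_r)
        r <- upr$params
        opt_r <- upr$st
      }
      sm_v <- if (is.null(smooth)) 0 else smooth$v
      comp[bi, ] <- c(adv_d, adv$v, corr$v, sm_v, tot$v)
      si <- si + 1L
      steps[[si]] <- c(epoch = ep, step = bi, adv_d = adv_d, adv_g = adv$v,
                       corr = corr$v, smooth = sm_v, total = tot$v)
    }
    epochs_log[[ep]] <- c(epoch = ep, adv_d = mean(comp[, 1]),
                          adv_g = mean(comp[, 2]), corr = mean(comp[, 3]),
                          smooth = mean(comp[, 4]), total = mean(comp[, 5]))
  }
  tape_reset()
  structure(list(
    params = list(g = g, r = r, d = d),
    opt = list(d = opt_d, g = opt_g, r = opt_r),
    cfg = cfg,
    epoch = cfg$epochs,
    history = list(
      epochs = as.data.frame(do.call(rbind, epochs_log)),
      steps = as.data.frame(do.call(rbind, steps)))),
    class = "swinreg_checkpoint")
}

#' Translate images with a trained checkpoint
#'
#' Applies the generator only: the registration network is a training-time
#' correction for misaligned supervision and is not part of the inference
#' path. Set `apply_registration = TRUE` (with a `reference` batch) to
#' inspect the translated-then-registered output.
#'
#' @param ckpt A `swinreg_checkpoint`.
#' @param images (H, W, B) array or H x W matrix in `[0, 1]`.
#' @param apply_registration Warp the translation towards `reference`.
#' @param reference Target-modality batch used only when
#'   `apply_registration = TRUE`.
#' @return (H, W, B) array in `[0, 1]` (matrix input returns a matrix).
#' @export
translate <- function(ckpt, images, apply_registration = FALSE,
                      reference = NULL) {
  stopifnot(inherits(ckpt, "swinreg_checkpoint"))
  was_mat <- is.matrix(images)
  out <- stg_forward(images, ckpt$cfg$generator, ckpt$params$g)
  if (apply_registration) {
    if (is.null(ckpt$params$r))
      err_config("checkpoint has no registration network")
    if (is.null(reference)) err_input("apply_registration needs a reference")
    dvf <- str_forward(out, reference, ckpt$cfg$registration, ckpt$params$r)
    out <- spatial_resample(out, dvf)
  }
  if (was_mat) out[, , 1] else out
}

#' Evaluate a checkpoint against aligned ground truth
#'
#' Translates every source image and scores it against `y_aligned` (which
#' must be present even for misaligned/unpaired training data).
#'
#' @param ckpt A `swinreg_checkpoint`.
#' @param dataset A `phantom_dataset` with `y_aligned` fields.
#' @return List with `table` (one row: scenario, mode, n and
#'   mean +/- sd of PSNR/MAE/SSIM) and `metrics` (the full
#'   [compute_metrics()] record).
#' @export
evaluate <- function(ckpt, dataset) {
  stopifnot(inherits(ckpt, "swinreg_checkpoint"))
  if (length(dataset) == 0L) err_input("empty dataset")
  truth <- lapply(dataset, function(s) s$y_aligned)
  if (any(vapply(truth, is.null, logical(1))))
    err_input("dataset lacks aligned ground truth (y_aligned)")
  H <- nrow(dataset[[1]]$x)
  W <- ncol(dataset[[1]]$x)
  x <- array(0, c(H, W, length(dataset)))
  for (i in seq_along(dataset)) x[, , i] <- dataset[[i]]$x
  pred <- translate(ckpt, x)
  mr <- compute_metrics(pred, truth)
  tab <- data.frame(
    scenario = ckpt$cfg$scenario, mode = ckpt$cfg$mode, n = length(dataset),
    psnr_mean = mr$summary$mean[1], psnr_sd = mr$summary$sd[1],
    mae_mean = mr$summary$mean[2], mae_sd = mr$summary$sd[2],
    ssim_mean = mr$summary$mean[3], ssim_sd = mr$summary$sd[3])
  list(table = tab, metrics = mr, predictions = pred)
}

#' Train and evaluate the four ablation scenarios
#'
#' Runs `baseline_gan`, `swin_g`, `swin_g_plus_r` and `mmtrans` with a
#' shared seed and shared data and evaluates each on `eval_dataset`.
#'
#' @param base_cfg A [train_config()]; its scenario field is overridden.
#' @param dataset Training data.
#' @param eval_dataset Held-out data with aligned ground truth (defaults
#'   to `dataset`).
#' @param scenarios Character vector of scenarios to run.
#' @return `list(table = 4-row comparison data frame, checkpoints = list)`.
#' @export
run_ablation <- function(base_cfg, dataset, eval_dataset = dataset,
                         scenarios = c("baseline_gan", "swin_g",
                                       "swin_g_plus_r", "mmtrans")) {
  rows <- list()
  ckpts <- list()
  for (sc in scenarios) {
    cfg <- train_config(
      learning_rate = base_cfg$learning_rate,
      reg_learning_rate = base_cfg$reg_learning_rate,
      disc_learning_rate = base_cfg$disc_learning_rate,
      epochs = base_cfg$epochs,
      batch_size = base_cfg$batch_size, weights = base_cfg$weights,
      seed = base_cfg$seed, scenario = sc, mode = base_cfg$mode,
      generator = base_cfg$generator, registration = base_cfg$registration,
      discriminator = base_cfg$discriminator)
    ck <- train(cfg, dataset)
    ev <- evaluate(ck, eval_dataset)
    rows[[sc]] <- ev$table
    ckpts[[sc]] <- ck
  }
  list(table = do.call(rbind, rows), checkpoints = ckpts)
}

#' Greedy one-at-a-time sweep over a loss weight
#'
#' Retrains with each candidate value of one of `kappa`, `lambda`, `mu`
#' while the other two stay at their configured values, mirroring a greedy
#' coordinate search over the objective weights.
#'
#' @param base_cfg A [train_config()].
#' @param dataset Training data.
#' @param param `"kappa"`, `"lambda"` or `"mu"`.
#' @param values Numeric candidates.
#' @param eval_dataset Data for scoring (defaults to `dataset`).
#' @return Data frame with one metrics row per candidate value.
#' @export
run_sweep <- function(base_cfg, dataset, param = c("kappa", "lambda", "mu"),
                      values, eval_dataset = dataset) {
  param <- match.arg(param)
  rows <- list()
  for (v in values) {
    w <- base_cfg$weights
    w[[param]] <- v
    cfg <- base_cfg
    cfg$weights <- w
    ck <- train(cfg, dataset)
    ev <- evaluate(ck, eval_dataset)
    row <- cbind(data.frame(param = param, value = v), ev$table)
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Save a checkpoint (binary RDS plus JSON metadata sidecar)
#'
#' @param ckpt A `swinreg_checkpoint`.
#' @param path Output file; a `<path>.json` sidecar records the epoch,
#'   scenario, seed and loss weights.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "swinreg_checkpoint"))
  saveRDS(ckpt, path)
  meta <- list(package = "swinreg",
               version = as.character(utils::packageVersion("swinreg")),
               epoch = ckpt$epoch, scenario = ckpt$cfg$scenario,
               mode = ckpt$cfg$mode, seed = ckpt$cfg$seed,
               weights = unclass(ckpt$cfg$weights))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return The `swinreg_checkpoint`.
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(readRDS(path), error = function(e)
    err_input(sprintf("cannot load checkpoint: %s", conditionMessage(e))))
  if (!inherits(ck, "swinreg_checkpoint"))
    err_input("file is not a swinreg checkpoint")
  ck
}
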