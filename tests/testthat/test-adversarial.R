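# Patch discriminator and the loss closed forms.

test_that("discriminator architecture arithmetic and zero-weight logits", {
  cfg <- tiny_disc() # 3 stride-2 blocks
  set.seed(50)
  p <- init_disc(cfg)
  img <- rand_image_batch(64, 64, 2, seed = 51)
  lg <- discriminator_forward(img, cfg, p)
  expect_identical(dim(lg), c(1L, 8L, 8L, 2L)) # 64 / 2^3
  expect_true(all(is.finite(lg)))

  p0 <- lapply(p, function(x) { x[] <- 0; x })
  lg0 <- discriminator_forward(img, cfg, p0)
  expect_true(all(lg0 == 0))

  expect_error(discriminator_forward(rand_image_batch(4, 4, 1), cfg, p),
               class = "swinreg_config_error")
})

test_that("adversarial loss closed forms at zero logits", {
  z <- array(0, c(1, 4, 4, 2))
  expect_equal(adversarial_loss(z, z, "discriminator"), 2 * log(2),
               tolerance = 1e-9)
  expect_equal(adversarial_loss(NULL, z, "generator"), log(2),
               tolerance = 1e-9)
  # the discriminator loss decreases monotonically toward 0 as it wins
  ls <- vapply(c(0, 2, 5, 10, 20),
               function(k) adversarial_loss(z + k, z - k, "discriminator"),
               1)
  expect_true(all(diff(ls) < 0))
  expect_lt(ls[length(ls)], 1e-4)
})

test_that("correction loss closed forms and composition", {
  y <- rand_image_batch(16, 16, 2, seed = 52)
  zero <- array(0, c(2, 16, 16, 2))

  # perfectly warped pair scores 0
  set.seed(53)
  dvf <- array(runif(2 * 16 * 16 * 2, -1, 1), c(2, 16, 16, 2))
  gx <- rand_image_batch(16, 16, 2, seed = 54)
  yw <- spatial_resample(gx, dvf)
  expect_equal(correction_loss(yw, gx, dvf), 0, tolerance = 1e-12)

  # constant offset with zero field
  gx2 <- y * 0 + 0.3
  expect_equal(correction_loss(gx2 + 0.2, gx2, zero), 0.2,
               tolerance = 1e-12)

  expect_error(correction_loss(y, rand_image_batch(8, 8, 2), zero),
               class = "swinreg_dim_error")

  # batch permutation invariance
  dvf1 <- dvf[, , , c(2, 1)]
  expect_equal(correction_loss(y[, , c(2, 1)], gx[, , c(2, 1)], dvf1),
               correction_loss(y, gx, dvf), tolerance = 1e-12)
})

test_that("total loss is the exact weighted sum and is linear", {
  w <- loss_weights() # kappa 1, lambda 20, mu 10
  expect_identical(total_loss(0.5, 0.1, 0.01, w), 0.5 + 2.0 + 0.1)
  expect_identical(total_loss(1, 1, 1, loss_weights(0, 0, 0)), 0)
  a <- c(0.3, 0.7, 0.2)
  expect_equal(total_loss(2 * a[1], 2 * a[2], 2 * a[3], w),
               2 * total_loss(a[1], a[2], a[3], w), tolerance = 1e-12)
  expect_error(loss_weights(-1, 1, 1), class = "swinreg_config_error")
})

test_that("one generator step on the correction loss decreases it", {
  cfg <- tiny_stg()
  rcfg <- tiny_str()
  set.seed(55)
  g <- init_stg(cfg)
  r <- init_str(rcfg)
  x <- swinreg:::ib_to_chw(rand_image_batch(16, 16, 2, seed = 56))
  y <- swinreg:::ib_to_chw(rand_image_batch(16, 16, 2, seed = 57))
  corr_value <- function(g, r) {
    swinreg:::tape_reset()
    fake <- swinreg:::fwd_stg(swinreg:::ad_const(x),
                              swinreg:::const_params(g), cfg)
    dvf <- swinreg:::fwd_str(fake, swinreg:::ad_const(y),
                             swinreg:::const_params(r), rcfg)
    swinreg:::ad_mean(swinreg:::ad_abs(swinreg:::ad_sub(
      swinreg:::ad_const(y), swinreg:::ad_warp(fake, dvf))))$v
  }
  before <- corr_value(g, r)
  swinreg:::tape_reset()
  Pg <- swinreg:::wrap_params(g)
  Pr <- swinreg:::wrap_params(r)
  fake <- swinreg:::fwd_stg(swinreg:::ad_const(x), Pg, cfg)
  dvf <- swinreg:::fwd_str(fake, swinreg:::ad_const(y), Pr, rcfg)
  loss <- swinreg:::ad_mean(swinreg:::ad_abs(swinreg:::ad_sub(
    swinreg:::ad_const(y), swinreg:::ad_warp(fake, dvf))))
  swinreg:::ad_backward(loss)
  st <- swinreg:::adam_new(g, lr = 1e-3)
  up <- swinreg:::adam_step(g, swinreg:::collect_grads(Pg), st)
  after <- corr_value(up$params, r)
  expect_lt(after, before)
})
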