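# The phantom generator: anatomy maps, modality transforms, deformation
# fields and the three dataset modes.

test_that("anatomy maps are deterministic, labelled and have background", {
  a1 <- make_anatomy(101, 32)
  a2 <- make_anatomy(101, 32)
  expect_identical(a1, a2)
  expect_true(all(a1 %in% 0:(attr(a1, "n_labels"))))
  for (seed in 1:100) {
    a <- make_anatomy(seed, 32)
    expect_gt(mean(a == 0), 0) # outer ellipse inscribed with margin
    expect_true(max(a) <= 7)   # <= n_shapes_max + 1
  }
})

test_that("modality transform is an exact LUT without noise/blur", {
  a <- make_anatomy(7, 32)
  img <- modality_transform(a, "A", noise_sd = 0, blur_sd = 0)
  lut <- swinreg:::modality_lut(attr(a, "n_labels"), "A")
  expect_identical(img, matrix(lut[a + 1L], 32, 32))
  expect_true(all(img >= 0 & img <= 1))
  noisy <- modality_transform(a, "B", noise_sd = 0.5, seed = 3)
  expect_true(all(noisy >= 0 & noisy <= 1)) # clamp contract

  # contrast inversion: per-tissue means anti-correlated across tissues
  ia <- modality_transform(a, "A", noise_sd = 0, blur_sd = 0)
  ib <- modality_transform(a, "B", noise_sd = 0, blur_sd = 0)
  tiss <- setdiff(sort(unique(as.vector(a))), 0)
  ma <- vapply(tiss, function(k) mean(ia[a == k]), 1)
  mb <- vapply(tiss, function(k) mean(ib[a == k]), 1)
  expect_lt(cor(ma, mb, method = "spearman"), 0)

  # same support: both modalities bright exactly on the anatomy
  expect_identical(ia > 0.1, a > 0)
  expect_identical(ib > 0.1, a > 0)
})

test_that("random smooth DVFs meet the amplitude contract", {
  expect_identical(random_smooth_dvf(1, 32, amplitude = 0),
                   array(0, c(2, 32, 32)))
  for (seed in 1:5) {
    d <- random_smooth_dvf(seed, 32, amplitude = 2, smoothness = 4)
    mag <- sqrt(d[1, , ]^2 + d[2, , ]^2)
    expect_equal(max(mag), 2, tolerance = 1e-6)
  }
  # smoother fields score lower on the smoothness penalty (median of 20)
  s_lo <- s_hi <- numeric(20)
  for (seed in 1:20) {
    s_lo[seed] <- smoothness_loss(random_smooth_dvf(seed, 32, 2, 8))
    s_hi[seed] <- smoothness_loss(random_smooth_dvf(seed, 32, 2, 1))
  }
  expect_lt(median(s_lo), median(s_hi))
})

test_that("dataset modes honour their contracts and are deterministic", {
  cfg <- phantom_config(n_samples = 10L, mode = "aligned", seed = 5L)
  ds <- make_dataset(cfg)
  expect_length(ds, 10L)
  expect_identical(dim(ds[[1]]$x), c(32L, 32L))
  expect_true(all(vapply(ds, function(s)
    identical(s$y_observed, s$y_aligned), logical(1))))
  expect_identical(make_dataset(cfg), ds) # bitwise determinism

  dm <- make_dataset(phantom_config(n_samples = 8L, mode = "misaligned",
                                    seed = 6L))
  for (s in dm) {
    expect_false(is.null(s$true_dvf))
    # replaying the stored field through the warp reproduces y_observed
    expect_identical(spatial_resample(s$y_aligned, s$true_dvf),
                     s$y_observed)
  }

  du <- make_dataset(phantom_config(n_samples = 8L, mode = "unpaired",
                                    seed = 7L))
  for (s in du) expect_false(isTRUE(all.equal(s$y_observed, s$y_aligned)))
  expect_error(phantom_config(n_samples = 1L, mode = "unpaired"),
               class = "swinreg_config_error")
  expect_error(phantom_config(image_size = 8L),
               class = "swinreg_config_error")
})

test_that("misaligned ground truth is recoverable by inverse warping", {
  # recovery error must stay below twice the bilinear interpolation error,
  # measured per sample as the damage done by a worst-case double
  # half-pixel shift of the clean target
  dm <- make_dataset(phantom_config(n_samples = 6L, mode = "misaligned",
                                    deform_amplitude = 2,
                                    deform_smoothness = 4, seed = 8L))
  for (s in dm) {
    rec <- mean(abs(spatial_resample(s$y_observed, invert_dvf(s$true_dvf)) -
                      s$y_aligned))
    h <- array(0, c(2, 32, 32))
    h[1, , ] <- 0.5
    hb <- h
    hb[1, , ] <- -0.5
    interp <- mean(abs(spatial_resample(spatial_resample(s$y_aligned, h),
                                        hb) - s$y_aligned))
    expect_lt(rec, 2 * interp)
  }
})
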