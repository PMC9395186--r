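# The autodiff engine: every operation's reverse-mode gradient is checked
# against central finite differences, and the optimizer is exercised on a
# closed-form problem.

ad <- function(name) get(name, envir = asNamespace("swinreg"))

grad_matches <- function(fwd, x, tol = 1e-5) {
  tape_reset <- ad("tape_reset")
  tape_reset()
  xn <- ad("ad_param")(x)
  loss <- fwd(xn)
  ad("ad_backward")(loss)
  got <- xn$g
  want <- num_grad(function(z) {
    tape_reset()
    ad("vv")(fwd(ad("ad_const")(z)))
  }, x)
  expect_lt(max(abs(got - want)), tol)
}

test_that("elementwise and reduction ops differentiate correctly", {
  set.seed(1)
  x <- array(rnorm(24), c(2, 3, 4))
  grad_matches(function(z) ad("ad_mean")(ad("ad_gelu")(z)), x)
  grad_matches(function(z) ad("ad_sum")(ad("ad_sq")(ad("ad_sigmoid")(z))), x)
  grad_matches(function(z) ad("ad_mean")(ad("ad_abs")(z)), x)
  grad_matches(function(z) ad("ad_mean")(ad("ad_logsigmoid")(z)), x)
  grad_matches(function(z) ad("ad_mean")(ad("ad_leakyrelu")(z, 0.2)), x)
})

test_that("linear algebra ops differentiate correctly", {
  set.seed(2)
  W <- matrix(rnorm(6), 2, 3)
  b <- rnorm(2)
  xm <- matrix(rnorm(12), 3, 4)
  grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(
    ad("ad_linear")(ad("ad_const")(W), z, ad("ad_const")(b)))), xm)
  grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(
    ad("ad_linear")(z, ad("ad_const")(xm), ad("ad_const")(b)))), W)
  A <- array(rnorm(24), c(2, 3, 4))
  B <- array(rnorm(24), c(3, 2, 4))
  for (tr in list(c(FALSE, FALSE), c(TRUE, TRUE))) {
    AA <- if (tr[1]) B else A
    grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(
      ad("ad_bmm")(z, ad("ad_const")(if (tr[2]) A else B), tr[1], tr[2]))),
      AA)
  }
})

test_that("normalisation and softmax ops differentiate correctly", {
  set.seed(3)
  xs <- matrix(rnorm(15), 3, 5)
  g <- rnorm(3); be <- rnorm(3)
  grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(ad("ad_softmax1")(z))),
               xs)
  grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(
    ad("ad_layernorm")(z, ad("ad_const")(g), ad("ad_const")(be)))), xs)
  grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(
    ad("ad_layernorm")(ad("ad_const")(xs), z, ad("ad_const")(be)))), g)
  x4 <- array(rnorm(64), c(2, 4, 4, 2))
  grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(
    ad("ad_instnorm")(z, ad("ad_const")(g[1:2]), ad("ad_const")(be[1:2])))),
    x4)
})

test_that("conv2d matches a direct oracle and differentiates", {
  set.seed(4)
  xc <- array(rnorm(3 * 6 * 6 * 2), c(3, 6, 6, 2))
  wc <- matrix(rnorm(4 * 27), 4, 27)
  bc <- rnorm(4)
  # direct triple-loop convolution oracle (channel-fastest patch order)
  conv_oracle <- function(x, w, b, stride = 1L, pad = 1L) {
    d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; Bn <- d[4]; k <- 3L
    Ho <- (H + 2 * pad - k) %/% stride + 1L
    Wo <- (W + 2 * pad - k) %/% stride + 1L
    out <- array(0, c(nrow(w), Ho, Wo, Bn))
    for (bb in 1:Bn) for (ro in 1:Ho) for (so in 1:Wo) {
      acc <- b
      for (i in 1:k) for (j in 1:k) {
        r <- (ro - 1) * stride - pad + i
        s <- (so - 1) * stride - pad + j
        if (r >= 1 && r <= H && s >= 1 && s <= W) {
          widx <- ((j - 1) * k + (i - 1)) * C + seq_len(C)
          acc <- acc + w[, widx, drop = FALSE] %*% x[, r, s, bb]
        }
      }
      out[, ro, so, bb] <- acc
    }
    out
  }
  swinreg:::tape_reset()
  y <- ad("ad_conv2d")(ad("ad_const")(xc), ad("ad_const")(wc),
                       ad("ad_const")(bc))
  expect_lt(max(abs(y$v - conv_oracle(xc, wc, bc))), 1e-12)
  grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(
    ad("ad_conv2d")(z, ad("ad_const")(wc), ad("ad_const")(bc)))), xc)
  grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(
    ad("ad_conv2d")(ad("ad_const")(xc), z, ad("ad_const")(bc),
                    stride = 2L, pad = 1L))), wc)
})

test_that("warp differentiates wrt image and flow", {
  set.seed(5)
  img <- array(rnorm(36 * 2), c(1, 6, 6, 2))
  flow <- array(runif(2 * 36 * 2, -0.4, 0.4), c(2, 6, 6, 2))
  grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(
    ad("ad_warp")(z, ad("ad_const")(flow)))), img)
  grad_matches(function(z) ad("ad_mean")(ad("ad_sq")(
    ad("ad_warp")(ad("ad_const")(img), z))), flow)
})

test_that("adam drives a quadratic to its minimum", {
  p <- list(w = matrix(5, 2, 2))
  st <- swinreg:::adam_new(p, lr = 0.2)
  for (i in 1:200) {
    swinreg:::tape_reset()
    pn <- swinreg:::wrap_params(p)
    loss <- ad("ad_mean")(ad("ad_sq")(pn$w))
    ad("ad_backward")(loss)
    up <- swinreg:::adam_step(p, swinreg:::collect_grads(pn), st)
    p <- up$params
    st <- up$st
  }
  expect_lt(max(abs(p$w)), 1e-2)
})
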