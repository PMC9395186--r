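# Differentiable operations for the tape engine.
#
# Array conventions: feature maps are (C, H, W, B) column-major arrays,
# matrices are (rows, cols), batched matrices are (r, c, slice) cubes.
# Gradients always carry the dim of the value they correspond to.

with_dim <- function(x, d) {
  dim(x) <- d
  x
}

ad_add <- function(a, b) {
  req <- any_req(a, b)
  node_new(a$v + b$v, req = req,
           backward = if (req) function(nd) {
             acc(a, nd$g)
             acc(b, nd$g)
           })
}

ad_sub <- function(a, b) {
  req <- any_req(a, b)
  node_new(a$v - b$v, req = req,
           backward = if (req) function(nd) {
             acc(a, nd$g)
             acc(b, -nd$g)
           })
}

ad_mul <- function(a, b) {
  req <- any_req(a, b)
  node_new(a$v * b$v, req = req,
           backward = if (req) function(nd) {
             acc(a, nd$g * b$v)
             acc(b, nd$g * a$v)
           })
}

# Multiply / add by a plain numeric scalar.
ad_smul <- function(a, s) {
  node_new(a$v * s, req = a$req,
           backward = if (a$req) function(nd) acc(a, nd$g * s))
}

ad_sadd <- function(a, s) {
  node_new(a$v + s, req = a$req,
           backward = if (a$req) function(nd) acc(a, nd$g))
}

# Add a constant array (same shape); used for attention masks.
ad_addc <- function(a, carr) {
  stopifnot(length(carr) == length(a$v))
  node_new(a$v + carr, req = a$req,
           backward = if (a$req) function(nd) acc(a, nd$g))
}

ad_matmul <- function(A, B) {
  req <- any_req(A, B)
  node_new(A$v %*% B$v, req = req,
           backward = if (req) function(nd) {
             g <- nd$g
             acc(A, tcrossprod(g, B$v))
             acc(B, crossprod(A$v, g))
           })
}

# Affine map: y = W x + b with W (out, in), x (in, N), b length out or NULL.
ad_linear <- function(W, x, b = NULL) {
  y <- W$v %*% x$v
  if (!is.null(b)) y <- y + b$v # recycles down columns (length out == nrow)
  req <- if (is.null(b)) any_req(W, x) else any_req(W, x, b)
  node_new(y, req = req,
           backward = if (req) function(nd) {
             g <- nd$g
             acc(W, tcrossprod(g, x$v))
             acc(x, crossprod(W$v, g))
             if (!is.null(b)) acc(b, rowSums(g))
           })
}

# Batched matrix multiply over cube slices.
ad_bmm <- function(A, B, transA = FALSE, transB = FALSE) {
  req <- any_req(A, B)
  v <- bmm_cpp(A$v, B$v, transA, transB)
  node_new(v, req = req,
           backward = if (req) function(nd) {
             g <- nd$g
             dim(g) <- dim(nd$v)
             if (!transA && !transB) {
               acc(A, bmm_cpp(g, B$v, FALSE, TRUE))
               acc(B, bmm_cpp(A$v, g, TRUE, FALSE))
             } else if (transA && !transB) {
               acc(A, bmm_cpp(B$v, g, FALSE, TRUE))
               acc(B, bmm_cpp(A$v, g, FALSE, FALSE))
             } else if (!transA && transB) {
               acc(A, bmm_cpp(g, B$v, FALSE, FALSE))
               acc(B, bmm_cpp(g, A$v, TRUE, FALSE))
             } else {
               acc(A, bmm_cpp(B$v, g, TRUE, TRUE))
               acc(B, bmm_cpp(g, A$v, TRUE, TRUE))
             }
           })
}

ad_reshape <- function(x, d) {
  node_new(with_dim(x$v, d), req = x$req,
           backward = if (x$req) function(nd) {
             acc(x, with_dim(nd$g, dim(x$v) %||% length(x$v)))
           })
}

ad_aperm <- function(x, perm) {
  inv <- order(perm)
  node_new(aperm(x$v, perm), req = x$req,
           backward = if (x$req) function(nd) {
             g <- nd$g
             dim(g) <- dim(nd$v)
             acc(x, aperm(g, inv))
           })
}

# Gather with implicit zero fill: idx == 0 reads as 0. The adjoint is a
# scatter-add into the input's shape.
ad_gather <- function(x, idx, outdim) {
  v <- gather_pad_cpp(x$v, idx)
  dim(v) <- outdim
  node_new(v, req = x$req,
           backward = if (x$req) function(nd) {
             g <- scatter_add_cpp(idx, nd$g, length(x$v))
             acc(x, with_dim(g, dim(x$v) %||% length(x$v)))
           })
}

# Contiguous row slice of a matrix (used to split the fused QKV projection).
ad_rows <- function(x, from, to) {
  v <- x$v[from:to, , drop = FALSE]
  node_new(v, req = x$req,
           backward = if (x$req) function(nd) {
             g <- matrix(0, nrow(x$v), ncol(x$v))
             g[from:to, ] <- nd$g
             acc(x, g)
           })
}

# Concatenate two arrays along dim 1 (channels).
ad_concat1 <- function(a, b) {
  da <- dim(a$v)
  db <- dim(b$v)
  stopifnot(length(da) == length(db), all(da[-1] == db[-1]))
  ma <- with_dim(a$v, c(da[1], prod(da[-1])))
  mb <- with_dim(b$v, c(db[1], prod(db[-1])))
  v <- with_dim(rbind(ma, mb), c(da[1] + db[1], da[-1]))
  req <- any_req(a, b)
  node_new(v, req = req,
           backward = if (req) function(nd) {
             g <- with_dim(nd$g, c(da[1] + db[1], prod(da[-1])))
             acc(a, with_dim(g[seq_len(da[1]), , drop = FALSE], da))
             acc(b, with_dim(g[da[1] + seq_len(db[1]), , drop = FALSE], db))
           })
}

# Softmax over dim 1 of an array viewed as a (k, N) matrix.
ad_softmax1 <- function(x) {
  d <- dim(x$v)
  k <- d[1]
  P <- softmax1_cpp(with_dim(x$v, c(k, prod(d[-1]))))
  node_new(with_dim(P, d), req = x$req,
           backward = if (x$req) function(nd) {
             G <- with_dim(nd$g, c(k, length(nd$g) %/% k))
             acc(x, with_dim(softmax1_bwd_cpp(P, G), d))
           })
}

# Layer normalization over dim 1 (channels) of a (C, N) matrix with
# per-channel affine parameters.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  X <- x$v
  C <- nrow(X)
  mu <- colMeans(X)
  xc <- X - rep(mu, each = C)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * rep(inv, each = C)
  y <- xh * gamma$v + beta$v # gamma, beta length C recycle down columns
  req <- any_req(x, gamma, beta)
  node_new(y, req = req,
           backward = if (req) function(nd) {
             G <- nd$g
             dim(G) <- dim(y)
             acc(gamma, rowSums(G * xh))
             acc(beta, rowSums(G))
             dxh <- G * gamma$v
             m1 <- colMeans(dxh)
             m2 <- colMeans(dxh * xh)
             dx <- (dxh - rep(m1, each = C) - xh * rep(m2, each = C)) *
               rep(inv, each = C)
             acc(x, dx)
           })
}

# Instance normalization of a (C, H, W, B) map: statistics over (H, W) for
# each channel and sample, per-channel affine.
ad_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$v)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  hw <- H * W
  Xp <- aperm(x$v, c(2, 3, 1, 4)) # (H, W, C, B)
  X <- with_dim(Xp, c(hw, C * B))
  mu <- colMeans(X)
  xc <- X - rep(mu, each = hw)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * rep(inv, each = hw)
  gcol <- rep(rep(gamma$v, times = B), each = hw)
  bcol <- rep(rep(beta$v, times = B), each = hw)
  y <- xh * gcol + bcol
  v <- aperm(with_dim(y, c(H, W, C, B)), c(3, 1, 2, 4))
  req <- any_req(x, gamma, beta)
  node_new(v, req = req,
           backward = if (req) function(nd) {
             g4 <- nd$g
             dim(g4) <- d
             G <- with_dim(aperm(g4, c(2, 3, 1, 4)), c(hw, C * B))
             gx <- colSums(G * xh) # per (c, b)
             acc(gamma, rowSums(matrix(gx, C, B)))
             acc(beta, rowSums(matrix(colSums(G), C, B)))
             dxh <- G * gcol
             m1 <- colMeans(dxh)
             m2 <- colMeans(dxh * xh)
             dX <- (dxh - rep(m1, each = hw) - xh * rep(m2, each = hw)) *
               rep(inv, each = hw)
             acc(x, aperm(with_dim(dX, c(H, W, C, B)), c(3, 1, 2, 4)))
           })
}

ad_gelu <- function(x) {
  pn <- pnorm(x$v)
  node_new(x$v * pn, req = x$req,
           backward = if (x$req) function(nd) {
             acc(x, nd$g * (pn + x$v * dnorm(x$v)))
           })
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  node_new(s, req = x$req,
           backward = if (x$req) function(nd) acc(x, nd$g * s * (1 - s)))
}

ad_leakyrelu <- function(x, slope = 0.2) {
  fac <- slope + (1 - slope) * (x$v > 0)
  node_new(x$v * fac, req = x$req,
           backward = if (x$req) function(nd) acc(x, nd$g * fac))
}

# Numerically stable log(sigmoid(x)); gradient is sigmoid(-x).
ad_logsigmoid <- function(x) {
  v <- ifelse(x$v > 0, -log1p(exp(-x$v)), x$v - log1p(exp(x$v)))
  node_new(v, req = x$req,
           backward = if (x$req) function(nd) {
             acc(x, nd$g / (1 + exp(x$v)))
           })
}

ad_abs <- function(x) {
  node_new(abs(x$v), req = x$req,
           backward = if (x$req) function(nd) acc(x, nd$g * sign(x$v)))
}

ad_sq <- function(x) {
  node_new(x$v * x$v, req = x$req,
           backward = if (x$req) function(nd) acc(x, 2 * nd$g * x$v))
}

ad_mean <- function(x) {
  n <- length(x$v)
  node_new(sum(x$v) / n, req = x$req,
           backward = if (x$req) function(nd) {
             g <- x$v
             g[] <- nd$g / n
             acc(x, g)
           })
}

ad_sum <- function(x) {
  node_new(sum(x$v), req = x$req,
           backward = if (x$req) function(nd) {
             g <- x$v
             g[] <- nd$g
             acc(x, g)
           })
}

# --- 2D convolution via cached im2col indices --------------------------------

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- builder()
    .idx_cache[[key]] <- v
  }
  v
}

# im2col gather index for x of dim (C, H, W, B), kernel k, given stride and
# zero padding. Column order of patch elements: channel fastest, then kernel
# row, then kernel col; output columns ordered (row, col, batch).
im2col_idx <- function(C, H, W, B, k, stride, pad) {
  key <- paste("im2col", C, H, W, B, k, stride, pad, sep = "_")
  cache_get(key, function() {
    Ho <- (H + 2 * pad - k) %/% stride + 1L
    Wo <- (W + 2 * pad - k) %/% stride + 1L
    A <- C * k * k
    co <- rep.int(0:(C - 1), k * k)
    io <- rep(rep(0:(k - 1), each = C), times = k)
    jo <- rep(0:(k - 1), each = C * k)
    ro <- (0:(Ho - 1)) * stride - pad
    so <- (0:(Wo - 1)) * stride - pad
    Rm <- outer(io, ro, "+")                      # (A, Ho)
    Sm <- outer(jo, so, "+")                      # (A, Wo)
    Rf <- Rm[, rep.int(seq_len(Ho), Wo * B), drop = FALSE]
    Sf <- Sm[, rep(rep(seq_len(Wo), each = Ho), times = B), drop = FALSE]
    bf <- rep(0:(B - 1), each = Ho * Wo)
    idx <- 1 + co + C * (Rf + H * (Sf + W * rep(bf, each = A)))
    bad <- Rf < 0 | Rf >= H | Sf < 0 | Sf >= W
    idx[bad] <- 0L
    storage.mode(idx) <- "integer"
    list(idx = idx, Ho = Ho, Wo = Wo, A = A)
  })
}

# Convolution: x (C, H, W, B), w (Cout, C*k*k), b length Cout or NULL.
ad_conv2d <- function(x, w, b = NULL, k = 3L, stride = 1L,
                      pad = (k - 1L) %/% 2L) {
  d <- dim(x$v)
  ii <- im2col_idx(d[1], d[2], d[3], d[4], k, stride, pad)
  NO <- ii$Ho * ii$Wo * d[4]
  cols <- gather_pad_cpp(x$v, ii$idx)
  dim(cols) <- c(ii$A, NO)
  y <- w$v %*% cols
  if (!is.null(b)) y <- y + b$v
  Cout <- nrow(w$v)
  dim(y) <- c(Cout, ii$Ho, ii$Wo, d[4])
  req <- if (is.null(b)) any_req(x, w) else any_req(x, w, b)
  node_new(y, req = req,
           backward = if (req) function(nd) {
             g <- nd$g
             dim(g) <- c(Cout, NO)
             acc(w, tcrossprod(g, cols))
             if (!is.null(b)) acc(b, rowSums(g))
             if (x$req) {
               gcols <- crossprod(w$v, g)
               acc(x, with_dim(scatter_add_cpp(ii$idx, as.numeric(gcols),
                                               length(x$v)), d))
             }
           })
}

# Nearest-neighbour upsampling by an integer factor (cached gather).
ad_upsample <- function(x, factor = 2L) {
  d <- dim(x$v)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  key <- paste("ups", C, H, W, B, factor, sep = "_")
  idx <- cache_get(key, function() {
    Hn <- H * factor
    Wn <- W * factor
    r <- rep(0:(Hn - 1) %/% factor, times = Wn)
    s <- rep(0:(Wn - 1) %/% factor, each = Hn)
    pix <- r + H * s # 0-based source pixel per target pixel
    i1 <- 1 + outer(0:(C - 1), pix * C, "+")
    idx <- outer(as.vector(i1), (0:(B - 1)) * C * H * W, "+")
    storage.mode(idx) <- "integer"
    idx
  })
  ad_gather(x, idx, c(C, H * factor, W * factor, B))
}

# Differentiable bilinear warp; see warp_fwd_cpp for conventions.
ad_warp <- function(img, flow) {
  d <- dim(img$v)
  if (any(!is.finite(flow$v))) err_numeric("non-finite displacement field")
  v <- warp_fwd_cpp(img$v, flow$v, d[1], d[2], d[3], d[4])
  dim(v) <- d
  req <- any_req(img, flow)
  node_new(v, req = req,
           backward = if (req) function(nd) {
             gr <- warp_bwd_cpp(img$v, flow$v, nd$g, d[1], d[2], d[3], d[4])
             acc(img, with_dim(gr$gimg, d))
             acc(flow, with_dim(gr$gflow, dim(flow$v)))
           })
}
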