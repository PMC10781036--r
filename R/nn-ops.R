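# Fused neural-network operations with hand-derived backward rules.
# Convolutions run through the compiled im2col/col2im kernels; weights for a
# dense convolution are stored as an (F x K*K*C) matrix (row-major over
# kh, kw, c to match the im2col row order).

# Dense 2-D convolution. x: (H, W, C, N) node; W: (F x K*K*C); b: length F.
# Uses the transposed im2col layout (positions x kernel-taps) so the heavy
# copies are contiguous and the GEMM is tall-skinny.
ndConv2d <- function(x, W, b, K, stride = 1L, pad = (K - 1L) %/% 2L) {
  d <- dim(x$value)
  H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  OH <- (H + 2L * pad - K) %/% stride + 1L
  OW <- (Wd + 2L * pad - K) %/% stride + 1L
  Fn <- nrow(W$value)
  M <- OH * OW * N
  cols <- im2col_t(x$value, H, Wd, C, N, K, stride, pad)   # M x K*K*C
  y <- tcrossprod(cols, W$value)                           # M x F
  y <- y + rep(b$value, each = M)
  out <- aperm(array(y, c(OH, OW, N, Fn)), c(1, 2, 4, 3))
  n <- nd(out, list(x, W, b))
  n$backfn <- function(s) {
    gm <- matrix(aperm(s$grad, c(1, 2, 4, 3)), M, Fn)
    .addGrad(W, crossprod(gm, cols))
    .addGrad(b, colSums(gm))
    dx <- col2im_t(gm %*% W$value, H, Wd, C, N, K, stride, pad)
    .addGrad(x, array(dx, d))
  }
  n
}

# Depthwise convolution (stride 1, same padding). w: (K, K, C); b: length C.
ndDepthwiseConv <- function(x, w, b, K) {
  d <- dim(x$value)
  y <- dwconv_fwd(x$value, d[1], d[2], d[3], d[4], w$value, K)
  y <- array(y, d) + rep(b$value, each = d[1] * d[2])
  n <- nd(y, list(x, w, b))
  n$backfn <- function(s) {
    g <- s$grad
    .addGrad(x, array(dwconv_bwd_x(g, d[1], d[2], d[3], d[4],
                                   w$value, K), d))
    .addGrad(w, array(dwconv_bwd_w(x$value, g,
                                   d[1], d[2], d[3], d[4], K), c(K, K, d[3])))
    gm <- matrix(s$grad, d[1] * d[2], d[3] * d[4])
    .addGrad(b, rowSums(matrix(colSums(gm), d[3], d[4])))
  }
  n
}

# ---- position-major (rows = (oh, ow, n) positions, cols = channels) ops.
# The CVT convolutional stage runs entirely in this layout: channel
# reductions are contiguous column operations and no transposition is needed
# between layers.

# x: (H*W*N x C) node; W: (F x K*K*C); b: length F. Output ((OH*OW*N) x F).
ndConv2dPos <- function(x, W, b, K, H, Wd, N, stride = 1L,
                        pad = (K - 1L) %/% 2L) {
  C <- ncol(x$value)
  OH <- (H + 2L * pad - K) %/% stride + 1L
  OW <- (Wd + 2L * pad - K) %/% stride + 1L
  M <- OH * OW * N
  cols <- im2col_pos(x$value, H, Wd, N, K, stride, pad)
  y <- tcrossprod(cols, W$value)
  y <- y + rep(b$value, each = M)
  n <- nd(y, list(x, W, b))
  n$shape <- c(OH, OW, N)
  n$backfn <- function(s) {
    g <- s$grad
    .addGrad(W, crossprod(g, cols))
    .addGrad(b, colSums(g))
    if (length(x$parents) || !is.null(x$backfn))  # skip dx for the input leaf
      .addGrad(x, col2im_pos(g %*% W$value, H, Wd, C, N, K, stride, pad))
  }
  n
}

# Batch normalization over the columns (channels) of a position-major
# matrix; the per-column arithmetic runs in compiled single-pass kernels.
ndBatchNormCols <- function(x, gamma, beta, stats, training,
                            momentum = 0.1, eps = 1e-5) {
  v <- x$value
  if (training) {
    st <- bn_cols_stats(v)
    mu <- st$mean; va <- st$var
    if (is.null(stats$mean)) {
      stats$mean <- mu; stats$var <- va
    } else {
      stats$mean <- (1 - momentum) * stats$mean + momentum * mu
      stats$var <- (1 - momentum) * stats$var + momentum * va
    }
  } else {
    if (is.null(stats$mean)) {
      st <- bn_cols_stats(v); mu <- st$mean; va <- st$var
    } else { mu <- stats$mean; va <- stats$var }
  }
  istd <- 1 / sqrt(va + eps)
  n <- nd(bn_cols_fwd(v, mu, istd, gamma$value, beta$value),
          list(x, gamma, beta))
  n$backfn <- function(s) {
    bw <- bn_cols_bwd(v, s$grad, mu, istd, gamma$value, training)
    .addGrad(gamma, bw$dgamma)
    .addGrad(beta, bw$dbeta)
    .addGrad(x, bw$dx)
  }
  n
}

ndMaxPool2Pos <- function(x, H, Wd, N) {
  r <- maxpool2_pos(x$value, H, Wd, N)
  v <- r$value
  n <- nd(v, list(x))
  n$shape <- c(H %/% 2L, Wd %/% 2L, N)
  n$backfn <- function(s) {
    dx <- maxpool2_bwd(s$grad, r$argmax, length(x$value))
    dim(dx) <- dim(x$value)
    .addGrad(x, dx)
  }
  n
}

# Batch normalization over the rows of a (d x m) matrix. In training mode the
# batch statistics are used and the running statistics in `stats` (an
# environment with $mean, $var) are updated in place; in inference mode the
# running statistics are used and treated as constants.
ndBatchNormMat <- function(x, gamma, beta, stats, training,
                           momentum = 0.1, eps = 1e-5) {
  v <- x$value
  m <- ncol(v)
  if (training) {
    mu <- rowMeans(v)
    xc <- v - mu
    va <- rowMeans(xc * xc)
    if (is.null(stats$mean)) {
      stats$mean <- mu; stats$var <- va
    } else {
      stats$mean <- (1 - momentum) * stats$mean + momentum * mu
      stats$var <- (1 - momentum) * stats$var + momentum * va
    }
  } else {
    mu <- if (is.null(stats$mean)) rowMeans(v) else stats$mean
    va <- if (is.null(stats$var)) rowMeans((v - mu)^2) else stats$var
    xc <- v - mu
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  out <- gamma$value * xhat + beta$value
  n <- nd(out, list(x, gamma, beta))
  n$backfn <- function(s) {
    g <- s$grad
    .addGrad(gamma, rowSums(g * xhat))
    .addGrad(beta, rowSums(g))
    dxhat <- g * gamma$value
    if (training) {
      # standard batch-norm backward through the batch statistics
      .addGrad(x, istd / m * (m * dxhat - rowSums(dxhat) -
                                xhat * rowSums(dxhat * xhat)))
    } else {
      .addGrad(x, dxhat * istd)
    }
  }
  n
}

# Batch norm per channel of an (H, W, C, N) map, computed in place on the
# native layout: a length-(H*W*C) vector recycles over the batch dimension in
# column-major arithmetic, so per-channel broadcasts need no transposition.
ndBatchNormConv <- function(x, gamma, beta, stats, training,
                            momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- HW * N
  bc <- function(v) rep(v, each = HW)       # per-channel -> per-plane
  chSum <- function(a) rowSums(matrix(.colSums(a, HW, C * N), C, N))
  v <- x$value
  if (training) {
    mu <- chSum(v) / m
    xc <- v - bc(mu)
    va <- chSum(xc * xc) / m
    if (is.null(stats$mean)) {
      stats$mean <- mu; stats$var <- va
    } else {
      stats$mean <- (1 - momentum) * stats$mean + momentum * mu
      stats$var <- (1 - momentum) * stats$var + momentum * va
    }
  } else {
    mu <- if (is.null(stats$mean)) chSum(v) / m else stats$mean
    xc <- v - bc(mu)
    va <- if (is.null(stats$var)) chSum(xc * xc) / m else stats$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * bc(istd)
  out <- xhat * bc(gamma$value) + bc(beta$value)
  dim(out) <- d
  n <- nd(out, list(x, gamma, beta))
  n$backfn <- function(s) {
    g <- s$grad
    .addGrad(gamma, chSum(g * xhat))
    .addGrad(beta, chSum(g))
    dxhat <- g * bc(gamma$value)
    if (training) {
      dx <- bc(istd / m) * (m * dxhat - bc(chSum(dxhat)) -
                              xhat * bc(chSum(dxhat * xhat)))
    } else dx <- dxhat * bc(istd)
    dim(dx) <- d
    .addGrad(x, dx)
  }
  n
}

# Layer normalization over the rows (features) of each column (token).
ndLayerNorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  dn <- nrow(v)
  mu <- colMeans(v)
  xc <- sweep(v, 2, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, "*")
  n <- nd(gamma$value * xhat + beta$value, list(x, gamma, beta))
  n$backfn <- function(s) {
    g <- s$grad
    .addGrad(gamma, rowSums(g * xhat))
    .addGrad(beta, rowSums(g))
    dxhat <- g * gamma$value
    t1 <- colSums(dxhat)
    t2 <- colSums(dxhat * xhat)
    .addGrad(x, sweep(dxhat - (rep(1, dn) %o% t1) / dn -
                        xhat * (rep(1, dn) %o% t2) / dn, 2, istd, "*"))
  }
  n
}

# Multi-head self-attention over T tokens per sample.
# x: (D x T*N) with token index fastest; projection weights are (D x D).
ndMultiHeadAttention <- function(x, Wq, Wk, Wv, Wo, bq, bk, bv, bo,
                                 nHeads, T, N) {
  D <- nrow(x$value)
  stopifnot(D %% nHeads == 0L)
  dh <- D %/% nHeads
  Q <- Wq$value %*% x$value + bq$value
  K <- Wk$value %*% x$value + bk$value
  V <- Wv$value %*% x$value + bv$value
  O <- matrix(0, D, T * N)
  Acache <- vector("list", N * nHeads)
  for (n_i in seq_len(N)) {
    cols <- ((n_i - 1L) * T + 1L):(n_i * T)
    for (h in seq_len(nHeads)) {
      rows <- ((h - 1L) * dh + 1L):(h * dh)
      S <- crossprod(Q[rows, cols, drop = FALSE],
                     K[rows, cols, drop = FALSE]) / sqrt(dh)
      S <- S - apply(S, 1, max)
      A <- exp(S); A <- A / rowSums(A)
      Acache[[(n_i - 1L) * nHeads + h]] <- A
      O[rows, cols] <- V[rows, cols, drop = FALSE] %*% t(A)
    }
  }
  out <- Wo$value %*% O + bo$value
  nn <- nd(out, list(x, Wq, Wk, Wv, Wo, bq, bk, bv, bo))
  nn$backfn <- function(s) {
    g <- s$grad
    .addGrad(Wo, g %*% t(O))
    .addGrad(bo, rowSums(g))
    dO <- t(Wo$value) %*% g
    dQ <- matrix(0, D, T * N); dK <- dQ; dV <- dQ
    for (n_i in seq_len(N)) {
      cols <- ((n_i - 1L) * T + 1L):(n_i * T)
      for (h in seq_len(nHeads)) {
        rows <- ((h - 1L) * dh + 1L):(h * dh)
        A <- Acache[[(n_i - 1L) * nHeads + h]]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- V[rows, cols, drop = FALSE]
        dV[rows, cols] <- dV[rows, cols] + dOh %*% A
        dA <- t(crossprod(Vh, dOh))              # T x T
        rs <- rowSums(dA * A)
        dS <- A * (dA - rs)
        dQ[rows, cols] <- dQ[rows, cols] +
          K[rows, cols, drop = FALSE] %*% t(dS) / sqrt(dh)
        dK[rows, cols] <- dK[rows, cols] +
          Q[rows, cols, drop = FALSE] %*% dS / sqrt(dh)
      }
    }
    .addGrad(Wq, dQ %*% t(x$value)); .addGrad(bq, rowSums(dQ))
    .addGrad(Wk, dK %*% t(x$value)); .addGrad(bk, rowSums(dK))
    .addGrad(Wv, dV %*% t(x$value)); .addGrad(bv, rowSums(dV))
    .addGrad(x, t(Wq$value) %*% dQ + t(Wk$value) %*% dK + t(Wv$value) %*% dV)
  }
  nn
}
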