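# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Every operation builds a graph node (an environment) holding the forward
# value, the parent nodes and a closure that routes the upstream gradient to
# the parents. `ndBackward()` runs the tape in reverse creation order.
# Feature matrices are features x batch; convolutional tensors are
# column-major (H, W, C, N) arrays. Fused nodes (conv, batch norm, attention)
# carry hand-derived backward rules, verified against finite differences in
# the test suite.

.ndState <- new.env(parent = emptyenv())
.ndState$id <- 0L

nd <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  .ndState$id <- .ndState$id + 1L
  e$id <- .ndState$id
  class(e) <- "ppgNode"
  e
}

ndValue <- function(x) if (inherits(x, "ppgNode")) x$value else x

.addGrad <- function(p, g) {
  if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  invisible(NULL)
}

# Reverse sweep from a scalar root. Collects the reachable subgraph, then
# fires each node's backward rule in decreasing creation order.
ndBackward <- function(root) {
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L)
  count <- 0L
  stack <- list(root)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    count <- count + 1L
    if (count > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[count]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(count)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  root$grad <- if (length(root$value) == 1L) 1 else array(1, dim(root$value))
  for (n in nodes[ord])
    if (!is.null(n$backfn) && !is.null(n$grad)) n$backfn(n)
  invisible(root)
}

# ---- elementwise / linear algebra primitives ----

ndAdd <- function(a, b) {
  n <- nd(a$value + b$value, list(a, b))
  n$backfn <- function(s) { .addGrad(a, s$grad); .addGrad(b, s$grad) }
  n
}

# x (d x m) plus a per-row bias vector b (length d).
ndAddBias <- function(x, b) {
  n <- nd(x$value + b$value, list(x, b))
  n$backfn <- function(s) {
    .addGrad(x, s$grad)
    .addGrad(b, rowSums(s$grad))
  }
  n
}

# x (d x T*N) plus a (d x T) matrix tiled N times along the columns
# (learned position embeddings).
ndAddTiled <- function(x, p, reps) {
  d <- nrow(p$value); Tn <- ncol(p$value)
  n <- nd(x$value + matrix(p$value, d, Tn * reps), list(x, p))
  n$backfn <- function(s) {
    .addGrad(x, s$grad)
    g <- array(s$grad, c(d, Tn, reps))
    .addGrad(p, rowSums(g, dims = 2))
  }
  n
}

ndMatmul <- function(a, b) {
  n <- nd(a$value %*% b$value, list(a, b))
  n$backfn <- function(s) {
    .addGrad(a, s$grad %*% t(b$value))
    .addGrad(b, t(a$value) %*% s$grad)
  }
  n
}

ndHadamard <- function(a, b) {
  n <- nd(a$value * b$value, list(a, b))
  n$backfn <- function(s) {
    .addGrad(a, s$grad * b$value)
    .addGrad(b, s$grad * a$value)
  }
  n
}

# a + alpha * b with a learnable scalar alpha (Eq. 6 fusion limit cases fall
# out of this parameterization: alpha = 0 recovers `a` exactly).
ndScalarMix <- function(a, alpha, b) {
  al <- as.numeric(alpha$value)[1]
  n <- nd(a$value + al * b$value, list(a, alpha, b))
  n$backfn <- function(s) {
    .addGrad(a, s$grad)
    .addGrad(b, al * s$grad)
    .addGrad(alpha, sum(s$grad * b$value))
  }
  n
}

ndRelu <- function(x) {
  n <- nd(pmax(x$value, 0), list(x))
  n$backfn <- function(s) .addGrad(x, s$grad * (x$value > 0))
  n
}

# Exact (erf-based) GELU: x * Phi(x).
ndGelu <- function(x) {
  v <- x$value
  ph <- stats::pnorm(v)
  n <- nd(v * ph, list(x))
  n$backfn <- function(s) .addGrad(x, s$grad * (ph + v * stats::dnorm(v)))
  n
}

ndSigmoid <- function(x) {
  sg <- 1 / (1 + exp(-x$value))
  n <- nd(sg, list(x))
  n$backfn <- function(s) .addGrad(x, s$grad * sg * (1 - sg))
  n
}

# Column-wise softmax of a (classes x batch) matrix.
ndSoftmax <- function(x) {
  v <- x$value
  v <- sweep(v, 2, apply(v, 2, max))
  e <- exp(v)
  sm <- sweep(e, 2, colSums(e), "/")
  n <- nd(sm, list(x))
  n$backfn <- function(s) {
    cs <- colSums(s$grad * sm)
    .addGrad(x, sm * sweep(s$grad, 2, cs))
  }
  n
}

# Fused softmax + categorical cross-entropy; Y is a one-hot
# (classes x batch) matrix. Value is the batch-mean loss.
ndSoftmaxCrossEntropy <- function(logits, Y) {
  v <- logits$value
  v <- sweep(v, 2, apply(v, 2, max))
  lse <- log(colSums(exp(v)))
  m <- ncol(v)
  loss <- mean(lse - colSums(Y * v))
  probs <- sweep(exp(v), 2, exp(lse), "/")
  n <- nd(loss, list(logits))
  n$probs <- probs
  n$backfn <- function(s) .addGrad(logits, s$grad * (probs - Y) / m)
  n
}

# Mean squared error against a fixed target (same shape).
ndMSE <- function(x, Y) {
  d <- x$value - Y
  n <- nd(mean(d^2), list(x))
  n$backfn <- function(s) .addGrad(x, s$grad * 2 * d / length(d))
  n
}

ndDropout <- function(x, rate) {
  if (rate <= 0) return(x)
  mask <- (stats::runif(length(x$value)) >= rate) / (1 - rate)
  dim(mask) <- dim(x$value)
  n <- nd(x$value * mask, list(x))
  n$backfn <- function(s) .addGrad(x, s$grad * mask)
  n
}

# ---- shape plumbing ----

# (H, W, C, N) -> channel matrix (C x H*W*N), token (h, w) fastest, then n.
ndChannelsToMat <- function(x, H, W, C, N) {
  v <- matrix(aperm(x$value, c(3, 1, 2, 4)), C)
  n <- nd(v, list(x))
  n$backfn <- function(s)
    .addGrad(x, aperm(array(s$grad, c(C, H, W, N)), c(2, 3, 1, 4)))
  n
}

ndMatToChannels <- function(x, H, W, C, N) {
  v <- aperm(array(x$value, c(C, H, W, N)), c(2, 3, 1, 4))
  n <- nd(v, list(x))
  n$backfn <- function(s)
    .addGrad(x, matrix(aperm(s$grad, c(3, 1, 2, 4)), C))
  n
}

# (H, W, C, N) -> flat (H*W*C x N)
ndFlatten <- function(x) {
  d <- dim(x$value)
  n <- nd(matrix(x$value, prod(d[1:3]), d[4]), list(x))
  n$backfn <- function(s) .addGrad(x, array(s$grad, d))
  n
}

ndConcatRows <- function(a, b) {
  da <- nrow(a$value)
  n <- nd(rbind(a$value, b$value), list(a, b))
  n$backfn <- function(s) {
    .addGrad(a, s$grad[seq_len(da), , drop = FALSE])
    .addGrad(b, s$grad[-seq_len(da), , drop = FALSE])
  }
  n
}

ndConcatChannels <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$value
  v[, , da[3] + seq_len(db[3]), ] <- b$value
  n <- nd(v, list(a, b))
  n$backfn <- function(s) {
    .addGrad(a, s$grad[, , seq_len(da[3]), , drop = FALSE])
    .addGrad(b, s$grad[, , da[3] + seq_len(db[3]), , drop = FALSE])
  }
  n
}

# Gather with zero padding: idx indexes into x's value (NA -> 0), each
# source element referenced at most once, so backward is a plain scatter.
ndGatherPad <- function(x, idx, outDim) {
  ok <- !is.na(idx)
  v <- numeric(length(idx))
  v[ok] <- x$value[idx[ok]]
  dim(v) <- outDim
  n <- nd(v, list(x))
  n$backfn <- function(s) {
    g <- array(0, dim(x$value))
    g[idx[ok]] <- s$grad[ok]
    .addGrad(x, g)
  }
  n
}

# Per-sample mean over T token columns: (D x T*N) -> (D x N).
ndMeanTokens <- function(x, T, N) {
  D <- nrow(x$value)
  arr <- array(x$value, c(D, T, N))
  v <- apply(arr, 3, rowMeans)
  dim(v) <- c(D, N)
  n <- nd(v, list(x))
  n$backfn <- function(s)
    .addGrad(x, (s$grad / T)[, rep(seq_len(N), each = T), drop = FALSE])
  n
}

# Global average pooling: (H, W, C, N) -> (C x N).
ndGap <- function(x) {
  d <- dim(x$value)
  m <- matrix(x$value, d[1] * d[2], d[3] * d[4])
  n <- nd(matrix(colMeans(m), d[3], d[4]), list(x))
  n$backfn <- function(s) {
    g <- matrix(rep(as.numeric(s$grad) / (d[1] * d[2]), each = d[1] * d[2]),
                d[1] * d[2], d[3] * d[4])
    .addGrad(x, array(g, d))
  }
  n
}
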