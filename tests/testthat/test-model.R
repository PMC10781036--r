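deskModel <- function() buildModel(modelConfig("desk", seed = 3L))

test_that("model construction is deterministic and validates its configuration", {
  m1 <- buildModel(modelConfig("desk", seed = 5L))
  m2 <- buildModel(modelConfig("desk", seed = 5L))
  expect_identical(modelParameters(m1), modelParameters(m2))
  m3 <- buildModel(modelConfig("desk", seed = 6L))
  expect_false(identical(modelParameters(m1), modelParameters(m3)))

  expect_lt(parameterCount(m1), 2e6)     # desk profile stays small
  expect_equal(parameterCount(m1), 184153)  # regression fixture
  summary <- capture.output(modelSummary(m1))
  expect_true(any(grepl("total trainable parameters", summary)))
  expect_error(buildModel(modelConfig("desk", nClasses = 1L)), "nClasses")
  expect_error(buildModel(modelConfig("desk", imageSide = 60L)), "nPool")
  expect_error(buildModel(modelConfig("desk", dropout = 1)), "dropout")
  expect_error(modelConfig("desk", bogusField = 1), "unknown")
})

test_that("forward pass has the contracted shapes and finite outputs", {
  m <- deskModel()
  imgs <- array(stats::runif(64 * 64 * 4), c(64, 64, 4))
  p <- predictProbs(m, imgs)
  expect_equal(dim(p), c(8, 4))
  expect_equal(colSums(p), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))

  # CVT output vector length = tokenDim; ConvMixer output = 2h (Eq. 5 concat)
  cv <- cvtFeatures(m, imgs)
  expect_equal(featureRole(cv), "CVT_map")
  expect_equal(dim(featureValues(cv)), c(64, 4))
  cm <- convMixerFeatures(m, imgs)
  expect_equal(featureRole(cm), "ConvMixer_map")
  expect_equal(dim(featureValues(cm)), c(64, 4))

  zero <- array(0, c(64, 64, 2))
  expect_true(all(is.finite(predictProbs(m, zero))))
})

test_that("the ConvMixer stem is a patch embedding with floor(side/p) geometry", {
  m <- deskModel()
  z0 <- convMixerStem(m, array(stats::runif(64 * 64 * 2), c(64, 64, 2)))
  expect_equal(featureRole(z0), "Z0")
  expect_equal(dim(featureValues(z0)), c(8, 8, 32, 2))

  # patch 5 on a 128 image: floor(128/5) = 25 (published geometry)
  m128 <- buildModel(modelConfig("desk", imageSide = 128L, patchSize = 5L,
                                 nPool = 4L, seed = 0L))
  z0b <- convMixerStem(m128, array(0.5, c(128, 128, 1)))
  expect_equal(dim(featureValues(z0b))[1:3], c(25, 25, 32))

  # patch = image side collapses to a single spatial cell
  mOne <- buildModel(modelConfig("desk", imageSide = 16L, patchSize = 16L,
                                 nPool = 2L, nTokens = 4L,
                                 cvtChannelPlan = c(4L, 8L), tokenDim = 8L,
                                 nHeads = 2L, mlpHidden = 8L, seed = 0L))
  z0c <- convMixerStem(mOne, array(0.3, c(16, 16, 1)))
  expect_equal(dim(featureValues(z0c))[1:3], c(1, 1, 32))
})

test_that("mixer blocks preserve shape and reduce to a constant map plus input when the depthwise path is zeroed", {
  m <- deskModel()
  z <- array(stats::rnorm(8 * 8 * 32 * 2), c(8, 8, 32, 2))
  out <- convMixerBlock(m, z, blockIndex = 1L)
  expect_equal(featureRole(out), "Zl+1")
  expect_equal(dim(featureValues(out)), dim(z))
  expect_true(all(is.finite(featureValues(out))))

  # zero the depthwise weights/bias: Eq. 3 gives Zl = BN(GELU(0)) + Zl-1,
  # i.e. the input plus a per-channel constant (the BN shift)
  nd <- ppgbioid:::nd
  zin <- nd(z)
  w0 <- nd(array(0, c(3, 3, 32))); b0 <- nd(numeric(32))
  gam <- nd(rep(1, 32)); bet <- nd(stats::rnorm(32))
  st <- new.env()
  dw <- ppgbioid:::ndDepthwiseConv(zin, w0, b0, 3L)
  zl <- ppgbioid:::ndAdd(
    ppgbioid:::ndBatchNormConv(ppgbioid:::ndGelu(dw), gam, bet, st, FALSE),
    zin)
  diffMap <- ppgbioid:::ndValue(zl) - z
  for (c in 1:32)
    expect_equal(as.numeric(diffMap[, , c, ]),
                 rep(ppgbioid:::ndValue(bet)[c], 8 * 8 * 2),
                 tolerance = 1e-12)

  expect_error(convMixerBlock(m, array(0, c(8, 8, 16, 2))), "channels")
})

test_that("Eq. 6 fusion obeys its algebraic limits", {
  m <- deskModel()
  cvt <- matrix(stats::rnorm(64 * 3), 64, 3)
  mix <- matrix(stats::rnorm(64 * 3), 64, 3)

  m@env$params$fuse_alpha <- 0
  f0 <- fuseFeatures(m, cvt, mix)
  expect_equal(featureRole(f0), "Dense_Features_map")
  expect_equal(featureValues(f0), as.array(cvt))

  m@env$params$fuse_alpha <- 1
  expect_equal(featureValues(fuseFeatures(m, cvt, mix * 0)), as.array(cvt))

  m@env$params$fuse_alpha <- 2
  ones <- matrix(1, 8, 2)
  m8 <- m; m8@env$params$fuse_alpha <- 2
  expect_equal(as.numeric(featureValues(fuseFeatures(m8, ones, ones))),
               rep(3, 16))
})

test_that("alpha = 0 reduces the full network to the CVT-only path", {
  cfg <- tinyModelConfig(alphaLearnable = FALSE, alpha = 0)
  m <- buildModel(cfg)
  m@env$params$fuse_alpha <- 0
  imgs <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  full <- predictProbs(m, imgs)

  # ablation: compute the head on the CVT features alone
  cvt <- featureValues(cvtFeatures(m, imgs))
  abl <- classifyFeatures(m, channelAttention(m, residualUnit(m, cvt)))
  expect_equal(full, abl, tolerance = 1e-12)
})

test_that("the residual unit is ReLU(x + transform(x)) with an identity-map limit", {
  m <- deskModel()
  x <- matrix(stats::rnorm(64 * 5), 64, 5)
  out <- residualUnit(m, x)
  expect_equal(featureRole(out), "Output")
  expect_true(all(featureValues(out) >= 0))
  expect_equal(dim(featureValues(out)), dim(x))

  m0 <- buildModel(modelConfig("desk", seed = 3L))
  m0@env$params$res_W[] <- 0
  m0@env$params$res_b[] <- 0
  expect_equal(featureValues(residualUnit(m0, x)), as.array(pmax(x, 0)))

  zeroIn <- matrix(0, 64, 2)
  expect_equal(featureValues(residualUnit(m0, zeroIn)),
               as.array(zeroIn))
})

test_that("channel attention gates lie in (0,1) and attenuate, with a forced-gate identity", {
  m <- deskModel()
  x <- matrix(stats::rnorm(64 * 6), 64, 6)
  W <- featureValues(channelAttention(m, x, returnGates = TRUE))
  expect_true(all(W > 0 & W < 1))
  feats <- featureValues(channelAttention(m, x))
  expect_true(all(abs(feats) <= abs(x) + 1e-12))

  # force the gate network so W = sigmoid(0) = 0.5 everywhere
  mF <- buildModel(modelConfig("desk", seed = 3L))
  mF@env$params$se_W1[] <- 0; mF@env$params$se_b1[] <- 0
  mF@env$params$se_W2[] <- 0; mF@env$params$se_b2[] <- 0
  expect_equal(featureValues(channelAttention(mF, x)), as.array(0.5 * x),
               tolerance = 1e-12)

  z <- matrix(0, 64, 2)
  expect_equal(featureValues(channelAttention(mF, z)), as.array(z))
})

test_that("the softmax head produces calibrated probability columns", {
  m <- deskModel()
  f <- matrix(stats::rnorm(64 * 7), 64, 7)
  p <- classifyFeatures(m, f)
  expect_equal(colSums(p), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))

  # symmetric logits give uniform probabilities; a dominant logit wins
  sm <- function(l) exp(l - max(l)) / sum(exp(l - max(l)))
  expect_equal(sm(c(0, 0)), c(0.5, 0.5))
  expect_equal(which.max(sm(c(10, 0, 0))), 1L)
})

test_that("uniform attention weights reduce pooled attention to a plain token mean", {
  nd <- ppgbioid:::nd
  D <- 8L; T <- 6L; N <- 3L
  set.seed(2)
  x <- nd(matrix(stats::rnorm(D * T * N), D))
  zeroW <- function() nd(matrix(0, D, D))
  idW <- nd(diag(D)); zb <- function() nd(numeric(D))
  att <- ppgbioid:::ndMultiHeadAttention(
    x, zeroW(), zeroW(), idW, idW, zb(), zb(), zb(), zb(),
    nHeads = 2L, T = T, N = N)
  pooled <- ppgbioid:::ndValue(ppgbioid:::ndMeanTokens(att, T, N))
  # with Wq = Wk = 0 every attention row is uniform: each output token is the
  # token mean, so pooling equals plain averaging — and any permutation of
  # the tokens within a sample leaves it unchanged
  plain <- sapply(seq_len(N), function(n)
    rowMeans(ppgbioid:::ndValue(x)[, ((n - 1) * T + 1):(n * T)]))
  expect_equal(pooled, plain, tolerance = 1e-12)

  perm <- sample(T)
  xp <- ppgbioid:::ndValue(x)
  for (n in seq_len(N)) {
    cols <- ((n - 1) * T + 1):(n * T)
    xp[, cols] <- xp[, cols][, perm]
  }
  att2 <- ppgbioid:::ndMultiHeadAttention(
    nd(xp), zeroW(), zeroW(), idW, idW, zb(), zb(), zb(), zb(),
    nHeads = 2L, T = T, N = N)
  pooled2 <- ppgbioid:::ndValue(ppgbioid:::ndMeanTokens(att2, T, N))
  expect_equal(pooled2, pooled, tolerance = 1e-12)
})

test_that("every forward pass on finite input is finite across seeds", {
  for (seed in 1:10) {
    cfg <- tinyModelConfig(seed = as.integer(seed))
    m <- buildModel(cfg)
    imgs <- array(stats::runif(16 * 16 * 2), c(16, 16, 2))
    expect_true(all(is.finite(predictProbs(m, imgs))))
  }
})
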