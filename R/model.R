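#' Hybrid CVT-ConvMixer model configuration
#'
#' Two named profiles are provided. `"paper-full"` follows the published
#' architecture description where it is explicit (17 3x3 conv layers with five
#' 2x2 max-pool stages in the CVT feature-learning stage, 7 patch tokens of
#' dimension 1024, 8 attention heads, ConvMixer patch size 5 / hidden 32 /
#' depth 7, 2048-unit MLP head); the convolutional channel widths are not
#' published, so `cvtChannelPlan` is explicit configuration with a VGG-like
#' default. `"desk"` is a scaled-down profile for desk-scale experiments:
#' 64x64 images, 6 conv layers `[8,16,16,32,32,64]` with 3 pools, 4 tokens of
#' dimension 64, 4 heads, ConvMixer patch size 8.
#'
#' @param profile `"desk"` or `"paper-full"`.
#' @param ... named overrides of any configuration field.
#' @return a list with class `ModelConfig`.
#' @export
modelConfig <- function(profile = c("desk", "paper-full"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "desk") list(
    profile = "desk", imageSide = 64L, patchSize = 8L, hiddenDim = 32L,
    mixerDepth = 7L, mixerKernel = 5L,
    cvtChannelPlan = c(8L, 16L, 16L, 32L, 32L, 64L), nPool = 3L,
    nTokens = 4L, tokenDim = 64L, nHeads = 4L, mlpHidden = 128L,
    nClasses = 8L, alpha = 1, alphaLearnable = TRUE, fusionMode = "sum",
    seReduction = 4L, dropout = 0.1, seed = 0L)
  else list(
    profile = "paper-full", imageSide = 128L, patchSize = 5L, hiddenDim = 32L,
    mixerDepth = 7L, mixerKernel = 5L,
    cvtChannelPlan = c(64L, 64L, 128L, 128L, 256L, 256L, 256L, 512L, 512L,
                       512L, 512L, 512L, 512L, 512L, 512L, 512L, 512L),
    nPool = 5L, nTokens = 7L, tokenDim = 1024L, nHeads = 8L,
    mlpHidden = 2048L, nClasses = 35L, alpha = 1, alphaLearnable = TRUE,
    fusionMode = "sum", seReduction = 4L, dropout = 0.2, seed = 0L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown ModelConfig field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "ModelConfig")
}

.validateModelConfig <- function(cfg) {
  fail <- function(field, msg) stop(sprintf("ModelConfig$%s: %s", field, msg),
                                    call. = FALSE)
  if (cfg$patchSize < 1) fail("patchSize", "must be >= 1")
  if (cfg$imageSide < cfg$patchSize)
    fail("imageSide", "must be at least the patch size")
  if (cfg$nClasses < 2) fail("nClasses", "must be >= 2")
  if (cfg$dropout < 0 || cfg$dropout >= 1) fail("dropout", "must be in [0, 1)")
  if (!is.finite(cfg$alpha)) fail("alpha", "must be finite")
  if (cfg$imageSide %% 2^cfg$nPool != 0)
    fail("nPool", sprintf("imageSide %d is not divisible by 2^%d",
                          cfg$imageSide, cfg$nPool))
  side <- cfg$imageSide %/% 2^cfg$nPool
  if (side^2 < cfg$nTokens)
    fail("nTokens", sprintf(
      "feature map after pooling has %d spatial positions, fewer than %d tokens",
      side^2, cfg$nTokens))
  if (cfg$tokenDim %% cfg$nHeads != 0)
    fail("nHeads", "tokenDim must be divisible by the head count")
  if ((2L * cfg$hiddenDim) %% cfg$nHeads != 0)
    fail("nHeads", "2*hiddenDim must be divisible by the head count")
  if (!cfg$fusionMode %in% c("sum", "concat"))
    fail("fusionMode", "must be 'sum' or 'concat'")
  invisible(cfg)
}

# Fused feature dimension (Eq. 6 output).
.fusedDim <- function(cfg) {
  if (cfg$fusionMode == "concat") cfg$tokenDim + 2L * cfg$hiddenDim
  else cfg$tokenDim
}

#' Assembled hybrid CVT-ConvMixer model
#'
#' @slot config the `ModelConfig` the model was built with.
#' @slot env environment holding the parameter list, batch-norm running
#'   statistics and optimizer state (mutated during training).
#' @exportClass HybridModel
setClass("HybridModel",
  representation(config = "list", env = "environment"))

#' @export
setMethod("show", "HybridModel", function(object) {
  cat(sprintf(
    "HybridModel (%s profile): %d x %d input, %d classes, %s trainable parameters\n",
    object@config$profile, object@config$imageSide, object@config$imageSide,
    object@config$nClasses, format(parameterCount(object), big.mark = ",")))
})

# He (fan-in) initialization for conv/ReLU paths, Xavier for linear and
# attention paths.
.heInit <- function(dims, fanIn) array(stats::rnorm(prod(dims), 0,
                                                    sqrt(2 / fanIn)), dims)
.xavierInit <- function(dims, fanIn, fanOut)
  array(stats::runif(prod(dims), -1, 1) * sqrt(6 / (fanIn + fanOut)), dims)

#' Build the hybrid CVT-ConvMixer model
#'
#' Wires image input through the two branches (CVT feature learning +
#' transformer encoding; ConvMixer patch embedding, depthwise/pointwise mixer
#' blocks, concatenation fusion, spatial self-attention and global pooling),
#' the attentional selective fusion, the residual unit, channel self-attention
#' and the softmax MLP head. Parameter initialization is deterministic in
#' `cfg$seed` (He for convolutional/ReLU paths, Xavier for linear/attention
#' paths).
#'
#' @param cfg a [modelConfig()].
#' @return a [HybridModel-class].
#' @export
buildModel <- function(cfg = modelConfig()) {
  .validateModelConfig(cfg)
  env <- new.env(parent = emptyenv())
  K <- 3L
  withSeed(childSeed(cfg$seed, "init"), {
    p <- list()
    # --- CVT feature-learning stage ---
    inC <- 1L
    for (i in seq_along(cfg$cvtChannelPlan)) {
      outC <- cfg$cvtChannelPlan[i]
      p[[sprintf("cvt_conv%d_W", i)]] <- .heInit(c(outC, K * K * inC),
                                                 K * K * inC)
      p[[sprintf("cvt_conv%d_b", i)]] <- numeric(outC)
      p[[sprintf("cvt_bn%d_gamma", i)]] <- rep(1, outC)
      p[[sprintf("cvt_bn%d_beta", i)]] <- numeric(outC)
      inC <- outC
    }
    side <- cfg$imageSide %/% 2^cfg$nPool
    P <- side^2
    gsize <- ceiling(P / cfg$nTokens)
    patchDim <- gsize * inC
    p$cvt_embed_W <- .xavierInit(c(cfg$tokenDim, patchDim), patchDim,
                                 cfg$tokenDim)
    p$cvt_embed_b <- numeric(cfg$tokenDim)
    p$cvt_pos <- .xavierInit(c(cfg$tokenDim, cfg$nTokens), cfg$tokenDim,
                             cfg$tokenDim)
    for (nm in c("q", "k", "v", "o")) {
      p[[paste0("cvt_W", nm)]] <- .xavierInit(c(cfg$tokenDim, cfg$tokenDim),
                                              cfg$tokenDim, cfg$tokenDim)
      p[[paste0("cvt_b", nm)]] <- numeric(cfg$tokenDim)
    }
    p$cvt_ln1_gamma <- rep(1, cfg$tokenDim); p$cvt_ln1_beta <- numeric(cfg$tokenDim)
    p$cvt_ln2_gamma <- rep(1, cfg$tokenDim); p$cvt_ln2_beta <- numeric(cfg$tokenDim)
    ffn <- 2L * cfg$tokenDim
    p$cvt_ffn1_W <- .xavierInit(c(ffn, cfg$tokenDim), cfg$tokenDim, ffn)
    p$cvt_ffn1_b <- numeric(ffn)
    p$cvt_ffn2_W <- .xavierInit(c(cfg$tokenDim, ffn), ffn, cfg$tokenDim)
    p$cvt_ffn2_b <- numeric(cfg$tokenDim)
    # --- ConvMixer branch ---
    h <- cfg$hiddenDim; ps <- cfg$patchSize; mk <- cfg$mixerKernel
    p$mix_stem_W <- .heInit(c(h, ps * ps * 1L), ps * ps)
    p$mix_stem_b <- numeric(h)
    p$mix_stem_bn_gamma <- rep(1, h); p$mix_stem_bn_beta <- numeric(h)
    for (l in seq_len(cfg$mixerDepth)) {
      p[[sprintf("mix_dw%d_W", l)]] <- .heInit(c(mk, mk, h), mk * mk)
      p[[sprintf("mix_dw%d_b", l)]] <- numeric(h)
      p[[sprintf("mix_dwbn%d_gamma", l)]] <- rep(1, h)
      p[[sprintf("mix_dwbn%d_beta", l)]] <- numeric(h)
      if (l < cfg$mixerDepth) {   # the last block feeds the Eq. 5 fusion
        p[[sprintf("mix_pw%d_W", l)]] <- .heInit(c(h, h), h)
        p[[sprintf("mix_pw%d_b", l)]] <- numeric(h)
        p[[sprintf("mix_pwbn%d_gamma", l)]] <- rep(1, h)
        p[[sprintf("mix_pwbn%d_beta", l)]] <- numeric(h)
      }
    }
    p$mix_e5pw_W <- .heInit(c(h, h), h)
    p$mix_e5pw_b <- numeric(h)
    p$mix_e5bn_gamma <- rep(1, h); p$mix_e5bn_beta <- numeric(h)
    D2 <- 2L * h
    for (nm in c("q", "k", "v", "o")) {
      p[[paste0("mix_W", nm)]] <- .xavierInit(c(D2, D2), D2, D2)
      p[[paste0("mix_b", nm)]] <- numeric(D2)
    }
    # --- fusion, residual unit, channel attention, head ---
    d <- .fusedDim(cfg)
    if (cfg$fusionMode == "sum" && D2 != cfg$tokenDim) {
      p$fuse_proj_W <- .xavierInit(c(cfg$tokenDim, D2), D2, cfg$tokenDim)
      p$fuse_proj_b <- numeric(cfg$tokenDim)
    }
    p$fuse_alpha <- cfg$alpha
    p$res_W <- .xavierInit(c(d, d), d, d)
    p$res_b <- numeric(d)
    r <- max(1L, d %/% cfg$seReduction)
    p$se_W1 <- .xavierInit(c(r, d), d, r); p$se_b1 <- numeric(r)
    p$se_W2 <- .xavierInit(c(d, r), r, d); p$se_b2 <- numeric(d)
    p$head_W1 <- .heInit(c(cfg$mlpHidden, d), d)
    p$head_b1 <- numeric(cfg$mlpHidden)
    p$head_W2 <- .xavierInit(c(cfg$nClasses, cfg$mlpHidden), cfg$mlpHidden,
                             cfg$nClasses)
    p$head_b2 <- numeric(cfg$nClasses)
    env$params <- p
  })
  env$bn <- new.env(parent = emptyenv())
  env$opt <- NULL
  new("HybridModel", config = unclass(cfg), env = env)
}

#' Trainable parameters of a model
#' @param model a [HybridModel-class]
#' @return named list of parameter arrays
#' @export
modelParameters <- function(model) model@env$params

#' Total trainable parameter count
#' @param model a [HybridModel-class]
#' @export
parameterCount <- function(model)
  sum(vapply(model@env$params, length, numeric(1)))

#' One-line-per-layer model summary
#' @param model a [HybridModel-class]
#' @return character vector (invisibly); printed to the console
#' @export
modelSummary <- function(model) {
  p <- model@env$params
  lines <- c(sprintf("HybridModel profile=%s imageSide=%d nClasses=%d",
                     model@config$profile, model@config$imageSide,
                     model@config$nClasses),
             sprintf("  %-22s %s", names(p),
                     vapply(p, function(a)
                       paste(if (is.null(dim(a))) length(a) else dim(a),
                             collapse = " x "), character(1))),
             sprintf("  total trainable parameters: %d",
                     as.integer(parameterCount(model))))
  cat(lines, sep = "\n")
  invisible(lines)
}

.bnStats <- function(model, name) {
  if (is.null(model@env$bn[[name]]))
    model@env$bn[[name]] <- new.env(parent = emptyenv())
  model@env$bn[[name]]
}

# Pool stages centered evenly within the conv stack (e.g. after layers
# 1, 3, 5 for 6 layers / 3 pools), so high-resolution layers are few.
.poolPositions <- function(nLayers, nPool)
  unique(pmax(1L, round((seq_len(nPool) - 0.5) * nLayers / nPool)))

# Index map assigning the post-pooling spatial positions (flattened h-fastest)
# to `nTokens` contiguous groups, zero-padded when indivisible; returns the
# gather index into the position-major ((P*N) x C) feature matrix producing
# the (patchDim x nTokens*N) patch matrix (patch entries channel-fastest).
.patchIndex <- function(P, C, N, nTokens) {
  gsize <- ceiling(P / nTokens)
  padded <- c(seq_len(P), rep(NA_integer_, gsize * nTokens - P))
  MR <- P * N
  idx <- matrix(NA_integer_, gsize * C, nTokens * N)
  for (n_i in seq_len(N)) for (t in seq_len(nTokens)) {
    pos <- padded[((t - 1L) * gsize + 1L):(t * gsize)]
    # element ((p, n), c) of the pos-major matrix sits at (p + P*(n-1)) + MR*(c-1);
    # the patch stacks the C-channel vectors of its positions in order.
    block <- outer(MR * (seq_len(C) - 1L), pos + P * (n_i - 1L), "+")
    block[, is.na(pos)] <- NA_integer_
    idx[, (n_i - 1L) * nTokens + t] <- as.integer(block)
  }
  idx
}

# Forward pass. `images`: (side, side, N) array. Returns the graph nodes of
# every architectural stage plus the wrapped parameter nodes.
.forward <- function(model, images, training = FALSE) {
  cfg <- model@config
  d <- dim(images)
  if (length(d) == 2L) { images <- array(images, c(d, 1L)); d <- dim(images) }
  if (d[1] != cfg$imageSide || d[2] != cfg$imageSide)
    stop(sprintf("expected %d x %d images, got %d x %d",
                 cfg$imageSide, cfg$imageSide, d[1], d[2]))
  N <- d[3]
  P <- lapply(model@env$params, nd)
  x <- nd(array(images, c(d[1], d[2], 1L, N)))
  st <- list()

  # ---- CVT branch: conv stage (ReLU then BN), pooling evenly distributed.
  # Runs in the position-major layout ((h, w, n) rows x channel columns).
  nL <- length(cfg$cvtChannelPlan)
  poolAfter <- .poolPositions(nL, cfg$nPool)
  z <- nd(matrix(images, d[1] * d[2] * N, 1L))
  side <- c(d[1], d[2])
  for (i in seq_len(nL)) {
    z <- ndConv2dPos(z, P[[sprintf("cvt_conv%d_W", i)]],
                     P[[sprintf("cvt_conv%d_b", i)]], K = 3L,
                     H = side[1], Wd = side[2], N = N)
    z <- ndRelu(z)
    z <- ndBatchNormCols(z, P[[sprintf("cvt_bn%d_gamma", i)]],
                         P[[sprintf("cvt_bn%d_beta", i)]],
                         .bnStats(model, sprintf("cvt_bn%d", i)), training)
    if (i %in% poolAfter) {
      z <- ndMaxPool2Pos(z, side[1], side[2], N)
      side <- side %/% 2L
    }
  }
  Pn <- side[1] * side[2]; Cf <- ncol(z$value)
  idx <- .patchIndex(Pn, Cf, N, cfg$nTokens)
  patches <- ndGatherPad(z, as.integer(idx), c(nrow(idx), ncol(idx)))
  tok <- ndAddBias(ndMatmul(P$cvt_embed_W, patches), P$cvt_embed_b)
  tok <- ndAddTiled(tok, P$cvt_pos, N)
  # one pre-norm transformer encoder block
  a <- ndMultiHeadAttention(ndLayerNorm(tok, P$cvt_ln1_gamma, P$cvt_ln1_beta),
                            P$cvt_Wq, P$cvt_Wk, P$cvt_Wv, P$cvt_Wo,
                            P$cvt_bq, P$cvt_bk, P$cvt_bv, P$cvt_bo,
                            cfg$nHeads, cfg$nTokens, N)
  tok1 <- ndAdd(tok, a)
  ff <- ndAddBias(ndMatmul(P$cvt_ffn2_W, ndGelu(
    ndAddBias(ndMatmul(P$cvt_ffn1_W,
                       ndLayerNorm(tok1, P$cvt_ln2_gamma, P$cvt_ln2_beta)),
              P$cvt_ffn1_b))), P$cvt_ffn2_b)
  tok2 <- ndAdd(tok1, ff)
  st$CVT_map <- ndMeanTokens(tok2, cfg$nTokens, N)

  # ---- ConvMixer branch ----
  ps <- cfg$patchSize; h <- cfg$hiddenDim
  z0 <- ndConv2d(x, P$mix_stem_W, P$mix_stem_b, K = ps, stride = ps, pad = 0L)
  z0 <- ndBatchNormConv(ndGelu(z0), P$mix_stem_bn_gamma, P$mix_stem_bn_beta,
                        .bnStats(model, "mix_stem_bn"), training)
  st$Z0 <- z0
  zm1 <- z0
  mixBlock <- function(zin, l, pointwise = TRUE) {
    dw <- ndDepthwiseConv(zin, P[[sprintf("mix_dw%d_W", l)]],
                          P[[sprintf("mix_dw%d_b", l)]], cfg$mixerKernel)
    zl <- ndAdd(ndBatchNormConv(ndGelu(dw),
                                P[[sprintf("mix_dwbn%d_gamma", l)]],
                                P[[sprintf("mix_dwbn%d_beta", l)]],
                                .bnStats(model, sprintf("mix_dwbn%d", l)),
                                training), zin)
    if (!pointwise) return(zl)
    dzl <- dim(zl$value)
    pwm <- ndChannelsToMat(zl, dzl[1], dzl[2], dzl[3], dzl[4])
    pw <- ndAddBias(ndMatmul(P[[sprintf("mix_pw%d_W", l)]], pwm),
                    P[[sprintf("mix_pw%d_b", l)]])
    pw <- ndBatchNormMat(ndGelu(pw), P[[sprintf("mix_pwbn%d_gamma", l)]],
                         P[[sprintf("mix_pwbn%d_beta", l)]],
                         .bnStats(model, sprintf("mix_pwbn%d", l)), training)
    ndMatToChannels(pw, dzl[1], dzl[2], dzl[3], dzl[4])
  }
  for (l in seq_len(cfg$mixerDepth - 1L)) zm1 <- mixBlock(zm1, l)
  f <- zm1
  # Eq. 5 fusion: pointwise path and the last block's depthwise-residual path
  B <- mixBlock(f, cfg$mixerDepth, pointwise = FALSE)
  df <- dim(f$value)
  fm <- ndChannelsToMat(f, df[1], df[2], df[3], df[4])
  A <- ndBatchNormMat(ndAddBias(ndMatmul(P$mix_e5pw_W, fm), P$mix_e5pw_b),
                      P$mix_e5bn_gamma, P$mix_e5bn_beta,
                      .bnStats(model, "mix_e5bn"), training)
  A <- ndMatToChannels(A, df[1], df[2], df[3], df[4])
  fused <- ndGelu(ndConcatChannels(A, B))
  dfu <- dim(fused$value)
  Tmix <- dfu[1] * dfu[2]
  tokm <- ndChannelsToMat(fused, dfu[1], dfu[2], dfu[3], N)
  att <- ndMultiHeadAttention(tokm, P$mix_Wq, P$mix_Wk, P$mix_Wv, P$mix_Wo,
                              P$mix_bq, P$mix_bk, P$mix_bv, P$mix_bo,
                              cfg$nHeads, Tmix, N)
  st$ConvMixer_map <- ndMeanTokens(att, Tmix, N)

  # ---- Eq. 6 attentional selective fusion ----
  mixv <- st$ConvMixer_map
  if (!is.null(P$fuse_proj_W))
    mixv <- ndAddBias(ndMatmul(P$fuse_proj_W, mixv), P$fuse_proj_b)
  dense <- if (cfg$fusionMode == "concat") {
    sc <- ndScalarMix(nd(array(0, dim(mixv$value))), P$fuse_alpha, mixv)
    ndConcatRows(st$CVT_map, sc)
  } else ndScalarMix(st$CVT_map, P$fuse_alpha, mixv)
  st$Dense_Features_map <- dense
  if (training && cfg$dropout > 0) dense <- ndDropout(dense, cfg$dropout)

  # ---- Eq. 7 residual unit ----
  out <- ndRelu(ndAdd(dense, ndAddBias(ndMatmul(P$res_W, dense), P$res_b)))
  st$Output <- out

  # ---- Eq. 8 channel self-attention (squeeze-excitation style gates) ----
  gate <- ndSigmoid(ndAddBias(ndMatmul(P$se_W2, ndRelu(
    ndAddBias(ndMatmul(P$se_W1, out), P$se_b1))), P$se_b2))
  st$W <- gate
  st$Features <- ndHadamard(gate, out)

  # ---- softmax MLP head ----
  hid <- ndRelu(ndAddBias(ndMatmul(P$head_W1, st$Features), P$head_b1))
  if (training && cfg$dropout > 0) hid <- ndDropout(hid, cfg$dropout)
  st$logits <- ndAddBias(ndMatmul(P$head_W2, hid), P$head_b2)
  list(params = P, stages = st, logits = st$logits)
}

.asImageBatch <- function(images) {
  if (is.matrix(images)) array(images, c(dim(images), 1L)) else images
}

#' Class probabilities for a batch of scalogram images
#'
#' Full inference-mode forward pass through both branches, fusion, residual
#' unit, channel attention and the softmax head.
#'
#' @param model a [HybridModel-class].
#' @param images `(side, side, N)` array (or a single `side x side` matrix)
#'   of images in \[0, 1\].
#' @param batchSize images per forward chunk (memory control).
#' @return `(nClasses x N)` matrix of class probabilities (columns sum to 1).
#' @export
predictProbs <- function(model, images, batchSize = 64L) {
  images <- .asImageBatch(images)
  N <- dim(images)[3]
  out <- matrix(0, model@config$nClasses, N)
  for (s in seq(1L, N, by = batchSize)) {
    e <- min(N, s + batchSize - 1L)
    fw <- .forward(model, images[, , s:e, drop = FALSE], training = FALSE)
    out[, s:e] <- ndValue(ndSoftmax(fw$logits))
  }
  out
}

# Run the forward pass and return one named architectural stage.
.stageValue <- function(model, images, stage) {
  fw <- .forward(model, .asImageBatch(images), training = FALSE)
  ndValue(fw$stages[[stage]])
}

#' CVT branch features
#'
#' Convolutional feature learning (3x3 conv / ReLU / batch-norm layers with
#' evenly distributed 2x2 max-pool stages), patch tokenization with learned
#' position embeddings, one transformer encoder block, and token-mean
#' aggregation.
#'
#' @inheritParams predictProbs
#' @return a [FeatureMap-class] with role `"CVT_map"`
#'   (`tokenDim x N`).
#' @export
cvtFeatures <- function(model, images)
  new("FeatureMap", values = as.array(.stageValue(model, images, "CVT_map")),
      role = "CVT_map")

#' ConvMixer patch-embedding stem
#'
#' The first ConvMixer layer: an `h`-channel convolution with kernel and
#' stride equal to the patch size, GELU activation, then batch normalization.
#'
#' @inheritParams predictProbs
#' @return a [FeatureMap-class] with role `"Z0"`
#'   (`side/p x side/p x h x N`).
#' @export
convMixerStem <- function(model, images)
  new("FeatureMap", values = as.array(.stageValue(model, images, "Z0")),
      role = "Z0")

#' One ConvMixer mixer block
#'
#' Applies block `blockIndex` to an `h`-channel feature map: the residual
#' depthwise stage `Zl = BN(GELU(DepthwiseConv(Zl-1))) + Zl-1` followed by
#' the pointwise stage `Zl+1 = BN(GELU(PointwiseConv(Zl)))`.
#'
#' @param model a [HybridModel-class].
#' @param z a [FeatureMap-class] (or array) with `hiddenDim` channels,
#'   `(H, W, h, N)`.
#' @param blockIndex which mixer block's parameters to use.
#' @return a [FeatureMap-class] with role `"Zl+1"` (same shape).
#' @export
convMixerBlock <- function(model, z, blockIndex = 1L) {
  v <- if (is(z, "FeatureMap")) z@values else z
  if (length(dim(v)) == 3L) v <- array(v, c(dim(v), 1L))
  cfg <- model@config
  if (dim(v)[3] != cfg$hiddenDim)
    stop(sprintf("expected %d channels, got %d", cfg$hiddenDim, dim(v)[3]))
  if (blockIndex >= cfg$mixerDepth)
    stop("blockIndex must address a full (depthwise + pointwise) block")
  P <- lapply(model@env$params, nd)
  l <- as.integer(blockIndex)
  zin <- nd(v)
  dw <- ndDepthwiseConv(zin, P[[sprintf("mix_dw%d_W", l)]],
                        P[[sprintf("mix_dw%d_b", l)]], cfg$mixerKernel)
  zl <- ndAdd(ndBatchNormConv(ndGelu(dw),
                              P[[sprintf("mix_dwbn%d_gamma", l)]],
                              P[[sprintf("mix_dwbn%d_beta", l)]],
                              .bnStats(model, sprintf("mix_dwbn%d", l)),
                              FALSE), zin)
  dzl <- dim(zl$value)
  pwm <- ndChannelsToMat(zl, dzl[1], dzl[2], dzl[3], dzl[4])
  pw <- ndBatchNormMat(ndGelu(ndAddBias(
    ndMatmul(P[[sprintf("mix_pw%d_W", l)]], pwm),
    P[[sprintf("mix_pw%d_b", l)]])),
    P[[sprintf("mix_pwbn%d_gamma", l)]],
    P[[sprintf("mix_pwbn%d_beta", l)]],
    .bnStats(model, sprintf("mix_pwbn%d", l)), FALSE)
  out <- ndMatToChannels(pw, dzl[1], dzl[2], dzl[3], dzl[4])
  new("FeatureMap", values = as.array(ndValue(out)), role = "Zl+1")
}

#' ConvMixer branch features
#'
#' Patch-embedding stem, the mixer block stack, the GELU/concatenation fusion
#' of the pointwise and depthwise-residual paths, spatial multi-head
#' self-attention over the fused map, and global average pooling.
#'
#' @inheritParams predictProbs
#' @return a [FeatureMap-class] with role `"ConvMixer_map"`
#'   (`2*hiddenDim x N`).
#' @export
convMixerFeatures <- function(model, images)
  new("FeatureMap",
      values = as.array(.stageValue(model, images, "ConvMixer_map")),
      role = "ConvMixer_map")

#' Attentional selective fusion of the branch features
#'
#' `Dense_Features_map = CVT_map + alpha * ConvMixer_map` with the model's
#' (possibly learnable) scalar `alpha`; the ConvMixer features are first
#' passed through the model's linear projection when the dimensions differ.
#' With `fusionMode = "concat"` the two parts are stacked instead of summed.
#'
#' @param model a [HybridModel-class].
#' @param cvtMap,mixerMap [FeatureMap-class] objects (or matrices) holding the
#'   branch features, features x batch.
#' @return a [FeatureMap-class] with role `"Dense_Features_map"`.
#' @export
fuseFeatures <- function(model, cvtMap, mixerMap) {
  cv <- if (is(cvtMap, "FeatureMap")) cvtMap@values else cvtMap
  mx <- if (is(mixerMap, "FeatureMap")) mixerMap@values else mixerMap
  cv <- as.matrix(cv); mx <- as.matrix(mx)
  p <- model@env$params
  if (!is.null(p$fuse_proj_W)) {
    mx <- p$fuse_proj_W %*% mx + p$fuse_proj_b
  } else if (nrow(mx) != nrow(cv) && model@config$fusionMode == "sum")
    stop("branch feature dimensions differ and no projection is configured")
  al <- as.numeric(p$fuse_alpha)[1]
  v <- if (model@config$fusionMode == "concat") rbind(cv, al * mx)
  else cv + al * mx
  new("FeatureMap", values = as.array(v), role = "Dense_Features_map")
}

#' Residual enhancement unit
#'
#' `output = ReLU(x + transform(x))` with a single linear transform, applied
#' to the fused feature vector.
#'
#' @param model a [HybridModel-class].
#' @param x a [FeatureMap-class] (or matrix), features x batch.
#' @return a [FeatureMap-class] with role `"Output"` (same shape, >= 0).
#' @export
residualUnit <- function(model, x) {
  v <- as.matrix(if (is(x, "FeatureMap")) x@values else x)
  p <- model@env$params
  out <- pmax(v + p$res_W %*% v + p$res_b, 0)
  new("FeatureMap", values = as.array(out), role = "Output")
}

#' Channel self-attention gating
#'
#' Gates `W = sigmoid(FC2(ReLU(FC1(pool(Output)))))` are computed from the
#' globally pooled channel statistics (for flat feature vectors the pooled
#' statistics are the features themselves) and applied by elementwise
#' multiplication: `Features = W * Output`. All gates lie strictly in (0, 1),
#' so the gated features never exceed the input in magnitude.
#'
#' @param model a [HybridModel-class].
#' @param x a [FeatureMap-class] (or matrix), features x batch.
#' @param returnGates return the gate map instead of the gated features.
#' @return a [FeatureMap-class] with role `"Features"` (or `"W"`).
#' @export
channelAttention <- function(model, x, returnGates = FALSE) {
  v <- as.matrix(if (is(x, "FeatureMap")) x@values else x)
  p <- model@env$params
  gate <- 1 / (1 + exp(-(p$se_W2 %*% pmax(p$se_W1 %*% v + p$se_b1, 0) +
                           p$se_b2)))
  if (returnGates) return(new("FeatureMap", values = as.array(gate), role = "W"))
  new("FeatureMap", values = as.array(gate * v), role = "Features")
}

#' Softmax MLP classification head
#'
#' Hidden ReLU layer of `mlpHidden` units followed by the class logits and a
#' softmax, so each column is a probability vector.
#'
#' @param model a [HybridModel-class].
#' @param features a [FeatureMap-class] (or matrix), features x batch.
#' @return `(nClasses x N)` probability matrix; columns sum to 1.
#' @export
classifyFeatures <- function(model, features) {
  v <- as.matrix(if (is(features, "FeatureMap")) features@values else features)
  p <- model@env$params
  logits <- p$head_W2 %*% pmax(p$head_W1 %*% v + p$head_b1, 0) + p$head_b2
  logits <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(logits)
  sweep(e, 2, colSums(e), "/")
}
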