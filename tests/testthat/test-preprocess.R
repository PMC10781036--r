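cfgDefault <- preprocessConfig()

test_that("bandpass filter passes the cardiac band and rejects out-of-band tones", {
  inBand <- sineSignal(1.5, 20, 250)
  out <- bandpassFilter(inBand, cfgDefault)
  expect_equal(length(out@samples), length(inBand@samples))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(out@samples) / rms(inBand@samples) - 1), 0.05)

  hf <- sineSignal(45, 20, 250)
  expect_lt(rms(bandpassFilter(hf, cfgDefault)@samples) / rms(hf@samples), 0.1)

  lf <- sineSignal(0.05, 60, 250)
  expect_lt(rms(bandpassFilter(lf, cfgDefault)@samples) / rms(lf@samples), 0.1)

  z <- PPGSignal(rep(0, 1000), 250)
  expect_equal(bandpassFilter(z, cfgDefault)@samples, rep(0, 1000))
  expect_error(bandpassFilter(sineSignal(1, 5, 12), cfgDefault), "Nyquist")
})

test_that("bandpass filtering is linear", {
  set.seed(7)
  x <- PPGSignal(rnorm(1000), 250)
  y <- PPGSignal(rnorm(1000), 250)
  axby <- PPGSignal(2 * x@samples + 3 * y@samples, 250)
  lhs <- bandpassFilter(axby, cfgDefault)@samples
  rhs <- 2 * bandpassFilter(x, cfgDefault)@samples +
    3 * bandpassFilter(y, cfgDefault)@samples
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("baseline removal tracks slow drift and leaves zero-mean output", {
  cc <- PPGSignal(rep(3.2, 500), 100)
  expect_lt(max(abs(removeBaseline(cc, cfgDefault)@samples)), 1e-9)
  expect_equal(removeBaseline(PPGSignal(rep(0, 300), 100),
                              cfgDefault)@samples, rep(0, 300))

  # adding a slow ramp changes the interior output only marginally
  t <- (0:999) / 100
  base <- sin(2 * pi * 2 * t)
  ramp <- 0.5 * t
  outClean <- removeBaseline(PPGSignal(base, 100), cfgDefault)@samples
  outRamp <- removeBaseline(PPGSignal(base + ramp, 100), cfgDefault)@samples
  interior <- 150:850
  expect_lt(max(abs(outClean[interior] - outRamp[interior])), 0.05)
})

test_that("PCA artifact removal reconstructs periodic structure and is exact in keep-all mode", {
  fs <- 100
  cfg <- preprocessConfig(pcaEpochS = 1, pcaVarianceKeep = 0.8)

  # pure periodic signal with epoch length = period: rank-1 epoch matrix
  # reproduced exactly
  t12 <- (0:(fs * 12 - 1)) / fs
  perfect <- sin(2 * pi * 1 * t12)
  out <- removeMotionArtifactsPCA(PPGSignal(perfect, fs), cfg)
  expect_lt(max(abs(out@samples - perfect[seq_along(out@samples)])), 1e-8)

  # a cardiac-like tone incommensurate with the epoch spreads over two
  # quadrature components; a transient burst in one epoch loads on a
  # trailing component and is dropped by the 80% variance cut
  t <- (0:(fs * 30 - 1)) / fs
  clean <- sin(2 * pi * 1.3 * t)
  corrupted <- clean
  corrupted[1301:1400] <- corrupted[1301:1400] +
    2.5 * sin(2 * pi * 5 * (t[1301:1400] - t[1301]))
  rec <- removeMotionArtifactsPCA(PPGSignal(corrupted, fs), cfg)
  expect_gte(stats::cor(rec@samples, clean[seq_along(rec@samples)]), 0.95)
  # and it genuinely improves on the corrupted input
  expect_gt(stats::cor(rec@samples, clean[seq_along(rec@samples)]),
            stats::cor(corrupted, clean))

  # keep-all mode is an identity on the epoch-truncated signal
  set.seed(1)
  noisy <- rnorm(fs * 7 + 13)
  all <- removeMotionArtifactsPCA(PPGSignal(noisy, fs),
                                  preprocessConfig(pcaVarianceKeep = 1))
  expect_equal(length(all@samples), fs * 7)
  expect_lt(max(abs(all@samples - noisy[seq_len(fs * 7)])), 1e-9)

  expect_error(removeMotionArtifactsPCA(PPGSignal(rnorm(120), fs), cfg),
               "two")
})

test_that("PCA reconstruction agrees with an explicit eigendecomposition oracle", {
  fs <- 50; nEp <- 8
  set.seed(3)
  x <- as.numeric(replicate(nEp, sin(2 * pi * (1:fs) / fs) + rnorm(fs, 0, .2)))
  cfg <- preprocessConfig(pcaEpochS = 1, pcaVarianceKeep = 0.9)
  out <- removeMotionArtifactsPCA(PPGSignal(x, fs), cfg)

  M <- matrix(x, nrow = nEp, byrow = TRUE)
  ctr <- colMeans(M)
  Mc <- sweep(M, 2, ctr)
  ev <- eigen(crossprod(Mc) / (nEp - 1), symmetric = TRUE)
  cum <- cumsum(ev$values) / sum(ev$values)
  k <- which(cum >= 0.9)[1]
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  rec <- sweep(Mc %*% V %*% t(V), 2, ctr, "+")
  expect_lt(max(abs(out@samples - as.numeric(t(rec)))), 1e-8)
})

test_that("normalization centers, peak-scales and is idempotent", {
  x <- PPGSignal(5 * sin(2 * pi * (0:499) / 100) + 2, 100)
  n1 <- normalizeAmplitude(x)
  expect_lt(abs(max(abs(n1@samples)) - 1), 1e-12)
  expect_lt(abs(mean(n1@samples)), 1e-12)
  n2 <- normalizeAmplitude(n1)
  expect_equal(n1@samples, n2@samples, tolerance = 1e-12)
  expect_equal(normalizeAmplitude(PPGSignal(rep(4, 50), 10))@samples,
               rep(0, 50))
})

test_that("cubic resampling preserves duration, identity and band-limited waveforms", {
  x <- PPGSignal(rnorm(125 * 480), 125)   # 8 minutes @ 125 Hz
  y <- resampleSignal(x, 250)
  expect_equal(length(y@samples), 120000)
  expect_equal(y@fs, 250)

  z <- sineSignal(3, 4, 250)
  expect_lt(max(abs(resampleSignal(z, 250)@samples - z@samples)), 1e-9)

  t125 <- (0:(125 * 4 - 1)) / 125
  s <- PPGSignal(sin(2 * pi * 2 * t125), 125)
  up <- resampleSignal(s, 250)
  t250 <- (seq_along(up@samples) - 1) / 250
  interior <- t250 < 3.9
  expect_lt(max(abs(up@samples[interior] -
                      sin(2 * pi * 2 * t250[interior]))), 1e-3)
})

test_that("segmentation obeys the count law and shares samples exactly", {
  sig <- PPGSignal(seq_len(1500), 50)  # 30 s @ 50 Hz
  cfg <- preprocessConfig(windowS = 5, overlap = 0.5)
  segs <- segmentSignal(sig, cfg)
  expect_length(segs, 11)
  expect_true(all(vapply(segs, function(s) length(s@samples), numeric(1)) == 250))
  expect_equal(segs[[1]]@samples[126:250], segs[[2]]@samples[1:125])

  one <- segmentSignal(PPGSignal(seq_len(250), 50), cfg)
  expect_length(one, 1)
  expect_equal(one[[1]]@samples, as.numeric(1:250))

  two <- segmentSignal(PPGSignal(seq_len(500), 50),
                       preprocessConfig(windowS = 5, overlap = 0))
  expect_length(two, 2)
  expect_equal(c(two[[1]]@samples, two[[2]]@samples), as.numeric(1:500))

  expect_length(segmentSignal(PPGSignal(seq_len(100), 50), cfg), 0)
})

test_that("segment count law holds against a sliding-window enumeration oracle", {
  set.seed(11)
  for (rep in 1:200) {
    W <- sample(10:100, 1)
    L <- W + sample(0:400, 1)
    overlap <- runif(1, 0, 0.9)
    fs <- 10
    cfg <- preprocessConfig(windowS = W / fs, overlap = overlap)
    S <- max(1L, round(W * (1 - overlap)))
    segs <- segmentSignal(PPGSignal(seq_len(L), fs), cfg)
    # explicit enumeration oracle
    starts <- c(); s0 <- 0
    while (s0 + W <= L) { starts <- c(starts, s0); s0 <- s0 + S }
    expect_length(segs, length(starts))
    expect_length(segs, floor((L - W) / S) + 1)
  }
})

test_that("spectral SNR matches periodogram expectations", {
  cfg <- preprocessConfig()
  inBand <- estimateSNR(sineSegment(1.2, 10, 250), cfg)
  expect_gte(snrDb(inBand), 20)

  outBand <- estimateSNR(sineSegment(20, 10, 250), cfg)
  expect_lte(snrDb(outBand), -10)

  # white noise: SNR ~ 10 log10(band width / complement width)
  expected <- 10 * log10((3.5 - 0.7) / (125 - (3.5 - 0.7)))
  set.seed(5)
  snrs <- replicate(10, {
    snrDb(estimateSNR(PPGSegment(rnorm(2500), 250), cfg))
  })
  expect_lt(abs(mean(snrs) - expected), 3)

  # an exact in-band DFT bin leaves only numerical dust outside the band
  k <- round(1.2 * 2500 / 250)
  x <- cos(2 * pi * k * (0:2499) / 2500)
  expect_gt(snrDb(estimateSNR(PPGSegment(x, 250), cfg)), 100)
})

test_that("quality screening keeps exactly the segments above threshold, in order", {
  mk <- function(snr) new("PPGSegment", samples = rnorm(10), fs = 10,
                          startTime = 0, subjectId = "a", snrDb = snr)
  segs <- list(mk(2), mk(5), mk(9))
  kept <- qualityScreen(segs, preprocessConfig(snrMinDb = 5))
  expect_length(kept, 2)
  expect_equal(vapply(kept, snrDb, numeric(1)), c(5, 9))
  expect_length(qualityScreen(segs, preprocessConfig(snrMinDb = -Inf)), 3)
  expect_length(qualityScreen(segs, preprocessConfig(snrMinDb = Inf)), 0)
})

test_that("the preprocessing chain equals its stage-by-stage composition and is deterministic", {
  id <- makeIdentity(5, 13)
  rec <- synthSignal(id, 15, 250, noiseConfig(), seed = 8)
  cfg <- preprocessConfig()
  a <- preprocessRecord(rec, cfg)
  b <- preprocessRecord(rec, cfg)
  expect_identical(lapply(a, samples), lapply(b, samples))

  manual <- bandpassFilter(rec, cfg)
  manual <- removeBaseline(manual, cfg)
  manual <- removeMotionArtifactsPCA(manual, cfg)
  manual <- normalizeAmplitude(manual)
  manual <- resampleSignal(manual, cfg$targetFs)
  msegs <- segmentSignal(manual, cfg)
  msegs <- lapply(msegs, estimateSNR, cfg = cfg)
  msegs <- qualityScreen(msegs, cfg)
  expect_equal(lapply(a, samples), lapply(msegs, samples))

  # survivors respect the normalization bound
  expect_true(all(vapply(a, function(s) max(abs(samples(s))), numeric(1)) <=
                    1 + 1e-9))

  short <- synthSignal(id, 2, 250, noiseOff(), seed = 0)
  expect_length(preprocessRecord(short, cfg), 0)

  # stage errors carry the stage name
  expect_error(preprocessRecord(PPGSignal(rnorm(100), 10), cfg),
               "bandpass_filter")
})
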