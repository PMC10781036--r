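# Shared fixtures. Everything is generated in code; heavier objects are
# built once per test run and memoised here.

# A deterministic identity with no heart-rate variability, convenient for
# closed-form beat counting.
fixedIdentity <- function(hr = 60, sysAmp = 1, sysWidth = 0.08,
                          dicAmp = 0.3, dicDelay = 0.3) {
  new("SynthIdentity", identityId = 1L, heartRateBpm = c(hr, 0),
      systolicAmplitude = sysAmp, systolicWidthS = sysWidth,
      dicroticAmplitude = dicAmp, dicroticDelayS = dicDelay, seed = 0L)
}

sineSegment <- function(freqHz, durationS = 5, fs = 250, amplitude = 1) {
  t <- (seq_len(round(durationS * fs)) - 1) / fs
  PPGSegment(amplitude * sin(2 * pi * freqHz * t), fs)
}

sineSignal <- function(freqHz, durationS = 10, fs = 250, amplitude = 1) {
  t <- (seq_len(round(durationS * fs)) - 1) / fs
  PPGSignal(amplitude * sin(2 * pi * freqHz * t), fs)
}

# Tiny model configuration: fast to build and run, exercises every stage.
tinyModelConfig <- function(...) {
  modelConfig("desk", imageSide = 16L, patchSize = 4L, hiddenDim = 8L,
              mixerDepth = 3L, mixerKernel = 3L, cvtChannelPlan = c(4L, 8L),
              nPool = 2L, nTokens = 4L, tokenDim = 8L, nHeads = 2L,
              mlpHidden = 16L, nClasses = 3L, dropout = 0, seed = 1L, ...)
}

# Memoised desk-scale cohort shared by the end-to-end acceptance checks:
# 8 identities x 12 records x 15 s @ 250 Hz -> 60 five-second segments per
# identity after 50%-overlap segmentation.
.fixtures <- new.env(parent = emptyenv())

deskCohortSE <- function() {
  if (!is.null(.fixtures$se)) return(.fixtures$se)
  cfg <- defaultRunConfig("desk", seed = 2024L)
  cohort <- synthCohort(cfg$simulate$nIdentities,
                        cfg$simulate$recordsPerIdentity,
                        cfg$simulate$durationS, cfg$simulate$fs,
                        do.call(noiseConfig, cfg$simulate$noise),
                        seed = cfg$seed)
  ppCfg <- structure(cfg$preprocess, class = "PreprocessConfig")
  segs <- list(); recIds <- character()
  for (i in seq_along(cohort)) {
    s <- preprocessRecord(cohort[[i]], ppCfg)
    segs <- c(segs, s)
    recIds <- c(recIds, rep(sprintf("rec%03d", i), length(s)))
  }
  scCfg <- structure(cfg$scalogram, class = "ScalogramConfig")
  .fixtures$se <- scalogramExperiment(segs, recIds, cfg = scCfg)
  .fixtures$se
}
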