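#' Per-identity pulse morphology parameters
#'
#' A synthetic "person": the parameters of the two-Gaussian-per-cycle pulse
#' model (systolic peak plus delayed dicrotic wave) together with mean heart
#' rate and beat-to-beat variability. Distinct identities differ in these
#' morphology parameters, which is the identity-specific structure the
#' classifier is asked to recover.
#'
#' @slot identityId integer identity label.
#' @slot heartRateBpm length-2 numeric: mean and standard deviation, beats/min.
#' @slot systolicAmplitude systolic peak amplitude (unitless).
#' @slot systolicWidthS systolic Gaussian width (sd), seconds.
#' @slot dicroticAmplitude dicrotic amplitude as a fraction of systolic.
#' @slot dicroticDelayS dicrotic delay after the systolic peak, seconds.
#' @slot seed integer seed the identity was drawn with.
#' @exportClass SynthIdentity
setClass("SynthIdentity",
  representation(identityId = "integer", heartRateBpm = "numeric",
                 systolicAmplitude = "numeric", systolicWidthS = "numeric",
                 dicroticAmplitude = "numeric", dicroticDelayS = "numeric",
                 seed = "integer"))

setValidity("SynthIdentity", function(object) {
  hr <- object@heartRateBpm
  if (length(hr) != 2L || hr[1] < 40 || hr[1] > 180)
    return("mean heart rate must lie in [40, 180] bpm")
  if (object@dicroticDelayS >= 60 / hr[1])
    return("dicrotic delay must be shorter than the mean cardiac period")
  if (object@systolicAmplitude <= 0 || object@systolicWidthS <= 0 ||
      object@dicroticAmplitude <= 0)
    return("amplitudes and widths must be positive")
  TRUE
})

#' @export
setMethod("show", "SynthIdentity", function(object) {
  cat(sprintf(
    "SynthIdentity #%d: HR %.1f+/-%.1f bpm, sys A=%.2f w=%.0f ms, dicrotic %.0f%% @ +%.0f ms\n",
    object@identityId, object@heartRateBpm[1], object@heartRateBpm[2],
    object@systolicAmplitude, 1000 * object@systolicWidthS,
    100 * object@dicroticAmplitude, 1000 * object@dicroticDelayS))
})

#' Additive noise configuration for the PPG simulator
#'
#' All noise terms are additive on top of the clean pulse train: white
#' measurement noise, slow sinusoidal baseline wander (respiration/pressure),
#' a high-frequency ambient interference tone (e.g. mains light flicker), and
#' sparse high-amplitude low-frequency motion-artifact bursts.
#'
#' @param whiteNoiseSd standard deviation of white noise (unitless).
#' @param baselineWanderAmplitude amplitude of the wander sinusoid.
#' @param baselineWanderFreqHz wander frequency, Hz (well below 0.5 Hz).
#' @param hfToneAmplitude amplitude of the ambient interference tone.
#' @param hfToneFreqHz interference tone frequency, Hz.
#' @param artifactBurstRate expected motion-artifact bursts per minute.
#' @param artifactBurstAmplitude burst amplitude (unitless).
#' @param seed integer seed for the noise streams.
#' @return a list with class `NoiseConfig`.
#' @export
noiseConfig <- function(whiteNoiseSd = 0.05,
                        baselineWanderAmplitude = 0.5,
                        baselineWanderFreqHz = 0.2,
                        hfToneAmplitude = 0.05,
                        hfToneFreqHz = 50,
                        artifactBurstRate = 2,
                        artifactBurstAmplitude = 2,
                        seed = 0L) {
  amps <- c(whiteNoiseSd, baselineWanderAmplitude, hfToneAmplitude,
            artifactBurstAmplitude)
  if (any(amps < 0)) stop("noise amplitudes must be >= 0")
  if (artifactBurstRate < 0) stop("artifact burst rate must be >= 0")
  structure(list(whiteNoiseSd = whiteNoiseSd,
                 baselineWanderAmplitude = baselineWanderAmplitude,
                 baselineWanderFreqHz = baselineWanderFreqHz,
                 hfToneAmplitude = hfToneAmplitude,
                 hfToneFreqHz = hfToneFreqHz,
                 artifactBurstRate = artifactBurstRate,
                 artifactBurstAmplitude = artifactBurstAmplitude,
                 seed = as.integer(seed)),
            class = "NoiseConfig")
}

#' Silent noise configuration (clean pulse train)
#' @param seed integer seed (kept for interface symmetry).
#' @return a `NoiseConfig` with all amplitudes and rates zero.
#' @export
noiseOff <- function(seed = 0L)
  noiseConfig(0, 0, 0.2, 0, 50, 0, 0, seed = seed)

#' Draw a synthetic identity
#'
#' Morphology parameters are drawn uniformly from documented physiological
#' ranges, deterministically in `(identityId, seed)`. The optional `spread`
#' knob in \[0, 1\] shrinks every range linearly toward its midpoint, which
#' lowers inter-identity variability (used to probe class separability).
#'
#' Ranges at `spread = 1`: heart-rate mean 55-95 bpm, heart-rate sd 1-3 bpm,
#' systolic amplitude 0.8-1.2, systolic width 60-110 ms, dicrotic amplitude
#' 20-45% of systolic, dicrotic delay 250-400 ms.
#'
#' @param identityId integer identity label.
#' @param seed integer seed (>= 0).
#' @param spread range-shrink factor in \[0, 1\]; 1 = full documented ranges.
#' @return a [SynthIdentity-class].
#' @export
makeIdentity <- function(identityId, seed, spread = 1) {
  stopifnot(seed >= 0, spread >= 0, spread <= 1)
  rng <- function(lo, hi) {
    mid <- (lo + hi) / 2; half <- (hi - lo) / 2 * spread
    stats::runif(1, mid - half, mid + half)
  }
  withSeed(childSeed(seed, "identity", identityId), {
    hrMean <- rng(55, 95)
    hrSd <- rng(1, 3)
    new("SynthIdentity",
        identityId = as.integer(identityId),
        heartRateBpm = c(hrMean, hrSd),
        systolicAmplitude = rng(0.8, 1.2),
        systolicWidthS = rng(0.06, 0.11),
        dicroticAmplitude = rng(0.20, 0.45),
        dicroticDelayS = rng(0.25, 0.40),
        seed = as.integer(seed))
  })
}

# Clean two-Gaussian pulse train on the time grid t for the given beat onsets.
.pulseTrain <- function(t, beatTimes, id) {
  x <- numeric(length(t))
  wS <- id@systolicWidthS
  wD <- 1.6 * wS  # the dicrotic wave is broader than the systolic upstroke
  aS <- id@systolicAmplitude
  aD <- id@dicroticAmplitude * aS
  dt <- t[2] - t[1]
  for (b in beatTimes) {
    lo <- max(1L, floor((b - 5 * wS) / dt) + 1L)
    hi <- min(length(t), ceiling((b + id@dicroticDelayS + 5 * wD) / dt) + 1L)
    if (lo > hi) next
    tt <- t[lo:hi]
    x[lo:hi] <- x[lo:hi] + aS * exp(-((tt - b)^2) / (2 * wS^2)) +
      aD * exp(-((tt - b - id@dicroticDelayS)^2) / (2 * wD^2))
  }
  x
}

#' Synthesize a single PPG record
#'
#' The waveform is a sum over cardiac cycles of a systolic Gaussian plus a
#' delayed, broader dicrotic Gaussian; beat periods jitter around the mean
#' cardiac period according to the identity's heart-rate variability. Noise
#' terms from `noise` are then added. Fully deterministic in all seeds.
#'
#' @param identity a [SynthIdentity-class].
#' @param durationS record duration, seconds (> 0).
#' @param fs sampling rate, Hz (> 0).
#' @param noise a `NoiseConfig` (see [noiseConfig()]).
#' @param seed integer seed for the per-record beat jitter and noise.
#' @return a [PPGSignal-class] of `round(durationS * fs)` samples.
#' @export
synthSignal <- function(identity, durationS, fs, noise = noiseConfig(),
                        seed = 0L) {
  if (!is.numeric(durationS) || durationS <= 0)
    stop("'durationS' must be positive")
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be positive")
  n <- round(durationS * fs)
  t <- (seq_len(n) - 1) / fs
  hr <- identity@heartRateBpm
  meanPeriod <- 60 / hr[1]
  periodSd <- 60 * hr[2] / hr[1]^2  # delta-method sd of the period

  withSeed(childSeed(seed, "record", identity@identityId), {
    nBeats <- ceiling(durationS / meanPeriod) + 3L
    periods <- pmax(0.3, meanPeriod + stats::rnorm(nBeats, 0, periodSd))
    beats <- 0.5 * meanPeriod + cumsum(c(0, periods[-nBeats]))
    beats <- beats[beats < durationS + 3 * meanPeriod]
    x <- .pulseTrain(t, beats, identity)

    if (noise$whiteNoiseSd > 0)
      x <- x + stats::rnorm(n, 0, noise$whiteNoiseSd)
    if (noise$baselineWanderAmplitude > 0)
      x <- x + noise$baselineWanderAmplitude *
        sin(2 * pi * noise$baselineWanderFreqHz * t + stats::runif(1, 0, 2 * pi))
    if (noise$hfToneAmplitude > 0)
      x <- x + noise$hfToneAmplitude *
        sin(2 * pi * noise$hfToneFreqHz * t + stats::runif(1, 0, 2 * pi))
    if (noise$artifactBurstRate > 0 && noise$artifactBurstAmplitude > 0) {
      nBurst <- stats::rpois(1, noise$artifactBurstRate * durationS / 60)
      if (nBurst > 0) {
        for (k in seq_len(nBurst)) {
          t0 <- stats::runif(1, 0, durationS)
          dur <- stats::runif(1, 0.3, 1.0)
          fb <- stats::runif(1, 0.2, 0.8)
          idx <- which(t >= t0 & t <= t0 + dur)
          if (length(idx)) {
            win <- sin(pi * (t[idx] - t0) / dur)^2  # smooth on/off envelope
            x[idx] <- x[idx] + noise$artifactBurstAmplitude * win *
              sin(2 * pi * fb * (t[idx] - t0))
          }
        }
      }
    }
    PPGSignal(x, fs, subjectId = as.character(identity@identityId),
              sourceTag = "synthetic")
  })
}

#' Generate a labeled synthetic cohort
#'
#' `nIdentities` identities are drawn with [makeIdentity()] and each
#' contributes `recordsPerIdentity` records of `durationS` seconds, so the
#' label distribution is exactly balanced. Deterministic in `seed`.
#'
#' @param nIdentities number of identities (>= 2; classification needs two).
#' @param recordsPerIdentity records per identity.
#' @param durationS record duration, seconds.
#' @param fs sampling rate, Hz.
#' @param noise a `NoiseConfig`.
#' @param seed integer master seed.
#' @param spread identity-range shrink factor passed to [makeIdentity()].
#' @param sourceTag source tag stamped on every record.
#' @return list of [PPGSignal-class] records, identity-major order.
#' @export
synthCohort <- function(nIdentities, recordsPerIdentity, durationS = 15,
                        fs = 250, noise = noiseConfig(), seed = 0L,
                        spread = 1, sourceTag = "synthetic") {
  if (nIdentities < 2)
    stop("'nIdentities' must be >= 2: classification needs at least 2 classes")
  out <- vector("list", nIdentities * recordsPerIdentity)
  k <- 0L
  for (i in seq_len(nIdentities)) {
    id <- makeIdentity(i, seed, spread = spread)
    for (r in seq_len(recordsPerIdentity)) {
      k <- k + 1L
      rec <- synthSignal(id, durationS, fs, noise,
                         seed = childSeed(seed, "cohort", i, r))
      rec@sourceTag <- sourceTag
      out[[k]] <- rec
    }
  }
  out
}
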