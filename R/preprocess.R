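#' Preprocessing parameters
#'
#' Defaults follow the conventional cardiac-PPG choices: a 0.5-8 Hz 4th-order
#' Butterworth bandpass applied forward-backward (zero phase), a 1 s centered
#' moving-average baseline, PCA artifact removal over 1 s epochs keeping 90%
#' cumulative variance, resampling to a common 250 Hz, 5 s windows with 50%
#' overlap, and a 5 dB in-band SNR screen over the 0.7-3.5 Hz cardiac band.
#'
#' @param bandLowHz,bandHighHz bandpass corner frequencies, Hz.
#' @param filterOrder Butterworth order.
#' @param baselineWindowS moving-average baseline window, seconds.
#' @param pcaEpochS epoch length for PCA artifact removal, seconds.
#' @param pcaVarianceKeep cumulative explained-variance fraction to keep.
#' @param targetFs common resampling rate, Hz.
#' @param windowS segment window length, seconds.
#' @param overlap fractional overlap between consecutive segments in \[0, 1).
#' @param snrMinDb minimum in-band SNR for a segment to survive screening, dB.
#' @param cardiacBandHz length-2 numeric, the cardiac band for SNR, Hz.
#' @return a list with class `PreprocessConfig`.
#' @export
preprocessConfig <- function(bandLowHz = 0.5, bandHighHz = 8,
                             filterOrder = 4, baselineWindowS = 1.0,
                             pcaEpochS = 1.0, pcaVarianceKeep = 0.9,
                             targetFs = 250, windowS = 5, overlap = 0.5,
                             snrMinDb = 5, cardiacBandHz = c(0.7, 3.5)) {
  stopifnot(bandLowHz > 0, bandHighHz > bandLowHz,
            overlap >= 0, overlap < 1,
            pcaVarianceKeep > 0, pcaVarianceKeep <= 1,
            length(cardiacBandHz) == 2L, cardiacBandHz[1] < cardiacBandHz[2])
  if (bandHighHz >= targetFs / 2)
    stop("'bandHighHz' must be below the Nyquist frequency of 'targetFs'")
  structure(list(bandLowHz = bandLowHz, bandHighHz = bandHighHz,
                 filterOrder = filterOrder, baselineWindowS = baselineWindowS,
                 pcaEpochS = pcaEpochS, pcaVarianceKeep = pcaVarianceKeep,
                 targetFs = targetFs, windowS = windowS, overlap = overlap,
                 snrMinDb = snrMinDb, cardiacBandHz = cardiacBandHz),
            class = "PreprocessConfig")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies the forward-backward response of an order-`filterOrder`
#' Butterworth bandpass, realized exactly in the frequency domain: the
#' signal spectrum is multiplied by the squared Butterworth magnitude
#' `|H(f)|^2 = 1 / (1 + Omega(f)^(2 order))` with the standard band
#' transform `Omega(f) = (f^2 - f_l f_h) / ((f_h - f_l) f)`. The response is
#' real, so the filter is zero-phase (no group delay), and the spectral
#' product is linear in the input to machine precision — a time-domain IIR
#' recursion at these pole radii is not. Boundary handling is circular (the
#' record is treated as one period).
#'
#' @param x a [PPGSignal-class].
#' @param cfg a `PreprocessConfig`.
#' @return filtered [PPGSignal-class] of the same length and rate.
#' @export
bandpassFilter <- function(x, cfg = preprocessConfig()) {
  fs <- x@fs
  if (cfg$bandHighHz >= fs / 2)
    stop(sprintf("bandpass high corner %g Hz is at or above Nyquist %g Hz",
                 cfg$bandHighHz, fs / 2))
  n <- length(x@samples)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n          # two-sided frequency axis
  om <- ifelse(f == 0, Inf,
               (f^2 - cfg$bandLowHz * cfg$bandHighHz) /
                 ((cfg$bandHighHz - cfg$bandLowHz) * f))
  G <- 1 / (1 + om^(2 * cfg$filterOrder))   # |H|^2: forward + backward pass
  y <- Re(stats::fft(stats::fft(x@samples) * G, inverse = TRUE)) / n
  initialize(x, samples = y)
}

# Centered moving average with reflection padding; window forced odd.
.movingAverage <- function(x, w) {
  w <- max(3L, as.integer(w)); if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  h <- min(h, n - 1L)
  w <- 2L * h + 1L
  xp <- c(rev(x[seq_len(h) + 1L]), x, rev(x[n - seq_len(h)]))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(h + 1L):(h + n)]
}

#' Remove residual baseline drift
#'
#' Subtracts a centered moving-average baseline (reflection-padded at the
#' edges), leaving the pulsatile component centered on zero.
#'
#' @inheritParams bandpassFilter
#' @return baseline-free [PPGSignal-class].
#' @export
removeBaseline <- function(x, cfg = preprocessConfig()) {
  w <- round(cfg$baselineWindowS * x@fs)
  if (w < 2) stop("baseline window must span at least 2 samples")
  base <- .movingAverage(x@samples, w)
  initialize(x, samples = x@samples - base)
}

#' PCA-based motion-artifact removal
#'
#' The signal is cut into consecutive non-overlapping epochs of
#' `pcaEpochS` seconds, stacked as the rows of a matrix and column-centered.
#' Principal components are ordered by explained variance; the reconstruction
#' keeps the leading components whose cumulative explained variance first
#' reaches `pcaVarianceKeep`, on the premise that the quasi-periodic cardiac
#' waveform concentrates in the leading components while transient
#' high-amplitude artifacts load on the trailing ones. Epochs are re-stitched
#' in order with the column means restored; trailing samples that do not fill
#' an epoch are dropped.
#'
#' @inheritParams bandpassFilter
#' @return artifact-suppressed [PPGSignal-class] (length truncated to a whole
#'   number of epochs).
#' @export
removeMotionArtifactsPCA <- function(x, cfg = preprocessConfig()) {
  e <- round(cfg$pcaEpochS * x@fs)
  n <- length(x@samples)
  nEp <- floor(n / e)
  if (nEp < 2)
    stop("signal must span at least two PCA epochs")
  M <- matrix(x@samples[seq_len(nEp * e)], nrow = nEp, ncol = e, byrow = TRUE)
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) return(initialize(x, samples = x@samples[seq_len(nEp * e)]))
  cum <- cumsum(v) / sum(v)
  k <- if (cfg$pcaVarianceKeep >= 1) length(v) else
    which(cum >= cfg$pcaVarianceKeep)[1]
  rec <- pc$x[, seq_len(k), drop = FALSE] %*%
    t(pc$rotation[, seq_len(k), drop = FALSE])
  rec <- sweep(rec, 2, pc$center, "+")
  initialize(x, samples = as.numeric(t(rec)))
}

#' Center and peak-normalize a signal
#'
#' Output is `(x - mean(x))` scaled so that `max(abs(.)) == 1`; an
#' all-constant input maps to all zeros. Idempotent.
#'
#' @param x a [PPGSignal-class].
#' @return normalized [PPGSignal-class].
#' @export
normalizeAmplitude <- function(x) {
  y <- x@samples - mean(x@samples)
  p <- max(abs(y))
  if (p > 0) y <- y / p
  initialize(x, samples = y)
}

#' Resample to a common rate by cubic interpolation
#'
#' Values on the new uniform grid are obtained by cubic spline interpolation
#' of the input on its original time grid; output length is
#' `round(duration * targetFs)`.
#'
#' @param x a [PPGSignal-class].
#' @param targetFs target sampling rate, Hz.
#' @return resampled [PPGSignal-class] with `fs = targetFs`.
#' @export
resampleSignal <- function(x, targetFs) {
  if (!is.numeric(targetFs) || targetFs <= 0) stop("'targetFs' must be positive")
  n <- length(x@samples)
  dur <- n / x@fs
  m <- round(dur * targetFs)
  tOld <- (seq_len(n) - 1) / x@fs
  tNew <- (seq_len(m) - 1) / targetFs
  y <- stats::spline(tOld, x@samples, xout = tNew, method = "fmm")$y
  initialize(x, samples = y, fs = targetFs)
}

#' Cut a record into overlapping fixed-length windows
#'
#' With window length `W = round(windowS * fs)` samples and stride
#' `S = round(W * (1 - overlap))`, the segment count is
#' `floor((L - W) / S) + 1`; trailing samples that do not fill a window are
#' dropped. A record shorter than one window yields an empty list.
#'
#' @inheritParams bandpassFilter
#' @return list of [PPGSegment-class] windows in temporal order.
#' @export
segmentSignal <- function(x, cfg = preprocessConfig()) {
  W <- round(cfg$windowS * x@fs)
  S <- max(1L, round(W * (1 - cfg$overlap)))
  L <- length(x@samples)
  if (L < W) return(list())
  starts <- seq(0L, L - W, by = S)
  lapply(starts, function(s)
    PPGSegment(x@samples[(s + 1L):(s + W)], x@fs,
               startTime = s / x@fs, subjectId = x@subjectId))
}

#' In-band spectral SNR of a segment
#'
#' The periodogram power inside the cardiac band (`cardiacBandHz`) is compared
#' with the power outside it (DC excluded):
#' `SNR = 10 log10(P_in / P_out)` in dB. If the out-of-band power is exactly
#' zero the `+Inf` sentinel is returned.
#'
#' @param seg a [PPGSegment-class].
#' @param cfg a `PreprocessConfig`.
#' @return the segment with its `snrDb` slot set.
#' @export
estimateSNR <- function(seg, cfg = preprocessConfig()) {
  x <- seg@samples
  n <- length(x)
  if (n < 2 * seg@fs / cfg$cardiacBandHz[1])
    stop("segment too short to resolve the cardiac band")
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * seg@fs / n
  half <- 2:(floor(n / 2) + 1L)   # positive frequencies, DC excluded
  f <- f[half]; p <- p[half]
  inBand <- f >= cfg$cardiacBandHz[1] & f <= cfg$cardiacBandHz[2]
  pIn <- sum(p[inBand]); pOut <- sum(p[!inBand])
  snr <- if (pOut == 0) Inf else 10 * log10(pIn / pOut)
  initialize(seg, snrDb = snr)
}

#' Keep only segments that pass the SNR screen
#'
#' @param segments list of [PPGSegment-class] with `snrDb` set.
#' @param cfg a `PreprocessConfig`; segments with `snrDb >= snrMinDb` are
#'   kept, order preserved.
#' @return filtered list of segments.
#' @export
qualityScreen <- function(segments, cfg = preprocessConfig()) {
  keep <- vapply(segments, function(s) {
    v <- s@snrDb
    !is.na(v) && v >= cfg$snrMinDb
  }, logical(1))
  segments[keep]
}

#' Full preprocessing chain for one record
#'
#' Applies, in order: bandpass filter, baseline removal, PCA artifact
#' removal, amplitude normalization, resampling to `targetFs`, segmentation,
#' per-segment SNR estimation and quality screening. Stage failures are
#' re-raised with the stage name attached.
#'
#' @inheritParams bandpassFilter
#' @return list of surviving [PPGSegment-class] windows.
#' @export
preprocessRecord <- function(x, cfg = preprocessConfig()) {
  stage <- function(name, f, obj) {
    tryCatch(f(obj), error = function(e)
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE))
  }
  y <- stage("bandpass_filter", function(o) bandpassFilter(o, cfg), x)
  y <- stage("remove_baseline", function(o) removeBaseline(o, cfg), y)
  y <- stage("remove_motion_artifacts_pca",
             function(o) removeMotionArtifactsPCA(o, cfg), y)
  y <- stage("normalize", normalizeAmplitude, y)
  y <- stage("resample", function(o) resampleSignal(o, cfg$targetFs), y)
  segs <- stage("segment", function(o) segmentSignal(o, cfg), y)
  segs <- lapply(segs, function(s)
    stage("estimate_snr", function(o) estimateSNR(o, cfg), s))
  qualityScreen(segs, cfg)
}
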