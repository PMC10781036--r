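#' Mother-wavelet specification
#'
#' Only the analytic Morlet wavelet is supported:
#' `psi(t) = pi^(-1/4) * exp(i * omega0 * t) * exp(-t^2 / 2)`,
#' a complex exponential under a unit-width Gaussian envelope. `omega0 = 6`
#' is the conventional admissibility-respecting center frequency.
#'
#' @param family wavelet family; only `"morlet"`.
#' @param omega0 center-frequency parameter, radians (> 0).
#' @return a list with class `WaveletSpec`.
#' @export
waveletSpec <- function(family = "morlet", omega0 = 6) {
  family <- match.arg(family, "morlet")
  assertScalar(omega0, "omega0", positive = TRUE)
  structure(list(family = family, omega0 = omega0), class = "WaveletSpec")
}

#' Evaluate the Morlet mother wavelet
#'
#' @param t time value(s), seconds (dimensionless once divided by the scale).
#' @param spec a [waveletSpec()].
#' @return complex vector `psi(t)`.
#' @export
morletWavelet <- function(t, spec = waveletSpec()) {
  pi^(-1 / 4) * exp(1i * spec$omega0 * t) * exp(-t^2 / 2)
}

#' Scale corresponding to a Fourier frequency
#'
#' For the Morlet wavelet the carrier of `psi(t/s)` oscillates at
#' `omega0 / (2 pi s)` Hz, so `s = omega0 / (2 pi f)`: small scales resolve
#' high frequencies and the map is strictly decreasing in `f`.
#'
#' @param fHz frequency value(s), Hz (> 0).
#' @param spec a [waveletSpec()].
#' @return wavelet scale(s), seconds.
#' @export
scaleForFrequency <- function(fHz, spec = waveletSpec()) {
  if (any(fHz <= 0)) stop("frequencies must be positive")
  spec$omega0 / (2 * pi * fHz)
}

#' Scalogram imaging parameters
#'
#' The default frequency grid is linear from 0.5 to 100 Hz over 128 bins
#' (the low edge avoids the scale divergence at 0 Hz) and images are rendered
#' at 128 x 128; `deskProfile()` uses a 64-bin, 0.5-20 Hz grid at 64 x 64,
#' which concentrates resolution on the cardiac fundamentals and harmonics
#' that actually carry identity information at desk scale.
#'
#' @param nFreqBins number of frequency bins.
#' @param freqMinHz,freqMaxHz frequency grid limits, Hz.
#' @param desiredLength time samples a segment is zero-padded to before the
#'   transform (uniform image geometry across segments).
#' @param imageSide output image side, pixels.
#' @param padPolicy only `"zero"` (zero extension) is implemented.
#' @return a list with class `ScalogramConfig`.
#' @export
scalogramConfig <- function(nFreqBins = 128, freqMinHz = 0.5, freqMaxHz = 100,
                            desiredLength = 1250, imageSide = 128,
                            padPolicy = "zero") {
  stopifnot(nFreqBins >= 2, freqMinHz > 0, freqMaxHz > freqMinHz,
            desiredLength > 0, imageSide >= 2)
  padPolicy <- match.arg(padPolicy, "zero")
  structure(list(nFreqBins = nFreqBins, freqMinHz = freqMinHz,
                 freqMaxHz = freqMaxHz, desiredLength = desiredLength,
                 imageSide = imageSide, padPolicy = padPolicy),
            class = "ScalogramConfig")
}

# Complex CWT coefficients W[scale, tau] for samples x at rate fs:
# W(s, tau_i) = (1/sqrt(s)) * sum_t x(t) * conj(psi((t - tau_i)/s)) * dt,
# with zero extension beyond the sampled support. FFT-accelerated
# correlation; the wavelet is truncated at |t/s| <= 6 where its Gaussian
# envelope is below 2e-8 of the peak.
.cwtCoefs <- function(x, fs, scales, spec) {
  n <- length(x)
  dt <- 1 / fs
  Ks <- pmax(1L, ceiling(6 * scales * fs))
  nfft <- stats::nextn(n + 2L * max(Ks) + 1L, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  out <- matrix(0i, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    s <- scales[si]; K <- Ks[si]
    j <- (-K):K
    k <- Conj(morletWavelet(j * dt / s, spec)) * dt / sqrt(s)
    # W_i = sum_j x_{i+j} k_j  ==  (x (*) g)_i with g_m = k_{-m}
    g <- complex(length.out = nfft)
    g[1] <- k[K + 1L]                       # m = 0
    g[1L + seq_len(K)] <- k[K + 1L - seq_len(K)]      # m > 0 -> k_{-m}
    g[nfft + 1L - seq_len(K)] <- k[K + 1L + seq_len(K)]  # m < 0 -> k_{+|m|}
    y <- stats::fft(X * stats::fft(g), inverse = TRUE) / nfft
    out[si, ] <- y[seq_len(n)]
  }
  out
}

#' Morlet CWT scalogram of a segment
#'
#' Computes the continuous wavelet transform of the segment on the configured
#' frequency grid and returns the coefficient magnitudes as a
#' [Scalogram-class]. The discretization is the Riemann sum of the CWT
#' integral on the sample grid with zero boundary extension, verifiable
#' against [cwtBruteforce()].
#'
#' @param seg a [PPGSegment-class] (or [PPGSignal-class]).
#' @param cfg a [scalogramConfig()].
#' @param spec a [waveletSpec()].
#' @return a [Scalogram-class]; rows follow the ascending frequency grid.
#' @export
cwtScalogram <- function(seg, cfg = scalogramConfig(), spec = waveletSpec()) {
  x <- seg@samples
  fs <- seg@fs
  if (length(x) < 1L) stop("empty segment")
  if (cfg$freqMaxHz > fs / 2)
    stop(sprintf("freqMaxHz %g exceeds the Nyquist frequency %g",
                 cfg$freqMaxHz, fs / 2))
  freqs <- seq(cfg$freqMinHz, cfg$freqMaxHz, length.out = cfg$nFreqBins)
  scales <- scaleForFrequency(freqs, spec)
  W <- .cwtCoefs(x, fs, scales, spec)
  new("Scalogram", magnitudes = Mod(W), freqsHz = freqs, scales = scales,
      timesS = (seq_along(x) - 1) / fs,
      segmentRef = if (is(seg, "PPGSegment"))
        sprintf("%s@%.2fs", seg@subjectId, seg@startTime) else NA_character_)
}

#' Brute-force CWT reference (test oracle)
#'
#' Evaluates the CWT Riemann sum by explicit construction of the integrand on
#' the full (scale, shift) grid — for every scale the wavelet is evaluated at
#' all `(t - tau)/s` pairs and summed directly. Quadratic in the segment
#' length; intended for small inputs (<= 512 samples) as an independent
#' reference for [cwtScalogram()].
#'
#' @param seg a [PPGSegment-class] or [PPGSignal-class].
#' @param scales numeric vector of wavelet scales.
#' @param spec a [waveletSpec()].
#' @return a [Scalogram-class] over the given scales.
#' @export
cwtBruteforce <- function(seg, scales, spec = waveletSpec()) {
  x <- seg@samples
  fs <- seg@fs
  n <- length(x)
  if (n > 4096) stop("brute-force oracle is meant for small inputs")
  dt <- 1 / fs
  t <- (seq_len(n) - 1) * dt
  W <- matrix(0i, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    # Psi[i, u] = conj(psi((t_u - tau_i)/s))
    Psi <- Conj(morletWavelet(outer(-t, t, "+") / s, spec))
    W[si, ] <- (Psi %*% x) * dt / sqrt(s)
  }
  new("Scalogram", magnitudes = Mod(W),
      freqsHz = scaleForFrequency(scales, spec),
      scales = scales, timesS = t, segmentRef = "bruteforce")
}

#' Complex CWT coefficients (internal grids exposed for verification)
#'
#' Lower-level variant of [cwtScalogram()] returning the complex coefficient
#' matrix for arbitrary scales, used in tests.
#'
#' @param seg a [PPGSegment-class] or [PPGSignal-class].
#' @param scales numeric vector of wavelet scales.
#' @param spec a [waveletSpec()].
#' @return complex matrix, scales x time.
#' @export
cwtCoefficients <- function(seg, scales, spec = waveletSpec()) {
  .cwtCoefs(seg@samples, seg@fs, scales, spec)
}

#' Render a scalogram as a normalized square image
#'
#' The magnitude matrix is resized to `imageSide x imageSide` by bilinear
#' interpolation and min-max scaled to \[0, 1\] per image; a constant-magnitude
#' scalogram maps to the all-zero image.
#'
#' @param scal a [Scalogram-class].
#' @param cfg a [scalogramConfig()].
#' @return numeric matrix in \[0, 1\] of size `imageSide x imageSide`.
#' @export
scalogramImage <- function(scal, cfg = scalogramConfig()) {
  m <- scal@magnitudes
  img <- EBImage::resize(m, w = cfg$imageSide, h = cfg$imageSide,
                         filter = "bilinear")
  img <- matrix(as.numeric(img), cfg$imageSide, cfg$imageSide)
  lo <- min(img); hi <- max(img)
  if (hi > lo) (img - lo) / (hi - lo) else img * 0
}

#' Scalogram images for a list of segments
#'
#' Each segment is zero-padded to `desiredLength` samples when shorter,
#' transformed with [cwtScalogram()] and rendered with [scalogramImage()];
#' the stacked matrix holds the flattened image of segment `i` in row `i`.
#'
#' @param segments list of [PPGSegment-class].
#' @param cfg a [scalogramConfig()].
#' @param spec a [waveletSpec()].
#' @return list with `images` (list of matrices) and `matrix`
#'   (`length(segments) x imageSide^2` stacked matrix).
#' @export
buildImageMatrix <- function(segments, cfg = scalogramConfig(),
                             spec = waveletSpec()) {
  n <- length(segments)
  imgs <- vector("list", n)
  M <- matrix(0, nrow = n, ncol = cfg$imageSide^2)
  for (i in seq_len(n)) {
    seg <- segments[[i]]
    if (length(seg@samples) < cfg$desiredLength)
      seg <- initialize(seg, samples = c(
        seg@samples, rep(0, cfg$desiredLength - length(seg@samples))))
    img <- scalogramImage(cwtScalogram(seg, cfg, spec), cfg)
    imgs[[i]] <- img
    M[i, ] <- as.numeric(img)
  }
  list(images = imgs, matrix = M)
}

#' Assemble segments into a SummarizedExperiment of scalogram images
#'
#' The assay `"scalogram"` holds one flattened image per column
#' (`imageSide^2 x segments`); `colData` records the subject label, source
#' record index, window start time and SNR, which the evaluation protocols
#' use for stratified, record-grouped splitting.
#'
#' @param segments list of [PPGSegment-class].
#' @param recordIds integer/character vector assigning each segment to its
#'   source record (grouping unit for cross-validation); defaults to one
#'   group per segment.
#' @param source source tag for all segments (recycled).
#' @param cfg a [scalogramConfig()].
#' @param spec a [waveletSpec()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with image-side
#'   metadata.
#' @export
scalogramExperiment <- function(segments, recordIds = seq_along(segments),
                                source = "synthetic",
                                cfg = scalogramConfig(),
                                spec = waveletSpec()) {
  built <- buildImageMatrix(segments, cfg, spec)
  cd <- S4Vectors::DataFrame(
    subject = vapply(segments, function(s) s@subjectId, character(1)),
    record = as.character(recordIds),
    startTime = vapply(segments, function(s) s@startTime, numeric(1)),
    snrDb = vapply(segments, function(s) s@snrDb, numeric(1)),
    source = rep_len(source, length(segments)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scalogram = t(built$matrix)), colData = cd)
  S4Vectors::metadata(se)$imageSide <- cfg$imageSide
  se
}
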