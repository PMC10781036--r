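#' Single-channel PPG time series
#'
#' Container for one raw or processed photoplethysmogram: a numeric sample
#' vector together with its sampling rate, subject label and source tag.
#'
#' @slot samples numeric vector of amplitude samples (arbitrary units).
#' @slot fs sampling rate in Hz.
#' @slot subjectId subject/identity label.
#' @slot sourceTag free-text provenance tag (e.g. a dataset name).
#' @exportClass PPGSignal
setClass("PPGSignal",
  representation(samples = "numeric", fs = "numeric",
                 subjectId = "character", sourceTag = "character"),
  prototype(subjectId = NA_character_, sourceTag = "synthetic"))

setValidity("PPGSignal", function(object) {
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("'fs' must be a single positive number")
  if (length(object@samples) < 1L) return("'samples' must be non-empty")
  if (!all(is.finite(object@samples))) return("all samples must be finite")
  TRUE
})

#' Quality-screened fixed-duration signal window
#'
#' @slot samples numeric vector of amplitude samples.
#' @slot fs sampling rate in Hz.
#' @slot startTime window start within the parent record, seconds.
#' @slot subjectId subject/identity label.
#' @slot snrDb estimated in-band signal-to-noise ratio in dB (NA until set).
#' @exportClass PPGSegment
setClass("PPGSegment",
  representation(samples = "numeric", fs = "numeric", startTime = "numeric",
                 subjectId = "character", snrDb = "numeric"),
  prototype(startTime = 0, subjectId = NA_character_, snrDb = NA_real_))

setValidity("PPGSegment", function(object) {
  if (object@fs <= 0) return("'fs' must be positive")
  if (length(object@samples) < 1L) return("empty segment")
  TRUE
})

#' Continuous-wavelet-transform magnitude image
#'
#' Rows index the frequency (equivalently wavelet scale) grid, columns the
#' time grid; entries are nonnegative coefficient magnitudes |W(s, tau)|.
#'
#' @slot magnitudes nonnegative matrix, frequencies x times.
#' @slot freqsHz frequency grid (strictly monotone), Hz.
#' @slot scales corresponding wavelet scales.
#' @slot timesS time grid, seconds.
#' @slot segmentRef provenance label of the source segment.
#' @exportClass Scalogram
setClass("Scalogram",
  representation(magnitudes = "matrix", freqsHz = "numeric",
                 scales = "numeric", timesS = "numeric",
                 segmentRef = "character"),
  prototype(segmentRef = NA_character_))

setValidity("Scalogram", function(object) {
  d <- dim(object@magnitudes)
  if (d[1] != length(object@freqsHz) || d[1] != length(object@scales))
    return("rows of 'magnitudes' must match freqsHz/scales length")
  if (d[2] != length(object@timesS))
    return("columns of 'magnitudes' must match timesS length")
  if (any(object@magnitudes < 0)) return("magnitudes must be >= 0")
  df <- diff(object@freqsHz)
  if (length(df) && !(all(df > 0) || all(df < 0)))
    return("'freqsHz' must be strictly monotone")
  TRUE
})

#' Role-tagged model activation
#'
#' Wraps an intermediate activation of the hybrid model together with a role
#' tag naming its place in the architecture (patch embedding `Z0`, mixer block
#' outputs `Zl`/`Zl+1`, branch outputs `CVT_map`/`ConvMixer_map`, the fused
#' `Dense_Features_map`, the residual-unit `Output`, channel-attention gates
#' `W` and the gated `Features`).
#'
#' @slot values numeric array (feature map, token matrix or flat vector).
#' @slot role role tag, one of the architecture stage names.
#' @exportClass FeatureMap
setClass("FeatureMap",
  representation(values = "array", role = "character"))

.featureRoles <- c("Z0", "Zl", "Zl+1", "CVT_map", "ConvMixer_map",
                   "Dense_Features_map", "Output", "W", "Features")

setValidity("FeatureMap", function(object) {
  if (!object@role %in% .featureRoles)
    return(sprintf("unknown role '%s'", object@role))
  if (!all(is.finite(object@values))) return("values must be finite")
  if (object@role == "W" &&
      (any(object@values <= 0) || any(object@values >= 1)))
    return("attention gates W must lie strictly in (0, 1)")
  TRUE
})

#' One-vs-rest evaluation report
#'
#' Per-class confusion counts plus the derived sensitivity, specificity,
#' precision, recall, F1 and accuracy, their macro (unweighted) averages, the
#' macro one-vs-rest ROC AUC, and the mean loss when available.
#'
#' @slot confusion data.frame with columns class, TP, FP, TN, FN.
#' @slot perClass data.frame of per-class metric values.
#' @slot macro named numeric vector of macro-averaged metrics.
#' @slot auc macro one-vs-rest ROC AUC.
#' @slot loss mean classification loss (NA when not evaluated).
#' @exportClass EvalReport
setClass("EvalReport",
  representation(confusion = "data.frame", perClass = "data.frame",
                 macro = "numeric", auc = "numeric", loss = "numeric"),
  prototype(auc = NA_real_, loss = NA_real_))

setValidity("EvalReport", function(object) {
  m <- rowSums(object@confusion[, c("TP", "FP", "TN", "FN")])
  if (length(unique(m)) > 1L)
    return("TP+FP+TN+FN must equal the sample count for every class")
  ok <- unlist(object@perClass[, setdiff(names(object@perClass), "class")])
  if (any(ok < -1e-12 | ok > 1 + 1e-12, na.rm = TRUE))
    return("metric fractions must lie in [0, 1]")
  TRUE
})

#' @describeIn PPGSignal number of samples
#' @param x object
#' @export
setMethod("length", "PPGSignal", function(x) length(x@samples))

#' @export
setMethod("show", "PPGSignal", function(object) {
  cat(sprintf("PPGSignal: %d samples @ %g Hz (%.2f s), subject=%s, source=%s\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs,
              object@subjectId, object@sourceTag))
})

#' @export
setMethod("show", "PPGSegment", function(object) {
  cat(sprintf("PPGSegment: %d samples @ %g Hz, start=%.2f s, subject=%s, SNR=%s dB\n",
              length(object@samples), object@fs, object@startTime,
              object@subjectId,
              if (is.na(object@snrDb)) "unset" else sprintf("%.1f", object@snrDb)))
})

#' @export
setMethod("show", "Scalogram", function(object) {
  cat(sprintf("Scalogram: %d freq bins (%.2f-%.2f Hz) x %d time bins\n",
              nrow(object@magnitudes), min(object@freqsHz), max(object@freqsHz),
              ncol(object@magnitudes)))
})

#' @export
setMethod("show", "FeatureMap", function(object) {
  cat(sprintf("FeatureMap[%s]: dims %s\n", object@role,
              paste(dim(object@values), collapse = " x ")))
})

#' @export
setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n  macro:",
      paste(sprintf("%s=%.3f", names(object@macro), object@macro), collapse = " "),
      sprintf("\n  AUC=%.3f loss=%.3f\n", object@auc, object@loss))
})

# ---- accessors ----

#' Amplitude samples of a signal or segment
#' @param x a [PPGSignal-class] or [PPGSegment-class]
#' @return numeric vector
#' @export
samples <- function(x) x@samples

#' Sampling rate in Hz
#' @param x a [PPGSignal-class] or [PPGSegment-class]
#' @export
samplingRate <- function(x) x@fs

#' Subject label
#' @param x a [PPGSignal-class] or [PPGSegment-class]
#' @export
subjectId <- function(x) x@subjectId

#' Segment SNR estimate in dB
#' @param x a [PPGSegment-class]
#' @export
snrDb <- function(x) x@snrDb

#' Scalogram magnitude matrix
#' @param x a [Scalogram-class]
#' @export
magnitudes <- function(x) x@magnitudes

#' Feature-map values and role
#' @param x a [FeatureMap-class]
#' @export
featureValues <- function(x) x@values

#' @rdname featureValues
#' @export
featureRole <- function(x) x@role

#' Macro-averaged metrics of an evaluation report
#' @param x an [EvalReport-class]
#' @export
macroMetrics <- function(x) x@macro

#' @rdname macroMetrics
#' @export
perClassMetrics <- function(x) x@perClass

#' @rdname macroMetrics
#' @export
confusion <- function(x) x@confusion

#' @rdname macroMetrics
#' @export
macroAUC <- function(x) x@auc

#' Construct a PPGSignal
#' @param samples numeric amplitude vector
#' @param fs sampling rate, Hz
#' @param subjectId subject label
#' @param sourceTag provenance tag
#' @return a [PPGSignal-class]
#' @export
PPGSignal <- function(samples, fs, subjectId = NA_character_,
                      sourceTag = "synthetic") {
  new("PPGSignal", samples = as.numeric(samples), fs = fs,
      subjectId = as.character(subjectId), sourceTag = sourceTag)
}

#' Construct a PPGSegment
#' @param samples numeric amplitude vector
#' @param fs sampling rate, Hz
#' @param startTime window start within the parent record, seconds
#' @param subjectId subject label
#' @param snrDb SNR estimate in dB (NA when not yet estimated)
#' @return a [PPGSegment-class]
#' @export
PPGSegment <- function(samples, fs, startTime = 0, subjectId = NA_character_,
                       snrDb = NA_real_) {
  new("PPGSegment", samples = as.numeric(samples), fs = fs,
      startTime = startTime, subjectId = as.character(subjectId), snrDb = snrDb)
}
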