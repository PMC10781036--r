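#' Read a PPG signal from CSV
#'
#' Expects a header row naming a time column (`time_s`) and an amplitude
#' column, optionally preceded by a `# fs=<Hz>` metadata comment. The
#' sampling rate is taken from the metadata line when present, otherwise
#' inferred from the time column, which must be uniform within a relative
#' jitter of 1e-6.
#'
#' @param path CSV file path.
#' @param subjectId optional subject label to stamp on the record.
#' @param sourceTag source tag.
#' @return a [PPGSignal-class].
#' @export
readSignalCSV <- function(path, subjectId = NA_character_,
                          sourceTag = "csv") {
  lines <- readLines(path, n = 2L)
  if (!length(lines)) stop("format error: empty file '", path, "'")
  fs <- NA_real_
  skip <- 0L
  if (grepl("^#", lines[1])) {
    m <- regmatches(lines[1], regexec("fs\\s*=\\s*([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(m) == 2L) fs <- as.numeric(m[2])
    skip <- 1L
  }
  df <- utils::read.csv(path, skip = skip)
  if (!nrow(df)) stop("format error: no samples in '", path, "'")
  ampCol <- intersect(c("amplitude", "value", "ppg"), names(df))
  if (!length(ampCol)) stop("format error: no amplitude column in '", path, "'")
  amp <- df[[ampCol[1]]]
  bad <- which(!is.finite(amp))
  if (length(bad))
    stop("format error: non-finite amplitude at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  timeCol <- intersect(c("time_s", "time", "t"), names(df))
  if (length(timeCol)) {
    tt <- df[[timeCol[1]]]
    if (length(tt) > 1) {
      dt <- diff(tt)
      if (any(abs(dt - dt[1]) > 1e-6 * max(abs(dt[1]), 1e-12)))
        stop("format error: non-uniform time grid in '", path, "'")
      if (is.na(fs)) fs <- 1 / dt[1]
    }
  }
  if (is.na(fs))
    stop("format error: sampling rate not given and not inferable in '",
         path, "'")
  PPGSignal(amp, fs, subjectId = subjectId, sourceTag = sourceTag)
}

#' Write a PPG signal as CSV
#'
#' Emits a `# fs=<Hz>` metadata line followed by `time_s,amplitude` rows,
#' the format [readSignalCSV()] reads back losslessly.
#'
#' @param x a [PPGSignal-class].
#' @param path output file path.
#' @export
writeSignalCSV <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", x@fs), con)
  writeLines("time_s,amplitude", con)
  tt <- (seq_along(x@samples) - 1) / x@fs
  writeLines(sprintf("%.10g,%.10g", tt, x@samples), con)
  invisible(path)
}

# Parse a PhysioNet-style header (.hea) file.
.parseHeader <- function(heaPath) {
  if (!file.exists(heaPath))
    stop("format error: missing header file '", heaPath, "'")
  ln <- readLines(heaPath)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  rec <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  nSig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(rec[3]) else 250
  nSamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lapply(ln[1 + seq_len(nSig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gainField <- f[3]
    gain <- as.numeric(sub("^([0-9.eE+-]+).*", "\\1", gainField))
    baseline <- if (grepl("\\(", gainField))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gainField)) else 0
    list(file = f[1], format = f[2], gain = ifelse(is.na(gain), 200, gain),
         baseline = baseline, name = if (length(f) >= 9) f[length(f)] else f[1])
  })
  list(record = rec[1], nSig = nSig, fs = fs, nSamp = nSamp, signals = sig)
}

#' Read a channel from a PhysioNet-style waveform record
#'
#' Minimal reader for a record/header file pair (`<record>.hea` +
#' `<record>.dat`) in the 16-bit little-endian interleaved sample format
#' ("format 16"); the named channel is extracted and converted to physical
#' units via the header gain and baseline. Other storage formats are not
#' supported and raise an error.
#'
#' @param path record path without extension (or the `.hea` path).
#' @param channelName name of the channel to extract.
#' @return a [PPGSignal-class] carrying the header's sampling frequency.
#' @export
readWFDBRecord <- function(path, channelName) {
  path <- sub("\\.hea$", "", path)
  hdr <- .parseHeader(paste0(path, ".hea"))
  names <- vapply(hdr$signals, `[[`, character(1), "name")
  ch <- which(names == channelName)
  if (!length(ch))
    stop("channel '", channelName, "' not found; available channels: ",
         paste(names, collapse = ", "))
  fmt <- hdr$signals[[ch]]$format
  if (fmt != "16")
    stop("unsupported signal storage format '", fmt, "' (only format 16)")
  datPath <- file.path(dirname(paste0(path, ".hea")), hdr$signals[[ch]]$file)
  if (!file.exists(datPath))
    stop("format error: missing data file '", datPath, "'")
  raw <- readBin(datPath, "integer", n = file.size(datPath) / 2L,
                 size = 2L, signed = TRUE, endian = "little")
  mat <- matrix(raw, nrow = hdr$nSig)
  adc <- mat[ch, ]
  if (!is.na(hdr$nSamp)) adc <- adc[seq_len(min(hdr$nSamp, length(adc)))]
  phys <- (adc - hdr$signals[[ch]]$baseline) / hdr$signals[[ch]]$gain
  PPGSignal(phys, hdr$fs, sourceTag = basename(path))
}

#' Write a scalogram image as 8-bit grayscale PNG
#'
#' Display-oriented lossy export; the full-precision stacked image matrix
#' written by the pipeline (CSV) remains the authoritative representation.
#'
#' @param img matrix in \[0, 1\] (rows = frequency bins, plotted bottom-up).
#' @param path output path.
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(pmin(pmax(img[nrow(img):1, , drop = FALSE], 0), 1), path)
  invisible(path)
}
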