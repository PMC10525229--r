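# Audio and label file I/O, signal conditioning, and event slicing.
#
# WAV support is deliberately minimal: uncompressed PCM 16-bit RIFF/WAVE,
# the format the synthetic generator writes. Multi-channel files are averaged
# to mono on read.

#' Read a PCM WAV file
#'
#' Reads an uncompressed PCM 16-bit RIFF/WAVE file. Multi-channel audio is
#' averaged to mono; samples are scaled to \[-1, 1\].
#'
#' @param path path to a `.wav` file.
#' @return an [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("read_wav: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)
  rate <- NULL; channels <- NULL; bits <- NULL; fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      channels <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, size = 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("read_wav: data chunk before fmt chunk in ", path)
      if (fmt != 1L || bits != 16L) {
        stop("read_wav: only uncompressed PCM 16-bit supported, got format ",
             fmt, " / ", bits, " bits in ", path)
      }
      n <- sz %/% 2L
      samples <- readBin(con, "integer", n, size = 2, endian = "little")
      if (length(samples) < n) {
        stop("read_wav: truncated data chunk in ", path, " (expected ", n,
             " samples, got ", length(samples), ")")
      }
      break
    } else {
      if (sz < 0) stop("read_wav: corrupt chunk size in ", path)
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
  if (is.null(samples)) stop("read_wav: no data chunk found in ", path)
  if (channels > 1L) {
    usable <- (length(samples) %/% channels) * channels
    m <- matrix(samples[seq_len(usable)], nrow = channels)
    samples <- colMeans(m)
  }
  audio_signal(samples / 32767, rate)
}

#' Write a PCM 16-bit mono WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16 bits. Writing is
#' bit-deterministic: identical signals produce identical files.
#'
#' @param x an [audio_signal()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "audio_signal"))
  s <- pmin(1, pmax(-1, x$samples))
  q <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                   # PCM
  writeBin(1L, con, size = 2, endian = "little")                   # mono
  writeBin(as.integer(round(x$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(x$rate)) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                   # block align
  writeBin(16L, con, size = 2, endian = "little")                  # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Low-pass filter configuration
#'
#' @param order Butterworth order (>= 1); the filter is applied forwards and
#'   backwards (zero phase), doubling the effective attenuation.
#' @param cutoff_mode `"noise_adaptive"` picks the cutoff from the signal's
#'   spectral energy distribution; `"fixed_hz"` uses `fixed_cutoff`.
#' @param fixed_cutoff cutoff in Hz when `cutoff_mode = "fixed_hz"`.
#' @param noise_percentile percentile of cumulative spectral energy (0-100)
#'   defining the adaptive cutoff.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(order = 4, cutoff_mode = c("noise_adaptive", "fixed_hz"),
                          fixed_cutoff = NULL, noise_percentile = 95) {
  cutoff_mode <- match.arg(cutoff_mode)
  stopifnot_scalar_num(order, "order", lower = 1)
  stopifnot_scalar_num(noise_percentile, "noise_percentile", lower = 1, upper = 100)
  if (cutoff_mode == "fixed_hz") {
    if (is.null(fixed_cutoff)) stop("fixed_hz mode requires fixed_cutoff")
    stopifnot_scalar_num(fixed_cutoff, "fixed_cutoff", lower = 1e-9)
  }
  structure(list(order = as.integer(order), cutoff_mode = cutoff_mode,
                 fixed_cutoff = fixed_cutoff, noise_percentile = noise_percentile),
            class = "filter_config")
}

# Adaptive cutoff: frequency below which `percentile`% of the spectral energy
# lies, clamped to [500 Hz, 0.45 * rate].
.adaptive_cutoff <- function(x, rate, percentile) {
  n <- length(x)
  mag2 <- Mod(stats::fft(x - mean(x)))^2
  half <- mag2[seq_len(n %/% 2 + 1)]
  tot <- sum(half)
  if (tot <= 0) return(0.45 * rate)
  cum <- cumsum(half) / tot
  k <- which(cum >= percentile / 100)[1]
  f <- (k - 1) * rate / n
  min(max(f, 500), 0.45 * rate)
}

#' Zero-phase Butterworth low-pass conditioning
#'
#' Conditions a recording before time-frequency analysis. In adaptive mode
#' the cutoff is the frequency below which `noise_percentile` percent of the
#' signal's spectral energy lies, clamped to \[500 Hz, 0.45 * rate\], so
#' broadband hiss above the mastication band is suppressed while transient
#' content is preserved. Filtering is zero phase (forward-backward).
#'
#' @param x an [audio_signal()].
#' @param cfg a [filter_config()].
#' @return filtered [audio_signal()] of identical length and rate.
#' @export
adaptive_lowpass <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "audio_signal"), inherits(cfg, "filter_config"))
  cutoff <- if (cfg$cutoff_mode == "fixed_hz") cfg$fixed_cutoff
            else .adaptive_cutoff(x$samples, x$rate, cfg$noise_percentile)
  nyq <- x$rate / 2
  if (cutoff >= nyq) {
    stop(sprintf("adaptive_lowpass: cutoff %.1f Hz >= Nyquist %.1f Hz", cutoff, nyq))
  }
  bf <- signal::butter(cfg$order, cutoff / nyq, type = "low")
  y <- as.numeric(signal::filtfilt(bf, x$samples))
  out <- audio_signal(y, x$rate)
  attr(out, "cutoff_hz") <- cutoff
  out
}

#' Slice a recording into labeled event segments
#'
#' Spans are half-open `[onset, offset)` seconds; sample `i` (1-based) covers
#' time `[(i-1)/rate, i/rate)`. Concatenating the slices of a gapless,
#' exhaustive track therefore reconstructs the signal exactly.
#'
#' @param x an [audio_signal()].
#' @param labels a [label_track()] whose spans lie within the signal.
#' @return list of [event_segment()], in label order.
#' @export
slice_events <- function(x, labels) {
  stopifnot(inherits(x, "audio_signal"), inherits(labels, "label_track"))
  n <- length(x$samples)
  dur <- n / x$rate
  out <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    on <- labels$onset_s[i]; off <- labels$offset_s[i]
    if (on < 0 || off > dur + 1e-9) {
      stop(sprintf("slice_events: span [%g, %g) outside signal of %.3f s (entry %d)",
                   on, off, dur, i))
    }
    i0 <- floor(on * x$rate + 1e-9) + 1L
    i1 <- min(n, floor(off * x$rate + 1e-9))
    out[[i]] <- event_segment(x$samples[i0:i1], x$rate,
                              label = as.character(labels$class[i]),
                              span = c(on, off))
  }
  out
}

#' Read / write event label tables
#'
#' Label CSVs have the header `onset_s,offset_s,class` with class codes in
#' `B, C, CB, S`. Rows are returned sorted by onset; overlapping or reversed
#' spans are rejected.
#'
#' @param path CSV path.
#' @return [read_labels()]: a [label_track()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("read_labels: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s", "class")
  if (!all(need %in% names(df))) {
    stop("read_labels: CSV must have header onset_s,offset_s,class")
  }
  bad <- which(!(df$class %in% jm_classes()))
  if (length(bad)) {
    stop("read_labels: invalid class token '", df$class[bad[1]], "' in row ", bad[1])
  }
  label_track(df$onset_s, df$offset_s, df$class)
}

#' @rdname read_labels
#' @param track a [label_track()].
#' @return [write_labels()]: `path`, invisibly.
#' @export
write_labels <- function(track, path) {
  stopifnot(inherits(track, "label_track"))
  df <- data.frame(onset_s = track$onset_s, offset_s = track$offset_s,
                   class = as.character(track$class))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
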