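# Core value types: jaw-movement classes, audio signals, label tracks and
# event segments. Plain S3 so objects stay printable and data.frame-friendly.

#' Jaw-movement event classes
#'
#' The four mastication event classes: `B` (bite), `C` (chew), `CB`
#' (chew-bite, a compound movement) and `S` (sort, jaw movements that
#' separate feed particles). The integer encoding is stable:
#' B = 0, C = 1, CB = 2, S = 3.
#'
#' @return character vector of the four class codes, in canonical order.
#' @export
jm_classes <- function() c("B", "C", "CB", "S")

#' @rdname jm_classes
#' @param x character vector of class codes.
#' @return `jm_class_factor()`: factor with the four canonical levels.
#' @export
jm_class_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), jm_classes())
  if (length(bad)) {
    stop("unknown jaw-movement class code(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = jm_classes())
}

#' Audio signal container
#'
#' A sampled mono waveform with its sampling rate. Samples are dimensionless
#' amplitudes, nominally in \[-1, 1\] after normalization.
#'
#' @param samples numeric vector of finite amplitudes.
#' @param rate sampling rate in Hz (> 0).
#' @return an object of class `audio_signal` with fields `samples` and `rate`.
#' @export
audio_signal <- function(samples, rate) {
  stopifnot_scalar_num(rate, "rate", lower = 1e-9)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("audio_signal: samples must be finite")
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param x an `audio_signal`.
#' @return duration in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$rate
}

#' Label track of timed, classed events
#'
#' An ordered table of non-overlapping event spans. Spans are half-open
#' `[onset, offset)` in seconds from the start of the recording.
#'
#' @param onset,offset numeric vectors of span endpoints in seconds.
#' @param class character vector of class codes (see [jm_classes()]).
#' @return a `label_track` data.frame with columns `onset_s`, `offset_s`,
#'   `class`, sorted by onset.
#' @export
label_track <- function(onset, offset, class) {
  onset <- as.numeric(onset); offset <- as.numeric(offset)
  if (length(onset) != length(offset) || length(onset) != length(class)) {
    stop("label_track: onset, offset and class must have equal length")
  }
  cls <- jm_class_factor(class)
  bad <- which(!(onset < offset))
  if (length(bad)) {
    stop("label_track: onset must precede offset (row ", bad[1], ")")
  }
  ord <- order(onset)
  onset <- onset[ord]; offset <- offset[ord]; cls <- cls[ord]
  if (length(onset) > 1L) {
    ov <- which(onset[-1] < offset[-length(offset)])
    if (length(ov)) {
      stop("label_track: overlapping spans (rows ", ov[1], " and ", ov[1] + 1L,
           " after sorting)")
    }
  }
  structure(data.frame(onset_s = onset, offset_s = offset, class = cls),
            class = c("label_track", "data.frame"))
}

#' A labeled slice of an audio signal
#'
#' @param samples numeric amplitude vector.
#' @param rate sampling rate in Hz.
#' @param label class code or `NA` for unlabeled segments.
#' @param span numeric length-2 vector `(onset_s, offset_s)` in the source
#'   recording, or `NULL`.
#' @return an object of class `event_segment`.
#' @export
event_segment <- function(samples, rate, label = NA_character_, span = NULL) {
  sig <- audio_signal(samples, rate)
  lab <- if (is.na(label)) NA_character_ else as.character(jm_class_factor(label))
  structure(list(samples = sig$samples, rate = rate, label = lab,
                 source_span = span),
            class = "event_segment")
}

#' @export
print.event_segment <- function(x, ...) {
  cat(sprintf("<event_segment> class=%s, %d samples @ %g Hz\n",
              ifelse(is.na(x$label), "?", x$label), length(x$samples), x$rate))
  invisible(x)
}
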