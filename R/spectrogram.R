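# Time-frequency imaging: STFT and Stockwell (S-) transform, log-magnitude
# normalization to [0, 1], and gray-level quantization.
#
# The normalized image is the substrate of all texture computations; rows are
# frequency bins ordered low to high, columns are time frames left to right.

#' Spectrogram configuration
#'
#' @param window_length analysis window in samples.
#' @param hop hop size in samples (0 < hop <= window_length).
#' @param window taper; only `"hamming"` is provided.
#' @param log_floor magnitudes are floored at this value before `log10`.
#' @param transform `"stft"` (default) or `"s_transform"`.
#' @return an object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window_length = 2048, hop = 1024,
                               window = "hamming", log_floor = 1e-10,
                               transform = c("stft", "s_transform")) {
  transform <- match.arg(transform)
  stopifnot_scalar_num(window_length, "window_length", lower = 2)
  stopifnot_scalar_num(hop, "hop", lower = 1, upper = window_length)
  stopifnot_scalar_num(log_floor, "log_floor", lower = .Machine$double.xmin)
  if (!identical(window, "hamming")) stop("only the Hamming window is supported")
  structure(list(window_length = as.integer(window_length), hop = as.integer(hop),
                 window = window, log_floor = log_floor, transform = transform),
            class = "spectrogram_config")
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

.finish_spectrogram <- function(mag, freq_axis, time_axis, log_floor) {
  img <- log10(pmax(mag, log_floor))
  vals <- rescale01(img)
  structure(list(values = vals, freq_axis = freq_axis, time_axis = time_axis),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freq bins x %d frames, values in [%g, %g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Short-time Fourier transform image of an event segment
#'
#' Frames the signal (`floor((N - window_length)/hop) + 1` frames), applies a
#' Hamming taper, takes the one-sided FFT magnitude, then `log10` with a
#' floor, then min-max scales to \[0, 1\]. A constant-magnitude input maps to
#' the all-zero image.
#'
#' @param seg an [event_segment()] or [audio_signal()].
#' @param cfg a [spectrogram_config()].
#' @return an object of class `spectrogram` with fields `values`
#'   (frequency rows, low to high, by time columns), `freq_axis` (Hz) and
#'   `time_axis` (s, frame centers).
#' @export
stft_image <- function(seg, cfg = spectrogram_config()) {
  x <- seg$samples
  rate <- seg$rate
  wl <- cfg$window_length
  if (length(x) < wl) {
    stop(sprintf(
      "stft_image: segment of %d samples is shorter than one window (%d); zero-pad the segment first",
      length(x), wl))
  }
  nfr <- (length(x) - wl) %/% cfg$hop + 1L
  w <- .hamming(wl)
  nb <- wl %/% 2L + 1L
  mag <- matrix(0, nb, nfr)
  for (k in seq_len(nfr)) {
    i0 <- (k - 1L) * cfg$hop
    fr <- x[(i0 + 1L):(i0 + wl)] * w
    mag[, k] <- Mod(stats::fft(fr))[seq_len(nb)]
  }
  freq_axis <- (0:(nb - 1L)) * rate / wl
  time_axis <- (seq_len(nfr) - 1L) * cfg$hop / rate + wl / (2 * rate)
  .finish_spectrogram(mag, freq_axis, time_axis, cfg$log_floor)
}

#' Stockwell (S-) transform image of an event segment
#'
#' Discrete Stockwell transform: for each frequency bin the signal's spectrum
#' is windowed with a Gaussian whose width scales inversely with frequency
#' (time-domain standard deviation `1/f` seconds, i.e. `rate/f` samples) and
#' inverse-transformed, yielding a progressively sharper time localization at
#' higher frequencies. The zero-frequency row is the signal mean. Time
#' columns are decimated by `cfg$hop`; magnitudes are log-scaled and
#' normalized exactly as in [stft_image()].
#'
#' @inheritParams stft_image
#' @return an object of class `spectrogram`.
#' @export
s_transform_image <- function(seg, cfg = spectrogram_config()) {
  x <- seg$samples
  rate <- seg$rate
  n <- length(x)
  if (n < cfg$window_length) {
    stop(sprintf(
      "s_transform_image: segment of %d samples is shorter than one window (%d); zero-pad the segment first",
      n, cfg$window_length))
  }
  H <- stats::fft(x)
  kmax <- n %/% 2L
  cols <- seq(1L, n, by = cfg$hop)
  mag <- matrix(0, kmax + 1L, length(cols))
  mag[1L, ] <- abs(mean(x))
  m <- 0:(n - 1L)
  msigned <- ifelse(m <= n / 2, m, m - n)
  for (k in seq_len(kmax)) {
    G <- exp(-2 * pi^2 * msigned^2 / k^2)
    Hk <- H[((m + k) %% n) + 1L]
    voice <- stats::fft(Hk * G, inverse = TRUE) / n
    mag[k + 1L, ] <- Mod(voice)[cols]
  }
  freq_axis <- (0:kmax) * rate / n
  time_axis <- (cols - 1L) / rate
  .finish_spectrogram(mag, freq_axis, time_axis, cfg$log_floor)
}

#' Quantize a normalized spectrogram into gray levels
#'
#' Uniformly bins \[0, 1\] into `ng` equal-width bins; value `v` maps to
#' level `floor(v * ng) + 1`, with `v = 1` mapping to `ng`.
#'
#' @param sp a `spectrogram` (or numeric matrix with values in \[0, 1\]).
#' @param ng number of gray levels (>= 2).
#' @return a `gray_image`: integer matrix of levels in `1..ng` with
#'   attribute `ng`.
#' @export
quantize <- function(sp, ng = 32) {
  stopifnot_scalar_num(ng, "ng", lower = 2)
  ng <- as.integer(ng)
  v <- if (inherits(sp, "spectrogram")) sp$values else sp
  if (min(v) < 0 || max(v) > 1) stop("quantize: values must lie in [0, 1]")
  lev <- pmin(floor(v * ng) + 1L, ng)
  img <- matrix(as.integer(lev), nrow(v), ncol(v))
  gray_image(img, ng)
}

#' Construct a gray-level image
#'
#' @param levels integer matrix with entries in `1..ng`.
#' @param ng number of gray levels.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(levels, ng) {
  ng <- as.integer(ng)
  if (ng < 2) stop("gray_image: ng must be >= 2")
  levels <- as.matrix(levels)
  storage.mode(levels) <- "integer"
  if (any(levels < 1L | levels > ng)) stop("gray_image: levels must lie in 1..ng")
  structure(levels, ng = ng, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d gray levels\n",
              nrow(x), ncol(x), attr(x, "ng")))
  invisible(x)
}

#' Export a spectrogram or gray image as PNG (for visual inspection)
#'
#' Requires the `png` package. Rows are flipped so low frequencies are at the
#' bottom of the exported image.
#'
#' @param x a `spectrogram` or `gray_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_png <- function(x, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("export_png requires the 'png' package")
  }
  v <- if (inherits(x, "spectrogram")) x$values
       else (unclass(x) - 1) / (attr(x, "ng") - 1)
  png::writePNG(v[rev(seq_len(nrow(v))), , drop = FALSE], target = path)
  invisible(path)
}
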