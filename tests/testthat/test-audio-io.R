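# WAV and label I/O, conditioning filter, event slicing.

test_that("wav round trip is exact to 16-bit quantization", {
  withr::with_seed(1, x <- runif(4000, -0.9, 0.9))
  sig <- audio_signal(x, 8000)
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(sig, p)
  back <- read_wav(p)
  expect_equal(back$rate, 8000)
  expect_true(max(abs(back$samples - x)) <= 1 / 32767)
  # second round trip is bit-identical (quantization is idempotent)
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(back, p2)
  expect_identical(read_wav(p2)$samples, back$samples)
})

test_that("stereo wavs with identical channels read like mono", {
  # hand-build a 2-channel PCM16 file with both channels equal
  withr::with_seed(2, x <- runif(500, -0.5, 0.5))
  q <- as.integer(round(x * 32767))
  p <- withr::local_tempfile(fileext = ".wav")
  con <- file(p, "wb")
  inter <- as.vector(rbind(q, q))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(inter)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(inter)), con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)
  expect_equal(read_wav(p)$samples, q / 32767)
})

test_that("truncated and malformed wav files error rather than return data", {
  sig <- audio_signal(sin(1:1000 / 10), 8000)
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(sig, p)
  full <- readBin(p, "raw", file.size(p))
  pt <- withr::local_tempfile(fileext = ".wav")
  writeBin(full[1:(length(full) - 500)], pt)
  expect_error(read_wav(pt), "truncated")
  pg <- withr::local_tempfile(fileext = ".wav")
  writeBin(charToRaw("not a wav file at all"), pg)
  expect_error(read_wav(pg), "RIFF")
  expect_error(read_wav(file.path(tempdir(), "missing_xyz.wav")), "no such")
})

test_that("low-pass conditioning preserves passband and rejects stopband", {
  rate <- 8000
  t <- (0:9999) / rate
  cfg <- filter_config(order = 4, "fixed_hz", fixed_cutoff = 1000)
  inband <- audio_signal(sin(2 * pi * 100 * t), rate)
  y <- adaptive_lowpass(inband, cfg)
  rms <- function(s) sqrt(mean(s$samples^2))
  expect_equal(rms(y), rms(inband), tolerance = 0.01)
  expect_equal(length(y$samples), length(inband$samples))
  # filtering an already-filtered in-band sine is idempotent (< 1% RMS change)
  expect_equal(rms(adaptive_lowpass(y, cfg)), rms(y), tolerance = 0.01)
  # 3 kHz sine against a 500 Hz cutoff: magnitude response predicts
  # |H|^2 = 1/(1+(f/fc)^(2*order)) twice (zero-phase) -> essentially zero
  cfg5 <- filter_config(order = 4, "fixed_hz", fixed_cutoff = 500)
  out <- adaptive_lowpass(audio_signal(sin(2 * pi * 3000 * t), rate), cfg5)
  expect_lt(rms(out), 0.1 * rms(inband))
  # zero in, zero out; cutoff at/above Nyquist rejected
  expect_equal(adaptive_lowpass(audio_signal(numeric(100), rate), cfg)$samples,
               numeric(100))
  expect_error(adaptive_lowpass(inband,
                                filter_config(4, "fixed_hz", fixed_cutoff = 4000)),
               "Nyquist")
})

test_that("adaptive cutoff tracks the spectral energy percentile", {
  rate <- 8000
  t <- (0:19999) / rate
  lowtone <- audio_signal(sin(2 * pi * 200 * t), rate)
  y <- adaptive_lowpass(lowtone, filter_config())
  # nearly all energy is at 200 Hz; the cutoff clamps at the 500 Hz floor
  expect_equal(attr(y, "cutoff_hz"), 500)
  expect_equal(sqrt(mean(y$samples^2)), sqrt(mean(lowtone$samples^2)),
               tolerance = 0.01)
})

test_that("slicing is half-open, length-exact and reconstructive", {
  rate <- 8000
  withr::with_seed(3, x <- audio_signal(rnorm(3 * rate), rate))
  segs <- slice_events(x, label_track(1.0, 2.0, "B"))
  expect_equal(length(segs[[1]]$samples), 8000)
  expect_equal(segs[[1]]$label, "B")
  expect_length(slice_events(x, label_track(numeric(0), numeric(0),
                                            character(0))), 0)
  # gapless exhaustive track reconstructs the signal sample for sample
  lt <- label_track(c(0, 1, 1.7), c(1, 1.7, 3), c("B", "C", "S"))
  segs <- slice_events(x, lt)
  expect_identical(unlist(lapply(segs, `[[`, "samples")), x$samples)
  expect_error(slice_events(x, label_track(2.5, 3.5, "B")), "outside")
})

test_that("label csv round trips, validates tokens and sorts rows", {
  lt <- label_track(c(0.5, 2.0), c(1.5, 2.8), c("CB", "S"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_labels(lt, p)
  expect_equal(read_labels(p), lt)
  # out-of-order rows on disk come back sorted by onset
  writeLines(c("onset_s,offset_s,class", "5,6,C", "1,2,B"), p)
  back <- read_labels(p)
  expect_equal(back$onset_s, c(1, 5))
  # invalid token errors with the offending row
  writeLines(c("onset_s,offset_s,class", "1,2,X"), p)
  expect_error(read_labels(p), "invalid class token 'X' in row 1")
  # overlapping spans rejected
  writeLines(c("onset_s,offset_s,class", "1,3,B", "2,4,C"), p)
  expect_error(read_labels(p), "overlap")
})

test_that("slicing a noiseless recording recovers event energy exactly where labeled", {
  cfg <- synth_config(noise_sd = 0)
  rec <- generate_recording(cfg, seed = 11)
  segs <- slice_events(rec$signal, rec$labels)
  expect_equal(length(segs), nrow(rec$labels))
  # outside labeled spans the signal is exactly zero
  mask <- rep(TRUE, length(rec$signal$samples))
  for (i in seq_len(nrow(rec$labels))) {
    i0 <- floor(rec$labels$onset_s[i] * cfg$sample_rate + 1e-9) + 1
    i1 <- floor(rec$labels$offset_s[i] * cfg$sample_rate + 1e-9)
    mask[i0:i1] <- FALSE
  }
  expect_true(all(rec$signal$samples[mask] == 0))
})
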