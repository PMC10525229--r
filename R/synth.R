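# Synthetic mastication audio and synthetic feature tables.
#
# The generator emulates the statistical structure of a field dataset of
# cattle jaw-movement (JM) recordings: four event classes with class-distinct
# intensity and impulsiveness signatures embedded in background noise.
#   B  (bite)      a few high-amplitude, exponentially decaying impulses;
#   C  (chew)      periodic low-amplitude band-limited bursts;
#   CB (chew-bite) superposition of one bite impulse on a chew train;
#   S  (sort)      a cluster of medium-high impulses with irregular spacing.

#' Configuration for the synthetic mastication-audio generator
#'
#' Defaults are desk-scale: 6 recordings of 20 s each with 5 events per class
#' per recording. `preset = "paper_scale"` switches to the field-study scale
#' (60 recordings of 100-300 s) for users who want full-size simulations.
#'
#' @param sample_rate sampling rate in Hz.
#' @param n_recordings number of recordings a simulation produces.
#' @param duration_range length-2 numeric, min and max recording duration (s).
#' @param events_per_class events of each class placed in one recording.
#' @param event_duration_range length-2 numeric, min/max single-event
#'   duration (s).
#' @param class_params named list (B, C, CB, S) of per-class acoustic recipes;
#'   each entry has `peak_amplitude` (linear gain), `impulse_decay` (s),
#'   `repetition_rate` (Hz, chew-type trains), `band` (Hz, length-2 passband),
#'   `n_impulses` (impulsive classes).
#' @param noise_sd standard deviation of the additive Gaussian noise floor
#'   (linear amplitude).
#' @param seed integer seed driving all randomness.
#' @param preset `"desk_scale"` (default) or `"paper_scale"`.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(sample_rate = 22050,
                         n_recordings = 6,
                         duration_range = c(20, 20),
                         events_per_class = 5,
                         event_duration_range = c(0.85, 0.95),
                         class_params = NULL,
                         noise_sd = 5e-4,
                         seed = 1L,
                         preset = c("desk_scale", "paper_scale")) {
  preset <- match.arg(preset)
  if (preset == "paper_scale") {
    n_recordings <- 60
    duration_range <- c(100, 300)
    events_per_class <- 15
  }
  if (is.null(class_params)) {
    class_params <- list(
      B = list(peak_amplitude = 0.9, impulse_decay = 0.006,
               repetition_rate = NA_real_, band = c(800, 4000), n_impulses = 3,
               ring_freq = 2800, ring_mix = 0.5),
      C = list(peak_amplitude = 0.25, impulse_decay = 0.090,
               repetition_rate = 4, band = c(300, 1200), n_impulses = NA_real_),
      CB = list(peak_amplitude = 0.9, impulse_decay = 0.006,
                repetition_rate = 4, band = c(300, 1200), n_impulses = 2),
      S = list(peak_amplitude = 0.6, impulse_decay = 0.012,
               repetition_rate = NA_real_, band = c(2000, 5000), n_impulses = 12,
               noise_bed = 0.08)
    )
  }
  stopifnot_scalar_num(sample_rate, "sample_rate", lower = 1)
  stopifnot_scalar_num(events_per_class, "events_per_class", lower = 1)
  stopifnot_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (length(duration_range) != 2L || duration_range[1] > duration_range[2]) {
    stop("duration_range must be (min, max) with min <= max")
  }
  if (event_duration_range[1] > event_duration_range[2] ||
      event_duration_range[1] <= 0) {
    stop("event_duration_range must be positive with min <= max")
  }
  if (!all(jm_classes() %in% names(class_params))) {
    stop("class_params must name all of ", paste(jm_classes(), collapse = ", "))
  }
  if (class_params$B$peak_amplitude <= class_params$C$peak_amplitude) {
    stop("bites must be louder than chews: peak_amplitude(B) > peak_amplitude(C)")
  }
  structure(list(sample_rate = sample_rate, n_recordings = n_recordings,
                 duration_range = duration_range,
                 events_per_class = events_per_class,
                 event_duration_range = event_duration_range,
                 class_params = class_params, noise_sd = noise_sd,
                 seed = as.integer(seed), preset = preset),
            class = "synth_config")
}

# Band-limited noise carrier with unit peak, used as the broadband "texture"
# of impacts and grinding. 4th-order Butterworth band-pass on white noise.
.bandlimited_noise <- function(n, band, rate) {
  nyq <- rate / 2
  lo <- max(band[1], 1) / nyq
  hi <- min(band[2], 0.95 * nyq) / nyq
  bf <- signal::butter(4, c(lo, hi), type = "pass")
  x <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  pk <- max(abs(x))
  if (pk > 0) x / pk else x
}

# Envelope of decaying impulses at sample indices `at` (1-based), decay tau s.
.impulse_envelope <- function(n, at, tau, rate, amps) {
  env <- numeric(n)
  k <- ceiling(6 * tau * rate)
  for (i in seq_along(at)) {
    idx <- at[i]:min(n, at[i] + k)
    env[idx] <- env[idx] + amps[i] * exp(-(idx - at[i]) / (tau * rate))
  }
  env
}

# Mix a resonant ring (tooth/jaw impact resonance) into a noise carrier; the
# ring shows up as a thin horizontal line in the time-frequency image.
.mix_ring <- function(car, p, rate) {
  if (is.null(p$ring_freq) || is.null(p$ring_mix) || p$ring_mix <= 0) return(car)
  ring <- sin(2 * pi * p$ring_freq * (seq_along(car) - 1) / rate)
  (1 - p$ring_mix) * car + p$ring_mix * ring
}

# Deterministic part of one event, given its duration; consumes RNG draws.
.event_core <- function(cls, cfg, dur) {
  rate <- cfg$sample_rate
  n <- max(1L, round(dur * rate))
  p <- cfg$class_params[[cls]]
  carrier <- .bandlimited_noise(n, p$band, rate)
  x <- switch(
    cls,
    B = {
      at <- sort(sample.int(max(1L, floor(0.75 * n)), p$n_impulses))
      amps <- stats::runif(p$n_impulses, 0.85, 1)
      .impulse_envelope(n, at, p$impulse_decay, rate, amps) *
        .mix_ring(carrier, p, rate)
    },
    C = {
      period <- rate / p$repetition_rate
      phase <- stats::runif(1, 0, period)
      at <- round(seq(1 + phase, n, by = period))
      at <- at[at <= n]
      if (!length(at)) at <- 1L
      amps <- stats::runif(length(at), 0.9, 1)
      .impulse_envelope(n, at, p$impulse_decay, rate, amps) * carrier
    },
    CB = {
      # chew train at chew amplitude plus superposed bite impulse(s); the
      # bite part is not renormalized, so chew-bite carries more energy.
      pc <- cfg$class_params$C
      period <- rate / pc$repetition_rate
      phase <- stats::runif(1, 0, period)
      at <- round(seq(1 + phase, n, by = period))
      at <- at[at <= n]
      if (!length(at)) at <- 1L
      amps <- stats::runif(length(at), 0.9, 1)
      # CB's band equals C's, so `carrier` reproduces the chew carrier the C
      # recipe would draw from the same RNG state: CB == C + bite, exactly.
      chew <- .impulse_envelope(n, at, pc$impulse_decay, rate, amps) * carrier
      pkc <- max(abs(chew))
      if (pkc > 0) chew <- chew * (pc$peak_amplitude / pkc)
      pb <- cfg$class_params$B
      nb <- max(1L, p$n_impulses)
      at_b <- sort(sample.int(max(1L, floor(0.75 * n)), nb))
      bite <- .impulse_envelope(n, at_b, pb$impulse_decay, rate,
                                rep(1, nb)) *
        .mix_ring(.bandlimited_noise(n, pb$band, rate), pb, rate)
      pkb <- max(abs(bite))
      if (pkb > 0) bite <- bite * (pb$peak_amplitude / pkb)
      return(chew + bite)
    },
    S = {
      # high-intensity bursts amid a sustained low-level jaw-noise bed
      at <- sort(sample.int(max(1L, floor(0.9 * n)), p$n_impulses))
      amps <- stats::runif(p$n_impulses, 0.7, 1)
      imp <- .impulse_envelope(n, at, p$impulse_decay, rate, amps) * carrier
      bed <- if (is.null(p$noise_bed)) 0 else
        p$noise_bed * .bandlimited_noise(n, c(200, min(6000, 0.45 * rate)), rate)
      imp + bed
    },
    stop("unknown jaw-movement class code: ", cls)
  )
  pk <- max(abs(x))
  if (pk > 0) x <- x * (p$peak_amplitude / pk)
  x
}

#' Generate the waveform of a single jaw-movement event
#'
#' Draws an event duration, a Gaussian noise floor and the class-specific
#' deterministic component, fully determined by `(cls, cfg, seed)`.
#'
#' @param cls one of `"B"`, `"C"`, `"CB"`, `"S"`.
#' @param cfg a [synth_config()].
#' @param seed integer seed; identical inputs give bit-identical waveforms.
#' @return an [audio_signal()].
#' @export
generate_event_waveform <- function(cls, cfg = synth_config(), seed = cfg$seed) {
  cls <- as.character(cls)
  if (!(cls %in% jm_classes())) {
    stop("unknown jaw-movement class code: ", cls)
  }
  with_seed(seed, {
    dur <- stats::runif(1, cfg$event_duration_range[1], cfg$event_duration_range[2])
    n <- max(1L, round(dur * cfg$sample_rate))
    noise <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
    audio_signal(.event_core(cls, cfg, dur) + noise, cfg$sample_rate)
  })
}

#' Generate one labeled synthetic recording
#'
#' Places `events_per_class` events of each class, in seeded random order and
#' at seeded random non-overlapping positions, on a Gaussian noise floor.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return list with elements `signal` ([audio_signal()]) and `labels`
#'   ([label_track()]); label entries match the placed events exactly.
#' @export
generate_recording <- function(cfg = synth_config(), seed = cfg$seed) {
  with_seed(seed, {
    rate <- cfg$sample_rate
    dur <- stats::runif(1, cfg$duration_range[1], cfg$duration_range[2])
    n <- max(1L, round(dur * rate))
    classes <- rep(jm_classes(), each = cfg$events_per_class)
    classes <- sample(classes)
    durs <- stats::runif(length(classes), cfg$event_duration_range[1],
                         cfg$event_duration_range[2])
    gap_min <- 0.05
    need <- sum(durs) + gap_min * (length(durs) + 1)
    if (need > dur) {
      stop(sprintf(
        "events do not fit: %.2f s required (events + minimum gaps) vs %.2f s available",
        need, dur))
    }
    # distribute the spare time as random extra gaps
    spare <- dur - need
    w <- stats::runif(length(durs) + 1)
    gaps <- gap_min + spare * w / sum(w)
    onsets <- cumsum(gaps[seq_along(durs)]) + c(0, cumsum(durs))[seq_along(durs)]
    offsets <- onsets + durs
    x <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
    for (i in seq_along(classes)) {
      ev <- .event_core(classes[i], cfg, durs[i])
      i0 <- floor(onsets[i] * rate) + 1L
      idx <- i0:min(n, i0 + length(ev) - 1L)
      x[idx] <- x[idx] + ev[seq_along(idx)]
      # snap the label to the samples actually written
      onsets[i] <- (i0 - 1L) / rate
      offsets[i] <- (i0 - 1L + length(ev)) / rate
    }
    list(signal = audio_signal(x, rate),
         labels = label_track(onsets, offsets, classes))
  })
}

#' Generate a synthetic feature table with planted informative columns
#'
#' Builds a table of `4 * n_per_class` rows (balanced over the four classes)
#' and `n_features` numeric columns. Columns in `informative` get
#' class-dependent means separated by `separation * noise_sd`; all other
#' columns are pure Gaussian noise. Used as a controlled test bed for the
#' genetic-algorithm feature selector.
#'
#' @param n_per_class rows per class (>= 2).
#' @param n_features number of feature columns.
#' @param informative integer set of informative column indices.
#' @param separation effect size between adjacent class means, in units of
#'   `noise_sd`.
#' @param noise_sd within-class standard deviation.
#' @param seed integer seed.
#' @return a `feature_table` data.frame: feature columns named after the 32
#'   canonical texture features (recycled/extended if `n_features != 32`)
#'   plus a `class` factor column.
#' @export
generate_feature_table <- function(n_per_class = 50, n_features = 32,
                                   informative = c(3, 7), separation = 6,
                                   noise_sd = 1, seed = 0L) {
  if (n_per_class < 2) stop("n_per_class must be >= 2")
  informative <- as.integer(informative)
  if (length(informative) == 0 && separation > 0) {
    stop("empty informative set with separation > 0: no signal to plant")
  }
  if (length(informative) && (min(informative) < 1 || max(informative) > n_features)) {
    stop("informative indices must lie in 1..n_features")
  }
  with_seed(seed, {
    n <- 4L * n_per_class
    cls <- jm_class_factor(rep(jm_classes(), each = n_per_class))
    X <- matrix(stats::rnorm(n * n_features, 0, noise_sd), n, n_features)
    for (k in seq_along(informative)) {
      j <- informative[k]
      # deterministic per-column permutation of class order so informative
      # columns carry complementary information
      ord <- ((seq_len(4) - 1 + k) %% 4) + 1
      mu <- separation * noise_sd * (ord - 1)
      X[, j] <- X[, j] + mu[as.integer(cls)]
    }
    nm <- texture_feature_names()
    if (n_features <= length(nm)) nm <- nm[seq_len(n_features)]
    else nm <- c(nm, paste0("X", seq_len(n_features - length(nm))))
    colnames(X) <- nm
    tab <- data.frame(X, check.names = FALSE)
    tab$class <- cls
    structure(tab, class = c("feature_table", "data.frame"))
  })
}
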