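#' Configuration of the synthetic-EEG generator
#'
#' Describes a synthetic rendition of the beat-response experiments: each
#' recording is a 6-Hz steady-state component with a frontal-dominant scalp
#' topography plus band-limited 1/f^alpha background noise, with lognormal
#' per-trial amplitude variability and a multiplicative condition effect
#' (scrambled > original; attended > ignored). All magnitudes are explicit
#' assumptions — the generator emulates the acquisition parameters
#' (13 channels, 1000 samples/s, two-minute recordings, 0.1-100 Hz band) but
#' no real data were available to calibrate amplitudes.
#'
#' @param n_subjects number of subjects (default 8).
#' @param trials_per_subject trials per subject (default 4).
#' @param beat_frequency_hz beat frequency (default 6).
#' @param sample_rate_hz sampling rate (default 1000; reducible for cheap
#'   simulations as long as it stays above twice the noise band edge).
#' @param duration_s recording duration in seconds (default 120, reducible).
#' @param channel_topography named per-channel relative gains in `[0, 1]`,
#'   frontal/central high and occipital low.
#' @param base_amplitude beat-component amplitude in volts at a gain-1
#'   channel (default 2e-6).
#' @param effect_multiplier condition gain ratio, scrambled/original and
#'   attended/ignored (default 1.25).
#' @param noise_exponent spectral exponent alpha of the 1/f^alpha noise
#'   (default 1).
#' @param noise_rms per-channel noise RMS in volts (default 5e-6).
#' @param noise_band_hz noise band edges in Hz (default `c(0.1, 100)`,
#'   the amplifier band).
#' @param noise_channel_correlation fraction of noise variance shared across
#'   channels through a common source (default 0, independent noise).
#' @param trial_cv lognormal coefficient of variation of the per-trial
#'   amplitude gain, shared by the two recordings of a trial (default 0.2).
#' @param phase_rad true response phase in radians (default 3.5,
#'   approximately a 93-ms latency at 6 Hz).
#' @param seed integer master seed; every recording derives its own
#'   substream deterministically from `(seed, subject, trial, condition)`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 8,
                             trials_per_subject = 4,
                             beat_frequency_hz = 6,
                             sample_rate_hz = 1000,
                             duration_s = 120,
                             channel_topography = default_topography(),
                             base_amplitude = 2e-6,
                             effect_multiplier = 1.25,
                             noise_exponent = 1,
                             noise_rms = 5e-6,
                             noise_band_hz = c(0.1, 100),
                             noise_channel_correlation = 0,
                             trial_cv = 0.2,
                             phase_rad = 3.5,
                             seed = 1) {
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive", call. = FALSE)
  n <- duration_s * sample_rate_hz
  if (abs(n - round(n)) > 1e-9) {
    stop("duration_s * sample_rate_hz must be an integer", call. = FALSE)
  }
  if (any(channel_topography < 0) || is.null(names(channel_topography))) {
    stop("channel_topography must be a named vector of non-negative gains",
         call. = FALSE)
  }
  if (effect_multiplier <= 0) stop("effect_multiplier must be positive",
                                   call. = FALSE)
  structure(
    list(n_subjects = n_subjects, trials_per_subject = trials_per_subject,
         beat_frequency_hz = beat_frequency_hz,
         sample_rate_hz = sample_rate_hz, duration_s = duration_s,
         channel_topography = channel_topography,
         base_amplitude = base_amplitude,
         effect_multiplier = effect_multiplier,
         noise_exponent = noise_exponent, noise_rms = noise_rms,
         noise_band_hz = noise_band_hz,
         noise_channel_correlation = noise_channel_correlation,
         trial_cv = trial_cv, phase_rad = phase_rad,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default scalp topography of the beat response
#'
#' Relative per-channel gains for the 13-channel montage: largest over the
#' frontal and central areas, smallest at the occipital pole.
#' @return Named numeric vector of gains in `[0, 1]`.
#' @export
default_topography <- function() {
  c(Fpz = 0.95, F5 = 0.85, Fz = 1.00, F6 = 0.90,
    T7 = 0.55, C3 = 0.80, Cz = 0.90, C4 = 0.80, T8 = 0.55,
    P5 = 0.50, Pz = 0.60, P6 = 0.50, Oz = 0.30)
}

# Condition gains: the scrambled melody and the attended presentation evoke
# the stronger response.
.condition_gain <- function(config, condition) {
  switch(condition,
    original = 1, ignored = 1,
    scrambled = config$effect_multiplier,
    attended = config$effect_multiplier,
    stop("unknown condition: ", condition, call. = FALSE)
  )
}

# Deterministic substream seed from integer keys (kept below 2^31 - 1).
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    h <- (h * 48271 + as.numeric(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

# Band-limited 1/f^alpha noise, one column per channel, unit RMS per column.
# Synthesized in the frequency domain: complex Gaussian coefficients shaped
# by f^(-alpha/2) inside the band, zero outside, Hermitian-symmetrized.
.pink_noise <- function(n, n_channels, sample_rate_hz, alpha, band_hz) {
  half <- floor(n / 2)
  f <- (1:half) * sample_rate_hz / n
  in_band <- f >= band_hz[1] & f <= band_hz[2]
  shape <- ifelse(in_band, f^(-alpha / 2), 0)
  m <- sum(in_band)
  coef <- matrix(0 + 0i, nrow = n, ncol = n_channels)
  re <- matrix(stats::rnorm(m * n_channels), m, n_channels)
  im <- matrix(stats::rnorm(m * n_channels), m, n_channels)
  coef[1L + which(in_band), ] <- (re + 1i * im) * shape[in_band]
  # Hermitian symmetry for a real signal; Nyquist (even n) left at zero
  coef[n + 1L - which(in_band), ] <- Conj(coef[1L + which(in_band), ])
  x <- Re(stats::mvfft(coef, inverse = TRUE)) / n
  sds <- apply(x, 2L, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2L, sds, "/")
}

#' Simulate one EEG recording with known ground truth
#'
#' Each channel carries
#' `base_amplitude * gain(ch) * condition_gain * trial_gain *
#' cos(2*pi*f_beat*t + phase)` plus band-limited 1/f^alpha noise scaled to
#' `noise_rms`. The per-trial gain is lognormal (unit mean, CV `trial_cv`)
#' and is shared by the two recordings of a trial, so condition differences
#' within a trial are unaffected by slow baseline drift between trials. The
#' recording is a deterministic function of `(seed, subject, trial,
#' condition)`.
#'
#' @param config a [synthetic_config()].
#' @param condition `"original"`, `"scrambled"`, `"attended"` or
#'   `"ignored"`.
#' @param subject,trial integer identifiers.
#' @return List with `recording` (an [eeg_recording()]) and `ground_truth`
#'   (list: per-channel true beat amplitude, phase, gains, ids).
#' @export
simulate_recording <- function(config, condition = "original",
                               subject = 1, trial = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  condition <- match.arg(condition,
                         c("original", "scrambled", "attended", "ignored"))
  n <- round(config$duration_s * config$sample_rate_hz)
  labels <- names(config$channel_topography)
  n_ch <- length(labels)

  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)

  # per-trial gain, shared by both recordings of the trial
  set.seed(derive_seed(config$seed, subject, trial, 0))
  sdlog <- sqrt(log(1 + config$trial_cv^2))
  trial_gain <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  cond_code <- match(condition, c("original", "scrambled", "attended", "ignored"))
  set.seed(derive_seed(config$seed, subject, trial, cond_code))

  cond_gain <- .condition_gain(config, condition)
  amp <- config$base_amplitude * config$channel_topography * cond_gain *
    trial_gain
  t <- (seq_len(n) - 1) / config$sample_rate_hz
  carrier <- cos(2 * pi * config$beat_frequency_hz * t + config$phase_rad)

  data <- tcrossprod(amp, carrier)  # channels x time
  if (config$noise_rms > 0) {
    rho <- config$noise_channel_correlation
    noise <- .pink_noise(n, n_ch, config$sample_rate_hz,
                         config$noise_exponent, config$noise_band_hz)
    if (rho > 0) {
      shared <- .pink_noise(n, 1L, config$sample_rate_hz,
                            config$noise_exponent, config$noise_band_hz)
      noise <- sqrt(1 - rho) * noise +
        sqrt(rho) * matrix(shared, n, n_ch)
    }
    data <- data + t(noise) * config$noise_rms
  }
  rec <- eeg_recording(
    data, sample_rate_hz = config$sample_rate_hz, channel_labels = labels,
    meta = list(subject = subject, trial = trial, condition = condition)
  )
  list(
    recording = rec,
    ground_truth = list(
      channel_amplitude = amp, phase = config$phase_rad,
      condition = condition, condition_gain = cond_gain,
      trial_gain = trial_gain, subject = subject, trial = trial
    )
  )
}

#' Simulate a full two-condition experiment
#'
#' Generates `n_subjects * trials_per_subject` trial pairs for one paradigm:
#' condition A is the baseline recording (original melody, or attended
#' music), condition B the counterpart (scrambled melody, or ignored music).
#' The presentation order within each trial is randomized and stored in the
#' pair's ground truth. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param paradigm `"comprehension"` or `"attention"`.
#' @return List of [trial_pair()]s carrying recordings and ground truth.
#' @export
simulate_experiment <- function(config,
                                paradigm = c("comprehension", "attention")) {
  stopifnot(inherits(config, "synthetic_config"))
  paradigm <- match.arg(paradigm)
  conds <- if (paradigm == "comprehension") {
    c(a = "original", b = "scrambled")
  } else {
    c(a = "attended", b = "ignored")
  }
  pairs <- list()
  for (s in seq_len(config$n_subjects)) {
    for (tr in seq_len(config$trials_per_subject)) {
      ra <- simulate_recording(config, conds[["a"]], subject = s, trial = tr)
      rb <- simulate_recording(config, conds[["b"]], subject = s, trial = tr)
      old <- .save_rng()
      set.seed(derive_seed(config$seed, s, tr, 9))
      order_first <- sample(c("a", "b"), 1L)
      .restore_rng(old)
      pairs[[length(pairs) + 1L]] <- trial_pair(
        recording_a = ra$recording, recording_b = rb$recording,
        subject = s, trial = tr, paradigm = paradigm,
        ground_truth = list(a = ra$ground_truth, b = rb$ground_truth,
                            presented_first = order_first)
      )
    }
  }
  pairs
}

#' Inject spike artifacts into a recording
#'
#' Adds brief large-amplitude excursions at random sample positions, for
#' exercising [screen_artifacts()].
#'
#' @param rec an [eeg_recording()].
#' @param n_spikes number of spikes per channel.
#' @param amplitude spike amplitude in units of the channel SD (default 20).
#' @param seed integer seed.
#' @return List with `recording` (the corrupted copy) and `positions`
#'   (list of injected sample indices per channel).
#' @export
inject_spikes <- function(rec, n_spikes, amplitude = 20, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  positions <- vector("list", nrow(rec$data))
  names(positions) <- rec$channel_labels
  for (i in seq_len(nrow(rec$data))) {
    idx <- sample.int(ncol(rec$data), n_spikes)
    s <- stats::sd(rec$data[i, ])
    if (s == 0) s <- 1
    rec$data[i, idx] <- rec$data[i, idx] +
      amplitude * s * sample(c(-1, 1), n_spikes, replace = TRUE)
    positions[[i]] <- sort(idx)
  }
  list(recording = rec, positions = positions)
}
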