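#' The 13-channel 10/10 montage used for beat-response recordings
#' @return Character vector of channel labels.
#' @export
default_montage <- function() {
  c("Fpz", "F5", "Fz", "F6", "T7", "C3", "Cz", "C4", "T8",
    "P5", "Pz", "P6", "Oz")
}

#' Construct a multi-channel EEG recording
#'
#' @param data numeric matrix, channels in rows and samples in columns,
#'   voltages in volts.
#' @param sample_rate_hz sampling rate (default 1000).
#' @param channel_labels unique channel names, one per row; defaults to the
#'   first `nrow(data)` labels of [default_montage()].
#' @param meta named list of metadata (`subject`, `trial`, `condition`, ...).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate_hz = 1000,
                          channel_labels = NULL, meta = list()) {
  data <- as.matrix(data)
  if (is.null(channel_labels)) {
    if (nrow(data) > length(default_montage())) {
      stop("supply channel_labels for montages beyond the default 13",
           call. = FALSE)
    }
    channel_labels <- default_montage()[seq_len(nrow(data))]
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("one channel label per data row is required", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive", call. = FALSE)
  }
  if (ncol(data) < sample_rate_hz) {
    stop("recording must last at least one second", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, sample_rate_hz = as.numeric(sample_rate_hz),
         channel_labels = channel_labels, meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %.6g s at %g samples/s\n",
    nrow(x$data), ncol(x$data) / x$sample_rate_hz, x$sample_rate_hz
  ))
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) == 1L, TRUE)
    if (any(keep)) {
      cat("  ", paste(names(x$meta)[keep], unlist(x$meta[keep]),
                      sep = "=", collapse = " "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Screen a recording for spike artifacts
#'
#' Flags samples whose absolute deviation from the channel median exceeds
#' `spike_k` times the channel MAD — an automated stand-in for visual
#' screening of short, large-amplitude spikes. A recording is marked for
#' repetition when any channel has more than `max_flagged_fraction` of its
#' samples flagged.
#'
#' @param rec an [eeg_recording()].
#' @param spike_k MAD multiplier above which a sample counts as a spike
#'   (default 8).
#' @param max_flagged_fraction largest tolerated flagged fraction per channel
#'   (default 0.01).
#' @return An object of class `artifact_report`: list with
#'   `flagged_fraction` (named per channel), `verdict` (`"pass"` or
#'   `"repeat"`), `degenerate_channels` (labels of constant channels) and the
#'   thresholds used.
#' @export
screen_artifacts <- function(rec, spike_k = 8, max_flagged_fraction = 0.01) {
  stopifnot(inherits(rec, "eeg_recording"))
  med <- apply(rec$data, 1L, stats::median)
  mad <- apply(rec$data, 1L, stats::mad)
  degenerate <- rec$channel_labels[mad == 0]
  frac <- vapply(seq_len(nrow(rec$data)), function(i) {
    if (mad[i] == 0) return(0)
    mean(abs(rec$data[i, ] - med[i]) > spike_k * mad[i])
  }, numeric(1))
  names(frac) <- rec$channel_labels
  if (length(degenerate)) {
    warning("constant (degenerate) channel(s): ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  structure(
    list(flagged_fraction = frac,
         verdict = if (any(frac > max_flagged_fraction)) "repeat" else "pass",
         degenerate_channels = degenerate,
         spike_k = spike_k, max_flagged_fraction = max_flagged_fraction),
    class = "artifact_report"
  )
}

#' Full-length complex Fourier spectrum per channel
#'
#' Computes the discrete Fourier transform of every channel over the full
#' recording, normalized single-sidedly so that a sinusoid of amplitude A at
#' an exact bin yields amplitude A, with cosine phase convention: an input
#' `A*cos(2*pi*f*t + phi)` gives a complex coefficient `A*exp(1i*phi)` at
#' bin f. Bin spacing is `1/duration` (1/120 Hz for a two-minute recording).
#'
#' @param rec an [eeg_recording()].
#' @return An object of class `channel_spectrum`: list with `freqs_hz`,
#'   `coefficients` (channels x bins complex matrix), `amplitude`
#'   (its modulus), `channel_labels` and `sample_rate_hz`.
#' @export
channel_spectrum <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (anyNA(rec$data)) stop("recording contains NA values", call. = FALSE)
  n <- ncol(rec$data)
  n_bins <- floor(n / 2) + 1L
  coef <- t(stats::mvfft(t(rec$data))[seq_len(n_bins), , drop = FALSE]) *
    (2 / n)
  coef[, 1L] <- coef[, 1L] / 2
  if (n %% 2 == 0) coef[, n_bins] <- coef[, n_bins] / 2
  rownames(coef) <- rec$channel_labels
  structure(
    list(
      freqs_hz = (seq_len(n_bins) - 1L) * rec$sample_rate_hz / n,
      coefficients = coef,
      amplitude = Mod(coef),
      channel_labels = rec$channel_labels,
      sample_rate_hz = rec$sample_rate_hz
    ),
    class = "channel_spectrum"
  )
}

#' Select beat-responsive channels
#'
#' A channel is beat-responsive when its spectral amplitude at the beat
#' frequency exceeds the mean amplitude of the neighboring bins (5-7 Hz,
#' excluding bins within `exclusion_halfwidth_hz` of the beat) by more than
#' `k_sd` standard deviations of those neighbors.
#'
#' @param spec a [channel_spectrum()].
#' @param f_beat_hz beat frequency (default 6).
#' @param band_hz neighbor band as `c(low, high)` in Hz (default `c(5, 7)`).
#' @param k_sd threshold in neighbor standard deviations (default 2).
#' @param exclusion_halfwidth_hz half-width of the excluded zone around the
#'   beat bin (default 0.1 Hz).
#' @return Character vector of beat-responsive channel labels (possibly
#'   empty), with attribute `"snr"` giving each channel's
#'   `(amplitude - neighbor mean) / neighbor SD`.
#' @export
beat_responsive_channels <- function(spec, f_beat_hz = 6, band_hz = c(5, 7),
                                     k_sd = 2, exclusion_halfwidth_hz = 0.1) {
  stopifnot(inherits(spec, "channel_spectrum"))
  if (f_beat_hz <= band_hz[1] || f_beat_hz >= band_hz[2]) {
    stop("band must contain the beat frequency", call. = FALSE)
  }
  beat_bin <- which.min(abs(spec$freqs_hz - f_beat_hz))
  nb <- which(spec$freqs_hz >= band_hz[1] & spec$freqs_hz <= band_hz[2] &
                abs(spec$freqs_hz - f_beat_hz) > exclusion_halfwidth_hz)
  if (length(nb) < 10L) {
    stop("fewer than 10 neighbor bins; record longer or widen the band",
         call. = FALSE)
  }
  amp_nb <- spec$amplitude[, nb, drop = FALSE]
  m <- rowMeans(amp_nb)
  s <- apply(amp_nb, 1L, stats::sd)
  if (any(s == 0)) {
    warning("zero-variance neighbor amplitudes; channel(s) excluded: ",
            paste(spec$channel_labels[s == 0], collapse = ", "),
            call. = FALSE)
  }
  z <- ifelse(s > 0, (spec$amplitude[, beat_bin] - m) / s, -Inf)
  responsive <- spec$channel_labels[z > k_sd]
  names(z) <- spec$channel_labels
  attr(responsive, "snr") <- z
  responsive
}

#' Segment-wise beat-frequency response of averaged channels
#'
#' Averages the selected channels' time series sample-wise, cuts the average
#' into consecutive segments (1 s by default), extracts the complex Fourier
#' coefficient at the beat frequency from each segment (same normalization
#' and phase convention as [channel_spectrum()]), and summarizes amplitude
#' and phase across segments. With the default `"modulus_mean"` mode the
#' reported amplitude is the mean of the per-segment amplitude moduli and the
#' SEM is their standard error; `"complex_mean"` instead reports the modulus
#' of the mean complex coefficient. The phase is always the argument of the
#' mean complex coefficient, in (-pi, pi].
#'
#' @param rec an [eeg_recording()].
#' @param channels labels of the channels to average (e.g. the output of
#'   [beat_responsive_channels()]).
#' @param f_beat_hz beat frequency (default 6).
#' @param segment_seconds segment length in seconds (default 1).
#' @param amplitude_mode `"modulus_mean"` (default) or `"complex_mean"`.
#' @return An object of class `beat_summary`: list with
#'   `responsive_channels`, `mean_amplitude`, `sem_amplitude`, `mean_phase`,
#'   `n_segments`, `per_segment_coefficients`, `per_segment_amplitude`,
#'   `f_beat_hz`, `segment_seconds` and `meta` (copied from the recording).
#' @export
average_beat_response <- function(rec, channels, f_beat_hz = 6,
                                  segment_seconds = 1,
                                  amplitude_mode = c("modulus_mean",
                                                     "complex_mean")) {
  stopifnot(inherits(rec, "eeg_recording"))
  amplitude_mode <- match.arg(amplitude_mode)
  if (length(channels) == 0L) {
    stop("empty channel set", call. = FALSE)
  }
  if (!all(channels %in% rec$channel_labels)) {
    stop("channel(s) not present in the recording: ",
         paste(setdiff(channels, rec$channel_labels), collapse = ", "),
         call. = FALSE)
  }
  avg <- colMeans(rec$data[channels, , drop = FALSE])
  coefs <- segment_coefficients(avg, rec$sample_rate_hz, f_beat_hz,
                                segment_seconds)
  amps <- Mod(coefs)
  n_seg <- length(coefs)
  mean_amp <- switch(amplitude_mode,
    modulus_mean = mean(amps),
    complex_mean = Mod(mean(coefs))
  )
  structure(
    list(
      responsive_channels = channels,
      mean_amplitude = mean_amp,
      sem_amplitude = if (n_seg > 1L) stats::sd(amps) / sqrt(n_seg) else 0,
      mean_phase = Arg(mean(coefs)),
      n_segments = n_seg,
      per_segment_coefficients = coefs,
      per_segment_amplitude = amps,
      f_beat_hz = f_beat_hz,
      segment_seconds = segment_seconds,
      amplitude_mode = amplitude_mode,
      meta = rec$meta
    ),
    class = "beat_summary"
  )
}

#' @export
print.beat_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<beat_summary> %.4g V (SEM %.2g) at %g Hz, phase %.3f rad,",
           " %d segments, %d channel(s)\n"),
    x$mean_amplitude, x$sem_amplitude, x$f_beat_hz, x$mean_phase,
    x$n_segments, length(x$responsive_channels)
  ))
  invisible(x)
}

# Complex coefficient at f_hz for each consecutive segment of a 1-D signal,
# with the single-sided A*exp(1i*phi) normalization.
segment_coefficients <- function(x, sample_rate_hz, f_hz, segment_seconds) {
  seg_n <- round(segment_seconds * sample_rate_hz)
  n_seg <- floor(length(x) / seg_n)
  if (n_seg < 1L) stop("signal shorter than one segment", call. = FALSE)
  segs <- matrix(x[seq_len(seg_n * n_seg)], nrow = seg_n, ncol = n_seg)
  t <- (seq_len(seg_n) - 1) / sample_rate_hz
  basis <- exp(-2i * pi * f_hz * t)
  drop(crossprod(segs, basis)) * (2 / seg_n)
}

#' Kolmogorov-Smirnov normality check of per-segment coefficients
#'
#' Standardizes the real and imaginary parts of the per-segment complex
#' Fourier coefficients (centering and scaling to unit SD) and tests each
#' against the standard normal distribution. Approximate normality of the
#' quadratures justifies the t-tests used downstream.
#'
#' @param coefficients complex vector of per-segment coefficients (at least
#'   20), or a `beat_summary`.
#' @return List with `p_real` and `p_imag`.
#' @export
ks_normality <- function(coefficients) {
  if (inherits(coefficients, "beat_summary")) {
    coefficients <- coefficients$per_segment_coefficients
  }
  if (length(coefficients) < 20L) {
    stop("need at least 20 coefficients", call. = FALSE)
  }
  standardize <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("zero variance in a quadrature", call. = FALSE)
    (v - mean(v)) / s
  }
  list(
    p_real = stats::ks.test(standardize(Re(coefficients)), "pnorm")$p.value,
    p_imag = stats::ks.test(standardize(Im(coefficients)), "pnorm")$p.value
  )
}

#' Convert response phase to latency
#'
#' A steady-state response with phase lag `phase_rad` at frequency `f_hz`
#' corresponds to a time delay of `phase_rad / (2 * pi * f_hz)` seconds; a
#' phase of about 3.5 rad at 6 Hz corresponds to roughly 94 ms.
#'
#' @param phase_rad phase in radians (cosine convention, positive = lag).
#' @param f_hz frequency in Hz (positive).
#' @return Latency in seconds.
#' @export
phase_to_latency <- function(phase_rad, f_hz) {
  if (any(f_hz <= 0)) stop("frequency must be positive", call. = FALSE)
  phase_rad / (2 * pi * f_hz)
}

#' @rdname phase_to_latency
#' @param latency_s latency in seconds.
#' @return `latency_to_phase`: phase in radians.
#' @export
latency_to_phase <- function(latency_s, f_hz) {
  if (any(f_hz <= 0)) stop("frequency must be positive", call. = FALSE)
  2 * pi * f_hz * latency_s
}
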