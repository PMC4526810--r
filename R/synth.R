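#' Synthesize a melody as an audio waveform
#'
#' Renders each note as a harmonic complex tone (fundamental plus
#' `n_harmonics` overtones with 1/k amplitude roll-off) at its equal-tempered
#' frequency, shaped by a short linear attack followed by an exponential decay
#' confined to the note's beat slot. Because every note carries the same
#' attack-decay envelope, the waveform envelope is periodic at the beat
#' frequency, which is what tags the cortical steady-state response.
#'
#' @param seq a [note_sequence()].
#' @param sample_rate_hz audio sampling rate (default 8000; any rate above
#'   twice the highest rendered harmonic is adequate).
#' @param attack_s linear attack time in seconds (default 0.01).
#' @param decay_tau_s exponential decay time constant in seconds; default is
#'   one third of the beat slot.
#' @param n_harmonics number of harmonics above the fundamental (default 3).
#' @param target_rms root-mean-square amplitude of the returned waveform
#'   (default 0.1); `0` yields an all-zero waveform.
#' @return Numeric waveform of exactly
#'   `n_notes / beat_frequency_hz * sample_rate_hz` samples.
#' @export
synthesize_audio <- function(seq, sample_rate_hz = 8000, attack_s = 0.01,
                             decay_tau_s = NULL, n_harmonics = 3,
                             target_rms = 0.1) {
  stopifnot(inherits(seq, "note_sequence"))
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number", call. = FALSE)
  }
  slot_s <- 1 / seq$beat_frequency_hz
  if (round(slot_s * sample_rate_hz) < 2) {
    stop("sample rate too low for the beat slot", call. = FALSE)
  }
  if (is.null(decay_tau_s)) decay_tau_s <- slot_s / 3
  n_notes <- nrow(seq$notes)
  total_n <- round(n_notes * slot_s * sample_rate_hz)
  # slot boundaries rounded per note so the total length is exact even when
  # the beat period is not a whole number of samples
  bounds <- round((0:n_notes) * slot_s * sample_rate_hz)

  wave <- numeric(total_n)
  freqs <- midi_to_hz(seq$notes$pitch)
  for (i in seq_len(n_notes)) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    t_slot <- (seq_along(idx) - 1) / sample_rate_hz
    shape <- pmin(t_slot / attack_s, 1) *
      exp(-pmax(t_slot - attack_s, 0) / decay_tau_s)
    tone <- numeric(length(idx))
    for (k in seq_len(n_harmonics + 1L)) {
      tone <- tone + sin(2 * pi * k * freqs[i] * t_slot) / k
    }
    wave[idx] <- shape * tone
  }
  rms <- sqrt(mean(wave^2))
  if (target_rms == 0 || rms == 0) return(numeric(total_n))
  wave * (target_rms / rms)
}

#' Convert MIDI pitch to frequency
#' @param pitch MIDI pitch number(s); 69 maps to 440 Hz.
#' @return Frequency in Hz under equal temperament.
#' @export
midi_to_hz <- function(pitch) 440 * 2^((pitch - 69) / 12)

#' Amplitude envelope via the analytic signal
#'
#' Computes the magnitude of the analytic signal (the Hilbert envelope) of a
#' waveform. For a narrow-band carrier the envelope recovers the amplitude
#' modulator; for the melodic stimuli it carries the 6-Hz beat structure.
#'
#' @param waveform finite numeric vector.
#' @param sample_rate_hz sampling rate of the waveform.
#' @return An object of class `envelope`: list with `samples` (non-negative
#'   amplitudes, same length as the input) and `sample_rate_hz`.
#' @export
compute_envelope <- function(waveform, sample_rate_hz) {
  if (length(waveform) == 0L) stop("empty waveform", call. = FALSE)
  if (!all(is.finite(waveform))) stop("waveform must be finite", call. = FALSE)
  env <- Mod(analytic_signal(waveform))
  structure(list(samples = env, sample_rate_hz = sample_rate_hz),
            class = "envelope")
}

# Analytic signal by one-sided spectrum doubling: positive frequencies are
# doubled, negative zeroed, DC and (for even length) Nyquist kept.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
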