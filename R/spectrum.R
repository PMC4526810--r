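#' Segment-averaged amplitude spectrum
#'
#' Cuts a signal into consecutive non-overlapping segments (1 s by default),
#' computes the single-sided amplitude spectrum of each segment with a
#' rectangular window, and returns the per-bin mean and standard error of the
#' mean over segments. The amplitude normalization is such that a sinusoid of
#' amplitude A at an exact bin frequency yields bin amplitude A. A two-minute
#' stimulus envelope analysed with 1-s segments gives 120 segments and 1-Hz
#' bin spacing, so a 6-Hz beat falls on an exact bin.
#'
#' @param signal numeric vector, or an `envelope` from [compute_envelope()]
#'   (in which case `sample_rate_hz` is taken from it).
#' @param sample_rate_hz sampling rate of `signal`.
#' @param segment_seconds segment length in seconds (default 1).
#' @return An object of class `amplitude_spectrum`: list with `freqs_hz`,
#'   `mean_amplitude`, `sem_amplitude` and `n_segments`.
#' @export
segmented_spectrum <- function(signal, sample_rate_hz = NULL,
                               segment_seconds = 1) {
  if (inherits(signal, "envelope")) {
    sample_rate_hz <- signal$sample_rate_hz
    signal <- signal$samples
  }
  if (is.null(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive", call. = FALSE)
  }
  seg_n <- round(segment_seconds * sample_rate_hz)
  n_seg <- as.integer(length(signal) %/% seg_n)
  if (n_seg < 1L) {
    stop("signal shorter than one segment", call. = FALSE)
  }
  segs <- matrix(signal[seq_len(seg_n * n_seg)], nrow = seg_n, ncol = n_seg)
  coef <- stats::mvfft(segs)
  n_bins <- floor(seg_n / 2) + 1L
  amp <- Mod(coef[seq_len(n_bins), , drop = FALSE]) * (2 / seg_n)
  amp[1L, ] <- amp[1L, ] / 2  # DC carries no conjugate bin
  if (seg_n %% 2 == 0) amp[n_bins, ] <- amp[n_bins, ] / 2  # Nyquist likewise
  mean_amp <- rowMeans(amp)
  sem <- if (n_seg > 1L) {
    apply(amp, 1L, stats::sd) / sqrt(n_seg)
  } else {
    rep(0, n_bins)
  }
  structure(
    list(
      freqs_hz = (seq_len(n_bins) - 1L) * sample_rate_hz / seg_n,
      mean_amplitude = mean_amp,
      sem_amplitude = sem,
      n_segments = n_seg
    ),
    class = "amplitude_spectrum"
  )
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf(
    "<amplitude_spectrum> %d bins (0-%.6g Hz), mean over %d segments\n",
    length(x$freqs_hz), max(x$freqs_hz), x$n_segments
  ))
  invisible(x)
}

#' Test two segment-averaged spectra for equivalence at chosen frequencies
#'
#' Declares two spectra equivalent at a frequency when the difference of the
#' mean amplitudes lies within `k_sem` pooled standard errors, i.e.
#' `|mean_a - mean_b| <= k_sem * sqrt(sem_a^2 + sem_b^2)`. Used to verify that
#' a scrambled melody retains the original's envelope spectrum at the beat
#' frequency and its harmonics.
#'
#' @param a,b `amplitude_spectrum` objects sharing the same frequency bins.
#' @param test_freqs_hz frequencies at which to test; defaults to 6, 12 and
#'   18 Hz (beat frequency and first two harmonics).
#' @param k_sem equivalence threshold in pooled-SEM units (default 2,
#'   approximately 95% pointwise coverage).
#' @return A data frame with one row per tested frequency: `freq_hz`,
#'   `mean_a`, `sem_a`, `mean_b`, `sem_b`, `diff`, `tolerance`, `margin`
#'   (`abs(diff) - tolerance`, negative when within the noise) and
#'   `equivalent`.
#' @export
spectra_equivalent <- function(a, b, test_freqs_hz = c(6, 12, 18), k_sem = 2) {
  stopifnot(inherits(a, "amplitude_spectrum"), inherits(b, "amplitude_spectrum"))
  if (length(a$freqs_hz) != length(b$freqs_hz) ||
      max(abs(a$freqs_hz - b$freqs_hz)) > 1e-9) {
    stop("spectra do not share frequency bins", call. = FALSE)
  }
  idx <- vapply(test_freqs_hz, function(f) which.min(abs(a$freqs_hz - f)), 1L)
  diff <- a$mean_amplitude[idx] - b$mean_amplitude[idx]
  tol <- k_sem * sqrt(a$sem_amplitude[idx]^2 + b$sem_amplitude[idx]^2)
  data.frame(
    freq_hz = a$freqs_hz[idx],
    mean_a = a$mean_amplitude[idx],
    sem_a = a$sem_amplitude[idx],
    mean_b = b$mean_amplitude[idx],
    sem_b = b$sem_amplitude[idx],
    diff = diff,
    tolerance = tol,
    margin = abs(diff) - tol,
    equivalent = abs(diff) <= tol
  )
}
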