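# A minimal one- or few-channel recording with known sinusoids.
make_rec <- function(signals, fs = 250, labels = NULL) {
  data <- do.call(rbind, signals)
  eeg_recording(data, sample_rate_hz = fs,
                channel_labels = labels %||% default_montage()[seq_along(signals)])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("channel spectrum recovers exact-bin amplitude and phase", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  rec <- make_rec(list(2e-6 * cos(2 * pi * 6 * t + 0.8)))
  sp <- channel_spectrum(rec)
  bin6 <- which.min(abs(sp$freqs_hz - 6))
  expect_equal(unname(sp$amplitude[1, bin6]), 2e-6, tolerance = 1e-12)
  expect_equal(unname(Arg(sp$coefficients[1, bin6])), 0.8, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[1, -c(1, bin6)]), 1e-15)

  # linearity: two exact-bin sinusoids both recovered
  rec2 <- make_rec(list(3 * cos(2 * pi * 6 * t) + 0.5 * cos(2 * pi * 11 * t)))
  sp2 <- channel_spectrum(rec2)
  expect_equal(unname(sp2$amplitude[1, which.min(abs(sp2$freqs_hz - 6))]), 3,
               tolerance = 1e-9)
  expect_equal(unname(sp2$amplitude[1, which.min(abs(sp2$freqs_hz - 11))]), 0.5,
               tolerance = 1e-9)

  bad <- rec
  bad$data[1, 5] <- NA
  expect_error(channel_spectrum(bad), "NA")
})

test_that("artifact screening flags injected spikes and passes clean data", {
  cfg <- fast_config(seed = 3)
  rec <- simulate_recording(cfg, "original", 1, 1)$recording
  rep_clean <- screen_artifacts(rec)
  expect_identical(rep_clean$verdict, "pass")
  expect_true(all(rep_clean$flagged_fraction < 1e-3))

  inj <- inject_spikes(rec, n_spikes = 10, amplitude = 20, seed = 9)
  rep_spk <- screen_artifacts(inj$recording)
  # recall: every injected sample exceeds the MAD threshold
  for (ch in default_montage()) {
    i <- match(ch, inj$recording$channel_labels)
    dev <- abs(inj$recording$data[i, ] - median(inj$recording$data[i, ]))
    thr <- 8 * mad(inj$recording$data[i, ])
    expect_true(all(dev[inj$positions[[ch]]] > thr))
  }

  zero <- make_rec(list(numeric(2 * 250), numeric(2 * 250)))
  expect_warning(rep0 <- screen_artifacts(zero), "degenerate")
  expect_identical(rep0$verdict, "pass")
  expect_setequal(rep0$degenerate_channels, zero$channel_labels)
})

test_that("beat-responsive criterion thresholds at mean + k SD of neighbors", {
  # constructed spectrum: neighbors with known mean/SD, beat bin adjustable
  freqs <- seq(0, 20, by = 0.05)
  bin6 <- which.min(abs(freqs - 6))
  nb <- which(freqs >= 5 & freqs <= 7 & abs(freqs - 6) > 0.1)
  set.seed(1)
  base <- abs(rnorm(length(freqs), 1, 0.2))
  mk_spec <- function(beat_amp) {
    amp <- rbind(base)
    amp[1, bin6] <- beat_amp
    structure(list(freqs_hz = freqs, amplitude = amp,
                   coefficients = amp + 0i, channel_labels = "Fz",
                   sample_rate_hz = 250),
              class = "channel_spectrum")
  }
  m <- mean(base[nb]); s <- sd(base[nb])
  expect_identical(
    as.character(beat_responsive_channels(mk_spec(m + 3 * s))), "Fz")
  expect_length(beat_responsive_channels(mk_spec(m + 1 * s)), 0)

  flat <- mk_spec(5)
  flat$amplitude[1, nb] <- 1
  expect_warning(res <- beat_responsive_channels(flat), "zero-variance")
  expect_length(res, 0)

  narrow <- mk_spec(5)
  expect_error(
    beat_responsive_channels(narrow, band_hz = c(5.9, 6.1),
                             exclusion_halfwidth_hz = 0.09),
    "neighbor bins")
})

test_that("ground-truth signal channels are recovered at high SNR", {
  # per-channel beat-bin SNR >= 5 by construction; recall over 100 seeds
  miss <- 0L
  for (s in 1:100) {
    cfg <- synthetic_config(duration_s = 30, sample_rate_hz = 250,
                            base_amplitude = 4e-6, seed = s)
    rec <- simulate_recording(cfg, "original", 1, 1)$recording
    resp <- beat_responsive_channels(channel_spectrum(rec))
    miss <- miss + (13L - length(resp))
  }
  expect_gte(1 - miss / (13 * 100), 0.99)
})

test_that("averaged beat response summarizes amplitude and phase", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  x <- cos(2 * pi * 6 * t)
  rec1 <- make_rec(list(x))
  s1 <- average_beat_response(rec1, "Fpz")
  expect_equal(s1$mean_amplitude, 1, tolerance = 1e-12)
  expect_equal(s1$sem_amplitude, 0, tolerance = 1e-12)
  expect_equal(s1$mean_phase, 0, tolerance = 1e-9)
  expect_identical(s1$n_segments, 20L)

  # averaging two identical channels changes nothing
  rec2 <- make_rec(list(x, x))
  s2 <- average_beat_response(rec2, c("Fpz", "F5"))
  expect_equal(s2$mean_amplitude, s1$mean_amplitude)
  expect_equal(s2$per_segment_coefficients, s1$per_segment_coefficients)

  expect_error(average_beat_response(rec1, character(0)), "empty")
  expect_error(average_beat_response(rec1, "Cz"), "not present")
})

test_that("amplitude averaging matches the Rice mean under segment noise", {
  fs <- 250
  dur <- 400
  t <- (0:(dur * fs - 1)) / fs
  A <- 1
  sigma_t <- 2
  set.seed(7)
  rec <- make_rec(list(A * cos(2 * pi * 6 * t) + rnorm(dur * fs, sd = sigma_t)),
                  fs = fs)
  s <- average_beat_response(rec, "Fpz")
  # white noise of variance sigma_t^2: per-segment quadrature SD at one bin
  sigma_q <- sigma_t * sqrt(2 / fs)
  expected <- rice_mean(A, sigma_q)
  mc_se <- sd(s$per_segment_amplitude) / sqrt(s$n_segments)
  expect_lt(abs(s$mean_amplitude - expected), 4 * mc_se)

  # the complex-mean mode is smaller (noise cancels instead of rectifying)
  s2 <- average_beat_response(rec, "Fpz", amplitude_mode = "complex_mean")
  expect_lt(s2$mean_amplitude, s$mean_amplitude)
})

test_that("beat extraction ignores signals on distant bins", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  base <- 2 * cos(2 * pi * 6 * t + 1.1)
  clutter <- 5 * cos(2 * pi * 9 * t) + 3 * cos(2 * pi * 2 * t + 0.4)
  s0 <- average_beat_response(make_rec(list(base)), "Fpz")
  s1 <- average_beat_response(make_rec(list(base + clutter)), "Fpz")
  expect_equal(s1$mean_amplitude, s0$mean_amplitude, tolerance = 1e-9)
  expect_equal(s1$mean_phase, s0$mean_phase, tolerance = 1e-9)
})

test_that("circular delay shifts the phase by exactly 2 pi f dt", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  x <- cos(2 * pi * 6 * t + 0.9)
  d <- 17                                   # samples of circular delay
  y <- c(x[(length(x) - d + 1):length(x)], x[1:(length(x) - d)])
  p0 <- average_beat_response(make_rec(list(x)), "Fpz")$mean_phase
  p1 <- average_beat_response(make_rec(list(y)), "Fpz")$mean_phase
  expect_lt(phase_error(p1, p0 - 2 * pi * 6 * d / fs), 1e-9)
})

test_that("segment-mean amplitude equals the full-length amplitude when noiseless", {
  cfg <- fast_config(noise_rms = 0, trial_cv = 0)
  rec <- simulate_recording(cfg, "original", 1, 1)$recording
  s <- average_beat_response(rec, default_montage())
  sp <- channel_spectrum(eeg_recording(rbind(colMeans(rec$data)),
                                       sample_rate_hz = 250,
                                       channel_labels = "Fz"))
  full_amp <- unname(sp$amplitude[1, which.min(abs(sp$freqs_hz - 6))])
  expect_equal(s$mean_amplitude, full_amp, tolerance = 1e-9)
})

test_that("KS normality check accepts Gaussian and rejects Cauchy quadratures", {
  set.seed(10)
  cover <- vapply(1:200, function(i) {
    z <- complex(real = rnorm(120), imaginary = rnorm(120))
    p <- ks_normality(z)
    p$p_real > 0.05 && p$p_imag > 0.05
  }, logical(1))
  expect_gte(mean(cover), 0.9)

  rejects <- vapply(1:100, function(i) {
    z <- complex(real = rcauchy(120), imaginary = rcauchy(120))
    p <- ks_normality(z)
    p$p_real < 0.05 && p$p_imag < 0.05
  }, logical(1))
  expect_gte(mean(rejects), 0.9)

  expect_error(ks_normality(rep(1 + 1i, 30)), "zero variance")
  expect_error(ks_normality(complex(real = rnorm(10), imaginary = rnorm(10))),
               "at least 20")
})

test_that("phase-latency conversion is exact and invertible", {
  expect_equal(phase_to_latency(0, 10), 0)
  expect_equal(phase_to_latency(pi, 0.5), 1.0)
  expect_equal(latency_to_phase(phase_to_latency(2.2, 6), 6), 2.2)
  expect_error(phase_to_latency(1, 0), "positive")
  expect_error(latency_to_phase(1, -2), "positive")
})
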