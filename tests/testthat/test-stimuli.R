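test_that("scrambling permutes whole segments and conserves structure", {
  seq4 <- note_sequence(c(60, 62, 64, 65), name = "toy")

  # fixed segment length 2 forces the partition [2, 2]; the only possible
  # outputs are the identity and the segment swap
  outs <- vapply(1:40, function(s) {
    paste(sequence_pitches(
      scramble_notes(seq4, scramble_spec(2, 2, seed = s))), collapse = ",")
  }, character(1))
  expect_true(all(outs %in% c("60,62,64,65", "64,65,60,62")))
  expect_true("64,65,60,62" %in% outs)

  # a 2-note sequence admits only one partition: output equals input
  seq2 <- note_sequence(c(71, 59))
  expect_identical(
    sequence_pitches(scramble_notes(seq2, scramble_spec(2, 6, seed = 1))),
    c(71L, 59L)
  )

  # onset beats renumbered from 0, durations all one beat
  scr <- scramble_notes(melody("ode_to_joy"), scramble_spec(seed = 7))
  expect_identical(scr$notes$onset_beat, seq_len(nrow(scr$notes)) - 1L)
  expect_true(all(scr$notes$duration_beats == 1))

  expect_error(scramble_notes(note_sequence(60), scramble_spec(2, 6)),
               "fewer notes")
})

test_that("scrambling conserves count, pitch multiset, duration and beat rate", {
  for (name in melody_names()) {
    orig <- melody(name)
    for (seed in 1:20) {
      scr <- scramble_notes(orig, scramble_spec(seed = seed))
      expect_identical(length(scr), length(orig))
      expect_identical(sort(sequence_pitches(scr)), sort(sequence_pitches(orig)))
      expect_equal(sequence_duration(scr), sequence_duration(orig))
      expect_equal(scr$beat_frequency_hz, orig$beat_frequency_hz)
    }
  }
})

test_that("segment partition respects the length bounds", {
  # reconstruct the partition indirectly: scrambled output of a strictly
  # increasing pitch ramp decomposes into maximal ascending runs = segments
  ramp <- note_sequence(10:89)
  for (seed in 1:10) {
    scr <- sequence_pitches(scramble_notes(ramp, scramble_spec(2, 6, seed = seed)))
    runs <- rle(cumsum(c(1, diff(scr) != 1)))$lengths
    # every run except possibly one remainder is within [2, 6]; adjacent
    # segments can merge into longer ascending runs, so runs may exceed 6
    # only as sums of valid lengths >= 2
    expect_true(sum(runs) == 80)
    expect_lte(sum(runs < 2), 1)
  }
})

test_that("pitch-change statistics follow the equal-temperament formula", {
  expect_equal(pitch_change_stats(note_sequence(c(60, 60, 60)))$mean, 0)
  expect_equal(pitch_change_stats(note_sequence(c(60, 60, 60)))$sd, 0)
  expect_equal(pitch_change_stats(note_sequence(c(60, 72)))$mean, 1.0)
  expect_equal(pitch_change_stats(note_sequence(c(60, 61)))$mean,
               2^(1 / 12) - 1, tolerance = 1e-12)
  expect_error(pitch_change_stats(note_sequence(60)), "two notes")

  # invariant under global transposition and under time reversal
  base <- melody("fur_elise", duration_s = NULL)
  ref <- pitch_change_stats(base)
  trans <- note_sequence(sequence_pitches(base) + 7)
  rev <- note_sequence(rev(sequence_pitches(base)))
  expect_equal(pitch_change_stats(trans)$mean, ref$mean)
  expect_equal(pitch_change_stats(trans)$sd, ref$sd)
  expect_equal(pitch_change_stats(rev)$mean, ref$mean)
  expect_equal(pitch_change_stats(rev)$sd, ref$sd)

  # scrambling only reshuffles intervals at segment junctions, so the mean
  # relative pitch change stays close to the original's
  for (nm in melody_names()) {
    orig <- melody(nm)
    scr <- scramble_notes(orig, scramble_spec(seed = 11))
    expect_lt(abs(pitch_change_stats(scr)$mean - pitch_change_stats(orig)$mean),
              0.05)
  }
})

test_that("audio synthesis has the right length, gain behavior and pitch", {
  seq12 <- note_sequence(rep(69, 12))
  w <- synthesize_audio(seq12, sample_rate_hz = 44100)
  expect_length(w, 2 * 44100)

  expect_identical(synthesize_audio(seq12, sample_rate_hz = 8000,
                                    target_rms = 0),
                   numeric(8000 / 6 * 12))

  # a single A4 note: dominant spectral peak at 440 Hz (FFT peak-pick oracle)
  w1 <- synthesize_audio(note_sequence(69), sample_rate_hz = 8000)
  spec <- Mod(fft(w1))[1:(length(w1) %/% 2)]
  f_peak <- (which.max(spec) - 1) * 8000 / length(w1)
  expect_lt(abs(f_peak - 440), 8000 / length(w1) + 1e-9)

  expect_error(synthesize_audio(seq12, sample_rate_hz = -1), "positive")
})

test_that("Hilbert envelope recovers amplitude and modulator", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  env <- compute_envelope(3 * cos(2 * pi * 50 * t), fs)
  mid <- env$samples[(fs):(3 * fs)]
  expect_true(all(abs(mid - 3) < 1e-6))

  expect_equal(compute_envelope(numeric(100), fs)$samples, numeric(100))

  # AM carrier: envelope matches the known modulator within 1%
  m <- 0.5
  modulator <- 1 + m * cos(2 * pi * 6 * t)
  x <- modulator * cos(2 * pi * 100 * t)
  env <- compute_envelope(x, fs)$samples
  inner <- (fs + 1):(3 * fs)
  expect_lt(max(abs(env[inner] - modulator[inner])) / max(modulator), 0.01)

  expect_error(compute_envelope(numeric(0), fs), "empty")
  expect_error(compute_envelope(c(1, NA), fs), "finite")
})

test_that("segmented spectrum is correctly normalized and averaged", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs

  # exact-bin sinusoid: amplitude recovered to 1e-9, SEM zero
  sp <- segmented_spectrum(cos(2 * pi * 6 * t), fs)
  expect_identical(sp$n_segments, 10L)
  bin6 <- which.min(abs(sp$freqs_hz - 6))
  expect_equal(sp$mean_amplitude[bin6], 1, tolerance = 1e-9)
  expect_lt(sp$sem_amplitude[bin6], 1e-9)

  # white noise: SEM equals the independently recomputed per-bin SD/sqrt(n)
  set.seed(42)
  x <- rnorm(20 * fs)
  sp <- segmented_spectrum(x, fs)
  segs <- matrix(x, nrow = fs)
  amps <- apply(segs, 2, function(s) Mod(fft(s))[2:(fs / 2)] * 2 / fs)
  expect_equal(sp$sem_amplitude[2:(fs / 2)],
               apply(amps, 1, sd) / sqrt(20), tolerance = 1e-12)

  expect_error(segmented_spectrum(rnorm(50), fs), "shorter")
})

test_that("spectrum equivalence report flags only inflated bins", {
  fs <- 120
  t <- (0:(30 * fs - 1)) / fs
  set.seed(1)
  x <- cos(2 * pi * 6 * t) + rnorm(length(t), sd = 0.5)
  a <- segmented_spectrum(x, fs)

  rep_same <- spectra_equivalent(a, a)
  expect_true(all(rep_same$equivalent))
  expect_true(all(rep_same$diff == 0))

  b <- a
  bin6 <- which.min(abs(a$freqs_hz - 6))
  b$mean_amplitude[bin6] <- a$mean_amplitude[bin6] +
    10 * sqrt(2) * a$sem_amplitude[bin6]
  rep_mod <- spectra_equivalent(a, b, test_freqs_hz = c(6, 12, 18))
  expect_false(rep_mod$equivalent[rep_mod$freq_hz == 6])
  expect_true(all(rep_mod$equivalent[rep_mod$freq_hz != 6]))

  short <- segmented_spectrum(rnorm(5 * 100), 100)
  expect_error(spectra_equivalent(a, short), "share")
})
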