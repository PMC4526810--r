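---
title: "Measuring the cortical response to the beat of music: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the cortical response to the beat of music: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatassr)
```

## The measurement problem

When a melody is played with one note on every beat, the beat rate dominates
the amplitude envelope of the sound, and the auditory cortex produces a
steady-state response (ASSR) at exactly that frequency. Because the
stimulation frequency is known — 6 Hz throughout this package — the neural
response can be read off a single spectral bin of the EEG, which makes the
paradigm usable with a handful of electrodes and two-minute recordings. The
scientific questions the pipeline addresses are whether this frequency-tagged
response is modulated by *comprehension* (a familiar tune versus a scrambled,
non-sensical rearrangement of the same notes) and by *attention* (listening
to the music versus ignoring it while reading), and whether those modulations
can be decoded from single trials.

`beatassr` implements the full chain: stimulus construction and scrambling,
beat-frequency response extraction from 13-channel EEG, a three-level
statistical ladder, difference-feature classification, and a synthetic-EEG
generator with known ground truth against which every stage is validated.

## Stimuli: scrambling that preserves low-level structure

A stimulus is a `note_sequence`: MIDI pitches at consecutive integer beats,
one note per beat, 6 beats per second, 720 notes for a two-minute
presentation. Four public-domain themes (Für Elise, Eine Kleine Nachtmusik,
Ode to Joy, Twinkle Twinkle Little Star) are encoded as built-in fixtures;
the themes are tiled to the target duration. The exact note-level edits used
in any particular experiment are not reproducible from a published score, so
these fixtures are *stand-ins with the same structural properties* (single
line, one note per beat, centered pitch range), not copies of any original
stimulus set.

`scramble_notes()` cuts the score into segments whose lengths are drawn
uniformly from 2–6 notes and permutes the segments uniformly at random. Two
choices here were genuinely open and are resolved as follows:

* **Remainder segment.** When the note count does not partition exactly into
  lengths 2–6, the final segment may be shorter than 2. This preserves every
  note; all full segments respect the bounds.
* **Sampling distributions.** Segment lengths are i.i.d. uniform over
  `{2,…,6}` drawn until the score is exhausted, and the permutation of
  segments is uniform. No other distribution is singled out by the design,
  and uniform is the minimal-assumption choice.

Scrambling provably conserves the note count, pitch multiset, total duration
and beat frequency (asserted over all four fixtures × 20 seeds in the test
suite). Two diagnostics verify that it also leaves *low-level* stimulus
structure intact:

1. **Envelope spectra.** `synthesize_audio()` renders each note as a harmonic
   complex (fundamental + 3 harmonics, 1/k roll-off) with a 10-ms attack and
   an exponential decay (time constant = one third of the beat slot) confined
   to its beat slot — a reproducible approximation of struck notes with a
   strong 6-Hz envelope component. `compute_envelope()` takes the magnitude
   of the analytic signal, and `segmented_spectrum()` averages 1-s rectangular
   windowed amplitude spectra (120 segments for a two-minute stimulus, so
   6 Hz is an exact bin and the estimator is unbiased there).
   `spectra_equivalent()` declares two spectra equivalent at a frequency when
   the mean difference is within `k_sem = 2` pooled standard errors
   (≈95% pointwise coverage — the operational meaning of "within the
   noise"). Original and scrambled fixtures pass at 6, 12 and 18 Hz.
2. **Pitch changes.** `pitch_change_stats()` computes, for each adjacent note
   pair, the frequency interval divided by the lower frequency, which is
   `2^(d/12) − 1` for a distance of `d` semitones. The literal per-pair
   definition is implemented. Note a subtlety: for strongly stepwise tunes
   (Ode to Joy, Twinkle) the new intervals created at segment junctions are
   systematically larger than the melodic steps they replace, so with ~700
   note pairs a two-sample t-test *can* detect scrambling even though the
   absolute change in the mean is small (< 0.05). The test suite therefore
   bounds the mean difference rather than asserting statistical
   indistinguishability, which depends on the interval structure of the
   particular melody.

## Beat-response extraction

`channel_spectrum()` computes the full-length DFT per channel with
single-sided normalization chosen so that a sinusoid `A·cos(2πft + φ)` at an
exact bin yields the complex coefficient `A·e^{iφ}`: amplitudes are read
directly in volts and phases follow the cosine convention (positive = lag,
reported in (−π, π]). No detrending, filtering or tapering is applied:
1-s analysis segments make 6 Hz an exact bin, and the recordings' native
0.1–100 Hz band needs no further shaping.

`beat_responsive_channels()` implements the channel criterion: a channel is
beat-responsive when its amplitude at 6 Hz exceeds the mean of the
neighboring 5–7 Hz bins by more than 2 of their standard deviations.
Neighbors are taken from the full-length spectrum (1/duration resolution),
excluding bins within 0.1 Hz of the beat; the SD is computed across neighbor
bins. On pure-noise recordings this criterion admits a channel falsely with
probability ≈ 0.04 (the amplitude of a Gaussian noise bin is Rayleigh, and
`P(R > μ_R + 2σ_R) = 0.037`, slightly inflated by threshold estimation),
which the acceptance suite verifies stays below 0.05 per channel.

`average_beat_response()` averages the selected channels' time series
sample-wise, cuts the average into 1-s segments, and extracts the 6-Hz
complex coefficient of each segment. The reported amplitude is the **mean of
the per-segment amplitude moduli** with its SEM across segments — the scalar
per-segment quantities that the downstream t-tests require. The alternative
(modulus of the complex mean, which cancels rather than rectifies noise) is
available via `amplitude_mode = "complex_mean"`. The phase is always the
argument of the mean complex coefficient. A consequence of the modulus mean
worth knowing: under additive noise its expectation is the Rice mean, which
exceeds the true amplitude by ≈ σ²/(2A); at the synthetic generator's
default signal-to-noise ratio this bias is ~1–2% and the acceptance suite
bounds it at 5%.

**Paired channel sets.** For the within-trial comparison, `analyze_pair()`
averages the *union* of the two recordings' beat-responsive channel sets, so
both summaries of a trial cover the same channels. If each recording used its
own set, a channel flipping in or out between the paired recordings would
move the average by a topography-dependent amount that has nothing to do
with the condition; in null simulations this leakage makes the population
test visibly conservative (type-I error ~0.01 instead of ~0.045). The
per-recording responsive sets are still reported. A trial in which *no*
channel is responsive in either recording is discarded, mirroring how a
non-responsive trial is handled in practice.

`ks_normality()` standardizes the real and imaginary parts of the
per-segment coefficients and tests each against the standard normal —
standardization is required because coefficients with signal present are not
zero-mean, and it makes the test conservative (parameters are estimated from
the data). `phase_to_latency()` converts the response phase to a time delay
(`τ = φ / 2πf`; 3.5 rad at 6 Hz ≈ 93 ms, consistent with cortical envelope-
tracking latencies near 100 ms).

Artifact screening (`screen_artifacts()`) replaces visual inspection with a
robust rule: samples deviating from the channel median by more than 8 MADs
are flagged, and a recording is marked for repetition when any channel has
more than 1% flagged samples. Both thresholds are configurable.

## The statistical ladder

Condition differences are always condition B minus condition A, where A is
the baseline presentation: **scrambled − original** for comprehension
(expected positive — the familiar tune evokes the weaker response) and
**ignored − attended** for attention (expected negative — attention enhances
the response).

* **Trial level**: per-segment amplitudes of the two recordings of a trial
  are paired by segment index (the only pairing the data admit) and compared
  with the classical paired t-test, two-tailed.
* **Subject level**: a one-tailed one-sample t-test on the subject's trial
  mean differences against zero, with the direction above; subjects need at
  least 2 trials (a discarded trial can leave 3 of 4).
* **Population level**: the same one-tailed test on the 8 subject means.

Zero-variance inputs are flagged as degenerate rather than silently returning
a p-value (identical arrays yield t = 0, p = 1; a nonzero constant difference
leaves p undefined). No multiple-testing correction is applied across trials
or subjects, matching how the three levels are conventionally reported;
`p.adjust` can be applied downstream if desired. Null simulations (effect
multiplier 1.0, 500 replicates of the full pipeline on 20-s recordings) show
the population-level test is calibrated (rejection rate ≈ 0.04, p-values
consistent with uniform).

## Classification

Per-trial feature vectors are the per-channel differences of the beat-bin
amplitudes between the paired recordings — differences, rather than raw
amplitudes, because slow baseline drift between trials cancels within a
pair. The mirrored category contains the sign-inverted rows, so the dataset
is antisymmetric by construction: column means are exactly zero and the LDA
boundary passes through the origin.

`lda_fit()` is the two-class pooled-covariance linear discriminant,
`w = S⁻¹(μ₊ − μ₋)` with the boundary midway between projected class means
(equal priors), ridge-stabilized by `ε·tr(S)/d` on the diagonal when the
pooled covariance is near-singular. `forward_select()` adds greedily the
channel that maximizes mean cross-validated LDA accuracy, stopping at
`max_features` (default 2, the wearable-EEG regime) or when no candidate
strictly improves; ties break in channel order, and all candidates within a
step are scored on identical partitions. The selection criterion is
cross-validated accuracy because accuracy is what the classifier is
ultimately reported on; the description of the selector as greedy forward
selection is taken at face value (no evolutionary search). `cross_validate()`
repeats 10-fold stratified partitions (default 100 iterations) and pools the
held-out correct fraction per iteration. A row and its mirrored copy are
always assigned to the same fold — the mirror is deterministic given its
partner, and splitting the pair would leak the training data into the test
fold. The trial-trained discriminant is then applied, unchanged, to the
subject-average rows (`evaluate_on_subject_averages()`); re-training at the
subject level is not performed.

One identifiability caveat: with a realistic frontal-dominant topography the
top channel gains are clustered (1.00, 0.95, 0.90, …), so which *particular*
high-gain channel is selected is tie-breaking noise — and once one channel
already separates the classes perfectly, selection stops before a second is
added. The meaningful, testable property is therefore that the selected
channels come from the high-gain frontal/central group, not that they are
exactly the two largest gains.

## The synthetic-EEG generator

`simulate_recording()` builds each channel as

```
base_amplitude × gain(ch) × condition_gain × trial_gain × cos(2π·6·t + φ)
  + 1/f^α noise band-limited to 0.1–100 Hz
```

with independent noise across channels (a shared-source option,
`noise_channel_correlation`, exists for robustness checks). The defaults are
the package's study conditions and were fixed once:

| parameter | default | rationale |
|---|---|---|
| subjects × trials | 8 × 4 | the experimental design being emulated |
| duration, rate | 120 s, 1000 Hz | acquisition parameters; both reducible |
| topography | Fz 1.00 … Oz 0.30 | frontal/central dominant, occipital minimum |
| `base_amplitude` | 2 µV | a strong, clean steady-state response; ~20× the noise in a 1/120-Hz bin, comfortably above the "several-fold over neighbors" regime |
| `noise_rms` | 5 µV | broadband background of an artifact-screened recording |
| `effect_multiplier` | 1.25 | condition gain ratio (scrambled/original, attended/ignored) |
| `trial_cv` | 0.2 | lognormal per-trial gain, shared by both recordings of a trial |
| `phase_rad` | 3.5 | ≈ 93-ms response latency at 6 Hz |
| α (noise exponent) | 1 | 1/f background |

The per-trial gain is shared within a pair deliberately: the paired design
exists to cancel slow state changes *between* trials, so within-trial
amplitude state is common to both recordings. Pink noise is synthesized
spectrally (complex Gaussian coefficients shaped by `f^(−α/2)` inside the
band, zero outside, Hermitian-symmetrized) and rescaled to the target RMS
exactly. Every recording is a deterministic function of
`(seed, subject, trial, condition)`.

**What the generator does and does not emulate.** It reproduces the
acquisition geometry (13-channel 10/10 montage, 0.1–100 Hz band), a
frontal-dominant scalp pattern, 1/f background, trial-to-trial amplitude
variability and multiplicative condition effects. It does **not** model
volume-conduction correlations (except optionally), eye-blink/EMG artifacts
(beyond optional injected spikes), non-sinusoidal or drifting responses, or
any relationship between the actual melody and the EEG — the stimulus and
recording modules are linked only by the beat frequency. Passing tests on
synthetic data therefore validate the *pipeline's statistics and recovery
properties*, not claims about real recordings; with a strong synthetic
effect, trial-level CV accuracies saturate near 100% rather than matching
any particular real-data accuracy.

## Numerical and scaling choices

* Amplitude normalization is checked to 1e-9 on exact-bin sinusoids;
  noiseless round trips (generator → extraction) recover amplitude and phase
  to 1e-9.
* Degenerate inputs (constant channels, zero-variance differences, empty
  channel sets, single-class training data) raise errors or are flagged
  explicitly — never silently coerced.
* Monte-Carlo problem sizes in the test-suite: experiment-level replicates
  run on 20-s recordings at 250 samples/s (the statistical calibration does
  not depend on duration or rate; 250 Hz keeps the full 0.1–100 Hz noise
  band below Nyquist); the 400-replicate effect-size sweep uses 10-s
  recordings; single-recording analyses (e.g. the channel-criterion
  calibration, 2500 pure-noise replicates) use the full 120 s so neighbor
  statistics have full resolution. The acceptance script runs the complete
  pipeline at the unreduced defaults.
* All randomness flows from explicit integer seeds; per-recording substreams
  are derived arithmetically from `(seed, subject, trial, condition)` and
  stay below 2³¹.

## Known limitations

* The EDF reader/writer covers plain EDF with a constant sampling rate (the
  subset the package writes); EDF+ annotations are not parsed.
* The MusicXML subset is part/measure/note/pitch/duration — enough to round-
  trip single-line one-note-per-beat scores, not general engraving.
* Melody fixtures are re-encodings of public-domain themes, not the original
  edited stimulus scores; pitch-change statistics differ across melodies
  (means ~0.08–0.24 here).
* Subject-average evaluation reuses trial-trained weights; with 8 subjects
  the subject-level accuracy is a coarse (multiples of 1/16) quantity.
* The statistical ladder treats segments as exchangeable within a recording;
  slow within-recording drift would violate this and is not modeled.
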