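#' Analysis-stage configuration
#'
#' Collects the tunable parameters of the analysis stages in one
#' serializable object (see [write_pipeline_config()]).
#'
#' @param beat_frequency_hz beat frequency in Hz (default 6).
#' @param neighbor_band_hz neighbor band for channel selection (default
#'   `c(5, 7)`).
#' @param k_sd channel-selection threshold in neighbor SDs (default 2).
#' @param exclusion_halfwidth_hz excluded zone around the beat bin (default
#'   0.1 Hz).
#' @param segment_seconds analysis segment length (default 1).
#' @param scramble_min,scramble_max scrambling segment bounds (defaults 2, 6).
#' @param max_features,folds,iterations,select_iterations classifier settings.
#' @param seed master seed for the classification stage.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(beat_frequency_hz = 6,
                            neighbor_band_hz = c(5, 7),
                            k_sd = 2,
                            exclusion_halfwidth_hz = 0.1,
                            segment_seconds = 1,
                            scramble_min = 2, scramble_max = 6,
                            max_features = 2, folds = 10, iterations = 100,
                            select_iterations = 20,
                            seed = 1) {
  cfg <- list(
    beat_frequency_hz = beat_frequency_hz,
    neighbor_band_hz = neighbor_band_hz,
    k_sd = k_sd,
    exclusion_halfwidth_hz = exclusion_halfwidth_hz,
    segment_seconds = segment_seconds,
    scramble_min = scramble_min, scramble_max = scramble_max,
    max_features = max_features, folds = folds, iterations = iterations,
    select_iterations = select_iterations,
    seed = seed
  )
  if (any(vapply(cfg, function(v) any(!is.finite(v)) || any(v <= 0), TRUE))) {
    stop("all pipeline_config settings must be positive numbers", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Analyse one recording: spectrum, channel selection, beat summary
#'
#' @param rec an [eeg_recording()].
#' @param config a [pipeline_config()].
#' @return List with `summary` (a `beat_summary`, `NULL` when no channel is
#'   beat-responsive), `responsive_channels`, `channel_amplitude` (named
#'   beat-bin amplitude of every montage channel, used as classification
#'   features) and `spectrum`.
#' @export
analyze_recording <- function(rec, config = pipeline_config()) {
  spec <- channel_spectrum(rec)
  responsive <- beat_responsive_channels(
    spec, f_beat_hz = config$beat_frequency_hz,
    band_hz = config$neighbor_band_hz, k_sd = config$k_sd,
    exclusion_halfwidth_hz = config$exclusion_halfwidth_hz
  )
  beat_bin <- which.min(abs(spec$freqs_hz - config$beat_frequency_hz))
  chan_amp <- spec$amplitude[, beat_bin]
  names(chan_amp) <- spec$channel_labels
  summary <- if (length(responsive) > 0L) {
    average_beat_response(rec, responsive,
                          f_beat_hz = config$beat_frequency_hz,
                          segment_seconds = config$segment_seconds)
  }
  list(summary = summary, responsive_channels = as.character(responsive),
       channel_amplitude = chan_amp, spectrum = spec)
}

#' Analyse both recordings of a trial pair
#'
#' Fills in `summary_a`, `summary_b`, `channel_amplitude_a` and
#' `channel_amplitude_b` of a [trial_pair()] from its raw recordings. The
#' within-trial amplitude comparison averages the union of the two
#' recordings' beat-responsive channel sets, so that both summaries of a
#' pair are computed over the same channels: averaging different channel
#' sets on the two sides would let the scalp topography, rather than the
#' condition, contribute to the paired difference. The per-recording
#' responsive sets are kept in `responsive_channels_a`/`_b`. A pair in which
#' neither recording has a beat-responsive channel is flagged
#' `responsive = FALSE` (such trials are discarded by
#' [run_experiment_pipeline()], mirroring the discard of a non-responsive
#' trial).
#'
#' @param pair a `trial_pair` carrying recordings.
#' @param config a [pipeline_config()].
#' @return The analysed `trial_pair`, with added fields
#'   `responsive_channels_a`, `responsive_channels_b`, `common_channels`
#'   and a logical `responsive`.
#' @export
analyze_pair <- function(pair, config = pipeline_config()) {
  stopifnot(inherits(pair, "trial_pair"))
  if (is.null(pair$recording_a) || is.null(pair$recording_b)) {
    stop("pair carries no recordings", call. = FALSE)
  }
  a <- analyze_recording(pair$recording_a, config)
  b <- analyze_recording(pair$recording_b, config)
  common <- union(a$responsive_channels, b$responsive_channels)
  common <- common[order(match(common, pair$recording_a$channel_labels))]
  if (length(common) > 0L) {
    pair$summary_a <- average_beat_response(
      pair$recording_a, common, f_beat_hz = config$beat_frequency_hz,
      segment_seconds = config$segment_seconds)
    pair$summary_b <- average_beat_response(
      pair$recording_b, common, f_beat_hz = config$beat_frequency_hz,
      segment_seconds = config$segment_seconds)
  }
  pair$channel_amplitude_a <- a$channel_amplitude
  pair$channel_amplitude_b <- b$channel_amplitude
  pair$responsive_channels_a <- a$responsive_channels
  pair$responsive_channels_b <- b$responsive_channels
  pair$common_channels <- common
  pair$responsive <- length(common) > 0L
  pair
}

#' Run the full experiment pipeline
#'
#' Orchestrates the analysis of a set of trial pairs end to end: per-recording
#' beat-response extraction, the three-level statistical ladder, and the
#' difference-feature classification with channel selection, repeated
#' cross-validation and subject-average evaluation. Pairs without
#' beat-responsive channels are reported and discarded. When `out_dir` is
#' given, the bundle is written out as JSON/CSV together with a provenance
#' record (configuration, its hash, seeds, package version).
#'
#' @param pairs list of `trial_pair`s with recordings (e.g. from
#'   [simulate_experiment()] or [load_experiment_dir()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return An object of class `pipeline_bundle`: list with `summaries`
#'   (long-format data frame), `ladder` (a `ladder_result`),
#'   `classification` (see [classify_experiment()]), `discarded_trials` and
#'   `provenance`.
#' @export
run_experiment_pipeline <- function(pairs, config = pipeline_config(),
                                    out_dir = NULL) {
  analysed <- lapply(pairs, analyze_pair, config = config)
  responsive <- vapply(analysed, function(p) isTRUE(p$responsive), TRUE)
  discarded <- lapply(analysed[!responsive], function(p) {
    list(subject = p$subject, trial = p$trial)
  })
  if (length(discarded)) {
    warning(sprintf("%d trial(s) without beat-responsive channels discarded",
                    length(discarded)), call. = FALSE)
  }
  analysed <- analysed[responsive]
  if (length(analysed) == 0L) {
    stop("no trial with beat-responsive channels in both recordings",
         call. = FALSE)
  }
  summaries <- summaries_table(analysed)
  ladder <- run_ladder(analysed)
  classification <- classify_experiment(
    analysed, max_features = config$max_features, folds = config$folds,
    iterations = config$iterations, seed = config$seed,
    select_iterations = config$select_iterations
  )
  bundle <- structure(
    list(
      summaries = summaries,
      ladder = ladder,
      classification = classification,
      discarded_trials = discarded,
      provenance = list(
        config = unclass(config),
        config_hash = config_hash(config),
        n_pairs = length(analysed),
        package_version = as.character(utils::packageVersion("beatassr"))
      )
    ),
    class = "pipeline_bundle"
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf("<pipeline_bundle> %d trial pairs (%s paradigm)\n",
              x$provenance$n_pairs, x$ladder$paradigm))
  print(x$ladder)
  cat(sprintf("  classifier: channels %s, trial CV accuracy %.3f, subject accuracy %.3f\n",
              paste(x$classification$selected_channels, collapse = "+"),
              x$classification$trial_accuracy,
              x$classification$subject_accuracy))
  invisible(x)
}

# Long-format summary table: one row per recording.
summaries_table <- function(analysed_pairs) {
  do.call(rbind, lapply(analysed_pairs, function(p) {
    row <- function(summ, amps, resp) {
      data.frame(
        subject = p$subject, trial = p$trial, paradigm = p$paradigm,
        condition = if (!is.null(summ$meta$condition)) summ$meta$condition
                    else NA_character_,
        mean_amplitude = summ$mean_amplitude,
        sem_amplitude = summ$sem_amplitude,
        mean_phase = summ$mean_phase,
        n_segments = summ$n_segments,
        n_responsive = length(resp),
        responsive_channels = paste(resp, collapse = "|")
      )
    }
    rbind(row(p$summary_a, p$channel_amplitude_a, p$responsive_channels_a),
          row(p$summary_b, p$channel_amplitude_b, p$responsive_channels_b))
  }))
}

# Stable hash of a configuration: md5 of its canonical JSON serialization.
config_hash <- function(config) {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             path)
  unname(tools::md5sum(path))
}
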