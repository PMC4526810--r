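#' Read an EEG recording from file
#'
#' Dispatches on the file extension: `.edf` is read with the built-in
#' minimal EDF reader, anything else as a delimited matrix (see
#' [read_eeg_csv()]). Voltages are normalized to volts.
#'
#' @param path file path.
#' @param ... passed to the format-specific reader.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, ...) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_edf(path, ...)
  } else {
    read_eeg_csv(path, ...)
  }
}

#' Write an EEG recording to file
#' @param rec an [eeg_recording()].
#' @param path destination; `.edf` selects EDF, otherwise a delimited matrix.
#' @param ... passed to the format-specific writer.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, ...) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(rec, path, ...)
  } else {
    write_eeg_csv(rec, path, ...)
  }
}

#' Delimited-matrix EEG files
#'
#' The dialect is auto-detected: the first row must carry the channel labels,
#' and when the first column is named `time` it holds the time axis in
#' seconds (used to infer the sampling rate); otherwise `sample_rate_hz`
#' must be supplied. Comma and tab separators are recognized from the
#' extension (`.tsv` = tab).
#'
#' @param path file path.
#' @param sample_rate_hz sampling rate, required when the file has no time
#'   column.
#' @param units `"V"` (default) or `"uV"`; microvolt files are scaled by
#'   1e-6 on reading.
#' @param meta metadata list attached to the recording.
#' @return An [eeg_recording()].
#' @export
read_eeg_csv <- function(path, sample_rate_hz = NULL, units = c("V", "uV"),
                         meta = list()) {
  units <- match.arg(units)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (tolower(names(df)[1]) == "time") {
    tcol <- df[[1]]
    df <- df[-1]
    if (is.null(sample_rate_hz)) {
      sample_rate_hz <- 1 / stats::median(diff(tcol))
    }
  } else if (is.null(sample_rate_hz)) {
    stop("file has no time column; supply sample_rate_hz", call. = FALSE)
  }
  data <- t(as.matrix(df))
  if (units == "uV") data <- data * 1e-6
  unknown <- setdiff(rownames(data), default_montage())
  if (length(unknown)) {
    warning("channel label(s) outside the 10/10 montage kept as-is: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  eeg_recording(data, sample_rate_hz = sample_rate_hz,
                channel_labels = rownames(data), meta = meta)
}

#' @rdname read_eeg_csv
#' @param rec an [eeg_recording()].
#' @param time_column write a leading `time` column in seconds (default
#'   TRUE).
#' @return `write_eeg_csv`: `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path, units = c("V", "uV"),
                          time_column = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  units <- match.arg(units)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  scale <- if (units == "uV") 1e6 else 1
  df <- as.data.frame(t(rec$data) * scale)
  names(df) <- rec$channel_labels
  if (time_column) {
    df <- cbind(time = (seq_len(ncol(rec$data)) - 1) / rec$sample_rate_hz, df)
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Minimal EDF (European Data Format) support ----------------------------
# Plain EDF, one data record per second, 16-bit little-endian samples with
# per-signal physical scaling in microvolts. No pre-installed R package reads
# EDF, so a minimal reader/writer for this subset is provided here.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write an EEG recording as EDF
#'
#' Writes plain EDF with one-second data records and 16-bit samples scaled
#' per channel in microvolts. The recording duration must be an integer
#' number of seconds.
#'
#' @param rec an [eeg_recording()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF export needs an integer sampling rate", call. = FALSE)
  }
  fs <- round(fs)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1L || ncol(rec$data) != n_rec * fs) {
    stop("EDF export needs a whole number of seconds", call. = FALSE)
  }
  ns <- nrow(rec$data)
  uv <- rec$data * 1e6
  pmax_ <- apply(abs(uv), 1L, max)
  pmax_[pmax_ == 0] <- 1
  dig <- round(sweep(uv, 1L, pmax_ / 32767, "/"))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    .edf_pad("0", 8), .edf_pad("synthetic subject", 80),
    .edf_pad("beatassr export", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(hdr_bytes, 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(1, 8), .edf_pad(ns, 4)
  ), con, eos = NULL)
  field <- function(values, width) {
    writeChar(paste(vapply(values, .edf_pad, "", width = width),
                    collapse = ""), con, eos = NULL)
  }
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.6g", -pmax_), 8)
  field(sprintf("%.6g", pmax_), 8)
  field(rep(-32767, ns), 8)
  field(rep(32767, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read a plain EDF file
#'
#' Reads the EDF subset written by [write_edf()] (and generally any plain
#' EDF with a constant sampling rate across signals). Values are scaled to
#' volts using the per-signal physical dimension (`uV`, `mV` or `V`).
#'
#' @param path EDF file path.
#' @param meta metadata list attached to the recording.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, meta = list()) {
  size <- file.info(path)$size
  if (is.na(size) || size < 256) {
    stop(sprintf("corrupt EDF header: file has %s bytes, need at least 256",
                 size), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                              # version
  rd(80); rd(80); rd(8); rd(8)       # patient, recording, date, time
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(hdr_bytes) || is.na(n_rec) || is.na(ns) || ns < 1L) {
    stop("corrupt EDF header: unparseable field within first 256 bytes",
         call. = FALSE)
  }
  if (size < hdr_bytes) {
    stop(sprintf("truncated EDF: header claims %d bytes, file ends at %d",
                 hdr_bytes, size), call. = FALSE)
  }
  fields <- function(width) {
    trimws(vapply(seq_len(ns), function(i) rd(width), ""))
  }
  labels <- fields(16)
  fields(80)
  dims <- fields(8)
  pmin_ <- as.numeric(fields(8))
  pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8))
  dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)

  expected <- hdr_bytes + 2 * n_rec * sum(spr)
  if (size < expected) {
    stop(sprintf("truncated EDF: expected %d bytes, file ends at %d",
                 expected, size), call. = FALSE)
  }
  seek(con, hdr_bytes)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      gain <- (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        pmin_[s] + (raw - dmin[s]) * gain
    }
  }
  unit_scale <- vapply(dims, function(d) {
    switch(tolower(d), "uv" = 1e-6, "mv" = 1e-3, "v" = 1, {
      warning("unknown physical dimension '", d, "'; assuming volts",
              call. = FALSE)
      1
    })
  }, numeric(1))
  data <- data * unit_scale
  unknown <- setdiff(labels, default_montage())
  if (length(unknown)) {
    warning("channel label(s) outside the 10/10 montage kept as-is: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  eeg_recording(data, sample_rate_hz = spr[1] / rec_dur,
                channel_labels = labels, meta = meta)
}

# ---- Note-sequence formats -------------------------------------------------

.step_table <- c("C", "C", "D", "D", "E", "F", "F", "G", "G", "A", "A", "B")
.alter_table <- c(0, 1, 0, 1, 0, 0, 1, 0, 1, 0, 1, 0)
.step_base <- c(C = 0, D = 2, E = 4, F = 5, G = 7, A = 9, B = 11)

#' Write a note sequence as minimal MusicXML
#'
#' Emits a single-part score-partwise document with one note per beat and
#' the beat frequency recorded in an identification miscellaneous field, the
#' subset understood by [read_musicxml()].
#'
#' @param seq a [note_sequence()].
#' @param path destination path.
#' @param notes_per_measure notes per measure (default 6, one measure per
#'   second at a 6-Hz beat).
#' @return `path`, invisibly.
#' @export
write_musicxml <- function(seq, path, notes_per_measure = 6) {
  stopifnot(inherits(seq, "note_sequence"))
  doc <- xml2::xml_new_root("score-partwise", version = "3.1")
  ident <- xml2::xml_add_child(doc, "identification")
  misc <- xml2::xml_add_child(ident, "miscellaneous")
  fld <- xml2::xml_add_child(misc, "miscellaneous-field",
                             name = "beat-frequency-hz")
  xml2::xml_set_text(fld, format(seq$beat_frequency_hz))
  pl <- xml2::xml_add_child(doc, "part-list")
  sp <- xml2::xml_add_child(pl, "score-part", id = "P1")
  pn <- xml2::xml_add_child(sp, "part-name")
  xml2::xml_set_text(pn, seq$name)
  part <- xml2::xml_add_child(doc, "part", id = "P1")
  pitches <- seq$notes$pitch
  n_measures <- ceiling(length(pitches) / notes_per_measure)
  for (m in seq_len(n_measures)) {
    meas <- xml2::xml_add_child(part, "measure", number = as.character(m))
    if (m == 1L) {
      attrs <- xml2::xml_add_child(meas, "attributes")
      div <- xml2::xml_add_child(attrs, "divisions")
      xml2::xml_set_text(div, "1")
    }
    idx <- ((m - 1L) * notes_per_measure + 1L):
      min(m * notes_per_measure, length(pitches))
    for (p in pitches[idx]) {
      note <- xml2::xml_add_child(meas, "note")
      pit <- xml2::xml_add_child(note, "pitch")
      pc <- p %% 12 + 1L
      st <- xml2::xml_add_child(pit, "step")
      xml2::xml_set_text(st, .step_table[pc])
      if (.alter_table[pc] != 0) {
        al <- xml2::xml_add_child(pit, "alter")
        xml2::xml_set_text(al, as.character(.alter_table[pc]))
      }
      oc <- xml2::xml_add_child(pit, "octave")
      xml2::xml_set_text(oc, as.character(p %/% 12L - 1L))
      dur <- xml2::xml_add_child(note, "duration")
      xml2::xml_set_text(dur, "1")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a minimal MusicXML score
#'
#' Parses the part/measure/note/pitch/duration subset of MusicXML: notes are
#' collected in document order, rests are skipped, and pitches converted to
#' MIDI numbers.
#'
#' @param path MusicXML file path.
#' @param beat_frequency_hz fallback beat frequency when the document does
#'   not record one (default 6).
#' @return A [note_sequence()].
#' @export
read_musicxml <- function(path, beat_frequency_hz = 6) {
  doc <- xml2::read_xml(path)
  bf <- xml2::xml_find_first(
    doc, ".//miscellaneous-field[@name='beat-frequency-hz']")
  if (!inherits(bf, "xml_missing")) {
    beat_frequency_hz <- as.numeric(xml2::xml_text(bf))
  }
  name <- xml2::xml_text(xml2::xml_find_first(doc, ".//part-name"))
  if (is.na(name)) name <- ""
  notes <- xml2::xml_find_all(doc, ".//note[pitch]")
  if (length(notes) == 0L) stop("no pitched notes found", call. = FALSE)
  pitches <- vapply(notes, function(nd) {
    step <- xml2::xml_text(xml2::xml_find_first(nd, "./pitch/step"))
    alter <- xml2::xml_text(xml2::xml_find_first(nd, "./pitch/alter"))
    octave <- as.integer(
      xml2::xml_text(xml2::xml_find_first(nd, "./pitch/octave")))
    alter <- if (is.na(alter)) 0L else as.integer(alter)
    (octave + 1L) * 12L + .step_base[[step]] + alter
  }, numeric(1))
  note_sequence(pitches, beat_frequency_hz = beat_frequency_hz, name = name)
}

#' JSON note-list files
#'
#' Reads and writes the compact JSON dialect
#' `{"name": ..., "beat_frequency_hz": ..., "pitches": [...]}`.
#'
#' @param path file path.
#' @return `read_notes_json`: a [note_sequence()].
#' @export
read_notes_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  note_sequence(obj$pitches,
                beat_frequency_hz = obj$beat_frequency_hz %||% 6,
                name = obj$name %||% "")
}

#' @rdname read_notes_json
#' @param seq a [note_sequence()].
#' @export
write_notes_json <- function(seq, path) {
  stopifnot(inherits(seq, "note_sequence"))
  jsonlite::write_json(
    list(name = seq$name, beat_frequency_hz = seq$beat_frequency_hz,
         pitches = seq$notes$pitch),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- WAV audio -------------------------------------------------------------

#' Write a waveform as a WAV file
#'
#' @param waveform numeric vector in `[-1, 1]` (clipped otherwise).
#' @param path destination path.
#' @param sample_rate_hz sampling rate.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate_hz, bits = 16) {
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32", call. = FALSE)
  n <- length(waveform)
  bytes_per <- bits / 8
  data_bytes <- n * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(round(sample_rate_hz)), con, size = 4, endian = "little")
  writeBin(as.integer(round(sample_rate_hz) * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  x <- pmax(pmin(waveform, 1), -1)
  if (bits == 16) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#' @param path WAV file path.
#' @return List with `waveform` and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 8) != "WAVEfmt ") stop("not a WAV file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  fmt <- readBin(con, integer(), size = 2, endian = "little")
  readBin(con, integer(), size = 2, endian = "little")
  fs <- readBin(con, integer(), size = 4, endian = "little")
  readBin(con, integer(), size = 4, endian = "little")
  readBin(con, integer(), size = 2, endian = "little")
  bits <- readBin(con, integer(), size = 2, endian = "little")
  if (readChar(con, 4) != "data") stop("missing data chunk", call. = FALSE)
  nbytes <- readBin(con, integer(), size = 4, endian = "little")
  wave <- if (bits == 16) {
    readBin(con, integer(), n = nbytes / 2, size = 2, signed = TRUE,
            endian = "little") / 32767
  } else if (bits == 32 && fmt == 3L) {
    readBin(con, numeric(), n = nbytes / 4, size = 4, endian = "little")
  } else {
    stop("unsupported WAV encoding", call. = FALSE)
  }
  list(waveform = wave, sample_rate_hz = fs)
}

# ---- Results, configuration and directory loading --------------------------

#' Serialize a pipeline bundle to disk
#'
#' Writes `summaries.csv` (long format), `ladder.json`, `classification.json`,
#' `topography.csv` (per-channel mean beat amplitudes for external plotting)
#' and `provenance.json` into `out_dir`.
#'
#' @param bundle a `pipeline_bundle` from [run_experiment_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(paradigm = bundle$ladder$paradigm,
         alternative = bundle$ladder$alternative,
         trials = bundle$ladder$trials,
         subjects = bundle$ladder$subjects,
         population = bundle$ladder$population),
    file.path(out_dir, "ladder.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"
  )
  cls <- bundle$classification
  jsonlite::write_json(
    list(selected_channels = cls$selected_channels,
         mean_accuracy = cls$cv$mean_accuracy,
         accuracies = cls$cv$accuracies,
         folds = cls$cv$folds, iterations = cls$cv$iterations,
         seed = cls$cv$seed,
         subject_accuracy = cls$subject_accuracy,
         weights = as.list(cls$model$weights), bias = cls$model$bias),
    file.path(out_dir, "classification.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    c(bundle$provenance,
      list(discarded_trials = bundle$discarded_trials)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config`: a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Load paired recordings from a directory
#'
#' Expects files named `sub<S>_trial<T>_<condition>.(csv|tsv|edf)` as written
#' by [write_experiment_dir()]. Trials missing either condition are listed
#' and skipped with a warning.
#'
#' @param dir directory of recordings.
#' @param paradigm `"comprehension"` or `"attention"`.
#' @param ... passed to [read_eeg()].
#' @return List of `trial_pair`s with recordings.
#' @export
load_experiment_dir <- function(dir,
                                paradigm = c("comprehension", "attention"),
                                ...) {
  paradigm <- match.arg(paradigm)
  conds <- if (paradigm == "comprehension") {
    c(a = "original", b = "scrambled")
  } else {
    c(a = "attended", b = "ignored")
  }
  files <- list.files(dir, pattern = "^sub\\d+_trial\\d+_.*\\.(csv|tsv|edf)$")
  info <- regmatches(files, regexec("^sub(\\d+)_trial(\\d+)_([a-z]+)\\.", files))
  tab <- data.frame(
    file = files,
    subject = as.integer(vapply(info, `[`, "", 2L)),
    trial = as.integer(vapply(info, `[`, "", 3L)),
    condition = vapply(info, `[`, "", 4L)
  )
  pairs <- list()
  skipped <- character(0)
  for (key in unique(paste(tab$subject, tab$trial))) {
    sub <- tab[paste(tab$subject, tab$trial) == key, ]
    fa <- sub$file[sub$condition == conds[["a"]]]
    fb <- sub$file[sub$condition == conds[["b"]]]
    if (length(fa) != 1L || length(fb) != 1L) {
      skipped <- c(skipped, key)
      next
    }
    mk_meta <- function(cond) list(subject = sub$subject[1],
                                   trial = sub$trial[1], condition = cond)
    pairs[[length(pairs) + 1L]] <- trial_pair(
      recording_a = read_eeg(file.path(dir, fa), meta = mk_meta(conds[["a"]]), ...),
      recording_b = read_eeg(file.path(dir, fb), meta = mk_meta(conds[["b"]]), ...),
      subject = sub$subject[1], trial = sub$trial[1], paradigm = paradigm
    )
  }
  if (length(skipped)) {
    warning("unpaired trial(s) skipped (subject trial): ",
            paste(skipped, collapse = "; "), call. = FALSE)
  }
  pairs
}

#' Write a simulated experiment to a directory
#'
#' Writes each recording of each trial pair as
#' `sub<S>_trial<T>_<condition>.<format>` plus a `ground_truth.json`
#' manifest recording the generator's true amplitudes and phases.
#'
#' @param pairs list of `trial_pair`s with recordings (see
#'   [simulate_experiment()]).
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_experiment_dir <- function(pairs, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (p in pairs) {
    for (side in c("a", "b")) {
      rec <- p[[paste0("recording_", side)]]
      fname <- sprintf("sub%d_trial%d_%s.%s", p$subject, p$trial,
                       rec$meta$condition, format)
      write_eeg(rec, file.path(dir, fname))
      gt <- p$ground_truth[[side]]
      if (!is.null(gt)) {
        manifest[[fname]] <- list(
          channel_amplitude = as.list(gt$channel_amplitude),
          phase = gt$phase, condition = gt$condition,
          condition_gain = gt$condition_gain, trial_gain = gt$trial_gain,
          note = "synthetic ground truth; all magnitudes are generator assumptions"
        )
      }
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Build trial pairs from a long-format amplitude table
#'
#' Accepts the canonical long format `{subject, trial, condition,
#' segment_index, amplitude}` (one row per analysis segment) and assembles
#' per-trial pairs suitable for [run_ladder()]. Condition names `original`
#' and `attended` are treated as condition A.
#'
#' @param df data frame or path to a CSV file in the long format.
#' @param paradigm `"comprehension"` or `"attention"`.
#' @return List of `trial_pair`s with summary stubs (per-segment amplitudes,
#'   means and SEMs; no phase information).
#' @export
pairs_from_long_table <- function(df,
                                  paradigm = c("comprehension", "attention")) {
  paradigm <- match.arg(paradigm)
  if (is.character(df)) df <- utils::read.csv(df)
  needed <- c("subject", "trial", "condition", "segment_index", "amplitude")
  if (!all(needed %in% names(df))) {
    stop("long table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  a_names <- c("original", "attended")
  mk_summary <- function(amp) {
    structure(
      list(responsive_channels = character(0), mean_amplitude = mean(amp),
           sem_amplitude = stats::sd(amp) / sqrt(length(amp)),
           mean_phase = NA_real_, n_segments = length(amp),
           per_segment_coefficients = NULL, per_segment_amplitude = amp,
           meta = list()),
      class = "beat_summary"
    )
  }
  lapply(split(df, list(df$subject, df$trial), drop = TRUE), function(d) {
    conds <- unique(d$condition)
    if (length(conds) != 2L) {
      stop("each trial needs exactly two conditions", call. = FALSE)
    }
    ca <- conds[conds %in% a_names]
    cb <- setdiff(conds, ca)
    if (length(ca) != 1L) {
      stop("cannot identify the baseline condition among: ",
           paste(conds, collapse = ", "), call. = FALSE)
    }
    da <- d[d$condition == ca, ]
    db <- d[d$condition == cb, ]
    trial_pair(
      summary_a = mk_summary(da$amplitude[order(da$segment_index)]),
      summary_b = mk_summary(db$amplitude[order(db$segment_index)]),
      subject = d$subject[1], trial = d$trial[1], paradigm = paradigm
    )
  })
}
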