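#' Construct a note sequence
#'
#' A note sequence is the score of a melodic stimulus: one note per beat,
#' played at a fixed beat frequency. Pitches follow the MIDI convention
#' (integer semitones, 60 = middle C). Onsets are consecutive integer beat
#' indices starting at 0 and every note lasts exactly one beat, so the
#' stimulus envelope is periodic at the beat frequency.
#'
#' @param pitches integer vector of MIDI pitches in `[0, 127]`.
#' @param beat_frequency_hz beat rate in Hz (default 6).
#' @param name identifier for the sequence.
#' @return An object of class `note_sequence` with elements `name`,
#'   `beat_frequency_hz` and `notes` (a data frame with columns `pitch`,
#'   `onset_beat`, `duration_beats`).
#' @export
note_sequence <- function(pitches, beat_frequency_hz = 6, name = "") {
  pitches <- as.integer(pitches)
  if (length(pitches) == 0L) {
    stop("a note sequence must contain at least one note", call. = FALSE)
  }
  if (anyNA(pitches) || any(pitches < 0L) || any(pitches > 127L)) {
    stop("pitches must be integers in [0, 127]", call. = FALSE)
  }
  if (!is.numeric(beat_frequency_hz) || length(beat_frequency_hz) != 1L ||
      beat_frequency_hz <= 0) {
    stop("beat_frequency_hz must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      name = as.character(name),
      beat_frequency_hz = as.numeric(beat_frequency_hz),
      notes = data.frame(
        pitch = pitches,
        onset_beat = seq_along(pitches) - 1L,
        duration_beats = rep(1, length(pitches))
      )
    ),
    class = "note_sequence"
  )
}

#' @export
print.note_sequence <- function(x, ...) {
  cat(sprintf(
    "<note_sequence> %s: %d notes at %.3g Hz (%.1f s)\n",
    if (nzchar(x$name)) x$name else "(unnamed)",
    nrow(x$notes), x$beat_frequency_hz,
    nrow(x$notes) / x$beat_frequency_hz
  ))
  invisible(x)
}

#' @export
length.note_sequence <- function(x) nrow(x$notes)

#' Pitches of a note sequence
#' @param seq a `note_sequence`.
#' @return Integer vector of MIDI pitches in beat order.
#' @export
sequence_pitches <- function(seq) {
  stopifnot(inherits(seq, "note_sequence"))
  seq$notes$pitch
}

#' Total stimulus duration in seconds
#' @param seq a `note_sequence`.
#' @return Duration in seconds (`n_notes / beat_frequency_hz`).
#' @export
sequence_duration <- function(seq) {
  stopifnot(inherits(seq, "note_sequence"))
  nrow(seq$notes) / seq$beat_frequency_hz
}

# Main themes of the four stimulus melodies, single line, one note per beat.
# These are public-domain themes re-encoded by hand; they stand in for the
# original edited scores, which were not distributed.
.melody_themes <- list(
  fur_elise = c(
    76, 75, 76, 75, 76, 71, 74, 72, 69, 64, 69, 71,
    64, 68, 71, 72, 64, 76, 75, 76, 75, 76, 71, 74,
    72, 69, 64, 69, 71, 64, 72, 71, 69
  ),
  eine_kleine_nachtmusik = c(
    67, 62, 67, 62, 67, 62, 67, 71, 74, 72, 69, 72,
    69, 72, 69, 66, 69, 62, 67, 67, 66, 67, 69, 67,
    66, 67, 71, 71, 69, 71, 72, 71, 69, 71, 74
  ),
  ode_to_joy = c(
    64, 64, 65, 67, 67, 65, 64, 62, 60, 60, 62, 64, 64, 62, 62,
    64, 64, 65, 67, 67, 65, 64, 62, 60, 60, 62, 64, 62, 60, 60
  ),
  twinkle_twinkle = c(
    60, 60, 67, 67, 69, 69, 67, 65, 65, 64, 64, 62, 62, 60,
    67, 67, 65, 65, 64, 64, 62, 67, 67, 65, 65, 64, 64, 62,
    60, 60, 67, 67, 69, 69, 67, 65, 65, 64, 64, 62, 62, 60
  )
)

#' Names of the built-in stimulus melodies
#' @return Character vector of melody names accepted by [melody()].
#' @export
melody_names <- function() names(.melody_themes)

#' Built-in stimulus melodies
#'
#' Returns one of four single-line melodies (Fuer Elise, Eine Kleine
#' Nachtmusik, Ode to Joy, Twinkle Twinkle Little Star), encoded from the
#' public-domain main themes with one note per beat. By default the theme is
#' repeated until the sequence lasts `duration_s` seconds at the beat
#' frequency, matching the two-minute stimulus presentations used in the
#' experiments.
#'
#' @param name one of [melody_names()].
#' @param beat_frequency_hz beat rate in Hz (default 6).
#' @param duration_s target duration in seconds; the theme is tiled and
#'   truncated to `duration_s * beat_frequency_hz` notes. Use `NULL` for a
#'   single statement of the theme.
#' @return A [note_sequence()].
#' @export
melody <- function(name, beat_frequency_hz = 6, duration_s = 120) {
  name <- match.arg(name, melody_names())
  pitches <- .melody_themes[[name]]
  if (!is.null(duration_s)) {
    n <- round(duration_s * beat_frequency_hz)
    pitches <- rep_len(pitches, n)
  }
  note_sequence(pitches, beat_frequency_hz = beat_frequency_hz, name = name)
}
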