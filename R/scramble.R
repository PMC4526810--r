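#' Scrambling specification
#'
#' Parameters of the melody-scrambling procedure: the score is cut into
#' segments whose lengths are drawn uniformly between `min_segment` and
#' `max_segment` notes, and the segments are then rearranged in a uniformly
#' random order. Scrambling destroys the recognizable tune while leaving the
#' pitch multiset, the note rate and hence the envelope spectrum intact.
#'
#' @param min_segment smallest segment length in notes (default 2).
#' @param max_segment largest segment length in notes (default 6).
#' @param seed integer RNG seed making the scramble reproducible; `NULL`
#'   uses the current RNG state.
#' @return An object of class `scramble_spec`.
#' @export
scramble_spec <- function(min_segment = 2, max_segment = 6, seed = NULL) {
  min_segment <- as.integer(min_segment)
  max_segment <- as.integer(max_segment)
  if (is.na(min_segment) || is.na(max_segment) ||
      min_segment < 1L || min_segment > max_segment) {
    stop("need 1 <= min_segment <= max_segment", call. = FALSE)
  }
  structure(
    list(min_segment = min_segment, max_segment = max_segment,
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "scramble_spec"
  )
}

#' Scramble a melody by segment permutation
#'
#' Cuts the note sequence into consecutive segments whose lengths are drawn
#' uniformly from `min_segment:max_segment` (the final remainder segment may
#' be shorter when the score does not partition exactly) and rearranges the
#' segments in a uniformly random order. Onset beats are renumbered
#' consecutively from 0, so the scrambled melody keeps the same note count,
#' pitch multiset, total duration and beat frequency as the original.
#'
#' @param seq a [note_sequence()] with at least `min_segment` notes.
#' @param spec a [scramble_spec()].
#' @return A [note_sequence()] named `<name>_scrambled`.
#' @export
scramble_notes <- function(seq, spec = scramble_spec()) {
  stopifnot(inherits(seq, "note_sequence"), inherits(spec, "scramble_spec"))
  n <- nrow(seq$notes)
  if (n < spec$min_segment) {
    stop("sequence has fewer notes than min_segment", call. = FALSE)
  }
  if (!is.null(spec$seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(spec$seed)
  }
  lens <- spec$min_segment:spec$max_segment
  lengths <- integer(0)
  remaining <- n
  while (remaining > 0L) {
    len <- lens[sample.int(length(lens), 1L)]
    if (len > remaining) len <- remaining
    lengths <- c(lengths, len)
    remaining <- remaining - len
  }
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  order <- sample.int(length(lengths))
  idx <- unlist(lapply(order, function(k) seq.int(starts[k], ends[k])),
                use.names = FALSE)
  note_sequence(
    seq$notes$pitch[idx],
    beat_frequency_hz = seq$beat_frequency_hz,
    name = paste0(seq$name, "_scrambled")
  )
}

#' Relative pitch-change statistics
#'
#' For each pair of successive notes the relative pitch change is the
#' frequency interval divided by the frequency of the lower tone: with a
#' semitone distance `d = |p2 - p1|` under equal temperament this equals
#' `2^(d/12) - 1`. Returns the mean and standard deviation of the relative
#' change over all adjacent note pairs; scrambling should leave these
#' low-level statistics essentially unchanged.
#'
#' @param seq a [note_sequence()] with at least two notes.
#' @return A list with elements `mean`, `sd` and `changes` (the per-pair
#'   relative changes).
#' @export
pitch_change_stats <- function(seq) {
  stopifnot(inherits(seq, "note_sequence"))
  p <- seq$notes$pitch
  if (length(p) < 2L) {
    stop("pitch changes need at least two notes", call. = FALSE)
  }
  d <- abs(diff(p))
  r <- 2^(d / 12) - 1
  list(mean = mean(r), sd = stats::sd(r), changes = r)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
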