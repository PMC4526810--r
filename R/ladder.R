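#' Pair the two recordings of a trial
#'
#' A trial pair holds the two two-minute recordings acquired within one trial:
#' condition A is the baseline presentation (original melody, or the ignored
#' music during reading), condition B its counterpart (scrambled melody, or
#' music; see [run_ladder()] for the sign conventions). Either raw
#' recordings, analysed summaries, or both may be supplied; [analyze_pair()]
#' fills in summaries and per-channel beat amplitudes from the recordings.
#'
#' @param recording_a,recording_b [eeg_recording()]s (optional when
#'   summaries are given).
#' @param summary_a,summary_b [average_beat_response()] summaries.
#' @param channel_amplitude_a,channel_amplitude_b named numeric vectors of
#'   per-channel beat amplitudes (all montage channels), used for
#'   classification features.
#' @param subject,trial identifiers.
#' @param paradigm `"comprehension"` or `"attention"`.
#' @param ground_truth optional list from the synthetic generator.
#' @return An object of class `trial_pair`.
#' @export
trial_pair <- function(recording_a = NULL, recording_b = NULL,
                       summary_a = NULL, summary_b = NULL,
                       channel_amplitude_a = NULL, channel_amplitude_b = NULL,
                       subject, trial,
                       paradigm = c("comprehension", "attention"),
                       ground_truth = NULL) {
  paradigm <- match.arg(paradigm)
  if (!is.null(summary_a) && !is.null(summary_b) &&
      summary_a$n_segments != summary_b$n_segments) {
    stop("paired summaries must share the segment count", call. = FALSE)
  }
  structure(
    list(recording_a = recording_a, recording_b = recording_b,
         summary_a = summary_a, summary_b = summary_b,
         channel_amplitude_a = channel_amplitude_a,
         channel_amplitude_b = channel_amplitude_b,
         subject = subject, trial = trial, paradigm = paradigm,
         ground_truth = ground_truth),
    class = "trial_pair"
  )
}

#' Paired t-test on the per-segment amplitudes of a trial
#'
#' Pairs the per-segment beat amplitudes of the two recordings of a trial by
#' segment index and applies the classical paired two-sample t-test
#' (two-tailed). When the paired differences have zero variance the result is
#' flagged degenerate: identical arrays give `t = 0, p = 1`; a nonzero
#' constant difference leaves `p` undefined (`NA`).
#'
#' @param pair a `trial_pair` with both summaries present (see
#'   [analyze_pair()]), or a list with numeric `a` and `b` amplitude vectors.
#' @return List with `t`, `p`, `df`, `mean_diff` (B - A) and `degenerate`.
#' @export
trial_test <- function(pair) {
  if (inherits(pair, "trial_pair")) {
    if (is.null(pair$summary_a) || is.null(pair$summary_b)) {
      stop("pair has no summaries; run analyze_pair() first", call. = FALSE)
    }
    a <- pair$summary_a$per_segment_amplitude
    b <- pair$summary_b$per_segment_amplitude
  } else {
    a <- pair$a
    b <- pair$b
  }
  if (length(a) != length(b)) {
    stop("paired amplitude arrays must have equal length", call. = FALSE)
  }
  d <- b - a
  n <- length(d)
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else NA_real_,
                df = n - 1L, mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = mean(d), degenerate = FALSE)
}

#' One-tailed one-sample t-test against zero
#'
#' Used at the subject level (on a subject's trial differences) and at the
#' population level (on the subject means) to test whether the mean response
#' difference exceeds zero (comprehension) or falls below zero (attention).
#'
#' @param values numeric vector with at least two elements.
#' @param alternative `"greater"` or `"less"`.
#' @return List with `t`, `p`, `df`, `mean`, `sem` and `degenerate`.
#' @export
one_tailed_one_sample_test <- function(values,
                                       alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(values) < 2L) {
    stop("need at least two values", call. = FALSE)
  }
  m <- mean(values)
  if (stats::sd(values) == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf, p = NA_real_,
                df = length(values) - 1L, mean = m, sem = 0,
                degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = 0, alternative = alternative)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean = m, sem = stats::sd(values) / sqrt(length(values)),
       degenerate = FALSE)
}

#' Three-level statistical ladder for condition differences
#'
#' Assesses the difference in beat-response amplitude between the two
#' conditions of each trial at three levels: individual trials (paired
#' t-test on per-segment amplitudes), individual subjects (one-tailed
#' one-sample t-test on the subject's trial differences) and the population
#' (one-tailed one-sample t-test on the subject means). The difference is
#' always condition B minus condition A, i.e. scrambled - original for the
#' comprehension paradigm (expected positive: the familiar tune evokes the
#' weaker response) and ignored - attended for the attention paradigm
#' (expected negative: attention enhances the response).
#'
#' @param pairs list of analysed `trial_pair`s of one paradigm.
#' @param paradigm `"comprehension"` or `"attention"`; defaults to the
#'   paradigm of the pairs.
#' @param min_trials_per_subject subjects with fewer trials are skipped at
#'   the subject level (default 2; a discarded non-responsive trial may
#'   leave a subject with three).
#' @return An object of class `ladder_result`: list with `paradigm`,
#'   `alternative`, `trials` (data frame: subject, trial, mean_diff, t, p),
#'   `subjects` (data frame: subject, n_trials, mean_diff, t, p),
#'   `population` (list: mean_diff, sem, t, p, n_subjects).
#' @export
run_ladder <- function(pairs, paradigm = NULL, min_trials_per_subject = 2) {
  if (length(pairs) == 0L) stop("no trial pairs supplied", call. = FALSE)
  paradigms <- unique(vapply(pairs, function(p) p$paradigm, character(1)))
  if (is.null(paradigm)) {
    if (length(paradigms) != 1L) {
      stop("pairs mix paradigms; supply a single-paradigm list", call. = FALSE)
    }
    paradigm <- paradigms
  } else if (!all(paradigms == paradigm)) {
    stop("pairs mix paradigms; supply a single-paradigm list", call. = FALSE)
  }
  alternative <- if (paradigm == "comprehension") "greater" else "less"

  trials <- do.call(rbind, lapply(pairs, function(p) {
    tt <- trial_test(p)
    data.frame(subject = p$subject, trial = p$trial,
               mean_diff = tt$mean_diff, t = tt$t, p = tt$p,
               degenerate = tt$degenerate)
  }))

  subjects <- do.call(rbind, lapply(split(trials, trials$subject), function(d) {
    if (nrow(d) < min_trials_per_subject) return(NULL)
    st <- one_tailed_one_sample_test(d$mean_diff, alternative)
    data.frame(subject = d$subject[1], n_trials = nrow(d),
               mean_diff = st$mean, t = st$t, p = st$p)
  }))
  rownames(subjects) <- NULL

  pop <- one_tailed_one_sample_test(subjects$mean_diff, alternative)
  structure(
    list(paradigm = paradigm, alternative = alternative,
         trials = trials, subjects = subjects,
         population = list(mean_diff = pop$mean, sem = pop$sem,
                           t = pop$t, p = pop$p,
                           n_subjects = nrow(subjects))),
    class = "ladder_result"
  )
}

#' @export
print.ladder_result <- function(x, ...) {
  cat(sprintf("<ladder_result> paradigm=%s (alternative=%s)\n",
              x$paradigm, x$alternative))
  cat(sprintf("  trials: %d, significant (p<0.05): %d\n",
              nrow(x$trials), sum(x$trials$p < 0.05, na.rm = TRUE)))
  cat(sprintf("  subjects: %d, significant: %d\n",
              nrow(x$subjects), sum(x$subjects$p < 0.05, na.rm = TRUE)))
  cat(sprintf("  population: mean diff %.4g V (SEM %.2g), t=%.3f, p=%.4g\n",
              x$population$mean_diff, x$population$sem,
              x$population$t, x$population$p))
  invisible(x)
}
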