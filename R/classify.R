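#' Build the paired-difference feature set
#'
#' For each trial, the feature vector is the per-channel difference of the
#' beat amplitudes between the paired recordings (condition B minus A:
#' scrambled - original, or ignored - attended), over all montage channels.
#' These rows form category +1; category -1 contains the sign-inverted rows,
#' so the dataset is antisymmetric by construction and the column means are
#' exactly zero. At the `"subject_average"` level each subject contributes
#' the mean over their trials instead.
#'
#' @param pairs list of analysed `trial_pair`s (with per-channel amplitudes;
#'   see [analyze_pair()]).
#' @param paradigm paradigm of the pairs (checked for consistency).
#' @param level `"trial"` (default) or `"subject_average"`.
#' @return An object of class `difference_features`: list with `X`
#'   (samples x channels matrix), `y` (labels in {+1, -1}),
#'   `channel_labels`, `level` and `unit_id` (identifier shared by a row and
#'   its mirrored copy, used for leakage-free fold assignment).
#' @export
build_difference_dataset <- function(pairs, paradigm = NULL,
                                     level = c("trial", "subject_average")) {
  level <- match.arg(level)
  if (length(pairs) == 0L) stop("no trial pairs supplied", call. = FALSE)
  paradigms <- unique(vapply(pairs, function(p) p$paradigm, character(1)))
  if (length(paradigms) != 1L ||
      (!is.null(paradigm) && paradigms != paradigm)) {
    stop("pairs must share a single paradigm", call. = FALSE)
  }
  labels <- names(pairs[[1]]$channel_amplitude_a)
  rows <- lapply(pairs, function(p) {
    a <- p$channel_amplitude_a
    b <- p$channel_amplitude_b
    if (is.null(a) || is.null(b) || !setequal(names(a), labels) ||
        !setequal(names(b), labels)) {
      stop("every pair must provide amplitudes for all montage channels",
           call. = FALSE)
    }
    b[labels] - a[labels]
  })
  D <- do.call(rbind, rows)
  subj <- vapply(pairs, function(p) as.character(p$subject), character(1))
  if (level == "subject_average") {
    D <- do.call(rbind, lapply(split(seq_len(nrow(D)), subj), function(i) {
      colMeans(D[i, , drop = FALSE])
    }))
    unit <- rownames(D)
  } else {
    unit <- paste(subj, vapply(pairs, function(p) as.character(p$trial),
                               character(1)), sep = "/")
  }
  structure(
    list(
      X = unname(rbind(D, -D)),
      y = rep(c(1, -1), each = nrow(D)),
      channel_labels = labels,
      level = level,
      unit_id = rep(unit, 2L)
    ),
    class = "difference_features"
  )
}

#' Fit a pooled-covariance linear discriminant
#'
#' Fits the two-class linear discriminant: `w = S_pooled^{-1} (mu_+ - mu_-)`
#' with the bias placing the boundary midway between the projected class
#' means (equal priors). When the pooled covariance is near-singular it is
#' ridge-stabilized by `regularization_eps * trace / dim` on the diagonal.
#' Prediction is `sign(w' x + b)`; on antisymmetric training data the bias
#' vanishes, so the boundary passes through the origin.
#'
#' @param X samples x features matrix.
#' @param y labels in {+1, -1}; both classes must be present with at least
#'   two samples each.
#' @param regularization_eps ridge factor (default 1e-8).
#' @return An object of class `beat_lda`: list with `weights`, `bias`,
#'   `class_means`, `pooled_cov`, `feature_labels`.
#' @export
lda_fit <- function(X, y, regularization_eps = 1e-8) {
  X <- as.matrix(X)
  if (length(unique(y)) != 2L || min(table(y)) < 2L) {
    stop("need both classes with at least two samples each", call. = FALSE)
  }
  fit <- .lda_core(X, y, regularization_eps)
  structure(
    c(fit, list(feature_labels = colnames(X),
                regularization_eps = regularization_eps)),
    class = "beat_lda"
  )
}

# Minimal pooled-covariance discriminant used by lda_fit and the CV loop.
.lda_core <- function(X, y, eps) {
  pos <- y > 0
  Xp <- X[pos, , drop = FALSE]
  Xn <- X[!pos, , drop = FALSE]
  mp <- colMeans(Xp)
  mn <- colMeans(Xn)
  Sp <- ((nrow(Xp) - 1) * stats::cov(Xp) + (nrow(Xn) - 1) * stats::cov(Xn)) /
    (nrow(Xp) + nrow(Xn) - 2)
  d <- ncol(X)
  w <- tryCatch(
    solve(Sp, mp - mn),
    error = function(e) {
      solve(Sp + diag(eps * sum(diag(Sp)) / d + eps, d), mp - mn)
    }
  )
  list(weights = w, bias = -sum(w * (mp + mn)) / 2,
       class_means = rbind(positive = mp, negative = mn), pooled_cov = Sp)
}

#' @export
print.beat_lda <- function(x, ...) {
  cat("<beat_lda>", length(x$weights), "feature(s); weights:",
      paste(sprintf("%.4g", x$weights), collapse = ", "),
      sprintf("bias %.4g\n", x$bias))
  invisible(x)
}

#' Predict class labels with a fitted discriminant
#' @param object a `beat_lda` model.
#' @param newdata samples x features matrix (columns matching the fit).
#' @param ... unused.
#' @return Numeric labels in {+1, -1} (scores of exactly zero map to +1).
#' @export
predict.beat_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_labels) && !is.null(colnames(newdata))) {
    if (!all(object$feature_labels %in% colnames(newdata))) {
      stop("newdata lacks the model's features", call. = FALSE)
    }
    newdata <- newdata[, object$feature_labels, drop = FALSE]
  }
  score <- drop(newdata %*% object$weights) + object$bias
  ifelse(score >= 0, 1, -1)
}

#' Repeated stratified cross-validation of the linear discriminant
#'
#' Runs `iterations` rounds of k-fold cross-validation. In each iteration the
#' samples are partitioned afresh at random, stratified so that both classes
#' appear in every training fold; when `unit_id`s are supplied (as produced
#' by [build_difference_dataset()]) a row and its sign-inverted mirror are
#' always assigned to the same fold, preventing leakage between training and
#' test data. The iteration accuracy is the pooled correct fraction over all
#' held-out folds.
#'
#' @param X samples x features matrix.
#' @param y labels in {+1, -1}.
#' @param folds number of folds (default 10; reduced with a warning when
#'   there are fewer units than folds).
#' @param iterations number of repeated partitions (default 100).
#' @param seed integer seed governing all partition randomness.
#' @param unit_id optional vector grouping rows into fold-assignment units.
#' @param regularization_eps passed to the discriminant fit.
#' @return An object of class `cv_result`: list with `mean_accuracy`,
#'   `accuracies` (one per iteration), `folds`, `iterations`, `seed` and
#'   `feature_labels`.
#' @export
cross_validate <- function(X, y, folds = 10, iterations = 100, seed = 1,
                           unit_id = NULL, regularization_eps = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(unique(y)) != 2L) stop("both classes required", call. = FALSE)
  if (is.null(unit_id)) unit_id <- seq_len(n)
  units <- split(seq_len(n), unit_id)
  n_units <- length(units)
  if (folds > n_units) {
    warning(sprintf("reducing folds from %d to the %d available units",
                    folds, n_units), call. = FALSE)
    folds <- n_units
  }
  # stratify units by their (first) class so every fold sees both classes
  unit_class <- vapply(units, function(i) y[i[1]], numeric(1))

  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  acc <- numeric(iterations)
  for (it in seq_len(iterations)) {
    fold_of <- integer(n_units)
    for (cl in unique(unit_class)) {
      idx <- which(unit_class == cl)
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    correct <- 0L
    for (f in seq_len(folds)) {
      test_rows <- unlist(units[fold_of == f], use.names = FALSE)
      train_rows <- setdiff(seq_len(n), test_rows)
      fit <- .lda_core(X[train_rows, , drop = FALSE], y[train_rows],
                       regularization_eps)
      score <- drop(X[test_rows, , drop = FALSE] %*% fit$weights) + fit$bias
      correct <- correct + sum(ifelse(score >= 0, 1, -1) == y[test_rows])
    }
    acc[it] <- correct / n
  }
  structure(
    list(mean_accuracy = mean(acc), accuracies = acc, folds = folds,
         iterations = iterations, seed = seed,
         feature_labels = colnames(X)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> mean accuracy %.3f over %d iterations of %d-fold CV\n",
    x$mean_accuracy, x$iterations, x$folds
  ))
  invisible(x)
}

#' Greedy forward channel selection by cross-validated accuracy
#'
#' Starting from the empty set, repeatedly adds the channel whose inclusion
#' maximizes the mean cross-validated discriminant accuracy; stops when no
#' candidate strictly improves the accuracy or when `max_features` channels
#' are selected. Ties are broken in channel order. All candidates within a
#' selection step are evaluated on identical partitions, and the whole
#' procedure is deterministic given `seed`.
#'
#' @param X samples x channels matrix with column names, or a
#'   `difference_features` object.
#' @param y labels in {+1, -1} (ignored when `X` is a
#'   `difference_features`).
#' @param max_features largest number of channels to select (default 2,
#'   matching two-channel wearable-EEG classifiers).
#' @param folds,iterations cross-validation settings used to score
#'   candidates (defaults 10 and 20; scoring needs fewer iterations than
#'   final evaluation).
#' @param seed integer seed.
#' @param unit_id optional fold-assignment units (see [cross_validate()]).
#' @return Character vector of selected channel labels, in selection order,
#'   with attribute `"accuracy"` giving the CV accuracy after each addition.
#' @export
forward_select <- function(X, y = NULL, max_features = 2, folds = 10,
                           iterations = 20, seed = 1, unit_id = NULL) {
  if (inherits(X, "difference_features")) {
    unit_id <- X$unit_id
    y <- X$y
    labels <- X$channel_labels
    X <- X$X
    colnames(X) <- labels
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("ch", seq_len(ncol(X)))
  if (max_features < 1) stop("max_features must be >= 1", call. = FALSE)
  selected <- character(0)
  best_acc <- -Inf
  trace <- numeric(0)
  candidates <- colnames(X)
  for (step in seq_len(min(max_features, ncol(X)))) {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    step_seed <- (as.numeric(seed) + step * 7919) %% .Machine$integer.max
    accs <- vapply(remaining, function(ch) {
      suppressWarnings(cross_validate(
        X[, c(selected, ch), drop = FALSE], y,
        folds = folds, iterations = iterations, seed = step_seed,
        unit_id = unit_id
      ))$mean_accuracy
    }, numeric(1))
    best <- which.max(accs)  # which.max takes the first (channel-order) tie
    if (accs[best] <= best_acc) break
    best_acc <- accs[best]
    selected <- c(selected, remaining[best])
    trace <- c(trace, best_acc)
  }
  attr(selected, "accuracy") <- trace
  selected
}

#' Evaluate a trained discriminant on subject-average features
#'
#' Applies a discriminant trained on trial-level differences (with its
#' selected channels fixed) to the subject-average difference rows and
#' reports the correct fraction over the `2 * n_subjects` rows.
#'
#' @param model a `beat_lda` fitted on the selected channels.
#' @param subject_set a `difference_features` at level `"subject_average"`.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_on_subject_averages <- function(model, subject_set) {
  stopifnot(inherits(model, "beat_lda"),
            inherits(subject_set, "difference_features"))
  if (subject_set$level != "subject_average") {
    stop("subject_set must be at subject_average level", call. = FALSE)
  }
  X <- subject_set$X
  colnames(X) <- subject_set$channel_labels
  if (!all(model$feature_labels %in% subject_set$channel_labels)) {
    stop("subject_set lacks the model's channels", call. = FALSE)
  }
  mean(predict(model, X) == subject_set$y)
}

#' Channel selection, cross-validation and subject-level evaluation
#'
#' Convenience wrapper running the full classification stage on analysed
#' trial pairs: builds the trial-level difference features, selects up to
#' `max_features` channels greedily, cross-validates the discriminant on the
#' selected channels with `iterations` repeated `folds`-fold partitions, fits
#' the final model on all trial rows, and evaluates it on the
#' subject-average rows.
#'
#' @param pairs list of analysed `trial_pair`s of one paradigm.
#' @param max_features,folds,iterations,seed see [forward_select()] and
#'   [cross_validate()].
#' @param select_iterations CV iterations used during selection (default 20).
#' @return List with `selected_channels`, `cv` (a `cv_result`), `model`
#'   (the final `beat_lda`), `trial_accuracy` (the CV mean accuracy) and
#'   `subject_accuracy`.
#' @export
classify_experiment <- function(pairs, max_features = 2, folds = 10,
                                iterations = 100, seed = 1,
                                select_iterations = 20) {
  trial_set <- build_difference_dataset(pairs, level = "trial")
  subject_set <- build_difference_dataset(pairs, level = "subject_average")
  sel <- forward_select(trial_set, max_features = max_features, folds = folds,
                        iterations = select_iterations, seed = seed)
  Xt <- trial_set$X
  colnames(Xt) <- trial_set$channel_labels
  cv <- cross_validate(Xt[, sel, drop = FALSE], trial_set$y, folds = folds,
                       iterations = iterations, seed = seed,
                       unit_id = trial_set$unit_id)
  model <- lda_fit(Xt[, sel, drop = FALSE], trial_set$y)
  list(
    selected_channels = as.character(sel),
    cv = cv,
    model = model,
    trial_accuracy = cv$mean_accuracy,
    subject_accuracy = evaluate_on_subject_averages(model, subject_set)
  )
}
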