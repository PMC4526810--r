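# Analysed-pair stubs carrying only per-channel amplitudes.
amp_pairs <- function(diffs, paradigm = "comprehension") {
  labels <- default_montage()
  lapply(seq_along(diffs), function(i) {
    base <- stats::setNames(rep(1, length(labels)), labels)
    trial_pair(
      channel_amplitude_a = base,
      channel_amplitude_b = base + stats::setNames(diffs[[i]], labels),
      subject = (i - 1) %/% 4 + 1, trial = (i - 1) %% 4 + 1,
      paradigm = paradigm
    )
  })
}

test_that("difference datasets are antisymmetric with correct counts", {
  d1 <- c(1, rep(0, 12))
  set <- build_difference_dataset(amp_pairs(list(d1)))
  expect_identical(dim(set$X), c(2L, 13L))
  expect_equal(set$X[1, ], d1)
  expect_equal(set$X[2, ], -d1)
  expect_identical(set$y, c(1, -1))
  expect_identical(set$unit_id[1], set$unit_id[2])

  # 31 trials (one discarded from 32) give 62 trial-level rows
  set.seed(3)
  diffs <- replicate(31, rnorm(13), simplify = FALSE)
  set31 <- build_difference_dataset(amp_pairs(diffs))
  expect_identical(nrow(set31$X), 62L)
  expect_equal(colMeans(set31$X), rep(0, 13))

  subj <- build_difference_dataset(amp_pairs(diffs), level = "subject_average")
  expect_identical(nrow(subj$X), 2L * 8L)

  broken <- amp_pairs(list(d1))
  broken[[1]]$channel_amplitude_b <- broken[[1]]$channel_amplitude_b[-1]
  expect_error(build_difference_dataset(broken), "all montage channels")
})

test_that("LDA matches the closed-form pooled-covariance discriminant", {
  set.seed(11)
  n <- 4000
  X <- rbind(cbind(rnorm(n, 1), rnorm(n)), cbind(rnorm(n, -1), rnorm(n)))
  y <- rep(c(1, -1), each = n)
  fit <- lda_fit(X, y)
  # population oracle: w = Sigma^-1 (mu+ - mu-) = I^-1 (2, 0)
  w_unit <- fit$weights / sqrt(sum(fit$weights^2))
  expect_lt(sum(abs(w_unit - c(1, 0))), 0.05)
  expect_lt(abs(fit$bias), 0.05)
  # Bayes accuracy for unit-variance classes 2 apart is pnorm(1)
  expect_gt(mean(predict(fit, X) == y), pnorm(1) - 0.03)

  expect_error(lda_fit(X, rep(1, 2 * n)), "both classes")
})

test_that("antisymmetric data put the LDA boundary through the origin", {
  set.seed(12)
  D <- matrix(rnorm(40), 20, 2) + 1
  X <- rbind(D, -D)
  y <- rep(c(1, -1), each = 20)
  fit <- lda_fit(X, y)
  expect_lt(abs(fit$bias), 1e-9)
  probe <- matrix(rnorm(40), 20, 2)
  expect_equal(predict(fit, probe), -predict(fit, -probe))
})

test_that("duplicated columns are handled by regularization", {
  set.seed(13)
  D <- matrix(rnorm(60), 30, 2) + 0.8
  X <- rbind(D, -D)
  y <- rep(c(1, -1), each = 30)
  fit2 <- lda_fit(X, y)
  X3 <- cbind(X, X[, 1])
  fit3 <- lda_fit(X3, y, regularization_eps = 1e-8)
  probe <- matrix(rnorm(50), , 2)
  expect_equal(predict(fit3, cbind(probe, probe[, 1])),
               predict(fit2, probe))
})

test_that("LDA direction agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(14)
  X <- rbind(matrix(rnorm(100, 1), 50, 2), matrix(rnorm(100, -0.5), 50, 2))
  y <- rep(c(1, -1), each = 50)
  fit <- lda_fit(X, y)
  ref <- MASS::lda(X, grouping = factor(y))
  w_ref <- drop(ref$scaling)
  w_ref <- w_ref * sign(sum(w_ref * fit$weights))
  cosine <- sum(w_ref * fit$weights) /
    sqrt(sum(w_ref^2) * sum(fit$weights^2))
  expect_equal(cosine, 1, tolerance = 1e-8)
})

test_that("cross-validation is calibrated, deterministic and leakage-safe", {
  set.seed(15)
  D <- cbind(rnorm(30, 3, 0.2), rnorm(30))
  X <- rbind(D, -D)
  y <- rep(c(1, -1), each = 30)
  unit <- rep(1:30, 2)
  cv <- cross_validate(X, y, folds = 10, iterations = 20, seed = 4,
                       unit_id = unit)
  expect_equal(cv$mean_accuracy, 1.0)

  # labels independent of features: accuracy near chance
  set.seed(16)
  Xr <- matrix(rnorm(400), 100, 4)
  yr <- rep(c(1, -1), 50)
  cvr <- cross_validate(Xr, yr, folds = 10, iterations = 30, seed = 4)
  expect_lt(abs(cvr$mean_accuracy - 0.5), 0.1)

  # identical seed, identical result (bit-level)
  cv2 <- cross_validate(X, y, folds = 10, iterations = 20, seed = 4,
                        unit_id = unit)
  expect_identical(cv$accuracies, cv2$accuracies)

  # label-flip equivariance: negating X and y changes nothing
  cvf <- cross_validate(-X, -y, folds = 10, iterations = 20, seed = 4,
                        unit_id = unit)
  expect_identical(cv$accuracies, cvf$accuracies)

  both <- c(1:4, 31:34)
  expect_warning(cross_validate(X[both, ], y[both], folds = 10, iterations = 2),
                 "reducing folds")
})

test_that("leave-one-out CV equals a brute-force oracle", {
  set.seed(17)
  X <- cbind(rnorm(24, 0.8), rnorm(24))
  y <- rep(c(1, -1), 12)
  n <- nrow(X)
  cv <- cross_validate(X, y, folds = n, iterations = 1, seed = 1)
  oracle <- mean(vapply(seq_len(n), function(i) {
    fit <- lda_fit(X[-i, , drop = FALSE], y[-i])
    predict(fit, X[i, , drop = FALSE]) == y[i]
  }, logical(1)))
  expect_equal(cv$mean_accuracy, oracle)
})

test_that("forward selection finds informative channels first", {
  set.seed(18)
  # one perfectly separating channel among noise
  n <- 24
  D <- cbind(matrix(rnorm(n * 3), n, 3), rnorm(n, 5, 0.3))
  X <- rbind(D, -D)
  colnames(X) <- c("n1", "n2", "n3", "sig")
  y <- rep(c(1, -1), each = n)
  sel <- forward_select(X, y, max_features = 2, seed = 2,
                        unit_id = rep(1:n, 2))
  expect_identical(sel[1], "sig")

  # all-noise channels: selection stops within bounds, accuracy near chance
  Xn <- matrix(rnorm(60 * 5), 60, 5)
  yn <- rep(c(1, -1), 30)
  seln <- forward_select(Xn, yn, max_features = 3, seed = 2)
  expect_lte(length(seln), 3)
  expect_lt(abs(max(attr(seln, "accuracy")) - 0.5), 0.2)

  expect_error(forward_select(X, y, max_features = 0), "max_features")
})

test_that("two informative channels beat noise channels across seeds", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 16
    D <- cbind(rnorm(n, 2, 0.4), rnorm(n, 1.6, 0.4),
               matrix(rnorm(n * 4, 0, 0.4), n, 4))
    X <- rbind(D, -D)
    colnames(X) <- c("i1", "i2", "x1", "x2", "x3", "x4")
    y <- rep(c(1, -1), each = n)
    sel <- forward_select(X, y, max_features = 2, iterations = 10,
                          seed = s, unit_id = rep(1:n, 2))
    all(sel %in% c("i1", "i2"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("subject-average evaluation reuses the trial-trained model", {
  set.seed(19)
  diffs <- lapply(1:32, function(i) rnorm(13, mean = default_topography()))
  pairs <- amp_pairs(diffs)
  trial_set <- build_difference_dataset(pairs)
  subj_set <- build_difference_dataset(pairs, level = "subject_average")
  Xt <- trial_set$X
  colnames(Xt) <- trial_set$channel_labels
  model <- lda_fit(Xt[, c("Fz", "F6")], trial_set$y)
  acc <- evaluate_on_subject_averages(model, subj_set)
  expect_gte(acc, 0.9)

  expect_error(evaluate_on_subject_averages(model, trial_set),
               "subject_average")
  bad <- subj_set
  bad$channel_labels <- paste0("Q", 1:13)
  expect_error(evaluate_on_subject_averages(model, bad), "channels")
})
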