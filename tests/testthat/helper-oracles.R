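# Independent closed-form oracles used across the suite.

# Mean of the Rice distribution with noncentrality nu and per-quadrature
# scale sigma: sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2)), with the
# generalized Laguerre polynomial written in terms of Bessel functions.
rice_mean <- function(nu, sigma) {
  x <- -nu^2 / (2 * sigma^2)
  laguerre_half <- exp(x / 2) *
    ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  sigma * sqrt(pi / 2) * laguerre_half
}

# Closed-form one-sample t statistic and p-values, written out from the
# definition so they stay independent of stats::t.test.
t_one_sample <- function(x, mu = 0) {
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(t = t, df = n - 1,
       p_two = 2 * pt(-abs(t), n - 1),
       p_greater = pt(t, n - 1, lower.tail = FALSE),
       p_less = pt(t, n - 1))
}

t_paired <- function(b, a) t_one_sample(b - a)

# Small, fast generator settings for Monte-Carlo-style unit tests.
fast_config <- function(...) {
  args <- list(...)
  if (is.null(args$duration_s)) args$duration_s <- 20
  if (is.null(args$sample_rate_hz)) args$sample_rate_hz <- 250
  do.call(synthetic_config, args)
}

# Wrap the measured minus true phase into (-pi, pi].
phase_error <- function(measured, true) {
  abs(Arg(exp(1i * (measured - true))))
}
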