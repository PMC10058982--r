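# shared fixtures built in code

default_geometry <- function() vessel_geometry(8e-4, 2e-4)

# a clean 30-frame QA curve set: half-sine systolic flow, tube-law-like
# area swinging with it (not run through the surrogate; for unit tests of
# the estimator primitives only)
toy_qa <- function(n = 30L, period = 1.12, slope = 5, intercept = 1e-3) {
  t <- (seq_len(n) - 1L) * period / n
  t_sys <- 0.35 * period
  q <- ifelse(t <= t_sys, 3e-4 * sin(pi * t / t_sys), 0)
  a <- (q - intercept) / slope + 8e-4   # exactly linear in flow
  qa_curves(t, q, a, period)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
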