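test_that("Gauss-Legendre rules match closed forms and standard tables", {
  r1 <- gauss_legendre_rule(1)
  expect_equal(r1$nodes, 0)
  expect_equal(r1$weights, 1)
  r2 <- gauss_legendre_rule(2)
  expect_equal(r2$nodes, c(-1, 1) / sqrt(3), tolerance = 1e-14)
  expect_equal(r2$weights, c(0.5, 0.5), tolerance = 1e-14)
  r4 <- gauss_legendre_rule(4)
  expect_equal(r4$nodes,
               c(-0.8611363116, -0.3399810436, 0.3399810436, 0.8611363116),
               tolerance = 1e-9)
  expect_equal(r4$weights,
               c(0.1739274226, 0.3260725774, 0.3260725774, 0.1739274226),
               tolerance = 1e-9)
  expect_error(gauss_legendre_rule(0), "positive integer")
})

test_that("rules are symmetric probability rules for any size", {
  for (n in c(2, 3, 4, 5, 8, 16)) {
    r <- gauss_legendre_rule(n)
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
    expect_equal(r$nodes, -rev(r$nodes), tolerance = 1e-12)
    expect_true(all(abs(r$nodes) < 1))
  }
})

test_that("the 4-point rule integrates degree <= 7 exactly against eta", {
  r <- gauss_legendre_rule(4)
  for (k in 0:7) {
    # closed-form moment of uniform density on [-1, 1]
    exact <- if (k %% 2 == 0) 1 / (k + 1) else 0
    expect_equal(sum(r$weights * r$nodes^k), exact, tolerance = 1e-12)
  }
})

test_that("uniform parameter carries the +/-23% support about E-hat", {
  p <- uniform_parameter(2.02e6)
  expect_equal(p$support_low, 0.77 * 2.02e6)
  expect_equal(p$support_high, 1.23 * 2.02e6)
  expect_error(uniform_parameter(-1), "center")
  expect_error(uniform_parameter(1, 1.2), "halfwidth_fraction")
})

test_that("quadrature mapping reproduces the standard factors and points", {
  r <- gauss_legendre_rule(4)
  # unit center: factors 1.2, 1.08, 0.92, 0.8 at two decimals
  fac <- parameter_values_from_rule(r, uniform_parameter(1, 0.23))
  expect_equal(round(fac, 2), c(1.2, 1.08, 0.92, 0.8))
  # 2.02 MPa center: 2.42, 2.18, 1.86, 1.62 MPa at two decimals
  vals <- parameter_values_from_rule(r, uniform_parameter(2.02e6, 0.23))
  expect_equal(round(vals / 1e6, 2), c(2.42, 2.18, 1.86, 1.62))
  expect_true(all(diff(vals) < 0))   # descending: x1 largest
  # degenerate halfwidth collapses every point onto the center
  same <- parameter_values_from_rule(r, uniform_parameter(2.02e6, 0))
  expect_equal(same, rep(2.02e6, 4))
})

test_that("Legendre evaluation honours closed forms and endpoint values", {
  z <- seq(-1, 1, length.out = 21)
  expect_equal(legendre_eval(0, z), rep(1, 21))
  expect_equal(legendre_eval(1, 0.5), 0.5)
  expect_equal(legendre_eval(2, 1), 1)
  expect_equal(legendre_eval(3, -1), -1)
  expect_equal(legendre_eval(2, z), (3 * z^2 - 1) / 2, tolerance = 1e-14)
  # quadrature nodes are roots of the matching-degree polynomial
  r4 <- gauss_legendre_rule(4)
  expect_equal(legendre_eval(4, r4$nodes), rep(0, 4), tolerance = 1e-9)
  expect_error(legendre_eval(2, 1.5), "outside")
  expect_warning(legendre_eval(2, 1.5, extrapolate = TRUE), "outside")
})

test_that("projection isolates basis polynomials and constants", {
  r <- gauss_legendre_rule(4)
  # constant model
  exp_const <- gpc_project(rep(7, 4), r, order = 3)
  expect_equal(exp_const$coefficients[, 1L], c(7, 0, 0, 0),
               tolerance = 1e-12)
  # the model IS P2
  exp_p2 <- gpc_project(legendre_eval(2, r$nodes), r, order = 3)
  expect_equal(exp_p2$coefficients[, 1L], c(0, 0, 1, 0), tolerance = 1e-12)
  # shape error
  expect_error(gpc_project(matrix(1, 3, 2), r), "3 rows")
})

test_that("projection of a smooth model matches a dense-quadrature oracle", {
  # a 16-point rule so that quadrature aliasing is negligible against the
  # 1e-6 comparison (a 4-point rule's r = 3 coefficient carries ~1%
  # aliasing from the higher harmonics of exp)
  r <- gauss_legendre_rule(16)
  e <- gpc_project(exp(r$nodes), r, order = 3)
  # oracle: trapezoid integration of the projection integral on 10^4 points
  z <- seq(-1, 1, length.out = 10001)
  dz <- z[2] - z[1]
  trap <- function(f) {
    v <- f(z)
    (sum(v) - (v[1] + v[length(v)]) / 2) * dz
  }
  for (deg in 0:3) {
    a_oracle <- (2 * deg + 1) *
      trap(function(z) exp(z) * legendre_eval(deg, z) * 0.5)
    expect_lt(abs(e$coefficients[deg + 1L, 1L] - a_oracle), 1e-6)
  }
})

test_that("surrogate evaluation reproduces polynomial models exactly", {
  r <- gauss_legendre_rule(4)
  # a0-only expansion is constant
  e0 <- gpc_project(rep(7, 4), r, order = 3)
  expect_equal(evaluate_surrogate(e0, 0.83), 7, tolerance = 1e-12)
  # cubic reproduced exactly: 2 z^3 - z at z = 0.3 is -0.246
  ec <- gpc_project(2 * r$nodes^3 - r$nodes, r, order = 3)
  expect_equal(evaluate_surrogate(ec, 0.3), -0.246, tolerance = 1e-12)
  # property: any random degree-<=3 polynomial at 50 random points
  set.seed(42)
  for (rep in 1:5) {
    coefs <- rnorm(4)
    model <- function(z) coefs[1] + coefs[2] * z + coefs[3] * z^2 +
      coefs[4] * z^3
    e <- gpc_project(model(r$nodes), r, order = 3)
    z50 <- runif(50, -1, 1)
    expect_equal(evaluate_surrogate(e, z50)[, 1L], model(z50),
                 tolerance = 1e-12)
  }
})

test_that("gPC moments match analytic values and a Monte-Carlo oracle", {
  r <- gauss_legendre_rule(4)
  # X = zeta: uniform on [-1, 1] has mean 0, variance 1/3
  m <- gpc_moments(gpc_project(r$nodes, r, order = 3))
  expect_equal(m$mean, 0, tolerance = 1e-14)
  expect_equal(m$std, sqrt(1 / 3), tolerance = 1e-12)
  # constant model has zero spread
  m0 <- gpc_moments(gpc_project(rep(3, 4), r, order = 3))
  expect_equal(m0$std, 0, tolerance = 1e-12)
  # smooth battery vs seeded Monte-Carlo draws through the same surrogate
  set.seed(123)
  zeta_mc <- runif(1e5, -1, 1)
  battery <- list(function(z) exp(z),
                  function(z) 1 / (2 + z),
                  function(z) sin(z) + 2)
  for (f in battery) {
    e <- gpc_project(f(r$nodes), r, order = 3)
    mom <- gpc_moments(e)
    vals <- evaluate_surrogate(e, zeta_mc)[, 1L]
    expect_rel(mom$mean, mean(vals), 0.01)
    expect_rel(mom$std, sd(vals), 0.01)
  }
})

test_that("PDF estimation: affine surrogate is flat, constant is a point mass", {
  r <- gauss_legendre_rule(4)
  e_lin <- gpc_project(2 + 0.5 * r$nodes, r, order = 3)
  pdf <- estimate_pdf(e_lin, n_samples = 1e5, seed = 9, n_bins = 32)
  expect_false(pdf$point_mass[1L])
  # unit integral
  expect_equal(sum(pdf$density[, 1L]) * pdf$bin_width[1L], 1,
               tolerance = 1e-9)
  # flat at 1 / (2 * a1) across the support [1.5, 2.5]
  expect_true(all(abs(pdf$density[, 1L] - 1) < 0.15))
  expect_gte(min(pdf$centers[, 1L]), 1.5)
  expect_lte(max(pdf$centers[, 1L]), 2.5)
  # constant surrogate
  e_const <- gpc_project(rep(4, 4), r, order = 3)
  pdf0 <- estimate_pdf(e_const, n_samples = 1e3, seed = 9)
  expect_true(pdf0$point_mass[1L])
  expect_error(estimate_pdf(e_lin, n_samples = 10), "n_samples")
})

test_that("a non-monotone cubic surrogate yields a double-lobed density", {
  r <- gauss_legendre_rule(4)
  # X = P3: turning points at zeta = +/- 1/sqrt(5), fold values -/+ 0.4472
  e <- gpc_project(legendre_eval(3, r$nodes), r, order = 3)
  # non-monotonicity on [-1, 1]
  z <- seq(-1, 1, length.out = 401)
  v <- evaluate_surrogate(e, z)[, 1L]
  expect_true(any(diff(v) > 0) && any(diff(v) < 0))
  pdf <- estimate_pdf(e, n_samples = 1e5, seed = 10, n_bins = 64)
  d <- pdf$density[, 1L]
  centers <- pdf$centers[, 1L]
  fold <- 0.4472
  lobe_lo <- max(d[abs(centers + fold) < 0.1])
  lobe_hi <- max(d[abs(centers - fold) < 0.1])
  valley <- min(d[abs(centers) < 0.2])
  expect_gt(lobe_lo, 1.5 * valley)
  expect_gt(lobe_hi, 1.5 * valley)
})

test_that("coefficient-decay diagnostics flag slow convergence", {
  r <- gauss_legendre_rule(4)
  # constant model: all ratios zero
  rat0 <- convergence_ratios(gpc_project(rep(5, 4), r, order = 3))
  expect_equal(unname(rat0[, 1L]), c(0, 0, 0), tolerance = 1e-12)
  # X = P3 + 10: ratios (0, 0, 0.1); exactly at threshold, no warning
  e <- gpc_project(legendre_eval(3, r$nodes) + 10, r, order = 3)
  expect_no_warning(rat <- convergence_ratios(e, threshold = 0.1))
  expect_equal(unname(rat[, 1L]), c(0, 0, 0.1), tolerance = 1e-12)
  expect_warning(convergence_ratios(e, threshold = 0.05), "truncation")
  # a0 = 0 is flagged and excluded
  ez <- gpc_project(cbind(legendre_eval(1, r$nodes), rep(1, 4)), r,
                    order = 3)
  ez$coefficients[1L, 1L] <- 0     # exact zero-mean sample
  expect_no_warning(ratz <- convergence_ratios(ez))
  expect_true(all(is.na(ratz[, 1L])))
  expect_equal(attr(ratz, "undefined"), 1L)
})

test_that("coefficient decay is monotone for a smooth nonlinear model", {
  # dense-projection oracle: high-order rule, smooth model
  r <- gauss_legendre_rule(12)
  e <- gpc_project(exp(0.8 * r$nodes), r, order = 5)
  mags <- abs(e$coefficients[, 1L])
  expect_true(all(diff(mags) < 0))
})
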