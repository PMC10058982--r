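#' Uniform uncertain parameter
#'
#' Describes the uncertain elastic modulus as a uniform random variable on
#' `[center * (1 - halfwidth_fraction), center * (1 + halfwidth_fraction)]`.
#' The default halfwidth of 0.23 widens the ~20% worst-case error of the
#' image-based stiffness estimate to a safe +/-23% band.  A halfwidth of 0
#' is accepted and collapses the parameter to a point mass (useful for
#' degenerate-uncertainty checks).
#'
#' @param center Central estimate (e.g. E-hat in Pa), > 0.
#' @param halfwidth_fraction Relative halfwidth, >= 0; default 0.23.
#' @return An object of class `uniform_parameter` with fields `center`,
#'   `halfwidth_fraction`, `support_low`, `support_high`.
#' @export
#' @examples
#' uniform_parameter(2.02e6)          # the +/-23% band about 2.02 MPa
uniform_parameter <- function(center, halfwidth_fraction = 0.23) {
  if (!is.finite(center) || center <= 0) {
    stop("center must be > 0", call. = FALSE)
  }
  if (!is.finite(halfwidth_fraction) || halfwidth_fraction < 0 ||
      halfwidth_fraction >= 1) {
    stop("halfwidth_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(list(center = center,
                 halfwidth_fraction = halfwidth_fraction,
                 support_low = center * (1 - halfwidth_fraction),
                 support_high = center * (1 + halfwidth_fraction)),
            class = "uniform_parameter")
}

#' @export
print.uniform_parameter <- function(x, ...) {
  cat(sprintf("<uniform_parameter> U[%.6g, %.6g] (center %.6g, +/-%g%%)\n",
              x$support_low, x$support_high, x$center,
              100 * x$halfwidth_fraction))
  invisible(x)
}

#' Gauss--Legendre quadrature rule on [-1, 1]
#'
#' Nodes are the roots of the degree-`n_points` Legendre polynomial,
#' computed by the Golub--Welsch eigenvalue method; weights are standard
#' Gauss--Legendre weights rescaled to the probability measure of the
#' uniform density eta(zeta) = 1/2 on `[-1, 1]`, so they sum to 1.  The
#' rule integrates polynomials of degree up to `2 * n_points - 1` exactly.
#'
#' @param n_points Number of quadrature points, >= 1.
#' @return An object of class `quadrature_rule` with fields `n_points`,
#'   `nodes` (ascending) and `weights`.
#' @export
#' @examples
#' gauss_legendre_rule(4)
gauss_legendre_rule <- function(n_points) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L) {
    stop("n_points must be a positive integer", call. = FALSE)
  }
  if (n_points == 1L) {
    nodes <- 0
    weights <- 1
  } else {
    # Golub-Welsch: symmetric tridiagonal Jacobi matrix of the Legendre
    # three-term recurrence; eigenvalues are the nodes, squared first
    # eigenvector components are the probability weights.
    k <- seq_len(n_points - 1L)
    b <- k / sqrt(4 * k^2 - 1)
    jac <- matrix(0, n_points, n_points)
    jac[cbind(k, k + 1L)] <- b
    jac[cbind(k + 1L, k)] <- b
    eig <- eigen(jac, symmetric = TRUE)
    ord <- order(eig$values)
    nodes <- eig$values[ord]
    weights <- eig$vectors[1L, ord]^2
    # enforce exact symmetry of the rule (kills eigen round-off asymmetry)
    nodes <- (nodes - rev(nodes)) / 2
    weights <- (weights + rev(weights)) / 2
    weights <- weights / sum(weights)
  }
  structure(list(n_points = n_points, nodes = nodes, weights = weights),
            class = "quadrature_rule")
}

#' @export
print.quadrature_rule <- function(x, ...) {
  cat(sprintf("<quadrature_rule> %d-point Gauss-Legendre (probability weights)\n",
              x$n_points))
  print(data.frame(node = x$nodes, weight = x$weights), row.names = FALSE)
  invisible(x)
}

#' Map quadrature nodes onto the uncertain-parameter support
#'
#' Affinely maps each node from `[-1, 1]` onto
#' `[support_low, support_high]`.  Values are returned in descending order,
#' so the first element x1 is the largest parameter value, matching the
#' conventional labelling x1 > x2 > ... of the quadrature points.
#'
#' @param rule A [gauss_legendre_rule()].
#' @param parameter A [uniform_parameter()].
#' @return Numeric vector of parameter values, descending.
#' @export
#' @examples
#' # the four stiffness values used for the deterministic runs about
#' # an image-based estimate of 2.02 MPa:
#' parameter_values_from_rule(gauss_legendre_rule(4),
#'                            uniform_parameter(2.02e6)) / 1e6
parameter_values_from_rule <- function(rule, parameter) {
  stopifnot(inherits(rule, "quadrature_rule"),
            inherits(parameter, "uniform_parameter"))
  center <- (parameter$support_low + parameter$support_high) / 2
  halfwidth <- (parameter$support_high - parameter$support_low) / 2
  sort(center + halfwidth * rule$nodes, decreasing = TRUE)
}

#' Evaluate a Legendre polynomial
#'
#' Degree-`r` Legendre polynomial by the three-term recurrence
#' `(k+1) P_{k+1} = (2k+1) zeta P_k - k P_{k-1}`, with the standard
#' normalization `P_r(1) = 1`.
#'
#' @param r Degree, integer >= 0.
#' @param zeta Evaluation point(s); must lie in `[-1, 1]` unless
#'   `extrapolate = TRUE`.
#' @param extrapolate Allow `|zeta| > 1` (with a warning); default `FALSE`.
#' @return Numeric vector, same length as `zeta`.
#' @export
legendre_eval <- function(r, zeta, extrapolate = FALSE) {
  r <- as.integer(r)
  if (is.na(r) || r < 0L) stop("degree r must be >= 0", call. = FALSE)
  if (any(abs(zeta) > 1 + 1e-12)) {
    if (extrapolate) {
      warning("evaluating Legendre polynomial outside [-1, 1]",
              call. = FALSE)
    } else {
      stop("zeta outside [-1, 1]; set extrapolate = TRUE to override",
           call. = FALSE)
    }
  }
  p_prev <- rep(1, length(zeta))        # P_0
  if (r == 0L) return(p_prev)
  p_cur <- zeta                          # P_1
  if (r == 1L) return(p_cur)
  for (k in 1L:(r - 1L)) {
    p_next <- ((2 * k + 1) * zeta * p_cur - k * p_prev) / (k + 1)
    p_prev <- p_cur
    p_cur <- p_next
  }
  p_cur
}

# Design matrix of Legendre polynomials: rows = zeta points, cols = degrees
# 0..order.
legendre_design <- function(zeta, order) {
  vapply(0:order, function(r) legendre_eval(r, zeta),
         numeric(length(zeta)))
}

#' Project deterministic model outputs onto the Legendre basis
#'
#' Non-intrusive spectral projection: given model outputs evaluated at the
#' quadrature nodes, each expansion coefficient is the discrete inner
#' product
#' `a_r = (2r + 1) * sum_q w_q * X(zeta_q) * P_r(zeta_q)`,
#' the Gauss--Legendre form of the projection integral with probability
#' weight eta = 1/2, for which `<P_r, P_r> = 1/(2r + 1)`.  Projection is
#' applied independently to every output sample (column), e.g. every time
#' instant of a flow or area curve.
#'
#' @param model_outputs Numeric matrix with one row per quadrature point
#'   (rows ordered to match `rule$nodes`, i.e. ascending zeta) and one
#'   column per output sample; a vector is treated as a single-column
#'   matrix.
#' @param rule The [gauss_legendre_rule()] at whose nodes the outputs were
#'   computed.
#' @param order Truncation order n; default 3.  Requires
#'   `rule$n_points >= order + 1`.
#' @return An object of class `gpc_expansion`: coefficients matrix of
#'   dimension `(order + 1) x n_samples`, plus `order` and `basis` fields.
#' @export
#' @examples
#' rule <- gauss_legendre_rule(4)
#' x <- legendre_eval(2, rule$nodes)       # the model IS P2
#' gpc_project(x, rule)$coefficients        # picks out a2 = 1
gpc_project <- function(model_outputs, rule, order = 3) {
  stopifnot(inherits(rule, "quadrature_rule"))
  order <- as.integer(order)
  if (is.na(order) || order < 0L) stop("order must be >= 0", call. = FALSE)
  if (rule$n_points < order + 1L) {
    stop(sprintf("a %d-point rule cannot resolve order %d (need >= %d points)",
                 rule$n_points, order, order + 1L), call. = FALSE)
  }
  if (is.null(dim(model_outputs))) {
    model_outputs <- matrix(model_outputs, ncol = 1L)
  }
  model_outputs <- as.matrix(model_outputs)
  if (nrow(model_outputs) != rule$n_points) {
    stop(sprintf(paste0("model_outputs has %d rows but the rule has %d ",
                        "points; one output set per quadrature point is ",
                        "required"),
                 nrow(model_outputs), rule$n_points), call. = FALSE)
  }
  if (any(!is.finite(model_outputs))) {
    stop("model_outputs contains non-finite values", call. = FALSE)
  }
  design <- legendre_design(rule$nodes, order)   # n_points x (order+1)
  scale <- 2 * (0:order) + 1
  coef <- scale * crossprod(design, rule$weights * model_outputs)
  structure(list(coefficients = coef, order = order, basis = "legendre"),
            class = "gpc_expansion")
}

#' @export
print.gpc_expansion <- function(x, ...) {
  cat(sprintf("<gpc_expansion> order %d (%s basis), %d sample(s)\n",
              x$order, x$basis, ncol(x$coefficients)))
  invisible(x)
}

#' Evaluate a gPC surrogate
#'
#' Computes `sum_r a_r P_r(zeta)` for each output sample.
#'
#' @param expansion A [gpc_project()] result.
#' @param zeta Standardized coordinate(s) in `[-1, 1]`.
#' @param extrapolate Passed to [legendre_eval()].
#' @return If `zeta` is scalar, a numeric vector with one value per output
#'   sample; otherwise a matrix `length(zeta) x n_samples`.
#' @export
evaluate_surrogate <- function(expansion, zeta, extrapolate = FALSE) {
  stopifnot(inherits(expansion, "gpc_expansion"))
  design <- legendre_design(zeta, expansion$order)
  if (length(zeta) == 1L) design <- matrix(design, nrow = 1L)
  out <- design %*% expansion$coefficients
  if (length(zeta) == 1L) drop(out) else out
}

#' Mean and standard deviation of a gPC expansion
#'
#' Closed-form moments under the uniform input density: the mean is the
#' zeroth coefficient and the variance is
#' `sum_{r>=1} a_r^2 / (2r + 1)` (the squared norms of the Legendre basis
#' under eta = 1/2).
#'
#' @param expansion A [gpc_project()] result.
#' @return List with numeric vectors `mean` and `std`, one entry per output
#'   sample.
#' @export
gpc_moments <- function(expansion) {
  stopifnot(inherits(expansion, "gpc_expansion"))
  coef <- expansion$coefficients
  m <- coef[1L, ]
  if (expansion$order == 0L) {
    v <- rep(0, ncol(coef))
  } else {
    r <- seq_len(expansion$order)
    v <- colSums(coef[r + 1L, , drop = FALSE]^2 / (2 * r + 1))
  }
  list(mean = unname(m), std = sqrt(pmax(v, 0)))
}

#' Sampled probability density of a gPC surrogate
#'
#' Draws `n_samples` values of zeta uniformly on `[-1, 1]` (seeded),
#' pushes them through the surrogate, and histograms each output sample
#' (e.g. each time instant) on `n_bins` equal-width bins spanning the
#' observed range, normalized to unit integral.  A Monte-Carlo estimator is
#' used rather than the analytic change of variables because a truncated
#' cubic surrogate may be non-monotone on `[-1, 1]`, making the analytic
#' density multi-branch (this is exactly the regime that produces
#' double-lobed densities).
#'
#' @param expansion A [gpc_project()] result.
#' @param n_samples Monte-Carlo draws, >= 1000; default 1e5.
#' @param seed Integer seed for the draws.
#' @param n_bins Number of histogram bins; default 64.
#' @return An object of class `gpc_pdf`: list with `density` and `centers`
#'   matrices (`n_bins x n_samples_out`), `bin_width` vector, and a logical
#'   `point_mass` vector flagging output samples whose surrogate is
#'   constant (zero-width value range); such columns carry the whole mass
#'   in a single bin.
#' @export
estimate_pdf <- function(expansion, n_samples = 1e5, seed = 1L,
                         n_bins = 64L) {
  stopifnot(inherits(expansion, "gpc_expansion"))
  n_samples <- as.integer(n_samples)
  n_bins <- as.integer(n_bins)
  if (is.na(n_samples) || n_samples < 1000L) {
    stop("n_samples must be >= 1000", call. = FALSE)
  }
  if (is.na(n_bins) || n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  zeta <- stats::runif(n_samples, -1, 1)
  vals <- evaluate_surrogate(expansion, zeta)   # n_samples x n_out
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1L)
  n_out <- ncol(vals)
  density <- matrix(0, n_bins, n_out)
  centers <- matrix(0, n_bins, n_out)
  bin_width <- numeric(n_out)
  point_mass <- logical(n_out)
  for (j in seq_len(n_out)) {
    v <- vals[, j]
    lo <- min(v)
    hi <- max(v)
    if (hi - lo <= max(1e-14, 1e-12 * abs(lo))) {
      point_mass[j] <- TRUE
      centers[, j] <- lo
      density[1L, j] <- 1   # conventional unit mass; width undefined
      bin_width[j] <- 0
      next
    }
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
    counts <- tabulate(pmin(pmax(findInterval(v, breaks,
                                              rightmost.closed = TRUE), 1L),
                            n_bins), nbins = n_bins)
    w <- breaks[2L] - breaks[1L]
    density[, j] <- counts / (n_samples * w)
    centers[, j] <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
    bin_width[j] <- w
  }
  structure(list(density = density, centers = centers,
                 bin_width = bin_width, point_mass = point_mass,
                 n_samples = n_samples, seed = as.integer(seed)),
            class = "gpc_pdf")
}

#' Coefficient-decay convergence diagnostics
#'
#' Truncation of the expansion at order n is trusted when the higher-order
#' coefficients are small relative to the zeroth: this returns the ratios
#' `|a_r / a_0|` for r = 1..n at every output sample and warns when the
#' maximum top-order ratio exceeds `threshold`.
#'
#' @param expansion A [gpc_project()] result.
#' @param threshold Warning threshold on `max |a_n / a_0|`; default 0.1.
#' @return Matrix `order x n_samples` of ratios (rows r = 1..n).  Samples
#'   with `a_0 = 0` yield `NA` ratios, are excluded from the warning
#'   summary, and are flagged in the `"undefined"` attribute.
#' @export
convergence_ratios <- function(expansion, threshold = 0.1) {
  stopifnot(inherits(expansion, "gpc_expansion"))
  if (expansion$order < 1L) {
    stop("convergence ratios need order >= 1", call. = FALSE)
  }
  coef <- expansion$coefficients
  a0 <- coef[1L, ]
  undefined <- a0 == 0
  ratios <- abs(sweep(coef[-1L, , drop = FALSE], 2L, a0, "/"))
  ratios[, undefined] <- NA_real_
  top <- ratios[nrow(ratios), !undefined]
  if (length(top) > 0L && any(top > threshold)) {
    warning(sprintf(paste0("gPC truncation suspect: max |a_%d/a_0| = %.3g ",
                           "exceeds %.3g; consider a higher order"),
                    expansion$order, max(top), threshold), call. = FALSE)
  }
  attr(ratios, "undefined") <- which(undefined)
  ratios
}
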