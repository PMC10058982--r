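#' Vessel geometry at diastole
#'
#' @param lumen_area_diastole Diastolic lumen area A0 (m^2).
#' @param wall_cross_sectional_area Wall cross-sectional area WCSA (m^2), the
#'   annulus between inner and outer wall contours at diastole.
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(lumen_area_diastole, wall_cross_sectional_area) {
  if (!is.finite(lumen_area_diastole) || lumen_area_diastole <= 0) {
    stop("lumen_area_diastole must be > 0", call. = FALSE)
  }
  if (!is.finite(wall_cross_sectional_area) || wall_cross_sectional_area <= 0) {
    stop("wall_cross_sectional_area must be > 0", call. = FALSE)
  }
  structure(list(lumen_area_diastole = lumen_area_diastole,
                 wall_cross_sectional_area = wall_cross_sectional_area),
            class = "vessel_geometry")
}

#' Locate the reflection-free early-systolic window on a QA curve
#'
#' The QA-loop method fits the flow--area relation only over the early
#' systolic upstroke, where the forward-travelling pulse has not yet been
#' contaminated by wave reflections and the Q(A) relation is approximately
#' linear.  The window is found on the first rising limb of the flow curve:
#' the contiguous run of samples whose flow lies between `low_fraction` and
#' `high_fraction` of the systolic peak, strictly before the peak sample.
#'
#' @param curves A [qa_curves()] object.
#' @param low_fraction,high_fraction Flow thresholds as fractions of the
#'   systolic peak flow; defaults 0.15 and 0.85 keep the fit away from the
#'   diastolic foot and from peak-flow flattening.
#' @return An object of class `early_systole_window` with integer fields
#'   `start_index`, `end_index` (inclusive, 1-based) and a `method` tag.
#' @export
#' @examples
#' qa <- synthesize_qa_curves(synthetic_spec(seed = 1))
#' detect_early_systole(qa)
detect_early_systole <- function(curves, low_fraction = 0.15,
                                 high_fraction = 0.85) {
  stopifnot(inherits(curves, "qa_curves"))
  if (!(low_fraction >= 0 && low_fraction < high_fraction &&
        high_fraction <= 1)) {
    stop("need 0 <= low_fraction < high_fraction <= 1", call. = FALSE)
  }
  q <- curves$flow
  p <- which.max(q)
  if (p == 1L || all(q[seq_len(p - 1L)] >= q[p])) {
    stop("degenerate input: flow has no rising limb before its peak",
         call. = FALSE)
  }
  lo <- low_fraction * q[p]
  hi <- high_fraction * q[p]
  # systolic foot: last sample before the peak still below the low
  # threshold (tolerates small ringing wiggles on the upstroke); if the
  # whole pre-peak trace sits above it, fall back to the pre-peak minimum
  below <- which(q[seq_len(p - 1L)] < lo)
  s0 <- if (length(below) > 0L) {
    max(below)
  } else {
    which.min(q[seq_len(p - 1L)])
  }
  cand <- seq.int(s0, p - 1L)
  keep <- cand[q[cand] >= lo & q[cand] <= hi]
  if (length(keep) > 0L) {
    # maximal contiguous run ending closest to the peak
    runs <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
    keep <- runs[[length(runs)]]
  }
  if (length(keep) < 3L) {
    stop(sprintf(paste0("early-systole window too small: %d qualifying ",
                        "sample(s), need >= 3 (widen the fractions or ",
                        "supply an explicit window)"), length(keep)),
         call. = FALSE)
  }
  early_systole_window(min(keep), max(keep), method = sprintf(
    "rising-limb fractional thresholds [%.2f, %.2f] of peak flow",
    low_fraction, high_fraction))
}

#' Explicit early-systole window
#'
#' Constructor for an index window on a QA curve, used by [fit_pwv()].  Most
#' users obtain one from [detect_early_systole()]; an explicit window can be
#' supplied when the selection rule is inappropriate (e.g. to mimic a
#' manually picked set of frames).
#'
#' @param start_index,end_index Inclusive 1-based sample indices,
#'   `start_index < end_index`, spanning at least 3 samples.
#' @param method Free-text tag recording how the window was chosen.
#' @return An object of class `early_systole_window`.
#' @export
early_systole_window <- function(start_index, end_index, method = "manual") {
  start_index <- as.integer(start_index)
  end_index <- as.integer(end_index)
  if (start_index < 1L || start_index >= end_index) {
    stop("need 1 <= start_index < end_index", call. = FALSE)
  }
  if (end_index - start_index + 1L < 3L) {
    stop("window must contain at least 3 samples", call. = FALSE)
  }
  structure(list(start_index = start_index, end_index = end_index,
                 method = method),
            class = "early_systole_window")
}

#' @export
print.early_systole_window <- function(x, ...) {
  cat(sprintf("<early_systole_window> samples %d..%d (%s)\n",
              x$start_index, x$end_index, x$method))
  invisible(x)
}

#' Pulse wave velocity from the QA loop
#'
#' Fits the first-order linear relation Q = PWV * A + const by ordinary
#' least squares over the early-systolic window; the slope dQ/dA is the
#' pulse wave velocity in m/s.
#'
#' @param curves A [qa_curves()] object.
#' @param window An `early_systole_window`, typically from
#'   [detect_early_systole()].
#' @return An object of class `pwv_estimate` with fields `pwv` (m/s),
#'   `r_squared` and `window`.
#' @export
fit_pwv <- function(curves, window) {
  stopifnot(inherits(curves, "qa_curves"),
            inherits(window, "early_systole_window"))
  n <- length(curves$time)
  if (window$end_index > n) {
    stop("window exceeds curve length", call. = FALSE)
  }
  idx <- seq.int(window$start_index, window$end_index)
  a <- curves$area[idx]
  q <- curves$flow[idx]
  if (max(a) - min(a) <= 0) {
    stop("degenerate fit: area is constant within the window", call. = FALSE)
  }
  fit <- stats::lm(q ~ a)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop(sprintf(paste0("non-physical QA slope %.4g m/s: the window is ",
                        "probably not on the early-systolic upstroke"),
                 slope), call. = FALSE)
  }
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((q - mean(q))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - ssr / sst)) else 1
  structure(list(pwv = slope, r_squared = r2, window = window),
            class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  cat(sprintf("<pwv_estimate> PWV = %.4g m/s (r^2 = %.4f, samples %d..%d)\n",
              x$pwv, x$r_squared, x$window$start_index, x$window$end_index))
  invisible(x)
}

#' Relative area change over the cardiac cycle
#'
#' RAC is the normalized peak-to-trough excursion of the lumen area.  The
#' default normalizes by the maximum area; `reference = "min"` and
#' `reference = "first"` (area of the first frame, conventionally diastolic)
#' are provided because the literature is not unanimous on the denominator.
#'
#' @param curves A [qa_curves()] object.
#' @param reference Denominator convention: `"max"` (default), `"min"` or
#'   `"first"`.
#' @return RAC, a dimensionless number in (0, 1) for `"max"`; the other
#'   conventions can exceed 1 in principle.
#' @export
compute_rac <- function(curves, reference = c("max", "min", "first")) {
  stopifnot(inherits(curves, "qa_curves"))
  reference <- match.arg(reference)
  a_max <- max(curves$area)
  a_min <- min(curves$area)
  if (a_max - a_min <= 0) {
    stop("zero deformation: area is constant over the cycle", call. = FALSE)
  }
  denom <- switch(reference, max = a_max, min = a_min,
                  first = curves$area[1L])
  (a_max - a_min) / denom
}

#' The chi correction factor
#'
#' chi = gamma / RAC links the empirical correction gamma (a function of
#' diastolic area, flow and internal pressure whose closed form is not part
#' of this package; it is supplied by the user) to the relative area change.
#' With chi = 1 the stiffness formula reduces to its original,
#' uncorrected form.
#'
#' @param gamma Dimensionless correction, > 0.
#' @param rac Relative area change in (0, 1), from [compute_rac()].
#' @return chi = gamma / rac.
#' @export
compute_chi <- function(gamma, rac) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (!is.finite(rac) || rac <= 0 || rac >= 1) {
    stop("rac must lie in (0, 1)", call. = FALSE)
  }
  gamma / rac
}

#' Elastic modulus of the vessel wall from PWV
#'
#' Implements the chi-corrected stiffness formula
#' `E = 3 * chi * rho * PWV^2 * (1 + A0 / WCSA)` (Pa), with A0 the diastolic
#' lumen area and WCSA the wall cross-sectional area.
#'
#' @param pwv A `pwv_estimate` from [fit_pwv()], or a bare positive number
#'   (m/s).
#' @param geometry A [vessel_geometry()].
#' @param blood_density Blood density rho (kg/m^3), default 1060.
#' @param chi Correction factor, default 1 (uncorrected formulation); supply
#'   [compute_chi()] output to apply the correction.
#' @param rac,gamma Optional bookkeeping values recorded in the result; when
#'   omitted they are back-filled so that `chi * rac = gamma` holds.
#' @return An object of class `elasticity_estimate` with fields
#'   `elastic_modulus` (Pa), `chi`, `gamma`, `rac`, `pwv` (m/s),
#'   `blood_density`, `r_squared`, `window`.
#' @export
#' @examples
#' geo <- vessel_geometry(8e-4, 2e-4)
#' estimate_elastic_modulus(5, geometry = vessel_geometry(9e-4, 1e-4))
estimate_elastic_modulus <- function(pwv, geometry, blood_density = 1060,
                                     chi = 1, rac = NA_real_,
                                     gamma = NA_real_) {
  window <- NULL
  r2 <- NA_real_
  if (inherits(pwv, "pwv_estimate")) {
    window <- pwv$window
    r2 <- pwv$r_squared
    pwv <- pwv$pwv
  }
  stopifnot(inherits(geometry, "vessel_geometry"))
  vals <- c(pwv = pwv, blood_density = blood_density, chi = chi)
  bad <- vals[!is.finite(vals) | vals <= 0]
  if (length(bad) > 0L) {
    stop("inputs must be strictly positive: ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  }
  area_ratio <- geometry$lumen_area_diastole /
    geometry$wall_cross_sectional_area
  e <- 3 * chi * blood_density * pwv^2 * (1 + area_ratio)
  # keep the chi * rac = gamma identity even when only one of them is known
  if (is.na(gamma) && !is.na(rac)) gamma <- chi * rac
  if (is.na(rac) && !is.na(gamma)) rac <- gamma / chi
  structure(list(elastic_modulus = e, chi = chi, gamma = gamma, rac = rac,
                 pwv = pwv, blood_density = blood_density,
                 r_squared = r2, window = window,
                 geometry = geometry),
            class = "elasticity_estimate")
}

#' @export
print.elasticity_estimate <- function(x, ...) {
  cat(sprintf("<elasticity_estimate> E = %.4g Pa (%.2f MPa)\n",
              x$elastic_modulus, x$elastic_modulus / 1e6))
  cat(sprintf("  PWV = %.4g m/s, chi = %.4g, RAC = %.4g, rho = %g kg/m^3\n",
              x$pwv, x$chi, x$rac, x$blood_density))
  if (!is.null(x$window)) {
    cat(sprintf("  window: samples %d..%d, r^2 = %.4f\n",
                x$window$start_index, x$window$end_index, x$r_squared))
  }
  invisible(x)
}

#' Pulse wave velocity implied by an elastic modulus
#'
#' Algebraic inverse of [estimate_elastic_modulus()]:
#' `PWV = sqrt(E / (3 * chi * rho * (1 + A0/WCSA)))`.  Used by the 0D
#' surrogate to convert a wall stiffness into a wave speed (and thence a
#' compliance).
#'
#' @inheritParams estimate_elastic_modulus
#' @param elastic_modulus E (Pa), > 0.
#' @return PWV in m/s.
#' @export
pwv_from_modulus <- function(elastic_modulus, geometry, blood_density = 1060,
                             chi = 1) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  vals <- c(elastic_modulus = elastic_modulus, blood_density = blood_density,
            chi = chi)
  bad <- vals[!is.finite(vals) | vals <= 0]
  if (length(bad) > 0L) {
    stop("inputs must be strictly positive: ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  }
  area_ratio <- geometry$lumen_area_diastole /
    geometry$wall_cross_sectional_area
  sqrt(elastic_modulus / (3 * chi * blood_density * (1 + area_ratio)))
}

#' Full chi-method chain: QA curves to elastic modulus
#'
#' Convenience wrapper running window detection, the QA-loop PWV fit, the
#' relative area change and the stiffness formula in one call.
#'
#' The gamma correction is not computed internally (its closed form depends
#' on pressure data this package does not model).  `gamma` may be `NULL`
#' (then chi = 1, the uncorrected formulation, and gamma is recorded as
#' chi * RAC so the chi * RAC = gamma identity holds), a positive scalar, or
#' a function `function(area, flow, pressure)` returning one.
#'
#' @inheritParams detect_early_systole
#' @inheritParams estimate_elastic_modulus
#' @param gamma `NULL`, a positive scalar, or a function of
#'   `(area, flow, pressure)`; see Details.
#' @param pressure Optional internal pressure (Pa) forwarded to a
#'   functional `gamma`.
#' @param window Optional explicit `early_systole_window`; when `NULL` the
#'   window is detected automatically.
#' @param rac_reference Denominator convention for [compute_rac()].
#' @return An `elasticity_estimate`.
#' @export
#' @examples
#' qa <- synthesize_qa_curves(synthetic_spec(seed = 42))
#' est <- estimate_elasticity(qa, geometry = vessel_geometry(8e-4, 2e-4))
#' est
estimate_elasticity <- function(curves, geometry, blood_density = 1060,
                                gamma = NULL, pressure = NULL,
                                low_fraction = 0.15, high_fraction = 0.85,
                                window = NULL,
                                rac_reference = c("max", "min", "first")) {
  stopifnot(inherits(curves, "qa_curves"))
  if (is.null(window)) {
    window <- detect_early_systole(curves, low_fraction, high_fraction)
  }
  pwv <- fit_pwv(curves, window)
  rac <- compute_rac(curves, reference = rac_reference)
  if (is.null(gamma)) {
    chi <- 1
    gamma_val <- chi * rac
  } else {
    gamma_val <- if (is.function(gamma)) {
      gamma(area = curves$area, flow = curves$flow, pressure = pressure)
    } else {
      gamma
    }
    chi <- compute_chi(gamma_val, rac)
  }
  estimate_elastic_modulus(pwv, geometry, blood_density = blood_density,
                           chi = chi, rac = rac, gamma = gamma_val)
}

#' Write a plain-text elasticity report
#'
#' @param estimate An `elasticity_estimate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_elasticity_report <- function(estimate, path) {
  stopifnot(inherits(estimate, "elasticity_estimate"))
  lines <- c(
    "# chi-method elasticity report",
    sprintf("elastic_modulus_pa,%.10g", estimate$elastic_modulus),
    sprintf("elastic_modulus_mpa,%.4f", estimate$elastic_modulus / 1e6),
    sprintf("pwv_m_per_s,%.10g", estimate$pwv),
    sprintf("rac,%.10g", estimate$rac),
    sprintf("chi,%.10g", estimate$chi),
    sprintf("gamma,%.10g", estimate$gamma),
    sprintf("blood_density_kg_per_m3,%.10g", estimate$blood_density),
    sprintf("r_squared,%.10g", estimate$r_squared),
    if (!is.null(estimate$window)) {
      sprintf("window_start_index,%d\nwindow_end_index,%d",
              estimate$window$start_index, estimate$window$end_index)
    }
  )
  writeLines(lines, path)
  invisible(path)
}
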