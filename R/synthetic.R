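#' Inflow waveform
#'
#' Periodic inlet flow descriptor used by [run_cycles()].  Either a
#' closed-form function of time or a sampled waveform (interpolated
#' linearly and periodically) can be supplied; [make_inflow_waveform()]
#' builds the standard half-sine systolic waveform.
#'
#' @param period Cardiac cycle duration (s), > 0.
#' @param fun Function of time (s) returning flow (m^3/s); evaluated on
#'   `[0, period)` after periodic reduction.
#' @param time,flow Sampled waveform (used when `fun` is `NULL`); `time`
#'   in `[0, period)`.
#' @return An object of class `inflow_waveform` with fields `period` and
#'   `fun` (a periodic function of absolute time).
#' @export
inflow_waveform <- function(period, fun = NULL, time = NULL, flow = NULL) {
  if (!is.finite(period) || period <= 0) {
    stop("period must be > 0", call. = FALSE)
  }
  if (is.null(fun)) {
    if (is.null(time) || is.null(flow) || length(time) != length(flow)) {
      stop("supply either fun or matching time/flow samples", call. = FALSE)
    }
    # periodic linear interpolant: close the cycle with the first sample
    tt <- c(time, time[1L] + period)
    qq <- c(flow, flow[1L])
    base_fun <- function(t) stats::approx(tt, qq, xout = t, rule = 2)$y
  } else {
    base_fun <- fun
  }
  periodic <- function(t) base_fun(t %% period)
  structure(list(period = period, fun = periodic),
            class = "inflow_waveform")
}

#' Half-sine systolic inflow waveform
#'
#' `Q(t) = Q_peak * sin(pi * t / T_sys)` during systole
#' (`T_sys = systolic_fraction * period`) and zero in diastole, with
#' `Q_peak = pi * SV / (2 * T_sys)` so the integral over one cycle equals
#' the stroke volume exactly.  This is a generic stand-in for a measured
#' patient inflow waveform.
#'
#' @param period Cycle duration (s); default 1.12.
#' @param stroke_volume SV (m^3) ejected per cycle; default 8e-5 (80 mL),
#'   which combined with the standard RCR outlet values yields a
#'   physiological mean aortic pressure near 100 mmHg.
#' @param systolic_fraction Fraction of the cycle occupied by systole, in
#'   (0, 1); default 0.35.
#' @param n_samples Number of samples of the attached sampled
#'   representation; default 224 (one cycle at 5 ms).
#' @return An [inflow_waveform()] with additional fields `stroke_volume`,
#'   `systolic_fraction`, `peak_flow`, `time`, `flow`.
#' @export
#' @examples
#' w <- make_inflow_waveform()
#' w$peak_flow                      # pi * SV / (2 * T_sys)
#' sum(w$flow) * w$period / 224     # integrates back to the stroke volume
make_inflow_waveform <- function(period = 1.12, stroke_volume = 8e-5,
                                 systolic_fraction = 0.35,
                                 n_samples = 224L) {
  if (!is.finite(stroke_volume) || stroke_volume <= 0) {
    stop("stroke_volume must be > 0", call. = FALSE)
  }
  if (!is.finite(systolic_fraction) || systolic_fraction <= 0 ||
      systolic_fraction >= 1) {
    stop("systolic_fraction must lie in (0, 1)", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 8L) {
    stop("n_samples must be >= 8", call. = FALSE)
  }
  t_sys <- systolic_fraction * period
  q_peak <- pi * stroke_volume / (2 * t_sys)
  fun <- function(t) ifelse(t >= 0 & t <= t_sys,
                            q_peak * sin(pi * t / t_sys), 0)
  w <- inflow_waveform(period, fun = fun)
  w$stroke_volume <- stroke_volume
  w$systolic_fraction <- systolic_fraction
  w$peak_flow <- q_peak
  w$time <- (seq_len(n_samples) - 1L) * period / n_samples
  w$flow <- fun(w$time)
  w
}

#' @export
print.inflow_waveform <- function(x, ...) {
  cat(sprintf("<inflow_waveform> period %.4g s", x$period))
  if (!is.null(x$stroke_volume)) {
    cat(sprintf(", SV %.3g m^3, systole %.0f%% of cycle, peak %.3g m^3/s",
                x$stroke_volume, 100 * x$systolic_fraction, x$peak_flow))
  }
  cat("\n")
  invisible(x)
}

#' Specification of a synthetic PCMRI-like QA dataset
#'
#' Describes the stated world of the generator: a single compliant segment
#' with known ground-truth wall stiffness, terminated by an
#' impedance-matched Windkessel, sampled at `n_frames` cardiac frames with
#' optional additive Gaussian measurement noise.
#'
#' @param ground_truth_modulus True wall elastic modulus E (Pa); default
#'   2.02e6.
#' @param geometry A [vessel_geometry()]; default A0 = 8e-4 m^2 (ascending
#'   aorta calibre) with WCSA = A0 / 4.
#' @param period Cycle duration (s); default 1.12.
#' @param n_frames Cardiac frames per cycle, >= 8; default 30
#'   (retrospectively gated PCMRI).
#' @param noise_sd_flow,noise_sd_area Additive Gaussian noise standard
#'   deviations (m^3/s, m^2) applied per frame; defaults 0.
#' @param seed Integer seed controlling the noise draws.
#' @param chi Correction factor shared by the generator and (by contract)
#'   the estimator; default 1.
#' @param stroke_volume,systolic_fraction Inflow shape, see
#'   [make_inflow_waveform()].
#' @param segment_length Segment length (m); default 0.1.
#' @param blood_density,blood_viscosity Blood constants.
#' @param mean_pressure Target mean arterial pressure (Pa) used to size the
#'   distal Windkessel resistance; default 13300 (~100 mmHg).
#' @param n_cycles,dt Surrogate run-in settings; defaults 10 cycles at
#'   5 ms.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(ground_truth_modulus = 2.02e6,
                           geometry = vessel_geometry(8e-4, 2e-4),
                           period = 1.12, n_frames = 30L,
                           noise_sd_flow = 0, noise_sd_area = 0,
                           seed = 1L, chi = 1,
                           stroke_volume = 8e-5, systolic_fraction = 0.35,
                           segment_length = 0.1,
                           blood_density = 1060, blood_viscosity = 0.05,
                           mean_pressure = 13300,
                           n_cycles = 10L, dt = 0.005) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 8L) {
    stop("n_frames must be >= 8", call. = FALSE)
  }
  if (!is.finite(period) || period <= 0) stop("period must be > 0",
                                              call. = FALSE)
  if (noise_sd_flow < 0 || noise_sd_area < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  if (!is.finite(ground_truth_modulus) || ground_truth_modulus <= 0) {
    stop("ground_truth_modulus must be > 0", call. = FALSE)
  }
  structure(list(ground_truth_modulus = ground_truth_modulus,
                 geometry = geometry, period = period, n_frames = n_frames,
                 noise_sd_flow = noise_sd_flow,
                 noise_sd_area = noise_sd_area,
                 seed = as.integer(seed), chi = chi,
                 stroke_volume = stroke_volume,
                 systolic_fraction = systolic_fraction,
                 segment_length = segment_length,
                 blood_density = blood_density,
                 blood_viscosity = blood_viscosity,
                 mean_pressure = mean_pressure,
                 n_cycles = as.integer(n_cycles), dt = dt),
            class = "synthetic_spec")
}

# Single-segment network configuration implementing the generator's stated
# world.  The terminal Windkessel is impedance matched (Rp equals the
# segment's characteristic impedance rho * pwv / A0) and its reservoir is
# slow (R_p * C = 20 cycles), so that over the early-systolic upstroke the
# measurement plane sees a reflection-free load and dQ/dA there equals the
# wave speed -- the 0D embodiment of the QA-loop method's central
# assumption.  The reservoir is warm-started at its exact periodic mean
# (Q_mean * Rd) because its relaxation time far exceeds the 10-cycle
# run-in.
single_segment_config <- function(spec) {
  geo <- spec$geometry
  pwv <- pwv_from_modulus(spec$ground_truth_modulus, geo,
                          blood_density = spec$blood_density,
                          chi = spec$chi)
  z_c <- spec$blood_density * pwv / geo$lumen_area_diastole
  c_wk <- 20 * spec$period / z_c
  q_mean <- spec$stroke_volume / spec$period
  rd <- spec$mean_pressure / q_mean - z_c
  if (rd <= 0) {
    stop(paste0("synthetic world infeasible: characteristic impedance ",
                "exceeds the total resistance implied by mean_pressure"),
         call. = FALSE)
  }
  pc0 <- q_mean * rd
  list(
    segments = list(vessel_segment(
      "CS1", spec$segment_length, geo$lumen_area_diastole,
      geo$wall_cross_sectional_area, spec$ground_truth_modulus,
      chi = spec$chi)),
    outlets = list(terminal = list(
      proximal_resistance = z_c, capacitance = c_wk,
      distal_resistance = rd, attach_after = "CS1",
      state_pressure = pc0)),
    blood_density = spec$blood_density,
    blood_viscosity = spec$blood_viscosity,
    initial_state = list(node_pressures = c(pc0, pc0),
                         segment_flows = 0,
                         outlet_pressures = pc0)
  )
}

#' Generate a synthetic PCMRI-like QA dataset with known ground truth
#'
#' Runs the single-segment surrogate described by `spec` to periodic steady
#' state, measures flow at the distal (outlet) interface and lumen area
#' from the distal node pressure through the linear tube law, resamples
#' both to `n_frames` uniform cardiac frames by linear interpolation
#' (emulating retrospective gating), and adds seeded Gaussian frame noise.
#'
#' With zero noise the chi-method chain applied to the output recovers the
#' ground-truth modulus to within a few percent; the residual is the
#' (small) reservoir drift over the early-systolic window plus resampling
#' error.
#'
#' @param spec A [synthetic_spec()].
#' @param inflow Optional [inflow_waveform()]; by default the half-sine
#'   waveform implied by `spec`.
#' @return A [qa_curves()] object with attributes `ground_truth_modulus`
#'   (Pa) and `synthetic_spec`.
#' @export
#' @examples
#' qa <- synthesize_qa_curves(synthetic_spec(seed = 7))
#' attr(qa, "ground_truth_modulus")
synthesize_qa_curves <- function(spec, inflow = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(inflow)) {
    inflow <- make_inflow_waveform(spec$period, spec$stroke_volume,
                                   spec$systolic_fraction,
                                   n_samples = round(spec$period / spec$dt))
  }
  network <- assemble_network(single_segment_config(spec))
  res <- run_cycles(network, inflow, n_cycles = spec$n_cycles,
                    dt = spec$dt)
  # measurement plane: flow into the matched outlet, area from the distal
  # node pressure (same node, so the fast node capacitor cancels out)
  q_fine <- res$outlet_flow[, 1L]
  a_fine <- res$area[, 1L]
  t_fine <- res$time
  # periodic closure for interpolation up to t = period
  tt <- c(t_fine, spec$period)
  qq <- c(q_fine, q_fine[1L])
  aa <- c(a_fine, a_fine[1L])
  t_frames <- (seq_len(spec$n_frames) - 1L) * spec$period / spec$n_frames
  q_s <- stats::approx(tt, qq, xout = t_frames)$y
  a_s <- stats::approx(tt, aa, xout = t_frames)$y
  if (spec$noise_sd_flow > 0 || spec$noise_sd_area > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(spec$seed)
    q_s <- q_s + stats::rnorm(spec$n_frames, sd = spec$noise_sd_flow)
    a_s <- a_s + stats::rnorm(spec$n_frames, sd = spec$noise_sd_area)
  }
  out <- qa_curves(t_frames, q_s, a_s, period = spec$period)
  attr(out, "ground_truth_modulus") <- spec$ground_truth_modulus
  attr(out, "synthetic_spec") <- spec
  out
}

#' Ready-made network configurations
#'
#' Three presets:
#' \describe{
#'   \item{`aorta_default`}{Five tapering segments (CS1 proximal to the
#'     valve, CS2 before and CS3 after the supra-aortic junction, CS4/CS5
#'     descending), three supra-aortic Windkessel outlets at the junction
#'     and a terminal descending-aorta Windkessel, with standard RCR
#'     values; wall stiffness 2.02 MPa throughout.  Geometry is a labelled
#'     synthetic fixture (A0 tapering 8e-4 to 3e-4 m^2, WCSA = A0/4,
#'     lengths summing to 0.35 m), not a patient measurement.}
#'   \item{`stiff_aorta`}{`aorta_default` with every segment's elastic
#'     modulus doubled.}
#'   \item{`single_segment`}{The generator topology of
#'     [synthesize_qa_curves()] at its default spec.}
#' }
#'
#' @param preset One of `"aorta_default"`, `"single_segment"`,
#'   `"stiff_aorta"`.
#' @return A configuration list accepted by [assemble_network()], also
#'   carrying an `inflow` element (period, stroke volume, systolic
#'   fraction) and a `labels` element.
#' @export
#' @examples
#' cfg <- make_fixture_config("aorta_default")
#' assemble_network(cfg)
make_fixture_config <- function(preset = c("aorta_default",
                                           "single_segment",
                                           "stiff_aorta")) {
  preset <- match.arg(preset)
  if (preset == "single_segment") {
    cfg <- single_segment_config(synthetic_spec())
    cfg$inflow <- list(period = 1.12, stroke_volume = 8e-5,
                       systolic_fraction = 0.35)
    cfg$labels <- "CS1"
    cfg$preset <- preset
    return(cfg)
  }
  a0 <- c(CS1 = 8e-4, CS2 = 7e-4, CS3 = 5e-4, CS4 = 4e-4, CS5 = 3e-4)
  len <- c(CS1 = 0.06, CS2 = 0.06, CS3 = 0.06, CS4 = 0.08, CS5 = 0.09)
  e_wall <- if (preset == "stiff_aorta") 2 * 2.02e6 else 2.02e6
  segments <- lapply(names(a0), function(lab) {
    vessel_segment(lab, len[[lab]], a0[[lab]], a0[[lab]] / 4, e_wall,
                   chi = 1)
  })
  outlets <- list(
    brachiocephalic_artery = list(
      proximal_resistance = 1.3e7, capacitance = 1.5e-9,
      distal_resistance = 1.3e9, attach_after = "CS2"),
    left_common_carotid_artery = list(
      proximal_resistance = 5.1e7, capacitance = 3.8e-10,
      distal_resistance = 5.0e9, attach_after = "CS2"),
    left_subclavian_artery = list(
      proximal_resistance = 1.1e7, capacitance = 1.7e-9,
      distal_resistance = 1.1e9, attach_after = "CS2"),
    descending_aorta = list(
      proximal_resistance = 2.5e6, capacitance = 7.7e-9,
      distal_resistance = 2.4e8, attach_after = "CS5")
  )
  cfg <- list(segments = segments, outlets = outlets,
              blood_density = 1060, blood_viscosity = 0.05,
              inflow = list(period = 1.12, stroke_volume = 8e-5,
                            systolic_fraction = 0.35),
              labels = names(a0), preset = preset)
  # warm-start at the DC (purely resistive) solution: the outlet reservoir
  # time constants Rd*C are ~1.9 s, so a cold start would still carry a
  # ~0.3% transient after the standard 10-cycle run-in
  cfg$initial_state <- dc_initial_state(cfg)
  cfg
}

# Mean-flow (DC) operating point of a network configuration: node
# pressures at the common mean pressure, outlet capacitors at their
# voltage-divider share, segment flows carrying the mean flow minus
# upstream offtakes.  Segment viscous resistances are negligible against
# the outlet resistances and are ignored here; the run-in removes the
# residual.
dc_initial_state <- function(config) {
  labels <- vapply(config$segments, function(s) s$label, character(1L))
  ns <- length(labels)
  q_mean <- config$inflow$stroke_volume / config$inflow$period
  g <- vapply(config$outlets, function(o) {
    1 / (o$proximal_resistance + o$distal_resistance)
  }, numeric(1L))
  p_bar <- q_mean / sum(g)
  q_out <- p_bar * g
  attach <- vapply(config$outlets, function(o) {
    match(o$attach_after, labels)
  }, integer(1L))
  seg_flow <- vapply(seq_len(ns), function(i) {
    q_mean - sum(q_out[attach < i])
  }, numeric(1L))
  pc <- vapply(seq_along(config$outlets), function(k) {
    o <- config$outlets[[k]]
    p_bar * o$distal_resistance /
      (o$proximal_resistance + o$distal_resistance)
  }, numeric(1L))
  list(node_pressures = rep(p_bar, ns + 1L),
       segment_flows = seg_flow,
       outlet_pressures = pc)
}

#' Set the wall elastic modulus of every segment in a configuration
#'
#' Helper used by the UQ batch driver: returns a copy of `config` with
#' every segment's `elastic_modulus` replaced.
#'
#' @param config A configuration list as from [make_fixture_config()].
#' @param elastic_modulus New E (Pa), > 0.
#' @return The modified configuration list.
#' @export
set_network_modulus <- function(config, elastic_modulus) {
  if (!is.finite(elastic_modulus) || elastic_modulus <= 0) {
    stop("elastic_modulus must be > 0", call. = FALSE)
  }
  config$segments <- lapply(config$segments, function(s) {
    s$elastic_modulus <- elastic_modulus
    s
  })
  config
}
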