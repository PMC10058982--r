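#' Compliant vessel segment specification
#'
#' One lumped segment of the 0D aortic network, labelled by the
#' cross-section whose flow and area it reports.
#'
#' @param label Cross-section tag, e.g. `"CS1"`.
#' @param length Segment length (m), > 0.
#' @param lumen_area_diastole Diastolic lumen area A0 (m^2), > 0.
#' @param wall_cross_sectional_area WCSA (m^2), > 0.
#' @param elastic_modulus Wall elastic modulus E (Pa), > 0.
#' @param chi Correction factor linking E to the wave speed; default 1.
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(label, length, lumen_area_diastole,
                           wall_cross_sectional_area, elastic_modulus,
                           chi = 1) {
  vals <- c(length = length, lumen_area_diastole = lumen_area_diastole,
            wall_cross_sectional_area = wall_cross_sectional_area,
            elastic_modulus = elastic_modulus, chi = chi)
  bad <- vals[!is.finite(vals) | vals <= 0]
  if (base::length(bad) > 0L) {
    stop("vessel_segment '", label, "': non-positive field(s): ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  }
  structure(list(label = as.character(label), length = length,
                 lumen_area_diastole = lumen_area_diastole,
                 wall_cross_sectional_area = wall_cross_sectional_area,
                 elastic_modulus = elastic_modulus, chi = chi),
            class = "vessel_segment")
}

#' Reduced-order parameters of a vessel segment
#'
#' Re-expresses a compliant segment as a resistance--inertance--compliance
#' triplet: the wave speed follows from the wall stiffness via
#' [pwv_from_modulus()], the volume compliance from the Bramwell--Hill
#' relation `C = A0 * L / (rho * PWV^2)`, the viscous resistance from
#' Poiseuille flow `R = 8 * pi * mu * L / A0^2`, and the blood inertance
#' from `L_inert = rho * L / A0`.
#'
#' @param spec A [vessel_segment()].
#' @param blood_density rho (kg/m^3), default 1060.
#' @param blood_viscosity Dynamic viscosity mu (kg/(m s)), default 0.05.
#' @return List of class `segment_params` with fields `pwv` (m/s),
#'   `compliance` (m^3/Pa), `resistance` (Pa s/m^3), `inertance`
#'   (Pa s^2/m^3).
#' @export
#' @examples
#' seg <- vessel_segment("CS1", 0.05, 8e-4, 2e-4, 2.02e6)
#' derive_segment_params(seg)
derive_segment_params <- function(spec, blood_density = 1060,
                                  blood_viscosity = 0.05) {
  stopifnot(inherits(spec, "vessel_segment"))
  if (!is.finite(blood_density) || blood_density <= 0 ||
      !is.finite(blood_viscosity) || blood_viscosity <= 0) {
    stop("blood density and viscosity must be > 0", call. = FALSE)
  }
  geo <- vessel_geometry(spec$lumen_area_diastole,
                         spec$wall_cross_sectional_area)
  pwv <- pwv_from_modulus(spec$elastic_modulus, geo,
                          blood_density = blood_density, chi = spec$chi)
  compliance <- spec$lumen_area_diastole * spec$length /
    (blood_density * pwv^2)
  resistance <- 8 * pi * blood_viscosity * spec$length /
    spec$lumen_area_diastole^2
  inertance <- blood_density * spec$length / spec$lumen_area_diastole
  out <- list(pwv = pwv, compliance = compliance, resistance = resistance,
              inertance = inertance)
  if (any(!vapply(out, function(v) is.finite(v) && v > 0, logical(1L)))) {
    stop("derived segment parameters must be positive and finite",
         call. = FALSE)
  }
  class(out) <- "segment_params"
  out
}

#' Three-element Windkessel outlet
#'
#' RCR outlet boundary model: proximal resistance `Rp`, compliance `C` and
#' distal resistance `Rd`, with the stored state pressure on the
#' capacitor.
#'
#' @param proximal_resistance Rp (kg s^-1 m^-4 = Pa s/m^3), > 0.
#' @param capacitance C (m^3/Pa), > 0.
#' @param distal_resistance Rd (kg s^-1 m^-4), > 0.
#' @param state_pressure Initial capacitor pressure (Pa); default 0.
#' @return An object of class `windkessel_outlet`.
#' @export
windkessel_outlet <- function(proximal_resistance, capacitance,
                              distal_resistance, state_pressure = 0) {
  vals <- c(proximal_resistance = proximal_resistance,
            capacitance = capacitance,
            distal_resistance = distal_resistance)
  bad <- vals[!is.finite(vals) | vals <= 0]
  if (length(bad) > 0L) {
    stop("windkessel_outlet: non-positive field(s): ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  }
  structure(list(proximal_resistance = proximal_resistance,
                 capacitance = capacitance,
                 distal_resistance = distal_resistance,
                 state_pressure = state_pressure),
            class = "windkessel_outlet")
}

#' Advance a Windkessel outlet by one explicit step
#'
#' Integrates the capacitor equation `dp_c/dt = (Q - p_c / Rd) / C` with
#' one explicit Euler step under the given inflow, and reports the
#' interface pressure `p = p_c + Q * Rp`.  Under constant inflow the
#' interface pressure converges to the closed form `Q * (Rp + Rd)`.
#'
#' @param outlet A [windkessel_outlet()].
#' @param inflow Flow into the outlet (m^3/s) over the step.
#' @param dt Step size (s), > 0.
#' @return List with `pressure` (interface pressure after the step, Pa) and
#'   `outlet` (the outlet with updated state).
#' @export
windkessel_step <- function(outlet, inflow, dt) {
  stopifnot(inherits(outlet, "windkessel_outlet"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  pc <- outlet$state_pressure +
    dt * (inflow - outlet$state_pressure / outlet$distal_resistance) /
      outlet$capacitance
  if (!is.finite(pc)) {
    stop("Windkessel state overflow: dt too large for this RC time constant",
         call. = FALSE)
  }
  outlet$state_pressure <- pc
  list(pressure = pc + inflow * outlet$proximal_resistance, outlet = outlet)
}

#' Assemble a lumped-parameter arterial network
#'
#' Builds the deterministic surrogate: a serial chain of compliant segments
#' with Windkessel outlets attached at named positions.  The aortic
#' topology is two ascending/arch segments, a supra-aortic junction
#' carrying three Windkessel outlets, three further segments, and a
#' terminal descending-aorta Windkessel.
#'
#' The network state is: one pressure per node (node 0 is the inlet, node i
#' the distal end of segment i), one flow per segment, and one capacitor
#' pressure per outlet.  Each node lumps half the compliance of its
#' adjacent segments.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{segments}{list of [vessel_segment()]s (or plain lists with the
#'       same fields), ordered from the inlet.}
#'     \item{outlets}{named list; each element has fields `proximal_resistance`,
#'       `capacitance`, `distal_resistance`, and `attach_after` (the label of
#'       the segment after whose distal node the outlet branches; the last
#'       segment's node is the terminal outlet position).}
#'     \item{blood_density}{kg/m^3, default 1060.}
#'     \item{blood_viscosity}{kg/(m s), default 0.05.}
#'     \item{initial_state}{optional named list with `node_pressures`,
#'       `segment_flows`, `outlet_pressures`; defaults to all zero.}
#'   }
#'   [make_fixture_config()] produces ready-made configurations.
#' @return An object of class `network_model`.
#' @export
assemble_network <- function(config) {
  if (is.null(config$segments) || length(config$segments) < 1L) {
    stop("configuration error: 'segments' is missing or empty",
         call. = FALSE)
  }
  if (is.null(config$outlets) || length(config$outlets) < 1L) {
    stop("configuration error: 'outlets' is missing or empty",
         call. = FALSE)
  }
  rho <- config$blood_density %||% 1060
  mu <- config$blood_viscosity %||% 0.05
  if (!is.finite(rho) || rho <= 0) {
    stop("configuration error: blood_density must be > 0", call. = FALSE)
  }
  if (!is.finite(mu) || mu <= 0) {
    stop("configuration error: blood_viscosity must be > 0", call. = FALSE)
  }
  segments <- lapply(config$segments, function(s) {
    if (inherits(s, "vessel_segment")) return(s)
    vessel_segment(s$label, s$length, s$lumen_area_diastole,
                   s$wall_cross_sectional_area, s$elastic_modulus,
                   s$chi %||% 1)
  })
  labels <- vapply(segments, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) {
    stop("configuration error: duplicated segment labels", call. = FALSE)
  }
  params <- lapply(segments, derive_segment_params,
                   blood_density = rho, blood_viscosity = mu)
  outlet_names <- names(config$outlets)
  if (is.null(outlet_names) || any(outlet_names == "")) {
    stop("configuration error: every outlet must be named", call. = FALSE)
  }
  outlets <- vector("list", length(config$outlets))
  attach_node <- integer(length(config$outlets))
  for (k in seq_along(config$outlets)) {
    o <- config$outlets[[k]]
    for (field in c("proximal_resistance", "capacitance",
                    "distal_resistance", "attach_after")) {
      if (is.null(o[[field]])) {
        stop(sprintf("configuration error: outlet '%s' is missing '%s'",
                     outlet_names[k], field), call. = FALSE)
      }
    }
    node <- match(o$attach_after, labels)
    if (is.na(node)) {
      stop(sprintf(paste0("configuration error: outlet '%s' attaches after ",
                          "unknown segment '%s'"),
                   outlet_names[k], o$attach_after), call. = FALSE)
    }
    outlets[[k]] <- windkessel_outlet(o$proximal_resistance, o$capacitance,
                                      o$distal_resistance,
                                      o$state_pressure %||% 0)
    attach_node[k] <- node
  }
  names(outlets) <- outlet_names
  if (!(length(segments) %in% attach_node)) {
    stop("configuration error: the terminal node needs an outlet",
         call. = FALSE)
  }
  ns <- length(segments)
  comp <- vapply(params, `[[`, numeric(1L), "compliance")
  # half-compliance lumped at each end of every segment
  node_cap <- numeric(ns + 1L)
  node_cap[1L] <- comp[1L] / 2
  if (ns > 1L) {
    node_cap[2:ns] <- (comp[1:(ns - 1L)] + comp[2:ns]) / 2
  }
  node_cap[ns + 1L] <- comp[ns] / 2
  init <- config$initial_state
  state <- list(
    node_pressures = init$node_pressures %||% numeric(ns + 1L),
    segment_flows = init$segment_flows %||% numeric(ns),
    outlet_pressures = init$outlet_pressures %||%
      numeric(length(outlets))
  )
  if (length(state$node_pressures) != ns + 1L ||
      length(state$segment_flows) != ns ||
      length(state$outlet_pressures) != length(outlets)) {
    stop("configuration error: initial_state dimensions do not match",
         call. = FALSE)
  }
  structure(list(segments = segments, params = params, outlets = outlets,
                 outlet_nodes = attach_node, node_capacitance = node_cap,
                 blood_density = rho, blood_viscosity = mu,
                 labels = labels, initial_state = state),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d segment(s) [%s], %d Windkessel outlet(s)\n",
              length(x$segments), paste(x$labels, collapse = ", "),
              length(x$outlets)))
  cat(sprintf("  rho = %g kg/m^3, mu = %g kg/(m s)\n",
              x$blood_density, x$blood_viscosity))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the surrogate to periodic steady state
#'
#' Integrates the network ODEs with a fixed-step classical 4th-order
#' Runge--Kutta scheme for `n_cycles` cardiac cycles and returns the final
#' cycle.  Periodicity is reported as the relative L2 difference between
#' the node-pressure traces of the last two cycles.
#'
#' Per-segment areas follow the linear tube law about diastole,
#' `A_i(t) = A0_i * (1 + (p_i(t) - p_dias_i) / (rho * pwv_i^2))`, with the
#' diastolic reference pressure taken as the minimum nodal pressure of the
#' final cycle (or a constant supplied via `p_diastolic`).
#'
#' The output grid step is `dt`; internally the integrator substeps
#' `dt` when a conservative linear stability estimate (node-capacitance
#' relaxation against the outlet proximal resistances, segment LC ringing,
#' Windkessel reservoir rates) demands it, since the resistive load on a
#' small junction or terminal node capacitance can make the system stiffer
#' than the 5 ms reporting step.
#'
#' @param network A [assemble_network()] result.
#' @param inflow An [inflow_waveform()] (or any function of time in
#'   seconds returning m^3/s, together with a `period` attribute).
#' @param n_cycles Number of cardiac cycles, >= 2; default 10.
#' @param dt Output time step (s); must divide the period to within one
#'   part in 1e6; default 0.005.
#' @param periodicity_tol Warning threshold on the periodicity error;
#'   default 1e-3.
#' @param substeps Optional override of the number of internal RK4
#'   substeps per output step (default: chosen automatically from the
#'   stability estimate); useful for step-refinement convergence checks.
#' @param p_diastolic Optional constant diastolic reference pressure (Pa)
#'   used in the tube law instead of the per-node cycle minimum.
#' @return An object of class `simulation_result` with fields `time`
#'   (final-cycle sample times starting at 0), `flow`, `area`, `pressure`
#'   (matrices, one column per segment label), `outlet_flow` (one column
#'   per outlet), `inflow` (sampled inlet flow), `periodicity_error`,
#'   `converged`, `period`, `dt` and the `network`.
#' @export
run_cycles <- function(network, inflow, n_cycles = 10, dt = 0.005,
                       periodicity_tol = 1e-3, p_diastolic = NULL,
                       substeps = NULL) {
  stopifnot(inherits(network, "network_model"))
  if (!inherits(inflow, "inflow_waveform")) {
    stop("inflow must be an inflow_waveform", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 2L) {
    stop("n_cycles must be >= 2", call. = FALSE)
  }
  period <- inflow$period
  spc <- period / dt
  if (abs(spc - round(spc)) > 1e-6 * spc) {
    stop("dt must divide the period to within one part in 1e6",
         call. = FALSE)
  }
  spc <- as.integer(round(spc))
  ns <- length(network$segments)
  no <- length(network$outlets)
  idx_p <- seq_len(ns + 1L)
  idx_q <- ns + 1L + seq_len(ns)
  idx_c <- 2L * ns + 1L + seq_len(no)
  r_seg <- vapply(network$params, `[[`, numeric(1L), "resistance")
  l_seg <- vapply(network$params, `[[`, numeric(1L), "inertance")
  cn <- network$node_capacitance
  rp <- vapply(network$outlets, `[[`, numeric(1L), "proximal_resistance")
  cwk <- vapply(network$outlets, `[[`, numeric(1L), "capacitance")
  rd <- vapply(network$outlets, `[[`, numeric(1L), "distal_resistance")
  onode <- network$outlet_nodes
  qin_fun <- inflow$fun
  rhs <- function(t, y) {
    p <- y[idx_p]
    q <- y[idx_q]
    pc <- y[idx_c]
    q_wk <- (p[onode + 1L] - pc) / rp
    dp <- numeric(ns + 1L)
    dp[1L] <- qin_fun(t) - q[1L]
    if (ns > 1L) {
      dp[2:ns] <- q[1:(ns - 1L)] - q[2:ns]
    }
    dp[ns + 1L] <- q[ns]
    for (k in seq_len(no)) {
      dp[onode[k] + 1L] <- dp[onode[k] + 1L] - q_wk[k]
    }
    dp <- dp / cn
    dq <- (p[1:ns] - p[2:(ns + 1L)] - r_seg * q) / l_seg
    dpc <- (q_wk - pc / rd) / cwk
    c(dp, dq, dpc)
  }
  # conservative stiffness estimate -> number of RK4 substeps per dt
  rate_node <- vapply(seq_len(ns + 1L), function(j) {
    g <- sum(1 / rp[onode + 1L == j])
    if (g > 0) g / cn[j] else 0
  }, numeric(1L))
  rate_lc <- sqrt((1 / cn[1:ns] + 1 / cn[2:(ns + 1L)]) / l_seg)
  rate_out <- (1 / rp + 1 / rd) / cwk
  rate_max <- max(rate_node, rate_lc, rate_out, r_seg / l_seg)
  n_sub <- if (is.null(substeps)) {
    max(1L, as.integer(ceiling(dt * rate_max / 1.5)))
  } else {
    max(1L, as.integer(substeps))
  }
  h <- dt / n_sub
  y <- c(network$initial_state$node_pressures,
         network$initial_state$segment_flows,
         network$initial_state$outlet_pressures)
  n_keep <- 2L * spc
  kept <- matrix(NA_real_, n_keep, length(y))
  keep_from <- (n_cycles - 2L) * spc
  total <- n_cycles * spc
  t <- 0
  for (step in seq_len(total)) {
    if (step > keep_from) kept[step - keep_from, ] <- y
    for (sub in seq_len(n_sub)) {
      k1 <- rhs(t, y)
      k2 <- rhs(t + h / 2, y + h / 2 * k1)
      k3 <- rhs(t + h / 2, y + h / 2 * k2)
      k4 <- rhs(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    if (any(!is.finite(y))) {
      stop(sprintf(paste0("surrogate diverged at t = %.4g s (step %d): ",
                          "reduce dt"), t, step), call. = FALSE)
    }
  }
  prev <- kept[seq_len(spc), , drop = FALSE]
  last <- kept[spc + seq_len(spc), , drop = FALSE]
  p_prev <- prev[, idx_p, drop = FALSE]
  p_last <- last[, idx_p, drop = FALSE]
  denom <- sqrt(sum(p_last^2))
  periodicity_error <- if (denom > 0) {
    sqrt(sum((p_last - p_prev)^2)) / denom
  } else {
    0
  }
  converged <- periodicity_error <= periodicity_tol
  if (!converged) {
    warning(sprintf(paste0("surrogate not periodic after %d cycles ",
                           "(periodicity error %.3g > %.3g)"),
                    n_cycles, periodicity_error, periodicity_tol),
            call. = FALSE)
  }
  time <- (seq_len(spc) - 1L) * dt
  # per-segment report pressure: distal node of each segment
  pressure <- p_last[, 1L + seq_len(ns), drop = FALSE]
  colnames(pressure) <- network$labels
  flow <- last[, idx_q, drop = FALSE]
  colnames(flow) <- network$labels
  pwv <- vapply(network$params, `[[`, numeric(1L), "pwv")
  a0 <- vapply(network$segments, `[[`, numeric(1L), "lumen_area_diastole")
  p_dias <- if (is.null(p_diastolic)) {
    apply(pressure, 2L, min)
  } else {
    rep(p_diastolic, ns)
  }
  area <- vapply(seq_len(ns), function(i) {
    a0[i] * (1 + (pressure[, i] - p_dias[i]) /
               (network$blood_density * pwv[i]^2))
  }, numeric(spc))
  colnames(area) <- network$labels
  pc_last <- last[, idx_c, drop = FALSE]
  outlet_flow <- vapply(seq_len(no), function(k) {
    (p_last[, onode[k] + 1L] - pc_last[, k]) / rp[k]
  }, numeric(spc))
  colnames(outlet_flow) <- names(network$outlets)
  structure(list(time = time, flow = flow, area = area,
                 pressure = pressure, outlet_flow = outlet_flow,
                 inflow = vapply(time, qin_fun, numeric(1L)),
                 diastolic_pressure = p_dias,
                 periodicity_error = periodicity_error,
                 converged = converged, period = period, dt = dt,
                 substeps = n_sub,
                 final_state = list(
                   node_pressures = y[idx_p],
                   segment_flows = y[idx_q],
                   outlet_pressures = y[idx_c]),
                 network = network),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(paste0("<simulation_result> %d samples over %.4g s cycle, ",
                     "dt = %g s\n"), length(x$time), x$period, x$dt))
  cat(sprintf("  periodicity error: %.3g (%s)\n", x$periodicity_error,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Extract QA curves at named cross-sections
#'
#' @param result A [run_cycles()] result.
#' @param labels Cross-section tags to extract; default all.
#' @return A named list of [qa_curves()], one per label.
#' @export
extract_curves <- function(result, labels = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  all_labels <- colnames(result$flow)
  if (is.null(labels)) labels <- all_labels
  unknown <- setdiff(labels, all_labels)
  if (length(unknown) > 0L) {
    stop("unknown cross-section label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- lapply(labels, function(lab) {
    qa_curves(result$time, result$flow[, lab], result$area[, lab],
              period = result$period)
  })
  names(out) <- labels
  out
}
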