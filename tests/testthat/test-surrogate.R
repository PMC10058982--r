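test_that("segment reduction matches Bramwell-Hill and Poiseuille arithmetic", {
  # E chosen so that pwv is exactly 5 m/s for A0/WCSA = 4, chi = 1:
  # E = 3 * 1060 * 25 * 5 = 397500 Pa
  seg <- vessel_segment("CS1", 0.05, 8e-4, 2e-4, 397500)
  par <- derive_segment_params(seg, 1060, 0.05)
  expect_equal(par$pwv, 5, tolerance = 1e-12)
  expect_equal(par$compliance, 8e-4 * 0.05 / (1060 * 25),
               tolerance = 1e-12)           # 1.509e-9 m^3/Pa
  expect_rel(par$compliance, 1.509e-9, 1e-3)
  expect_equal(par$resistance, 8 * pi * 0.05 * 0.05 / (8e-4)^2,
               tolerance = 1e-12)           # 9.817e4 Pa s/m^3
  expect_rel(par$resistance, 9.817e4, 1e-4)
  expect_equal(par$inertance, 1060 * 0.05 / 8e-4, tolerance = 1e-12)
  # doubling E halves compliance exactly
  seg2 <- vessel_segment("CS1", 0.05, 8e-4, 2e-4, 2 * 397500)
  expect_equal(derive_segment_params(seg2)$compliance, par$compliance / 2,
               tolerance = 1e-12)
  expect_error(vessel_segment("CS1", -0.05, 8e-4, 2e-4, 1e6),
               "non-positive")
})

test_that("Windkessel relaxes to the closed-form steady state", {
  # descending-aorta RCR values
  o <- windkessel_outlet(2.5e6, 7.7e-9, 2.4e8)
  q <- 5e-5
  dt <- 0.005
  for (i in seq_len(20000)) {
    st <- windkessel_step(o, q, dt)
    o <- st$outlet
  }
  expect_rel(st$pressure, q * (2.5e6 + 2.4e8), 1e-6)   # 1.2125e4 Pa
  expect_rel(st$pressure, 1.2125e4, 1e-6)
})

test_that("Windkessel decays exponentially with the Rd*C time constant", {
  rd <- 2.4e8; cw <- 7.7e-9
  tau <- rd * cw
  o <- windkessel_outlet(2.5e6, cw, rd, state_pressure = 1e4)
  dt <- tau / 2000
  n <- 2000L                      # integrate one time constant
  for (i in seq_len(n)) o <- windkessel_step(o, 0, dt)$outlet
  expect_rel(o$state_pressure, 1e4 * exp(-1), 1e-3)
  expect_error(windkessel_step(o, 0, -1), "dt")
})

test_that("network assembly validates topology and loads RCR values verbatim", {
  cfg <- make_fixture_config("aorta_default")
  net <- assemble_network(cfg)
  expect_length(net$segments, 5L)
  expect_length(net$outlets, 4L)
  expect_equal(net$labels, paste0("CS", 1:5))
  # standard RCR table values land unchanged in the outlets
  bca <- net$outlets$brachiocephalic_artery
  expect_equal(bca$proximal_resistance, 1.3e7)
  expect_equal(bca$capacitance, 1.5e-9)
  expect_equal(bca$distal_resistance, 1.3e9)
  expect_equal(net$outlets$descending_aorta$distal_resistance, 2.4e8)
  expect_equal(net$outlets$left_common_carotid_artery$capacitance, 3.8e-10)
  expect_equal(net$outlets$left_subclavian_artery$proximal_resistance,
               1.1e7)
  # removing the terminal outlet is a configuration error naming it
  cfg2 <- cfg
  cfg2$outlets$descending_aorta <- NULL
  cfg2$initial_state <- NULL
  expect_error(assemble_network(cfg2), "terminal")
  # missing field error names outlet and field
  cfg3 <- cfg
  cfg3$outlets$brachiocephalic_artery$capacitance <- NULL
  expect_error(assemble_network(cfg3), "brachiocephalic_artery.*capacitance")
  # unknown attachment
  cfg4 <- cfg
  cfg4$outlets$brachiocephalic_artery$attach_after <- "CS9"
  expect_error(assemble_network(cfg4), "CS9")
})

test_that("null forcing from a zero state keeps every output at zero", {
  cfg <- make_fixture_config("aorta_default")
  cfg$initial_state <- NULL      # cold, zero start
  net <- assemble_network(cfg)
  zero_inflow <- inflow_waveform(1.12, fun = function(t) 0 * t)
  res <- run_cycles(net, zero_inflow, n_cycles = 2)
  expect_equal(max(abs(res$flow)), 0)
  expect_equal(max(abs(res$pressure)), 0)
  expect_equal(max(abs(res$outlet_flow)), 0)
  # tube law pins the areas at their diastolic values
  a0 <- vapply(net$segments, `[[`, numeric(1L), "lumen_area_diastole")
  expect_equal(unname(res$area[1L, ]), a0)
})

test_that("constant inflow conserves mass across the outlets", {
  cfg <- make_fixture_config("aorta_default")
  net <- assemble_network(cfg)
  q0 <- 7e-5
  const_inflow <- inflow_waveform(1.12, fun = function(t) rep(q0, length(t)))
  res <- run_cycles(net, const_inflow, n_cycles = 10)
  expect_rel(sum(colMeans(res$outlet_flow)), q0, 0.005)
})

test_that("the default fixture reaches a periodic physiological state", {
  cfg <- make_fixture_config("aorta_default")
  net <- assemble_network(cfg)
  inflow <- make_inflow_waveform(1.12, 8e-5, 0.35, 224)
  res <- run_cycles(net, inflow, n_cycles = 10, dt = 0.005)
  expect_lt(res$periodicity_error, 1e-3)
  expect_true(res$converged)
  expect_length(res$time, 224L)       # period / dt samples
  # mass conservation over the converged cycle
  expect_rel(sum(colMeans(res$outlet_flow)), mean(res$inflow), 0.005)
  # physiological pressure envelope (diastolic ~70, systolic ~105 mmHg)
  expect_gt(min(res$pressure) / 133.32, 40)
  expect_lt(max(res$pressure) / 133.32, 150)
  # refining the integrator step changes the final cycle by < 0.5%
  res2 <- run_cycles(net, inflow, n_cycles = 10, dt = 0.005,
                     substeps = 2L * res$substeps)
  rel_change <- max(abs(res$pressure - res2$pressure)) /
    diff(range(res$pressure))
  expect_lt(rel_change, 0.005)
})

test_that("stiffening every segment shrinks the area excursion at CS1", {
  inflow <- make_inflow_waveform(1.12, 8e-5, 0.35, 224)
  e_vals <- parameter_values_from_rule(gauss_legendre_rule(4),
                                       uniform_parameter(2.02e6, 0.23))
  ptt <- vapply(e_vals, function(e) {
    cfg <- set_network_modulus(make_fixture_config("aorta_default"), e)
    res <- run_cycles(assemble_network(cfg), inflow)
    diff(range(res$area[, "CS1"]))
  }, numeric(1L))
  # e_vals descending, excursion must increase as the wall softens
  expect_true(all(diff(ptt) > 0))
})

test_that("curve extraction yields valid QA sets within the physiological envelope", {
  cfg <- make_fixture_config("aorta_default")
  net <- assemble_network(cfg)
  inflow <- make_inflow_waveform(1.12, 8e-5, 0.35, 224)
  res <- run_cycles(net, inflow)
  curves <- extract_curves(res)
  expect_named(curves, paste0("CS", 1:5))
  for (lab in names(curves)) {
    qa <- curves[[lab]]
    expect_s3_class(qa, "qa_curves")
    expect_length(qa$time, 224L)
    a0 <- net$segments[[match(lab, net$labels)]]$lumen_area_diastole
    expect_true(all(qa$area >= 0.8 * a0 & qa$area <= 1.5 * a0))
  }
  expect_error(extract_curves(res, "CS9"), "CS9")
  # flow spread across E at the descending sections is smaller than the
  # area spread at CS1 (relative to each quantity's pulse)
  e_vals <- parameter_values_from_rule(gauss_legendre_rule(4),
                                       uniform_parameter(2.02e6, 0.23))
  runs <- lapply(e_vals, function(e) {
    cfg_e <- set_network_modulus(cfg, e)
    run_cycles(assemble_network(cfg_e), inflow)
  })
  spread <- function(get) {
    traces <- vapply(runs, get, numeric(224L))
    max(apply(traces, 1L, function(x) diff(range(x)))) /
      diff(range(rowMeans(traces)))
  }
  q_spread_cs4 <- spread(function(r) r$flow[, "CS4"])
  q_spread_cs5 <- spread(function(r) r$flow[, "CS5"])
  a_spread_cs1 <- spread(function(r) r$area[, "CS1"])
  expect_lt(q_spread_cs4, a_spread_cs1)
  expect_lt(q_spread_cs5, a_spread_cs1)
})
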