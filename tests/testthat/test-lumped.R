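# 0D building blocks: Stevino generators, leg-vein law, Windkessel
# rates, venous valves.

test_that("Stevino hydrostatic gradient", {
  expect_equal(hydrostatic_gradient(list(rho = 1050, anatomical_height = 0.5,
                                         alpha = 0)), 0)
  expect_equal(hydrostatic_gradient(list(rho = 1050, anatomical_height = 0.5,
                                         alpha = pi / 2)),
               1050 * 9.81 * 0.5 / 133.322, tolerance = 1e-12)  # 38.63 mmHg
})

test_that("legs venous law: anchor points, saturation and compliance", {
  law <- list(C0 = 19, deltaV_max = 480, V_u = 700)
  expect_equal(leg_vein_volume(0, law), 700)
  expect_equal(leg_vein_volume(1e9, law), 700 + 480, tolerance = 1e-4)
  # derivative at 0 equals C0 (finite-difference, both sides; V_u = 0
  # avoids losing digits to the large volume offset)
  law0 <- list(C0 = 19, deltaV_max = 480, V_u = 0)
  h <- 1e-6
  fd <- (leg_vein_volume(h, law0) - leg_vein_volume(-h, law0)) / (2 * h)
  expect_equal(fd, 19, tolerance = 1e-9)
  expect_equal(leg_vein_compliance(0, law), 19)
  # linear branch below zero
  expect_equal(leg_vein_volume(-5, law), 700 - 5 * 19)
  # compliance decreases monotonically with distension
  expect_true(all(diff(leg_vein_compliance(seq(0, 80, 5), law)) < 0))
  # inverse law round trip
  p <- c(-10, 0, 5, 20, 60)
  expect_equal(leg_vein_pressure(leg_vein_volume(p, law), law), p,
               tolerance = 1e-9)
})

test_that("RLC compartment relaxes through R with time constant RC", {
  # isolated compartment discharging to a zero-pressure sink
  spec <- list(resistance = 0.5, inertance = 0, compliance = 8)
  p <- 20
  dt <- 1e-3
  tau <- spec$resistance * spec$compliance
  for (i in seq_len(round(tau / dt))) {      # integrate one time constant
    r1 <- compartment_rates(list(p = p, Q_out = 0), 0, spec, 0)
    q1 <- r1$Q_out
    p_mid <- p + dt * (0 - q1) / spec$compliance
    r2 <- compartment_rates(list(p = p_mid, Q_out = 0), 0, spec, 0)
    p <- p + dt * ((0 - q1) + (0 - r2$Q_out)) / (2 * spec$compliance)
  }
  expect_equal(p, 20 * exp(-1), tolerance = 0.01)
  # Ohmic steady limit
  r <- compartment_rates(list(p = 30, Q_out = 0), 0, spec, p_down = 10)
  expect_equal(r$Q_out, (30 - 10) / 0.5)
  # with inertance, the momentum equation includes the generator
  spec2 <- list(resistance = 0.5, inertance = 0.002, compliance = 8)
  r2 <- compartment_rates(list(p = 10, Q_out = 4), 6, spec2,
                          p_down = 12, dp_h = 5)
  expect_equal(r2$dQ_dt, (10 - 12 - 0.5 * 4 + 5) / 0.002)
  expect_equal(r2$dp_dt, (6 - 4) / 8)
})

test_that("pulmonary 2-element Windkessel approaches a step with tau=RC", {
  spec <- list(resistance = 0.04, compliance = 5)
  p <- 10; dt <- 5e-4
  Qin <- 120                                   # step inflow, sink at 10
  tau <- spec$resistance * spec$compliance
  for (i in seq_len(round(tau / dt))) {
    k1 <- pulmonary_rates(list(p = p), Qin, spec, 10)$dp_dt
    k2 <- pulmonary_rates(list(p = p + dt * k1), Qin, spec, 10)$dp_dt
    p <- p + dt * (k1 + k2) / 2
  }
  p_inf <- 10 + Qin * spec$resistance
  expect_equal((p_inf - p) / (p_inf - 10), exp(-1), tolerance = 0.01)
  # steady flow: dp/dt = 0
  expect_equal(pulmonary_rates(list(p = p_inf), Qin, spec, 10)$dp_dt, 0,
               tolerance = 1e-9)
})

test_that("venous valve: diode limits and steady orifice flow", {
  vp <- valve_params(A_max = 1.2, A_min = 0.01, K_open = 20, K_close = 20,
                     l_eff = 1.5)
  # sustained closing pressure drives zeta to 0 monotonically
  vs <- list(zeta = 1, Q = 0)
  z <- numeric(200)
  for (i in 1:200) { vs <- venous_valve_step(vs, -5, vp, 1e-3); z[i] <- vs$zeta }
  expect_true(all(diff(z) <= 1e-12))
  expect_lt(z[200], 0.05)
  # fully open steady flow converges to the Bernoulli orifice value
  vp2 <- valve_params(A_max = 1.2, A_min = 0.01, K_open = 2000, K_close = 20,
                      l_eff = 1.5)
  vs <- list(zeta = 1, Q = 0)
  for (i in 1:4000) vs <- venous_valve_step(vs, 4, vp2, 5e-5)
  A_si <- 1.2e-4
  Q_expected <- A_si * sqrt(2 * (4 * 133.322) / 1050) * 1e6   # ml/s
  expect_equal(vs$Q, Q_expected, tolerance = 1e-3)
  expect_equal(vs$Q, valve_steady_flow(4, 1.2), tolerance = 1e-3)
  # reverse leak bounded by the A_min orifice
  vs <- list(zeta = 0, Q = 0)
  for (i in 1:4000) vs <- venous_valve_step(vs, -40, vp, 5e-5)
  expect_equal(abs(vs$Q), valve_steady_flow(40, 0.01), tolerance = 1e-2)
})

test_that("venous valve rectifies a sinusoidal pressure forcing", {
  # default venous-valve parameters of the shipped model
  vp <- valve_params(A_max = 1.2, A_min = 0.005, K_open = 20, K_close = 40,
                     l_eff = 1.5)
  vs <- list(zeta = 0.5, Q = 0)
  dt <- 2e-4
  fwd <- 0; bwd <- 0
  for (i in seq_len(round(4 / dt))) {          # four 1 Hz cycles
    dp <- 2 * sin(2 * pi * i * dt)
    vs <- venous_valve_step(vs, dp, vp, dt)
    if (vs$Q > 0) fwd <- fwd + vs$Q * dt else bwd <- bwd - vs$Q * dt
  }
  expect_gt(fwd, 0)
  expect_lt(bwd / fwd, 0.02)
})
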