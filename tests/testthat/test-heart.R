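# Time-varying elastance, cardiac valves, intrathoracic pressure.

test_that("normalized elastance anchors and systole scaling", {
  vent <- elastance_params(2.8, 0.12, 15, "ventricle")
  # zero at onset, one at time-to-peak
  expect_equal(normalized_elastance(vent$onset_frac, vent, RR = 1), 0)
  t_peak <- vent$onset_frac + vent$k_contract * sqrt(1) / 1
  expect_equal(normalized_elastance(t_peak - 1e-12, vent, RR = 1), 1,
               tolerance = 1e-6)
  # activation vanishes outside systole
  expect_equal(normalized_elastance(0.9, vent, RR = 1), 0)
  # the time integral of e over one beat shrinks as RR shrinks
  integ <- function(RR) {
    tb <- seq(0, 1 - 1e-9, length.out = 4001)
    mean(normalized_elastance(tb, vent, RR)) * RR
  }
  expect_lt(integ(0.6), integ(1.0))
  expect_lt(integ(0.45), integ(0.6))
  # but occupies a growing FRACTION of the beat (systole favored at
  # high heart rate)
  frac <- function(RR) (vent$k_contract + vent$k_relax) * sqrt(RR) / RR
  expect_gt(frac(0.6), frac(1.0))
  # atrium: single late bump, zero at onset, peak mid-bump
  atr <- elastance_params(0.34, 0.2, 14, "atrium", onset_frac = 0.8,
                          k_contract = 0.09, k_relax = 0.09)
  expect_equal(normalized_elastance(0.8, atr, RR = 1), 0)
  expect_equal(normalized_elastance(0.8 + 0.09, atr, RR = 1), 1,
               tolerance = 1e-9)
})

test_that("chamber pressure is the elastance line", {
  expect_equal(chamber_pressure(list(V = 15), 2, 15, -4), -4)
  expect_equal(chamber_pressure(list(V = 65), 2, 15, -4), 96)
  V <- seq(20, 120, 10)
  p <- chamber_pressure(list(V = V), 1.5, 15, 0)
  expect_equal(diff(p), rep(15, length(V) - 1))
})

test_that("cardiac valve: no flow when closed, quadratic root when open", {
  vp <- valve_params(A_max = 4, A_min = 0, K_open = 30, K_close = 40,
                     l_eff = 1, R_visc = 0.008)
  st <- list(zeta = 0, Q = 0)
  for (i in 1:500) st <- cardiac_valve_flow(-10, st, vp, 1e-4)
  expect_equal(st$zeta, 0)
  expect_lt(abs(st$Q), 1e-3)
  # fully open steady flow solves dp = B Q|Q| + R_visc Q
  vp2 <- valve_params(A_max = 4, A_min = 0, K_open = 5000, K_close = 40,
                      l_eff = 1, R_visc = 0.008)
  st <- list(zeta = 1, Q = 0)
  for (i in 1:20000) st <- cardiac_valve_flow(5, st, vp2, 5e-5)
  expect_equal(st$Q, valve_steady_flow(5, 4, R_visc = 0.008),
               tolerance = 1e-3)
  # no instantaneous flow reversal: inertance limits dQ per step
  st1 <- cardiac_valve_flow(-20, st, vp2, 1e-4)
  expect_gt(st1$Q, 0)
})

test_that("intrathoracic pressure falls with inclination", {
  par <- list(p_it_supine = -4, delta_p_it = 3)
  expect_equal(intrathoracic_pressure(0, par), -4)
  expect_equal(intrathoracic_pressure((70 * pi / 180), par),
               -4 - 3 * sin((70 * pi / 180)))
  a <- (seq(0, 70, 5) * pi / 180)
  expect_true(all(diff(intrathoracic_pressure(a, par)) < 0))
})
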