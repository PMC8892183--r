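# 1D solver verification against analytic oracles: equilibrium, wave
# speed, hydrostatics, reflections, junctions, convergence.

# small inflow pulse used by several wave experiments
.pulse <- function(t0 = 0.08, width = 0.02, amp = 5e-6, t_max = 2) {
  tp <- seq(0, t_max, by = 5e-4)
  list(t = tp, Q = amp * exp(-((tp - t0) / width)^2))
}

test_that("a quiescent uniform vessel stays in equilibrium", {
  out <- run_vessel_1d(1, 0.01, 5, inlet = list(type = "closed"),
                       outlet = list(type = "closed"),
                       dt = 1e-4, dx = 0.05, t_end = 1, p_init = 0)
  n <- nrow(out$A)
  expect_equal(out$A[n, ], out$A[1, ], tolerance = 1e-12)
  expect_equal(max(abs(out$Q[n, ])), 0, tolerance = 1e-12)
})

test_that("small pulses propagate at the analytic tube-law wave speed", {
  c0 <- 5
  p <- .pulse()
  out <- run_vessel_1d(2, 0.01, c0,
                       inlet = list(type = "flow", t = p$t, Q = p$Q),
                       outlet = list(type = "matched", p = 0),
                       dt = 5e-5, dx = 0.02, t_end = 0.42, record_every = 2)
  i1 <- which.min(abs(out$x - 0.5))
  i2 <- which.min(abs(out$x - 1.5))
  s1 <- out$p[, i1]; s2 <- out$p[, i2]
  # cross-correlation delay between the two stations
  lags <- seq(0, 0.3, by = diff(out$time[1:2]))
  cc <- vapply(seq_along(lags), function(k) {
    n <- length(s1) - (k - 1)
    sum(s1[seq_len(n)] * s2[seq_len(n) + (k - 1)])
  }, numeric(1))
  delay <- lags[which.max(cc)]
  c_measured <- 1.0 / delay
  expect_equal(c_measured, c0, tolerance = 0.02)
})

test_that("closed vertical vessel reaches hydrostatic equilibrium", {
  out <- run_vessel_1d(1, 0.01, 5, inlet = list(type = "closed"),
                       outlet = list(type = "closed"),
                       dt = 5e-5, dx = 0.05, t_end = 4, alpha = pi / 2,
                       proj = 1, p_init = 5000, gamma_visc = 10,
                       record_every = 1000)
  n <- nrow(out$p)
  grad <- (out$p[n, ncol(out$p)] - out$p[n, 1]) / (max(out$x) - min(out$x))
  expect_equal(grad, 1050 * 9.81, tolerance = 0.01)
  expect_lt(max(abs(out$Q[n, ])), 1e-7)
})

test_that("closed outlet doubles an incident compression pulse", {
  c0 <- 5
  p <- .pulse(amp = 4e-6)
  out <- run_vessel_1d(2, 0.01, c0,
                       inlet = list(type = "flow", t = p$t, Q = p$Q),
                       outlet = list(type = "closed"),
                       dt = 5e-5, dx = 0.02, t_end = 0.5, record_every = 4)
  # the incident amplitude decays slightly with distance (friction);
  # measure it at two stations and extrapolate to the closed end
  iA <- which.min(abs(out$x - 1.0))
  iB <- which.min(abs(out$x - 1.5))
  pA <- max(out$p[out$time < 0.08 + 1.0 / c0 + 0.04, iA])
  pB <- max(out$p[out$time < 0.08 + 1.5 / c0 + 0.04, iB])
  inc_end <- pB * (pB / pA)                 # extrapolated incident at x = 2
  pend <- max(out$p[, ncol(out$p)])
  expect_equal(pend / inc_end, 2, tolerance = 0.05)
})

test_that("matched terminal impedance absorbs the pulse", {
  p <- .pulse(amp = 5e-6)
  out <- run_vessel_1d(2, 0.01, 5,
                       inlet = list(type = "flow", t = p$t, Q = p$Q),
                       outlet = list(type = "matched", p = 0),
                       dt = 5e-5, dx = 0.02, t_end = 0.8, record_every = 4)
  imid <- which.min(abs(out$x - 1.0))
  inc <- max(out$p[, imid])
  # after the pulse has exited (plus round-trip time to the outlet),
  # any residual at mid-vessel is reflected energy
  resid <- max(abs(out$p[out$time > 0.65, imid]))
  expect_lt(resid / inc, 0.05)
})

test_that("steady inflow with a resistive outlet transports a uniform flow", {
  tp <- c(0, 0.5, 20)
  out <- run_vessel_1d(1, 0.01, 5,
                       inlet = list(type = "flow", t = tp, Q = c(0, 3e-5, 3e-5)),
                       outlet = list(type = "impedance", p = 0,
                                     Z = 5e7),
                       dt = 5e-5, dx = 0.025, t_end = 8, record_every = 1000)
  n <- nrow(out$Q)
  expect_equal(max(abs(out$Q[n, ] - 3e-5)) / 3e-5, 0, tolerance = 1e-3)
})

test_that("junctions conserve mass and split symmetric children evenly", {
  p <- .pulse(amp = 5e-6, t_max = 1)
  out <- run_bifurcation_1d(list(length = 0.3, radius = 0.01, wave_speed_ref = 5),
                            list(length = 0.3, radius = 0.0072, wave_speed_ref = 5.5),
                            n_children = 2,
                            inlet = list(type = "flow", t = p$t, Q = p$Q),
                            dt = 5e-5, dx = 0.02, t_end = 0.5)
  # identical children receive identical mid-vessel flows
  expect_equal(out$mid[, 4], out$mid[, 6], tolerance = 1e-12)
  # junction mass defect below 1e-12 of the peak parent flow
  expect_lt(max(out$mass_defect), 1e-12 * max(out$q_parent))
})

test_that("an identical continuation vessel is a transparent interface", {
  p <- .pulse(amp = 5e-6, t_max = 1)
  out <- run_bifurcation_1d(list(length = 0.5, radius = 0.01, wave_speed_ref = 5),
                            list(length = 0.5, radius = 0.01, wave_speed_ref = 5),
                            n_children = 1,
                            inlet = list(type = "flow", t = p$t, Q = p$Q),
                            dt = 2.5e-5, dx = 0.01, t_end = 0.55)
  # the pulse passes x=0.25 (parent mid) once; any later signal there
  # is a reflection off the junction
  inc <- max(out$mid[, 1])
  late <- max(abs(out$mid[out$time > 0.35, 1]))
  expect_lt(late / inc, 0.02)
})

test_that("mass is conserved to machine precision in a closed vessel", {
  out <- run_vessel_1d(1, 0.01, 5, inlet = list(type = "closed"),
                       outlet = list(type = "closed"),
                       dt = 1e-4, dx = 0.05, t_end = 10, alpha = pi / 3,
                       proj = 1, p_init = 3000, gamma_visc = 10,
                       record_every = 5000)
  v0 <- sum(out$A[1, ]) * out$dx
  v1 <- sum(out$A[nrow(out$A), ]) * out$dx
  # < 0.1% per minute required; the budget-exact boundary treatment
  # keeps it at rounding level
  expect_lt(abs(v1 - v0) / v0 * 6, 1e-3)
})

test_that("halving the element size reduces the wave-profile error by
           at least a factor two", {
  c0 <- 5
  p <- .pulse(t0 = 0.06, width = 0.025, amp = 5e-6)
  runA <- function(dx) {
    run_vessel_1d(2, 0.01, c0,
                  inlet = list(type = "flow", t = p$t, Q = p$Q),
                  outlet = list(type = "matched", p = 0),
                  dt = 2e-5, dx = dx, t_end = 0.25,
                  record_every = ceiling(0.25 / 2e-5))
  }
  ref <- runA(0.005)
  n <- nrow(ref$A)
  err <- vapply(c(0.04, 0.02), function(dx) {
    out <- runA(dx)
    pi_ref <- approx(ref$x, ref$p[nrow(ref$p), ], xout = out$x)$y
    sqrt(mean((out$p[nrow(out$p), ] - pi_ref)^2))
  }, numeric(1))
  expect_gt(err[1] / err[2], 2)
})

test_that("a CFL violation is reported with the vessel and required step", {
  expect_error(
    run_vessel_1d(1, 0.01, 5, dt = 0.02, dx = 0.05, t_end = 0.1,
                  p_init = 3000),
    "CFL.*fixture.*reduce dt")
})
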