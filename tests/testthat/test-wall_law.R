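# Elastic-viscoelastic tube law and the axial gravity source term.

test_that("tube law reproduces its reference state and scalings", {
  law <- wall_law(beta = 4e5, A0 = 5e-4, gamma_visc = 8,
                  reference_pressure = 1000)
  # reference state: A = A0, no motion, no external pressure
  expect_equal(wall_pressure(law$A0, law), 1000)
  # linearity in beta of the elastic part away from A0
  law2 <- wall_law(beta = 8e5, A0 = 5e-4, reference_pressure = 0)
  law1 <- wall_law(beta = 4e5, A0 = 5e-4, reference_pressure = 0)
  A <- 6e-4
  expect_equal(wall_pressure(A, law2), 2 * wall_pressure(A, law1))
  # direct evaluation: sqrt(A) = 1.1 sqrt(A0), beta*sqrt(A0)/A0 = 1e4 Pa
  A0 <- 4e-4
  beta <- 1e4 * A0 / sqrt(A0)
  lawd <- wall_law(beta, A0)
  expect_equal(wall_pressure(1.21 * A0, lawd), 1e3, tolerance = 1e-12)
  # monotone increasing in A at dA_dt = 0
  As <- seq(0.5, 2, by = 0.1) * A0
  expect_true(all(diff(wall_pressure(As, lawd)) > 0))
  # viscoelastic term adds gamma/(A0 sqrt(A)) * dA/dt
  expect_equal(wall_pressure(law$A0, law, dA_dt = 1e-4) - 1000,
               law$gamma_visc / (law$A0 * sqrt(law$A0)) * 1e-4)
})

test_that("non-positive areas are rejected as a solver state error", {
  law <- wall_law(4e5, 5e-4)
  expect_error(wall_pressure(0, law), "blow-up")
  expect_error(wall_pressure(-1e-5, law), "blow-up")
})

test_that("axial gravity source vanishes supine and scales as rho g A", {
  ctx <- list(tilt_angle_alpha = 0, longitudinal_projection = 1)
  expect_equal(axial_gravity_term(ctx, 1e-4, rho = 1050), 0)
  ctx$tilt_angle_alpha <- pi / 2
  expect_equal(axial_gravity_term(ctx, 1e-4, rho = 1050),
               -1050 * 9.81 * 1e-4)              # -1.03 N/m
  # sign flips for headward-running vessels
  ctx$longitudinal_projection <- -1
  expect_equal(axial_gravity_term(ctx, 1e-4, rho = 1050),
               +1050 * 9.81 * 1e-4)
})

test_that("wave speed follows the characteristic analysis of the law", {
  A0 <- pi * 0.01^2
  c0 <- 5
  law <- wall_law(2 * 1050 * c0^2 * sqrt(A0), A0)
  expect_equal(wave_speed(law, rho = 1050), c0, tolerance = 1e-12)
  expect_equal(wave_speed(law, A = 16 * A0, rho = 1050), 2 * c0,
               tolerance = 1e-12)
})
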