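# Baroreflex sigmoids, effectors, cerebral autoregulation, Davson ICP.

test_that("autonomic activity sigmoids are antagonistic and saturating", {
  a <- autonomic_activities(90, 90, nu = 7)
  expect_equal(a$n_sym, 0.5)
  expect_equal(a$n_para, 0.5)
  expect_equal(a$n_sym + a$n_para, 1)
  # hypotension drives sympathetic activation toward 1
  expect_gt(autonomic_activities(20, 90)$n_sym, 0.99)
  # direct evaluation at 10% hypotension, nu = 7
  a2 <- autonomic_activities(81, 90, nu = 7)
  expect_equal(a2$n_sym, 1 / (1 + 0.9^7), tolerance = 1e-12)  # ~0.6766
  # complementarity over a pressure sweep
  for (p in seq(40, 160, 20)) {
    a3 <- autonomic_activities(p, 90)
    expect_equal(a3$n_sym + a3$n_para, 1, tolerance = 1e-12)
  }
  expect_warning(autonomic_activities(-5, 90), "clamped")
})

test_that("effectors hold their basal fixed point and follow a
           first-order step response", {
  eff <- list(value = 68, basal = 68, G_sym = 30, G_para = 55,
              tau = 3, lo = 40, hi = 180)
  bal <- list(n_sym = 0.5, n_para = 0.5)
  for (i in 1:100) eff <- effector_update(bal, eff, 0.01)
  expect_equal(eff$value, 68, tolerance = 1e-12)
  # step to full sympathetic: monotone rise with time constant tau
  drive <- list(n_sym = 1, n_para = 0)
  x_inf <- 68 + 30 * 0.5 + 55 * 0.5
  eff <- list(value = 68, basal = 68, G_sym = 30, G_para = 55,
              tau = 3, lo = 40, hi = 180)
  xs <- numeric(600)
  for (i in 1:600) { eff <- effector_update(drive, eff, 0.01) ; xs[i] <- eff$value }
  expect_true(all(diff(xs) > 0))
  # value after one time constant
  expect_equal((x_inf - xs[300]) / (x_inf - 68), exp(-1), tolerance = 0.01)
  # zero gains: regulation-off mode holds the state
  eff0 <- list(value = 68, basal = 68, G_sym = 0, G_para = 0,
               tau = 3, lo = 40, hi = 180)
  for (i in 1:50) eff0 <- effector_update(drive, eff0, 0.01)
  expect_equal(eff0$value, 68)
})

test_that("cardiopulmonary reflex shares the sigmoid and spares the heart", {
  expect_equal(cardiopulmonary_activities(7, 7)$n_sym, 0.5)
  # reduced preload raises the resistance-driving activity
  expect_gt(cardiopulmonary_activities(4, 7)$n_sym, 0.5)
  # the full model wires this afferent only to vascular effectors: at
  # balanced arterial afferent, HR stays basal whatever the atrial error
  rec <- ts_supine()
  expect_equal(unique(rec$signals[, "hr"]), 68)
})

test_that("cerebral autoregulation dilates on low flow with Poiseuille
           resistance scaling", {
  st <- list(x_aut = 0, CBF_ref = 12, G_aut = 20, tau_aut = 10,
             C_a0 = 1, C_min = 0.5, C_max = 2.2)
  st0 <- cerebral_autoregulation(12, st, 0.01)
  expect_equal(st0$x_aut, 0)
  expect_equal(st0$C_a, 1)
  # sustained low flow: filtered error goes negative, compliance rises
  for (i in 1:3000) st <- cerebral_autoregulation(9, st, 0.01)
  expect_lt(st$x_aut, 0)
  expect_gt(st$C_a, 1)
  expect_lte(st$C_a, 2.2)
  # constriction saturates at C_min
  st2 <- list(x_aut = 0, CBF_ref = 12, G_aut = 20, tau_aut = 10,
              C_a0 = 1, C_min = 0.5, C_max = 2.2)
  for (i in 1:5000) st2 <- cerebral_autoregulation(25, st2, 0.01)
  expect_gte(st2$C_a, 0.5)
  expect_lt(st2$C_a, 0.55)
  # halving arteriolar volume quadruples resistance
  expect_equal(autoreg_resistance(0.5, 1) / autoreg_resistance(1, 1), 4)
})

test_that("intracranial pressure follows Davson and is continuous at
           jugular collapse", {
  geo <- list(h_head_ra = 0.31, rho = 1050)
  st <- list(R_csf = 480, I_f = 0.00583)
  # supine: p_ic = R_csf I_f + cvp
  expect_equal(intracranial_pressure(7, 0, geo, st), 480 * 0.00583 + 7)
  # continuity where the SVC pressure crosses zero
  a <- 40 * pi / 180
  lo <- intracranial_pressure(5, a, geo, st, p_svc = -1e-9)
  hi <- intracranial_pressure(5, a, geo, st, p_svc = +1e-9)
  expect_equal(lo, hi, tolerance = 1e-9)
  # strictly decreasing in alpha at fixed cvp
  as <- seq(0.05, pi / 2, length.out = 12)
  ps <- vapply(as, function(x) intracranial_pressure(5, x, geo, st,
                                                     p_svc = 3), numeric(1))
  expect_true(all(diff(ps) < 0))
})
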