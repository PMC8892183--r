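# Coupled-engine behavior: determinism, beats, conservation, closed-loop
# balance, steady states.

test_that("the minimal closed loop beats and conserves volume", {
  fx <- fixture_networks()
  num <- sim_control(dt = 2e-4, dx = 0.05, out_dt = 0.01,
                     pre_min_beats = 12, pre_max_beats = 16)
  rec <- run_protocol(fx$minimal_closed_loop, tilt_schedule(0, 0, 1), num)
  expect_s3_class(rec, "simulation_record")
  expect_gt(nrow(rec$beats), 10)
  sig <- rec$signals
  drift <- abs(sig[nrow(sig), "V_total"] - sig[1, "V_total"])
  mins <- max(rec$time) / 60
  expect_lt(drift / sig[1, "V_total"] / mins, 0.005)
  # the loop is pressurized and pulsatile
  w <- sig[, "time"] > max(rec$time) - 2
  expect_gt(max(sig[w, "p_aortic_root"]) - min(sig[w, "p_aortic_root"]), 10)
})

test_that("identical configurations give bit-identical records", {
  model <- ts_model()
  num <- sim_control(dt = 2e-4, dx = 0.05, out_dt = 0.01,
                     pre_min_beats = 8, pre_max_beats = 10)
  r1 <- run_protocol(model, tilt_schedule(0, 0, 1), num)
  r2 <- run_protocol(model, tilt_schedule(0, 0, 1), num)
  expect_identical(r1$signals, r2$signals)
  expect_identical(r1$beats, r2$beats)
})

test_that("beat boundaries are the ventricular activation onsets", {
  rec <- ts_supine()
  bt <- detect_beats(rec)
  # constant commanded heart rate: boundaries 60/HR apart to rounding
  expect_equal(max(abs(diff(bt) - 60 / 68)), 0, tolerance = 1e-6)
  # count of beats in T seconds at fixed HR within one beat
  T <- max(bt) - min(bt)
  expect_lt(abs((length(bt) - 1) - T * 68 / 60), 1.5)
})

test_that("global volume is conserved through a full tilt protocol", {
  rec <- ts_hut70()
  sig <- rec$signals
  drift <- abs(sig[nrow(sig), "V_total"] - sig[1, "V_total"])
  mins <- max(rec$time) / 60
  expect_lt(drift / sig[1, "V_total"] / mins, 0.005)
  # interface (junction) residuals stay at solver tolerance
  expect_lt(rec$max_junction_resid, 1e-9)
})

test_that("beat-averaged terminal outflow equals the venous return", {
  rec <- ts_supine()
  bt <- rec$beats$t
  t0 <- bt[length(bt) - 8]          # exactly eight complete beats
  inflow <- mean(beat_means(rec, "q_aortic", t0))
  sig <- rec$signals
  k <- sig[, "time"] >= t0 & sig[, "time"] < bt[length(bt)]
  vret <- mean(sig[k, "q_svc"] + sig[k, "q_ivc_thoracic"] +
                 sig[k, "q_cor_out"])
  expect_lt(abs(inflow - vret) / inflow, 0.005)
})

test_that("with posture fixed the supine limit cycle is periodic", {
  rec <- cached_run("supine_fine", function() {
    run_protocol(ts_model(), tilt_schedule(0, 0, 1),
                 sim_control(dt = 1e-4, dx = 0.05, out_dt = 0.005,
                             pre_min_beats = 45, pre_max_beats = 110,
                             steady_tol = 1e-4, steady_beats = 10))
  })
  bm <- utils::tail(rec$beats$map_root, 10)
  expect_lt(max(abs(bm - mean(bm))) / mean(bm), 1e-4)
  rr <- utils::tail(rec$beats$RR, 10)
  expect_lt(max(abs(rr - mean(rr))) / mean(rr), 1e-4)
})

test_that("reducing preload reduces stroke volume (Frank-Starling)", {
  fx <- fixture_networks()$minimal_closed_loop
  num <- sim_control(dt = 2e-4, dx = 0.05, out_dt = 0.01,
                     pre_min_beats = 14, pre_max_beats = 18)
  # preload is varied through the circulating stressed volume: the
  # initial venous/venular pressures scale by +/-20%
  sv <- vapply(c(0.8, 1.0, 1.2), function(f) {
    m <- fx
    ven <- m$compartments$kind %in% c("venule", "vein", "vena_cava_inferior")
    m$compartments$p_init[ven] <- m$compartments$p_init[ven] * f
    rec <- run_protocol(m, tilt_schedule(0, 0, 1), num)
    mean(utils::tail(rec$beats$sv, 5))
  }, numeric(1))
  expect_true(all(diff(sv) > 0))
})

test_that("the left-ventricular pressure-volume loop is traversed
           counterclockwise with positive area", {
  rec <- ts_supine()
  sig <- rec$signals
  bt <- rec$beats$t
  nb <- length(bt)
  k <- sig[, "time"] >= bt[nb - 1] & sig[, "time"] < bt[nb]
  V <- sig[k, "V_lv"]; p <- sig[k, "p_lv"]
  j <- c(seq_along(V)[-1], 1)
  signed <- sum(V * p[j] - V[j] * p) / 2
  expect_gt(signed, 0)                 # counterclockwise in (V, p)
  expect_gt(pv_loop_area(V, p), 1000)  # mmHg ml, beating steady state
})

test_that("tilt-up followed by tilt-down restores the supine state", {
  rec <- ts_updown(4)$down             # supine -> 70 -> supine
  pre <- steady_state_metrics(rec, t_end = supine_tilt_start(rec))
  fin <- steady_state_metrics(rec)
  for (p in c("MAP_aortic_root", "HR", "SV", "CO", "CVP")) {
    expect_lt(abs(fin[p] - pre[p]) / abs(pre[p]), 0.02)
  }
})
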