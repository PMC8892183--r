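# Beat metrics, loop areas, hydrostatic decomposition, ensemble
# averaging and steady-state reporting.

# a tiny synthetic record with two flat beats at constant pressure
.flat_record <- function(p_const = 80) {
  tt <- seq(0, 2, by = 0.01)
  sig <- cbind(time = tt, alpha = 0,
               p_aortic_root = p_const, q_aortic_root = 1,
               p_ra = 5, p_lv = 50, V_lv = 100,
               q_aortic = 90, cbf = 12,
               V_ra = 60, V_rv = 110, V_la = 60,
               V_pulmonary_artery = 160, V_pulmonary_vein = 400)
  structure(list(time = tt, signals = sig,
                 beats = data.frame(t = c(0, 1, 2), RR = c(1, 1, NA)),
                 segments = list(list(type = "hold"))),
            class = "simulation_record")
}

test_that("degenerate constant-pressure beats give MAP = SBP = DBP", {
  rec <- .flat_record(80)
  bm <- beat_metrics(rec, sites = "aortic_root")
  expect_equal(bm$MAP_aortic_root, c(80, 80))
  expect_equal(bm$SBP_aortic_root, bm$DBP_aortic_root)
  expect_equal(bm$PP_aortic_root, c(0, 0))
  expect_equal(bm$HR, c(60, 60))
  # SV is the flow integral over the beat; CO = SV x HR
  expect_equal(bm$SV, c(90, 90))
  expect_equal(bm$CO, c(5.4, 5.4))
  # TTI reduces to 60 x mean LV pressure regardless of RR
  expect_equal(bm$TTI, c(3000, 3000))
  expect_error(beat_metrics(rec, sites = "nowhere"), "unknown site")
})

test_that("stroke work equals the loop area (rectangle and trapezoid)", {
  V <- c(50, 120, 120, 50)
  p <- c(10, 10, 100, 100)
  expect_equal(pv_loop_area(V, p), 70 * 90)     # 6300 mmHg ml
  # smooth ellipse: shoelace matches the analytic area closely
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  V2 <- 85 + 35 * cos(th); p2 <- 55 + 45 * sin(th)
  expect_equal(pv_loop_area(V2, p2), pi * 35 * 45, tolerance = 1e-3)
})

test_that("TTI identity holds on a simulated record", {
  rec <- ts_supine()
  bm <- beat_metrics(rec)
  sig <- rec$signals
  bt <- rec$beats$t
  nb <- nrow(bm)
  k <- sig[, "time"] >= bt[nb] & sig[, "time"] < bt[nb + 1]
  expect_equal(bm$TTI[nb], 60 * mean(sig[k, "p_lv"]), tolerance = 1e-9)
})

test_that("hydrostatic decomposition removes exactly the heart-referenced
           column", {
  # supine and heart-level sites are unchanged
  expect_equal(hydrostatic_decomposition(12, 1.2, 0), 12)
  expect_equal(hydrostatic_decomposition(12, 0, 70), 12)
  # the subtracted column at z = 1.2 m, 70 degrees
  col <- 1050 * 9.81 * 1.2 * sin(70 * pi / 180) / 133.322   # 87.1 mmHg
  expect_equal(hydrostatic_decomposition(100, 1.2, 70), 100 - col,
               tolerance = 1e-9)
  # round trip is exact
  dp <- 57.3
  dps <- hydrostatic_decomposition(dp, 0.8, 42)
  expect_identical(dps + (dp - dps), dp)
})

test_that("ensemble averaging is grid- and stretch-invariant with a
           total-variance band", {
  # identical beats: zero SD, mean reproduces the beat
  beat <- sin(seq(0, pi, length.out = 73))
  ew <- ensemble_waveform(list(beat, beat, beat), n_points = 100)
  expect_equal(max(ew$sd), 0)
  expect_equal(ew$mean, sin(seq(0, pi, length.out = 100)), tolerance = 1e-3)
  # two constant beats at 80 and 120: mean 100, sd 20 everywhere
  ew2 <- ensemble_waveform(list(rep(80, 50), rep(120, 80)), n_points = 64)
  expect_equal(ew2$mean, rep(100, 64))
  expect_equal(ew2$sd, rep(20, 64))
  # stretching a beat in time leaves the normalized waveform unchanged
  long <- sin(seq(0, pi, length.out = 700))
  ew3 <- ensemble_waveform(list(beat, long), n_points = 100)
  expect_lt(max(ew3$sd), 1e-3)
  # grouped input: law of total variance combines within and between
  ew4 <- ensemble_waveform(list(list(rep(80, 10), rep(100, 10)),
                                list(rep(110, 10), rep(130, 10))),
                           n_points = 8)
  expect_equal(unique(ew4$mean), 105)
  expect_equal(unique(ew4$sd)^2, 10^2 + 15^2)
  expect_error(ensemble_waveform(list()), "empty")
})

test_that("steady-state report computes relative changes and flags
           literature ranges", {
  rec <- ts_supine()
  rep0 <- steady_state_report(rec, rec)
  expect_true(all(abs(rep0$rel_change_pct) < 0.5))
  # synthetic CO scaling reported verbatim
  sup <- c(CO = 6.0); tlt <- c(CO = 6.0 * 0.81)
  expect_equal(100 * (tlt - sup) / sup, c(CO = -19))
  ranges <- reference_ranges()
  expect_true(all(c("param", "rel_lo", "rel_hi") %in% names(ranges)))
  rep1 <- steady_state_report(ts_hut70(), ts_hut70(), reference = ranges)
  # central and brachial MAP are reported separately and diverge under tilt
  expect_true(all(c("MAP_aortic_root", "MAP_brachial_mid") %in% rep1$param))
  dbr <- rep1$rel_change_pct[rep1$param == "MAP_brachial_mid"]
  dc <- rep1$rel_change_pct[rep1$param == "MAP_aortic_root"]
  expect_gt(dbr, dc)
})

test_that("record export writes beats and a summary", {
  dir <- tempfile()
  export_record(ts_supine(), dir)
  expect_true(file.exists(file.path(dir, "beats.csv")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$model, "healthy_male")
  expect_true(!is.null(js$supine_steady$SV))
  unlink(dir, recursive = TRUE)
})
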