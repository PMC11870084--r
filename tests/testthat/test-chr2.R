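# Four-state ChR2 photocycle: conservation, dark behavior,
# rectification, calibration and trace-driven currents.

test_that("photocycle conserves occupancy and relaxes to closed in the dark", {
  p <- chr2_params()
  state <- chr2_dark_state()
  # drive open with light, then relax in the dark
  state <- step_photocycle(state, v = -75.4, irradiance = 100, dt = 20,
                           params = p)
  occ <- state[c("o1", "o2", "c1", "c2")]
  expect_equal(sum(occ), 1, tolerance = 1e-9)
  expect_true(state["o1"] > 1e-4)
  for (k in 1:6)
    state <- step_photocycle(state, v = -75.4, irradiance = 0, dt = 5000,
                             params = p)
  expect_lt(state["o1"], 1e-9)
  expect_lt(state["o2"], 1e-9)
  expect_equal(sum(state[c("o1", "o2", "c1", "c2")]), 1,
               tolerance = 1e-9)
  expect_error(step_photocycle(state, v = NaN, irradiance = 1, dt = 1),
               "finite")
})

test_that("photocurrent is zero with closed channels and rectified with voltage", {
  p <- calibrate_chr2()
  expect_identical(photocurrent(chr2_dark_state(), -80, p), 0)
  st <- c(o1 = 0.01, o2 = 0.002, c1 = 0.978, c2 = 0.01, p = 1)
  i_hold <- photocurrent(st, -75.4, p)
  i_zero <- photocurrent(st, 0, p)
  expect_lt(i_hold, 0)  # inward below reversal
  expect_lt(abs(i_zero), abs(i_hold) / 5)
  # same ratio as the rectification drive, open states fixed
  expect_equal(i_zero / i_hold,
               chr2_rectification(0, p) / chr2_rectification(-75.4, p),
               tolerance = 1e-12)
})

test_that("desensitization: o1 rises then declines under sustained light", {
  p <- chr2_params()
  # subthreshold intensity: slow rise, decline over hundreds of ms
  orc <- euler_photocycle_dense(-75.4, irr = 13.6, t_end = 600, p,
                                dt = 0.002, every = 500)
  i_max <- which.max(orc$o1)
  expect_gt(orc$t[i_max], 2)
  expect_lt(orc$t[i_max], 550)         # peak inside the window
  expect_lt(orc$o1[length(orc$o1)], orc$o1[i_max] * 0.995)
  # faster, pronounced desensitization at the pacing intensity: peak
  # within tens of ms, clear decline
  orc_hi <- euler_photocycle_dense(-75.4, irr = 315, t_end = 400, p,
                                   dt = 0.002, every = 500)
  i_hi <- which.max(orc_hi$o1)
  expect_lt(orc_hi$t[i_hi], 80)
  expect_lt(orc_hi$o1[length(orc_hi$o1)], orc_hi$o1[i_hi] * 0.9)
  # package integrator matches the fine-step explicit oracle
  seg <- data.frame(t0 = 0, t1 = orc$t, irr = 13.6)
  seg$t0 <- c(0, head(orc$t, -1))
  sol <- optoclamp:::chr2_integrate(c(0, 0, 0, 0), seg,
                                    function(t) -75.4, p, dt_out = 1)
  o1_pkg <- approx(sol$t, sol$states[, 1], xout = orc$t)$y
  expect_equal(o1_pkg, orc$o1, tolerance = 2e-3)
})

test_that("conductance calibration reproduces the target peak exactly and rescales linearly", {
  p1 <- calibrate_chr2(-0.45, 13.6, -75.4, 20)
  cal <- attr(p1, "calibration")
  expect_lt(cal$rel_error, 1e-4)
  # linearity: doubling the target doubles the conductance scale
  p2 <- calibrate_chr2(-0.90, 13.6, -75.4, 20)
  expect_equal(p2$g_chr2, 2 * p1$g_chr2, tolerance = 1e-9)
  # idempotence: recalibrating a calibrated model leaves g unchanged
  p3 <- calibrate_chr2(-0.45, 13.6, -75.4, 20, params = p1)
  expect_equal(p3$g_chr2, p1$g_chr2, tolerance = 1e-6)
  # holding potential enters only through the rectification drive
  p4 <- calibrate_chr2(-0.45, 13.6, -60, 20)
  # dominated by the rectification drive; the residual ~1% reflects the
  # voltage dependence of the closing rate during the pulse
  expect_equal(p4$g_chr2 / p1$g_chr2,
               chr2_rectification(-75.4, p1) / chr2_rectification(-60, p1),
               tolerance = 0.02)
  expect_error(calibrate_chr2(0.45, 13.6, -75.4, 20), "negative")
  expect_error(calibrate_chr2(-0.45, 13.6, 40, 20), "outward")
})

test_that("adaptive integration matches a fixed-step explicit oracle on the calibration pulse", {
  p <- calibrate_chr2()
  orc <- euler_photocycle_dense(-75.4, irr = 13.6, t_end = 20, p,
                                dt = 0.001, every = 50)
  i_orc <- p$g_chr2 * chr2_rectification(-75.4, p) *
    (orc$o1 + p$gamma * orc$o2)
  peak_orc <- i_orc[which.max(abs(i_orc))]
  expect_equal(peak_orc, -0.45, tolerance = 0.005)  # 0.5%
})

test_that("current along a flat trace reproduces the calibrated peak in pA", {
  p <- calibrate_chr2()
  dt <- 0.1
  cl <- 275
  trace <- data.frame(time_ms = seq(0, cl, by = dt), v_mV = -75.4)
  pulses <- data.frame(start_ms = 100, duration_ms = 20,
                       irradiance_uW_mm2 = 13.6, role = "sub")
  prot0 <- light_protocol(pulses, cycle_length_ms = cl, n_cycles = 1,
                          prepace_s = 0)
  cur <- current_along_trace(trace, prot0, p, c_m = 100)
  expect_equal(min(cur$i_pA), -45, tolerance = 0.1)
  # zero irradiance -> identically zero current
  prot_dark <- light_protocol(
    data.frame(start_ms = 100, duration_ms = 20,
               irradiance_uW_mm2 = 0, role = "sub"),
    cycle_length_ms = cl, n_cycles = 1, prepace_s = 0)
  cur0 <- current_along_trace(trace, prot_dark, p, c_m = 100)
  expect_true(all(cur0$i_pA == 0))
  # pre-pacing with pacing light reduces the probe peak (desensitization)
  prot_pre <- light_protocol(rbind(
    data.frame(start_ms = 10, duration_ms = 10,
               irradiance_uW_mm2 = 200, role = "pace"),
    pulses), cycle_length_ms = cl, n_cycles = 1, prepace_s = 3)
  cur_pre <- current_along_trace(trace, prot_pre, p, c_m = 100)
  w <- cur_pre$time_ms >= 100 & cur_pre$time_ms <= 130
  expect_gt(min(cur_pre$i_pA[w]), min(cur$i_pA))  # smaller magnitude
  expect_error(current_along_trace(trace[1:100, ], prot0, p),
               "full cycle")
})

test_that("occupancy stays conserved over a long illuminated run", {
  p <- calibrate_chr2()
  seg <- do.call(rbind, lapply(0:19, function(k)
    data.frame(t0 = k * 275 + c(0, 10, 20),
               t1 = k * 275 + c(10, 20, 275),
               irr = c(0, 200, 0))))
  sol <- optoclamp:::chr2_integrate(c(0, 0, 0, 0), seg,
                                    function(t) -75.4, p, dt_out = 5)
  occ_sum <- rowSums(sol$states[, 1:3])  # o1+o2+c2; c1 = 1 - sum
  expect_true(all(occ_sum >= -1e-9 & occ_sum <= 1 + 1e-9))
  expect_true(all(is.finite(sol$states)))
})
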