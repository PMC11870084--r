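# Experimental trace-analysis pipeline.

test_that("cycle averaging reduces noise by 1/sqrt(n)", {
  # identical noiseless cycles average to a single cycle
  rec0 <- flat_recording(5, bump_cycles = 1:5, bump_amp = 2)
  avg0 <- average_cycles(rec0, "with")
  one <- rec0$v_mV[rec0$time_ms < 275]
  expect_equal(avg0$v_mV, one, tolerance = 1e-12)
  expect_equal(attr(avg0, "n_cycles"), 5L)
  # zero-mean noise, sd 0.5, 100 cycles -> residual sd ~ 0.05
  rec <- flat_recording(100, noise_sd = 0.5, seed = 11)
  avg <- average_cycles(rec, "all")
  resid_sd <- stats::sd(avg$v_mV - (-75.4))
  expect_equal(resid_sd, 0.05, tolerance = 0.15)
  expect_equal(mean(avg$v_mV), -75.4, tolerance = 0.01)
})

test_that("delta_e recovers an injected relaxation and is zero for identical traces", {
  recA <- flat_recording(2, bump_cycles = 2, bump_amp = 0)
  a <- average_cycles(recA, "without")
  expect_equal(delta_e(a, a)$delta_e_mV, 0, tolerance = 1e-12)
  # injected exponential relaxation of known amplitude, mild noise
  rec <- flat_recording(60, noise_sd = 0.3, seed = 4,
                        bump_cycles = seq(2, 60, by = 2), bump_amp = 2)
  aw <- average_cycles(rec, "with")
  ao <- average_cycles(rec, "without")
  de <- delta_e(aw, ao)
  expect_equal(de$delta_e_mV, 2, tolerance = 0.06)
  expect_gt(de$t_ms, 150)  # within the probe window
})

test_that("AP phase markers on an idealized AP have closed-form times and ordering", {
  # trapezoid AP: rest -80, upstroke 1 ms to +20, linear repolarization
  # over 50 ms, then rest
  dt <- 0.1
  t <- seq(0, 400, by = dt)
  v <- rep(-80, length(t))
  up <- t >= 50 & t < 51
  v[up] <- -80 + (t[up] - 50) * 100          # 100 V/s ramp
  rep_ <- t >= 51 & t < 101
  v[rep_] <- 20 - (t[rep_] - 51) * 2         # -2 mV/ms
  avg <- data.frame(time_ms = t, v_mV = v)
  ph <- detect_phases(avg)
  # max dV/dt in the middle of the 1-ms upstroke; amplitude 100 mV
  expect_equal(ph$amplitude_mV, 100, tolerance = 1e-6)
  # APDx: time from init until repolarized x% of amplitude:
  # V = 20 - 2 (t - 51); 70% repolarized at V = -50 -> t = 86
  expect_equal(ph$apd70_ms, 86 - ph$t_init_ms, tolerance = 0.2)
  expect_equal(ph$apd90_ms, 96 - ph$t_init_ms, tolerance = 0.2)
  expect_equal(ph$t_plateau_ms, 0.5 * ph$apd70_ms)
  expect_lt(ph$t_init_ms, ph$t_plateau_ms + ph$t_init_ms)
  expect_lt(ph$apd70_ms, ph$apd90_ms)
  expect_lt(ph$apd90_ms, 200)  # before the diastole window
  expect_equal(as.numeric(max_upstroke(avg)), 100, tolerance = 0.01)
  # no AP -> detection error
  flat <- data.frame(time_ms = t, v_mV = rep(-80, length(t)))
  expect_error(detect_phases(flat), "no AP")
})

test_that("phase ordering holds on model-generated APs", {
  chr2 <- test_chr2()
  cfg <- synth_config(seed = 21, noise_sd = 0, n_cycles = 4)
  rec <- gen_recording(cfg, chr2 = chr2, sub_irr = 0)
  avg <- average_cycles(rec, "all")
  ph <- detect_phases(avg)
  expect_gt(ph$amplitude_mV, 70)
  expect_true(ph$apd70_ms < ph$apd90_ms)
  expect_true(0.5 * ph$apd70_ms < ph$apd70_ms)
  expect_true(ph$apd90_ms < 200)
})

test_that("offset correction pins the diastolic potential", {
  rec <- flat_recording(3, v0 = -70.4)
  cor <- offset_correct(rec, optical_depol = 0)
  expect_equal(cor$metadata$offset_shift_mV, -5, tolerance = 1e-9)
  t <- cor$time_ms
  dia <- cor$v_mV[t >= 200 & t <= 240]
  expect_equal(mean(dia), -75.4, tolerance = 1e-9)
  # optically depolarized recording: corrected to -75.4 + 3.5
  cor2 <- offset_correct(rec, optical_depol = 3.5)
  dia2 <- cor2$v_mV[t >= 200 & t <= 240]
  expect_equal(mean(dia2), -71.9, tolerance = 1e-9)
  # already-correct trace is unchanged
  rec3 <- flat_recording(3, v0 = -75.4)
  cor3 <- offset_correct(rec3, optical_depol = 0)
  expect_equal(cor3$v_mV, rec3$v_mV, tolerance = 1e-9)
})

test_that("Ohm's-law conversions handle units explicitly", {
  expect_equal(compute_rm(1, 20), 50)         # 1 mV / 20 pA = 50 Mohm
  expect_error(compute_rm(1, 0), "zero")
  expect_equal(dad_current(1, 50), 20)        # 1 mV / 50 Mohm = 20 pA
  expect_equal(dad_current(1.87, 56.3), 33.2, tolerance = 1e-3)
  expect_equal(dad_current(0, 40), 0)
})

test_that("full pipeline recovers the input resistance of a passive cell", {
  for (seed in c(42, 7, 99)) {
    cfg <- synth_config(seed = seed, noise_sd = 0.5, n_cycles = 50,
                        true_rm = 60)
    rec <- gen_passive_recording(cfg)
    aw <- average_cycles(rec, "with")
    ao <- average_cycles(rec, "without")
    de <- delta_e(aw, ao)
    rm_est <- compute_rm(de$delta_e_mV, attr(rec, "truth")$i_peak_pA)
    expect_equal(rm_est, 60, tolerance = 0.05)
  }
})

test_that("delta_e is linear in the injected current in the passive regime", {
  cfg <- synth_config(seed = 8, noise_sd = 0.3, n_cycles = 50,
                      true_rm = 60)
  de_at <- function(i_amp) {
    rec <- gen_passive_recording(cfg, i_amp_pA = i_amp)
    delta_e(average_cycles(rec, "with"),
            average_cycles(rec, "without"))$delta_e_mV
  }
  d1 <- de_at(20); d2 <- de_at(40)
  expect_equal(d2 / d1, 2, tolerance = 0.05)
})

test_that("DAD detection recovers injected events after the 100-ms filter", {
  cfg <- synth_config(seed = 5, noise_sd = 0.3,
                      dad_events = data.frame(time_s = c(3, 6),
                                              amplitude_mV = c(1.23, 1.87)))
  rec <- gen_dad_trace(cfg)
  truth <- attr(rec, "truth")
  ev <- detect_dads(rec)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$time_ms, c(3000, 6000), tolerance = 0.05)
  expect_equal(ev$amplitude_mV, truth$filtered_amplitudes,
               tolerance = 0.07)
  # ordering of amplitudes preserved
  expect_lt(ev$amplitude_mV[1], ev$amplitude_mV[2])
  # flat noisy trace -> no events
  cfg0 <- synth_config(seed = 6, noise_sd = 0.3)
  expect_equal(nrow(detect_dads(gen_dad_trace(cfg0))), 0L)
  # two bumps 150 ms apart resolve into two events
  cfg2 <- synth_config(seed = 9, noise_sd = 0.1,
                       dad_events = data.frame(time_s = c(4, 4.15),
                                               amplitude_mV = c(1.2, 1.2)))
  ev2 <- detect_dads(gen_dad_trace(cfg2))
  expect_equal(nrow(ev2), 2L)
})

test_that("repeating the 100-ms moving average barely changes slow events", {
  dt <- 0.1
  tt <- seq(-500, 1500, by = dt)
  # slow transient (rise 150 ms, decay 400 ms): slower than 200 ms
  ev <- exp(-tt / 400) - exp(-tt / 150)
  ev[tt < 0] <- 0
  f1 <- moving_average(ev, dt, 100)
  f2 <- moving_average(f1, dt, 100)
  expect_lt(abs(max(f2) - max(f1)) / max(f1), 0.01)
})

test_that("quality control applies the amplitude, resistance and pairing rules", {
  mk <- function(id, amp, r0, r1, depth = 100) {
    rec <- flat_recording(2)
    rec$metadata <- list(id = id, ap_amplitude_mV = amp, depth_um = depth,
                         electrode_r_initial_mohm = r0,
                         electrode_r_final_mohm = r1)
    rec
  }
  recs <- list(mk("ok", 85, 20, 25), mk("small", 69.9, 20, 22),
               mk("drift", 90, 20, 32.5), mk("nometa", 80, NA, NA))
  out <- qc_filter(recs)
  expect_equal(vapply(out$accepted, function(r) r$metadata$id, ""), "ok")
  expect_equal(out$log$accepted, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(out$log$reason[2], "amplitude")
  expect_match(out$log$reason[3], "resistance")
  expect_match(out$log$reason[4], "missing")
  expect_true(pair_eligible(100, 175))
  expect_false(pair_eligible(100, 185))
})

test_that("linear interpolation is exact at knots and refuses extrapolation", {
  expect_equal(interpolate_at(c(0, 7), c(0, 14), 3.5), 7)
  expect_equal(interpolate_at(c(0, 1, 4), c(2, 3, 12), 2), 6)
  expect_equal(interpolate_at(c(0, 1, 4), c(2, 3, 12), 1), 3)
  expect_error(interpolate_at(c(0, 7), c(0, 14), 8), "extrapolation")
})
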