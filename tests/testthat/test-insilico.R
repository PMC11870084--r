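# In-silico protocols: RMP, input resistance, pacing threshold,
# calibrations and intervention classification.

test_that("paced RMP sits near the quiescent resting potential", {
  rmp <- measure_rmp(model_modifiers(), test_chr2(), test_opts())
  # independent oracle: long quiescent run
  prot <- light_protocol(
    data.frame(start_ms = 0, duration_ms = 0, irradiance_uW_mm2 = 0),
    cycle_length_ms = 20000, n_cycles = 1, prepace_s = 0)
  rq <- simulate_myocyte(model_modifiers(), prot, test_chr2(),
                         record = FALSE)
  expect_equal(rmp, unname(rq$state["v"]), tolerance = 0.02)  # relative
  expect_lt(rmp, -75); expect_gt(rmp, -90)
})

test_that("subthreshold R_m agrees with a constant-current injection oracle", {
  chr2 <- test_chr2()
  opts <- test_opts()
  rm1 <- measure_rm(model_modifiers(), chr2, opts)
  expect_gt(rm1$r_m_mohm, 10); expect_lt(rm1$r_m_mohm, 500)
  expect_gt(rm1$delta_e_mV, 0.5); expect_lt(rm1$delta_e_mV, 5)
  expect_lt(rm1$i_peak_pApF, 0)

  # oracle: a 20-ms small constant-current injection (via a leak switched
  # on only during the probe window) at the same diastolic phase
  cond <- optoclamp:::condition_cycles(model_modifiers(), chr2, opts)
  g <- 3e-4
  run_phase <- function(mods, y, t_len) {
    prot <- light_protocol(
      data.frame(start_ms = 0, duration_ms = 0, irradiance_uW_mm2 = 0),
      cycle_length_ms = t_len, n_cycles = 1, prepace_s = 0)
    simulate_myocyte(mods, prot, chr2, init = y)
  }
  pace_cycle <- function(mods, y, until) {
    prot <- light_protocol(
      data.frame(start_ms = opts$pace_start_ms,
                 duration_ms = opts$pace_ms,
                 irradiance_uW_mm2 = opts$pace_irr, role = "pace"),
      cycle_length_ms = until, n_cycles = 1, prepace_s = 0)
    simulate_myocyte(mods, prot, chr2, init = y)
  }
  t_on <- opts$pace_start_ms + opts$sub_delay_ms
  m0 <- model_modifiers()
  mg <- model_modifiers(g_leak = g)
  pre <- pace_cycle(m0, cond$y, t_on)
  inj <- run_phase(mg, pre$state, opts$sub_ms)
  rest <- run_phase(m0, inj$state, opts$cycle_length_ms - t_on -
                      opts$sub_ms)
  ctrl1 <- run_phase(m0, pre$state, opts$sub_ms)
  ctrl2 <- run_phase(m0, ctrl1$state, opts$cycle_length_ms - t_on -
                       opts$sub_ms)
  dv <- c(inj$v_mV, rest$v_mV[-1]) - c(ctrl1$v_mV, ctrl2$v_mV[-1])
  RTF <- 8.314 * 298 / 96.5
  st <- inj$state
  ena <- RTF * log((0.9 * 140000 + 0.1 * 5400) /
                     (0.9 * st["nai"] + 0.1 * st["ki"]))
  ek <- RTF * log(5400 / st["ki"])
  i_inj <- abs(i_leak(mean(inj$v_mV), g, unname(ena), unname(ek)))
  r_oracle <- unname(max(dv) / i_inj)
  expect_equal(rm1$r_m_rel, r_oracle, tolerance = 0.05)
})

test_that("probe pulse that fires an AP is rejected as not subthreshold", {
  opts_hot <- test_opts()
  opts_hot$sub_irr <- 600
  expect_error(measure_rm(model_modifiers(), test_chr2(), opts_hot),
               "not subthreshold")
})

test_that("pacing threshold brackets capture and responds to Na+ block", {
  chr2 <- test_chr2()
  opts <- test_opts()
  thr <- measure_pacing_threshold(model_modifiers(), chr2, opts)
  expect_false(thr$capped)
  expect_gt(thr$i_thr_pApF, 0)
  cond <- optoclamp:::condition_cycles(model_modifiers(), chr2, opts)
  at <- optoclamp:::capture_test(model_modifiers(), chr2, opts, cond$y,
                                 thr$irradiance_uW_mm2)
  below <- optoclamp:::capture_test(model_modifiers(), chr2, opts,
                                    cond$y,
                                    thr$irradiance_uW_mm2 / 1.011)
  expect_true(at$capture)
  expect_false(below$capture)
  # Na+ block raises the threshold current (its own adaptive pacing)
  mods_na <- model_modifiers(s_Na = 0.5)
  opts_na <- optoclamp:::resolve_pace_opts(mods_na, chr2,
                                           protocol_options())
  thr_na <- measure_pacing_threshold(mods_na, chr2, opts_na)
  expect_gt(thr_na$i_thr_pApF, thr$i_thr_pApF)
})

test_that("leak calibration hits the requested RMP shift and is monotone", {
  chr2 <- test_chr2()
  opts <- protocol_options()
  cal0 <- calibrate_leak(0, model_modifiers(), chr2, opts)
  expect_identical(cal0$g_leak, 0)
  cal35 <- calibrate_leak(3.5, model_modifiers(), chr2, opts)
  expect_gt(cal35$g_leak, 0)
  expect_equal(cal35$drmp, 3.5, tolerance = 0.02 / 3.5)
  cal7 <- calibrate_leak(7, model_modifiers(), chr2, opts)
  expect_gt(cal7$g_leak, cal35$g_leak)
  expect_equal(cal7$drmp, 7, tolerance = 0.02 / 7)
})

test_that("intervention classification covers the four quadrants and ties", {
  expect_equal(classify_intervention(c(5, 5, -5, -5, 0),
                                     c(5, -5, -5, 5, 0)),
               c("I", "II", "III", "IV", "boundary"))
  expect_equal(classify_intervention(NA, 1), NA_character_)
  # reduced I_K1: R_m up, I_thr down -> quadrant II
  expect_equal(classify_intervention(42, -17), "II")
  # reduced rectification: R_m down, I_thr up -> quadrant IV
  expect_equal(classify_intervention(-8.6, 31.8), "IV")
})

test_that("modifier sweep reports zero deltas at the default point", {
  chr2 <- test_chr2()
  sw <- sweep_modifier("s_K1", c(0.7, 1, 1.4), chr2 = chr2,
                       opts = protocol_options(), metrics = c("rmp", "rm"))
  expect_true(all(sw$stable))
  i1 <- which(sw$value == 1)
  expect_equal(sw$d_rm_percent[i1], 0, tolerance = 1e-9)
  expect_equal(sw$d_rmp_mV[i1], 0, tolerance = 1e-9)
  # monotone response of R_m to I_K1 scaling
  expect_true(all(diff(sw$rm_rel) < 0))
})
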