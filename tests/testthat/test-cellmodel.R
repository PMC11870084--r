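# Cardiomyocyte model: current formulas, drug block, quiescent and paced
# behavior, stability detection.

test_that("I_K1 formula matches direct scalar evaluation", {
  # zero driving force
  expect_equal(i_k1(v = -87, ko = 5.4, e_k = -87), 0)
  # hand evaluation at +10 mV driving force, ko = 5.4 (formula units)
  expect_equal(i_k1(v = -77, ko = 5.4, e_k = -87, ir = 0.0896),
               0.2938 * (5.4 / 215.4) * 10 / (1 + exp(0.896)),
               tolerance = 1e-12)
  expect_equal(i_k1(v = -77, ko = 5.4, e_k = -87, ir = 0.0896),
               0.02135, tolerance = 1e-3)
  # weaker rectification passes more outward current
  expect_gt(i_k1(-77, 5.4, e_k = -87, ir = 0.0332),
            i_k1(-77, 5.4, e_k = -87, ir = 0.0896))
  # scale factor is multiplicative
  expect_equal(i_k1(-77, 5.4, e_k = -87, s_K1 = 2),
               2 * i_k1(-77, 5.4, e_k = -87))
})

test_that("leak current follows the stated Na/K conductance mix", {
  expect_equal(i_leak(-75, 0, 65, -90), 0)
  # reversal where (v - e_na) = 0.5 (v - e_k)
  v_rev <- 2 * 65 - (-90)
  expect_equal(i_leak(v_rev, 0.01, 65, -90), 0, tolerance = 1e-12)
  expect_equal(i_leak(-75, 1, 65, -90), -147.5)
})

test_that("Hill block factor", {
  expect_equal(block_factor(0, 1, 1), 1)
  expect_equal(block_factor(5, 5, 2), 0.5)
  expect_equal(block_factor(10, 5, 2), 0.2)
  expect_error(block_factor(-1, 5, 1), ">= 0")
})

test_that("drug profiles map concentration to channel blocks", {
  p <- drug_profile("lidocaine", concentration = 40)
  m <- apply_drug(model_modifiers(), p)
  expect_equal(m$drug_blocks$INa, 0.5)
  expect_null(m$drug_blocks$IK1)
  p2 <- drug_profile("amiodarone", concentration = 10)
  m2 <- apply_drug(model_modifiers(), p2)
  expect_equal(m2$drug_blocks$INa, 0.5)
  expect_true(m2$drug_blocks$IK1 > 0 && m2$drug_blocks$IK1 < 0.5)
  # blocks compose multiplicatively on the remaining conductance
  m3 <- apply_drug(m, p)
  expect_equal(m3$drug_blocks$INa, 0.75)
})

test_that("quiescent model rests at the published potential with tight ion bookkeeping", {
  prot <- light_protocol(
    data.frame(start_ms = 0, duration_ms = 0, irradiance_uW_mm2 = 0),
    cycle_length_ms = 60000, n_cycles = 1, prepace_s = 0)
  y0 <- myocyte_initial_state()
  rec <- simulate_myocyte(model_modifiers(), prot, chr2_params(),
                          record = FALSE)
  y1 <- rec$state
  expect_equal(unname(y1["v"]), unname(y0["v"]), tolerance = 1e-4)
  # concentration drift < 1% over one minute of simulated time
  for (nm in c("nai", "ki", "cai"))
    expect_lt(abs(y1[nm] / y0[nm] - 1), 0.01)
})

test_that("paced model fires one AP per pulse and is stable", {
  chr2 <- test_chr2()
  prot <- light_protocol(
    data.frame(start_ms = 10, duration_ms = 10,
               irradiance_uW_mm2 = 200, role = "pace"),
    cycle_length_ms = 275, n_cycles = 6, prepace_s = 0)
  rec <- simulate_myocyte(model_modifiers(), prot, chr2)
  t <- rec$time_ms
  peaks <- vapply(0:5, function(k)
    max(rec$v_mV[t >= k * 275 & t < (k + 1) * 275]), numeric(1))
  expect_true(all(peaks > 0))           # one AP per pulse
  expect_true(is_stable(rec))
  # all-light-off trace settles at rest: no APs
  prot0 <- light_protocol(
    data.frame(start_ms = 10, duration_ms = 10,
               irradiance_uW_mm2 = 0, role = "pace"),
    cycle_length_ms = 275, n_cycles = 3, prepace_s = 0)
  rec0 <- simulate_myocyte(model_modifiers(), prot0, chr2)
  expect_lt(max(rec0$v_mV), -70)
  expect_true(is_stable(rec0))
})

test_that("no regenerative upstroke without fast sodium current", {
  chr2 <- test_chr2()
  prot <- light_protocol(
    data.frame(start_ms = 10, duration_ms = 10,
               irradiance_uW_mm2 = 500, role = "pace"),
    cycle_length_ms = 275, n_cycles = 1, prepace_s = 0)
  rec <- simulate_myocyte(model_modifiers(s_Na = 0), prot, chr2)
  expect_lt(max(rec$v_mV), -20)
})

test_that("stability detector flags drift and spontaneous APs per consecutive pair", {
  # constructed trace: diastole drifting 0.5 mV per cycle
  cl <- 275; dt <- 0.1
  n <- 4
  t <- seq(0, n * cl - dt, by = dt)
  drift <- 0.5 * floor(t / cl)
  v <- -80 + drift
  pace <- data.frame(start_ms = (0:(n - 1)) * cl + 10, duration_ms = 1,
                     irradiance_uW_mm2 = 0, role = "pace")
  rec <- opto_recording(t, v, pulses = pace, cycle_length_ms = cl)
  expect_true(is_stable(rec, tolerance = 1))    # 0.5 < 1 per pair
  expect_false(is_stable(rec, tolerance = 0.4)) # exceeds per-pair bound
  # spontaneous AP between pulses
  v2 <- v; v2[t > 2 * cl + 150 & t < 2 * cl + 160] <- 20
  rec2 <- opto_recording(t, v2, pulses = pace, cycle_length_ms = cl)
  expect_false(is_stable(rec2))
})

test_that("recording container round-trips through the text format", {
  rec <- flat_recording(2, noise_sd = 0.2, seed = 3,
                        bump_cycles = 2, bump_amp = 2)
  rec$metadata <- list(id = "synthetic-1", ap_amplitude_mV = 85,
                       depth_um = 120, electrode_r_initial_mohm = 22,
                       electrode_r_final_mohm = 25)
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$v_mV, rec$v_mV, tolerance = 1e-12)
  expect_equal(back$time_ms, rec$time_ms, tolerance = 1e-12)
  expect_equal(back$metadata$depth_um, 120)
  expect_equal(nrow(back$pulses), nrow(rec$pulses))
  unlink(path)
})

test_that("light protocols and drug profiles round-trip through JSON configs", {
  prot <- light_protocol(
    data.frame(start_ms = c(10, 250), duration_ms = c(10, 20),
               irradiance_uW_mm2 = c(200, 15), role = c("pace", "sub")),
    cycle_length_ms = 275, n_cycles = 3, prepace_s = 15)
  path <- tempfile(fileext = ".json")
  write_light_protocol(prot, path)
  back <- read_light_protocol(path)
  expect_equal(back$pulses$irradiance_uW_mm2, c(200, 15))
  expect_equal(back$cycle_length_ms, 275)
  unlink(path)
  expect_error(light_protocol(
    data.frame(start_ms = c(0, 5), duration_ms = c(10, 10),
               irradiance_uW_mm2 = c(1, 1)), 275), "overlap")
})
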