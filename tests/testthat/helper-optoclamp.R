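# shared fixtures: calibrated ChR2 parameters and protocol options are
# computed once per session; the package-level conditioning cache already
# shares paced states across tests.

.fixtures <- new.env(parent = emptyenv())

test_chr2 <- function() {
  if (is.null(.fixtures$chr2)) .fixtures$chr2 <- calibrate_chr2()
  .fixtures$chr2
}

test_opts <- function() {
  if (is.null(.fixtures$opts))
    .fixtures$opts <- optoclamp:::resolve_pace_opts(
      model_modifiers(), test_chr2(), protocol_options())
  .fixtures$opts
}

# rectification-calibrated ir and matching leak, shared between the
# calibration and threshold acceptance checks
test_cal_ir <- function() {
  if (is.null(.fixtures$cal_ir))
    .fixtures$cal_ir <- calibrate_ir(8.7, 3.5, chr2 = test_chr2(),
                                     opts = protocol_options())
  .fixtures$cal_ir
}

# fixed-step explicit Euler oracle for the ChR2 photocycle at constant
# voltage and piecewise-constant irradiance; independent of the package's
# adaptive integrator
euler_photocycle <- function(v, segments, params, dt = 0.001) {
  y <- c(0, 0, 0, 0)  # o1, o2, c2, p
  out_t <- numeric(0); out_o1 <- numeric(0); out_o2 <- numeric(0)
  for (i in seq_len(nrow(segments))) {
    nstep <- round((segments$t1[i] - segments$t0[i]) / dt)
    irr <- segments$irr[i]
    for (k in seq_len(nstep)) {
      y <- y + dt * optoclamp:::chr2_deriv(y, v, irr, params)
    }
    out_t <- c(out_t, segments$t1[i])
    out_o1 <- c(out_o1, y[1]); out_o2 <- c(out_o2, y[2])
  }
  list(y = y, t = out_t, o1 = out_o1, o2 = out_o2)
}

# dense-output variant recording every `every`-th step
euler_photocycle_dense <- function(v, irr, t_end, params, dt = 0.001,
                                   every = 100) {
  y <- c(0, 0, 0, 0)
  n <- round(t_end / dt)
  keep <- seq(every, n, by = every)
  o1 <- numeric(length(keep)); o2 <- numeric(length(keep))
  j <- 1L
  for (k in seq_len(n)) {
    y <- y + dt * optoclamp:::chr2_deriv(y, v, irr, params)
    if (j <= length(keep) && k == keep[j]) {
      o1[j] <- y[1]; o2[j] <- y[2]; j <- j + 1L
    }
  }
  list(t = keep * dt, o1 = o1, o2 = o2, y = y)
}

# flat-potential recording with n cycles and per-cycle probe annotations,
# for trace-pipeline unit tests
flat_recording <- function(n_cycles, cl = 275, dt = 0.1, v0 = -75.4,
                           noise_sd = 0, seed = 1,
                           bump_cycles = integer(0), bump_amp = 0,
                           bump_start = 150, bump_tau = 8) {
  t <- seq(0, n_cycles * cl - dt, by = dt)
  v <- rep(v0, length(t))
  # rise to a flat top, hold, then decay: the plateau makes the peak
  # robust to the pipeline's short smoothing window
  shape <- function(tt) (1 - exp(-tt / bump_tau)) *
    exp(-pmax(tt - 45, 0) / (3 * bump_tau))
  peak <- max(shape(seq(0, 200, by = dt)))
  for (k in bump_cycles) {
    t0 <- (k - 1) * cl + bump_start
    idx <- t >= t0 & t < k * cl
    v[idx] <- v[idx] + (bump_amp / peak) * shape(t[idx] - t0)
  }
  if (noise_sd > 0)
    v <- v + optoclamp:::with_seed(seed, rnorm(length(v), sd = noise_sd))
  pace <- data.frame(start_ms = (seq_len(n_cycles) - 1) * cl,
                     duration_ms = 1, irradiance_uW_mm2 = 0,
                     role = "pace")
  sub <- if (length(bump_cycles))
    data.frame(start_ms = (bump_cycles - 1) * cl + bump_start,
               duration_ms = 20, irradiance_uW_mm2 = 1, role = "sub")
  else NULL
  opto_recording(t, v, pulses = rbind(pace, sub), cycle_length_ms = cl)
}
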