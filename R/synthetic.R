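# Seeded synthetic-data generators: every input the analysis pipeline
# consumes can be produced with known ground truth, so all stages are
# testable without any experimental data.

# evaluate expr under a local seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a finite numeric seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Configuration for the synthetic-recording generators
#'
#' @param seed RNG seed (required; every generator is a pure function of
#'   its configuration and seed).
#' @param noise_sd additive white recording noise (mV), default 0.3
#'   (typical sharp-microelectrode noise).
#' @param n_cycles number of stimulation cycles, default 50 (averaging
#'   over multiple cycles is part of the pipeline under test).
#' @param cycle_length_ms pacing cycle length (ms), default 275.
#' @param true_rm input resistance of the passive surrogate cell
#'   (megohms).
#' @param c_m membrane capacitance of the passive surrogate (pF).
#' @param true_lambda space constant used by the illumination-series
#'   generator (mm).
#' @param dad_events data.frame (`time_s`, `amplitude_mV`) of
#'   afterdepolarization events injected into the pacing pause.
#' @param drift_mV_per_s linear baseline offset drift.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed, noise_sd = 0.3, n_cycles = 50,
                         cycle_length_ms = 275, true_rm = 60, c_m = 100,
                         true_lambda = 1.12,
                         dad_events = data.frame(
                           time_s = numeric(0), amplitude_mV = numeric(0)),
                         drift_mV_per_s = 0) {
  stopifnot(noise_sd >= 0, n_cycles >= 1, cycle_length_ms > 0,
            true_rm > 0, c_m > 0, true_lambda > 0)
  structure(list(seed = seed, noise_sd = noise_sd, n_cycles = n_cycles,
                 cycle_length_ms = cycle_length_ms, true_rm = true_rm,
                 c_m = c_m, true_lambda = true_lambda,
                 dad_events = dad_events,
                 drift_mV_per_s = drift_mV_per_s),
            class = "synth_config")
}

# add noise and drift to a clean trace
degrade <- function(time_ms, v, config) {
  with_seed(config$seed, {
    v + rnorm(length(v), sd = config$noise_sd) +
      config$drift_mV_per_s * time_ms / 1000
  })
}

#' Generate a synthetic paced recording from the cell model
#'
#' Wraps [simulate_myocyte()]: the coupled cardiomyocyte/ChR2 model is
#' simulated under a pacing protocol (optionally with subthreshold probe
#' pulses in selected cycles), then additive white noise and a linear
#' offset drift are applied. The noise-free template and all generator
#' parameters are stored in the `truth` attribute.
#'
#' @param config a [synth_config()].
#' @param modifiers a [model_modifiers()].
#' @param chr2 calibrated [chr2_params()].
#' @param pace_irr,pace_ms pacing pulse (uW/mm^2, ms).
#' @param sub_irr,sub_ms,sub_delay_ms subthreshold probe pulse; applied in
#'   every second cycle when `sub_irr > 0` (delay relative to the pacing
#'   pulse onset).
#' @return an `opto_recording` with attribute `truth` (list with the
#'   noise-free trace, the photocurrent trace and the generator
#'   parameters).
#' @export
gen_recording <- function(config, modifiers = model_modifiers(),
                          chr2 = calibrate_chr2(),
                          pace_irr = 200, pace_ms = 10,
                          sub_irr = 15, sub_ms = 20, sub_delay_ms = 240) {
  stopifnot(inherits(config, "synth_config"))
  cl <- config$cycle_length_ms
  n <- config$n_cycles
  pace <- data.frame(start_ms = 10, duration_ms = pace_ms,
                     irradiance_uW_mm2 = pace_irr, role = "pace")
  prot1 <- light_protocol(pace, cycle_length_ms = cl, n_cycles = 1,
                          prepace_s = 0)
  # conditioning to the paced rhythm, then alternate with/without probe
  cond <- simulate_myocyte(modifiers, light_protocol(
    pace, cycle_length_ms = cl, n_cycles = 3, prepace_s = 0), chr2,
    record = FALSE)
  y <- cond$state
  sub <- data.frame(start_ms = 10 + sub_delay_ms, duration_ms = sub_ms,
                    irradiance_uW_mm2 = sub_irr, role = "sub")
  traces <- vector("list", n)
  pulses <- NULL
  for (k in seq_len(n)) {
    with_sub <- sub_irr > 0 && k %% 2L == 0L
    p <- if (with_sub) rbind(pace, sub) else pace
    prot <- light_protocol(p, cycle_length_ms = cl, n_cycles = 1,
                           prepace_s = 0)
    rec <- simulate_myocyte(modifiers, prot, chr2, init = y)
    y <- rec$state
    off <- (k - 1) * cl
    sel <- rec$time_ms < cl - 1e-9 | k == n
    traces[[k]] <- data.frame(time_ms = rec$time_ms[sel] + off,
                              v_mV = rec$v_mV[sel],
                              i_chr2 = rec$i_chr2_pApF[sel])
    pk <- p; pk$start_ms <- pk$start_ms + off
    pulses <- rbind(pulses, pk)
  }
  tr <- do.call(rbind, traces)
  v_noisy <- degrade(tr$time_ms, tr$v_mV, config)
  out <- opto_recording(tr$time_ms, v_noisy, pulses = pulses,
                        cycle_length_ms = cl,
                        metadata = list(synthetic = TRUE,
                                        seed = config$seed))
  out$i_chr2_pApF <- tr$i_chr2
  attr(out, "truth") <- list(v_clean = tr$v_mV, i_chr2 = tr$i_chr2,
                             config = config)
  out
}

#' Generate a passive-membrane (RC) recording
#'
#' A single-compartment passive membrane with known input resistance and
#' capacitance responds to a repeated current pulse; the surrogate
#' validates the Ohm's-law input-resistance pipeline against a closed
#' form. The injected current is either an ideal rectangular pulse
#' (`current = "step"`) or the calibrated ChR2 photocurrent waveform at
#' the resting potential (`current = "chr2"`).
#'
#' @param config a [synth_config()] (uses `true_rm`, `c_m`, `noise_sd`,
#'   `n_cycles`, `cycle_length_ms`, `seed`).
#' @param current `"step"` or `"chr2"`.
#' @param i_amp_pA amplitude of the step current (pA), ignored for
#'   `"chr2"`.
#' @param pulse_ms pulse duration (ms); the default 50 ms is long
#'   relative to the membrane time constant `R*C` so the response
#'   approaches the Ohm's-law plateau.
#' @param delay_ms pulse onset within each cycle (ms).
#' @param irr_uW irradiance of the ChR2 waveform (uW/mm^2).
#' @param chr2 calibrated [chr2_params()] for `current = "chr2"`.
#' @param v_rest resting potential (mV).
#' @return an `opto_recording` with attribute `truth` (noise-free trace,
#'   injected current in pA, analytic steady-state `delta_e`, config).
#' @export
gen_passive_recording <- function(config, current = c("step", "chr2"),
                                  i_amp_pA = 20, pulse_ms = 50,
                                  delay_ms = 150, irr_uW = 15,
                                  chr2 = NULL, v_rest = -75.4) {
  stopifnot(inherits(config, "synth_config"))
  current <- match.arg(current)
  cl <- config$cycle_length_ms
  dt <- 0.1
  t_cyc <- seq(0, cl - dt, by = dt)
  i_cyc <- numeric(length(t_cyc))   # pA, inward negative
  if (current == "step") {
    on <- t_cyc >= delay_ms & t_cyc < delay_ms + pulse_ms
    i_cyc[on] <- -abs(i_amp_pA)
  } else {
    if (is.null(chr2)) chr2 <- calibrate_chr2()
    seg <- data.frame(t0 = c(0, delay_ms, delay_ms + pulse_ms),
                      t1 = c(delay_ms, delay_ms + pulse_ms, cl),
                      irr = c(0, irr_uW, 0))
    sol <- chr2_integrate(c(0, 0, 0, 0), seg, function(t) v_rest, chr2,
                          dt_out = dt)
    i_dens <- chr2$g_chr2 * chr2_rectification(v_rest, chr2) *
      (sol$states[, 1L] + chr2$gamma * sol$states[, 2L])
    i_cyc <- approx(sol$t, i_dens * config$c_m, xout = t_cyc,
                    rule = 2)$y
  }
  # integrate RC membrane: dV/dt = -(V - v_rest)/(R C) - I/C
  # (R in Mohm, C in pF, I in pA, t in ms: R*C in ms, I/C in mV/ms)
  tau <- config$true_rm * config$c_m / 1000
  n_cyc <- config$n_cycles
  v <- numeric(length(t_cyc) * n_cyc)
  vk <- v_rest
  a <- exp(-dt / tau)
  zero <- numeric(length(t_cyc))
  for (k in seq_len(n_cyc)) {
    # current injected in alternate cycles only (paired with/without)
    ik <- if (k %% 2L == 0L) i_cyc else zero
    for (j in seq_along(t_cyc)) {
      # exact exponential step for piecewise-constant current
      v_inf <- v_rest - ik[j] * config$true_rm / 1000
      vk <- v_inf + (vk - v_inf) * a
      v[(k - 1) * length(t_cyc) + j] <- vk
    }
  }
  time_ms <- seq(0, by = dt, length.out = length(v))
  sub_cycles <- which(seq_len(n_cyc) %% 2L == 0L) - 1L
  pulses <- do.call(rbind, lapply(sub_cycles, function(k)
    data.frame(start_ms = k * cl + delay_ms, duration_ms = pulse_ms,
               irradiance_uW_mm2 = if (current == "chr2") irr_uW else 0,
               role = "sub")))
  # annotate cycle onsets as zero-irradiance "pace" markers for alignment
  pace <- data.frame(start_ms = (seq_len(n_cyc) - 1L) * cl,
                     duration_ms = 0.1, irradiance_uW_mm2 = 0,
                     role = "pace")
  v_noisy <- degrade(time_ms, v, config)
  out <- opto_recording(time_ms, v_noisy, pulses = rbind(pace, pulses),
                        cycle_length_ms = cl,
                        metadata = list(synthetic = TRUE,
                                        seed = config$seed))
  i_full <- unlist(lapply(seq_len(n_cyc), function(k)
    if (k %% 2L == 0L) i_cyc else zero))
  out$i_chr2_pApF <- i_full / config$c_m
  attr(out, "truth") <- list(
    v_clean = v, i_pA = i_full,
    i_peak_pA = i_cyc[which.max(abs(i_cyc))],
    delta_e_steady_mV = max(abs(i_cyc)) * config$true_rm / 1000,
    config = config)
  out
}

#' Generate an illumination-size series with known space constant
#'
#' Forward model of the space-constant experiment:
#' `delta_e_i = amplitude * (f * g)(0; b_i, true_lambda) + noise`.
#'
#' @param true_lambda space constant (mm).
#' @param amplitude response amplitude (mV).
#' @param b edge positions (mm).
#' @param noise_sd additive noise (mV); may be 0.
#' @param seed RNG seed.
#' @param far_edge far edge (mm) or `-Inf`.
#' @param direction,phase tags, see [illumination_series()].
#' @param variant weight-function variant.
#' @return an [illumination_series()] with attribute `truth`.
#' @export
gen_lambda_series <- function(true_lambda, amplitude = 3,
                              b = seq(-2, 0.3, length.out = 8),
                              noise_sd = 0, seed = 1, far_edge = -Inf,
                              direction = "longitudinal",
                              phase = "diastole",
                              variant = c("printed", "symmetric")) {
  variant <- match.arg(variant)
  stopifnot(true_lambda > 0)
  clean <- amplitude * convolve_fg(0, b, far_edge, true_lambda, variant)
  de <- if (noise_sd > 0)
    with_seed(seed, clean + rnorm(length(b), sd = noise_sd))
  else clean
  out <- illumination_series(b, de, far_edge = far_edge,
                             direction = direction, phase = phase)
  attr(out, "truth") <- list(true_lambda = true_lambda,
                             amplitude = amplitude, clean = clean,
                             noise_sd = noise_sd, seed = seed,
                             variant = variant)
  out
}

# difference-of-exponentials afterdepolarization template, unit peak
dad_shape <- function(t_ms, rise_ms = 30, decay_ms = 80) {
  s <- exp(-t_ms / decay_ms) - exp(-t_ms / rise_ms)
  s[t_ms < 0] <- 0
  t_peak <- log(decay_ms / rise_ms) / (1 / rise_ms - 1 / decay_ms)
  s / (exp(-t_peak / decay_ms) - exp(-t_peak / rise_ms))
}

#' Generate a diastolic pause trace with injected afterdepolarizations
#'
#' A quiescent baseline at the resting potential with smooth
#' difference-of-exponentials transients (30-ms rise, 80-ms decay) of the
#' configured amplitudes, plus recording noise — emulating the pause after
#' a fast-pacing run in which delayed afterdepolarizations are analyzed.
#'
#' @param config a [synth_config()]; events are taken from
#'   `config$dad_events` (`time_s` within the pause, `amplitude_mV`).
#' @param pause_s pause duration (s).
#' @param v_rest baseline potential (mV).
#' @param rise_ms,decay_ms event shape time constants.
#' @return an `opto_recording` with attribute `truth` (clean trace,
#'   events, filtered-template peak amplitudes after the standard 100-ms
#'   moving average).
#' @export
gen_dad_trace <- function(config, pause_s = 10, v_rest = -75.4,
                          rise_ms = 30, decay_ms = 80) {
  stopifnot(inherits(config, "synth_config"), pause_s >= 1)
  ev <- config$dad_events
  if (nrow(ev)) {
    if (any(ev$time_s < 0 | ev$time_s > pause_s))
      stop("dad events must lie within the pause")
    o <- order(ev$time_s)
    ev <- ev[o, , drop = FALSE]
    if (nrow(ev) > 1L && any(diff(ev$time_s) * 1000 < 4 * rise_ms))
      stop("overlapping events refused")
  }
  dt <- 0.1
  t <- seq(0, pause_s * 1000, by = dt)
  v <- rep(v_rest, length(t))
  for (i in seq_len(nrow(ev))) {
    v <- v + ev$amplitude_mV[i] *
      dad_shape(t - ev$time_s[i] * 1000, rise_ms, decay_ms)
  }
  # amplitude surviving the standard 100-ms moving average
  tmpl <- dad_shape(seq(-200, 600, by = dt), rise_ms, decay_ms)
  tmpl_f <- moving_average(tmpl, dt, 100)
  atten <- max(tmpl_f)
  v_noisy <- degrade(t, v, config)
  out <- opto_recording(t, v_noisy, pulses = NULL,
                        cycle_length_ms = NA_real_,
                        metadata = list(synthetic = TRUE,
                                        seed = config$seed))
  attr(out, "truth") <- list(v_clean = v, events = ev,
                             filter_attenuation = atten,
                             filtered_amplitudes =
                               ev$amplitude_mV * atten,
                             config = config)
  out
}

#' Generate paired relative R_m / lambda series under a power law
#'
#' `x_i` are increasing relative input-resistance values; `y_i =
#' x_i^b_true * exp(noise)` with lognormal multiplicative noise —
#' emulating the joint measurement of input resistance and space constant
#' under progressive I_K1 block, whose expected relation is the square
#' root law `lambda ~ sqrt(R_m)`.
#'
#' @param b_true true exponent (0.5 for the square-root law).
#' @param n number of pairs, >= 5.
#' @param noise multiplicative noise level (sd of log y).
#' @param seed RNG seed.
#' @param x_range range of relative R_m values.
#' @return data.frame (`x`, `y`) with attribute `truth`.
#' @export
gen_rm_lambda_pairs <- function(b_true = 0.5, n = 20, noise = 0.1,
                                seed = 1, x_range = c(1, 2.5)) {
  stopifnot(n >= 5)
  x <- seq(x_range[1L], x_range[2L], length.out = n)
  y <- with_seed(seed, x^b_true * exp(rnorm(n, sd = noise)))
  out <- data.frame(x = x, y = y)
  attr(out, "truth") <- list(b_true = b_true, noise = noise, seed = seed)
  out
}
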