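# Four-state ChR2(H134R) photocycle: two open states (o1, o2) with
# conductance ratio gamma, two closed states (c1, c2), light-dependent
# transitions driven by an activation variable p, and an empirical
# voltage-dependent rectification of the open-channel current.

#' ChR2 model parameters
#'
#' Parameters of the four-state channelrhodopsin-2 (H134R) photocycle model
#' and its voltage-dependent rectification. The defaults are the published
#' empirical values for ChR2(H134R) at 465 nm; `g_chr2` is a multiplicative
#' conductance scale that is normally set by [calibrate_chr2()] so that a
#' defined subthreshold light pulse reproduces a measured peak photocurrent
#' density.
#'
#' Light enters the model twice: as the absorbed-photon rate `k_flux *
#' irradiance * p` (1/ms) driving the closed-to-open transitions, and as a
#' normalized photon flux `k_phi * irradiance` (in 1e16 photons/s/cm^2)
#' modulating the inter-open transitions and the activation switch.
#' Irradiance is expressed in uW/mm^2 throughout.
#'
#' @param g_chr2 conductance scale (pA/pF per unit rectification drive);
#'   must be > 0. The photocurrent is
#'   `g_chr2 * rect(v) * (o1 + gamma * o2)` with `rect(v) =
#'   r0 - r1 * exp(-v / rk)` (inward negative below the ~+13.6 mV
#'   reversal).
#' @param gamma conductance of the second open state relative to the
#'   first, in (0, 1].
#' @param eps1,eps2 quantum efficiencies of the two light-driven
#'   closed-to-open transitions.
#' @param tau_act time constant (ms) of the light-activation variable p.
#' @param gd2 o2 -> c2 closing rate (1/ms).
#' @param k_flux irradiance-to-photon-absorption-rate conversion
#'   (1/ms per uW/mm^2) at 465 nm.
#' @param k_phi irradiance-to-normalized-photon-flux conversion
#'   (1e16 photons/s/cm^2 per uW/mm^2).
#' @param r0,r1,rk parameters of the empirical rectification drive (mV).
#' @return an object of class `chr2_params` (a named list).
#' @export
chr2_params <- function(g_chr2 = 1, gamma = 0.1,
                        eps1 = 0.8535, eps2 = 0.14,
                        tau_act = 1.3, gd2 = 0.05,
                        k_flux = 2.183e-5, k_phi = 0.02365,
                        r0 = 10.6408, r1 = 14.6408, rk = 42.7671) {
  stopifnot(is.numeric(g_chr2), length(g_chr2) == 1L, g_chr2 > 0,
            is.numeric(gamma), length(gamma) == 1L,
            gamma > 0, gamma <= 1)
  p <- list(g_chr2 = g_chr2, gamma = gamma, eps1 = eps1, eps2 = eps2,
            tau_act = tau_act, gd2 = gd2, k_flux = k_flux, k_phi = k_phi,
            r0 = r0, r1 = r1, rk = rk,
            # fixed rate-law constants
            e12_0 = 0.011, e12_s = 0.005, e12_h = 0.024,
            e21_0 = 0.008, e21_s = 0.004, e21_h = 0.004,
            s0_gain = 120, s0_half = 0.1,
            gd1_0 = 0.075, gd1_a = 0.043,
            gr_0 = 4.34587e-5, gr_k = 0.0211539274)
  class(p) <- "chr2_params"
  p
}

#' @export
print.chr2_params <- function(x, ...) {
  cat("Four-state ChR2(H134R) photocycle model\n")
  cat(sprintf("  conductance scale g_chr2: %.6g pA/pF per drive unit%s\n",
              x$g_chr2,
              if (!is.null(attr(x, "calibration"))) " (calibrated)" else ""))
  cat(sprintf("  open-state conductance ratio gamma: %.3g\n", x$gamma))
  cal <- attr(x, "calibration")
  if (!is.null(cal))
    cat(sprintf(
      "  calibrated to %.3g pA/pF at %.3g uW/mm^2, %.4g mV, %g-ms pulse\n",
      cal$target_peak, cal$irradiance, cal$v_hold, cal$pulse_ms))
  invisible(x)
}

#' Dark-adapted ChR2 state
#'
#' All channels in the first closed state; the activation variable p is 0.
#'
#' @return named numeric vector with elements `o1`, `o2`, `c1`, `c2`, `p`.
#' @export
chr2_dark_state <- function() {
  c(o1 = 0, o2 = 0, c1 = 1, c2 = 0, p = 0)
}

# validate a photocycle state vector
check_chr2_state <- function(state) {
  if (!is.numeric(state) || length(state) < 4L)
    stop("ChR2 state must be numeric with elements o1, o2, c1, c2 (and p)")
  nm <- c("o1", "o2", "c1", "c2")
  if (!all(nm %in% names(state)))
    stop("ChR2 state must be named with o1, o2, c1, c2")
  occ <- state[nm]
  if (any(!is.finite(occ)) || any(occ < -1e-9) || any(occ > 1 + 1e-9))
    stop("ChR2 occupancies must lie in [0, 1]")
  if (abs(sum(occ) - 1) > 1e-6)
    stop("ChR2 occupancies must sum to 1")
  invisible(state)
}

# transition rates of the photocycle at membrane potential v (mV) and
# irradiance irr (uW/mm^2)
chr2_rates <- function(v, irr, params) {
  phiu <- params$k_phi * irr
  list(
    k1 = params$eps1 * params$k_flux * irr,   # multiplied by p downstream
    k2 = params$eps2 * params$k_flux * irr,
    e12 = params$e12_0 + params$e12_s * log(1 + phiu / params$e12_h),
    e21 = params$e21_0 + params$e21_s * log(1 + phiu / params$e21_h),
    gd1 = params$gd1_0 + params$gd1_a * tanh(-(v + 20) / 20),
    gd2 = params$gd2,
    gr = params$gr_0 * exp(-params$gr_k * v),
    s0 = 0.5 * (1 + tanh(params$s0_gain * (phiu - params$s0_half)))
  )
}

# derivative of (o1, o2, c2, p); c1 by conservation
chr2_deriv <- function(y, v, irr, params) {
  r <- chr2_rates(v, irr, params)
  o1 <- y[1L]; o2 <- y[2L]; c2 <- y[3L]; p <- y[4L]
  c1 <- 1 - o1 - o2 - c2
  k1 <- r$k1 * p
  k2 <- r$k2 * p
  c(k1 * c1 - (r$gd1 + r$e12) * o1 + r$e21 * o2,
    k2 * c2 + r$e12 * o1 - (r$gd2 + r$e21) * o2,
    r$gd2 * o2 - (k2 + r$gr) * c2,
    (r$s0 - p) / params$tau_act)
}

#' Advance the ChR2 photocycle by one time step
#'
#' Integrates the four-state photocycle over `dt` milliseconds at a fixed
#' membrane potential and irradiance, using an adaptive stiff solver
#' (relative tolerance 1e-8).
#'
#' @param state named state vector as returned by [chr2_dark_state()].
#' @param v membrane potential (mV).
#' @param irradiance light intensity (uW/mm^2), >= 0.
#' @param dt step length (ms), > 0.
#' @param params a [chr2_params()] object.
#' @return the state after `dt`, same format as the input.
#' @export
step_photocycle <- function(state, v, irradiance, dt,
                            params = chr2_params()) {
  check_chr2_state(state)
  if (!is.finite(v) || !is.finite(irradiance) || irradiance < 0)
    stop("membrane potential and irradiance must be finite; irradiance >= 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  p0 <- if ("p" %in% names(state)) unname(state["p"]) else 0
  y0 <- c(unname(state["o1"]), unname(state["o2"]),
          unname(state["c2"]), p0)
  sol <- deSolve::lsoda(
    y = y0, times = c(0, dt),
    func = function(t, y, parms) list(chr2_deriv(y, v, irradiance, params)),
    rtol = 1e-8, atol = 1e-12)
  y <- sol[nrow(sol), -1L]
  out <- c(o1 = y[[1L]], o2 = y[[2L]], c2 = y[[3L]], p = y[[4L]])
  c(o1 = unname(out["o1"]), o2 = unname(out["o2"]),
    c1 = unname(1 - out["o1"] - out["o2"] - out["c2"]),
    c2 = unname(out["c2"]), p = unname(out["p"]))
}

#' Voltage-dependent rectification drive of the ChR2 photocurrent
#'
#' The empirical factor `r0 - r1 * exp(-v / rk)` (units of mV); negative
#' below the reversal potential (about +13.6 mV), so that the photocurrent
#' `g_chr2 * chr2_rectification(v) * (o1 + gamma * o2)` is inward
#' (negative) at diastolic potentials.
#'
#' @param v membrane potential (mV).
#' @param params a [chr2_params()] object.
#' @return numeric vector, same length as `v`.
#' @export
chr2_rectification <- function(v, params = chr2_params()) {
  params$r0 - params$r1 * exp(-v / params$rk)
}

#' ChR2 photocurrent density
#'
#' @param state photocycle state (see [chr2_dark_state()]).
#' @param v membrane potential (mV).
#' @param params a [chr2_params()] object.
#' @return current density in pA/pF; inward current is negative.
#' @export
photocurrent <- function(state, v, params = chr2_params()) {
  check_chr2_state(state)
  if (!is.finite(v)) stop("membrane potential must be finite")
  params$g_chr2 * chr2_rectification(v, params) *
    (unname(state["o1"]) + params$gamma * unname(state["o2"]))
}

# integrate the photocycle along piecewise-constant irradiance segments
# with a (possibly time-varying) membrane potential function vfun(t).
# segments: data.frame(t0, t1, irr). Returns final y and, if times is
# given, the dense solution on those times.
chr2_integrate <- function(y0, segments, vfun, params, dt_out = NA) {
  y <- y0
  keep_t <- numeric(0)
  keep_y <- NULL
  for (i in seq_len(nrow(segments))) {
    t0 <- segments$t0[i]; t1 <- segments$t1[i]; irr <- segments$irr[i]
    if (t1 <= t0) next
    times <- if (is.na(dt_out)) c(t0, t1) else
      unique(c(t0, seq(ceiling(t0 / dt_out) * dt_out, t1, by = dt_out), t1))
    sol <- deSolve::lsoda(
      y = y, times = times,
      func = function(t, y, parms) list(chr2_deriv(y, vfun(t), irr, params)),
      rtol = 1e-8, atol = 1e-12)
    y <- as.numeric(sol[nrow(sol), -1L])
    if (!is.na(dt_out)) {
      keep <- sol[, 1L] %% dt_out < 1e-9 | dt_out - sol[, 1L] %% dt_out < 1e-9
      keep_t <- c(keep_t, sol[keep, 1L])
      keep_y <- rbind(keep_y, sol[keep, -1L, drop = FALSE])
    }
  }
  if (is.na(dt_out)) return(list(y = y))
  dup <- duplicated(round(keep_t / dt_out))
  list(y = y, t = keep_t[!dup], states = keep_y[!dup, , drop = FALSE])
}

#' Calibrate the ChR2 conductance scale against a measured peak current
#'
#' Finds the conductance scale `g_chr2` such that a light pulse of the
#' stated duration and irradiance, applied at a fixed holding potential to
#' the dark-adapted photocycle, produces the given peak photocurrent
#' density. Because the photocurrent is strictly linear in `g_chr2`, one
#' simulation at unit scale followed by exact rescaling suffices; the peak
#' is the extremum of the current within the pulse window.
#'
#' @param target_peak target peak current density (pA/pF), < 0 (inward).
#' @param irradiance pulse irradiance (uW/mm^2), > 0.
#' @param v_hold holding potential (mV).
#' @param pulse_ms pulse duration (ms).
#' @param params starting [chr2_params()]; all fields except `g_chr2` are
#'   kept.
#' @return a `chr2_params` object with calibrated `g_chr2` and a
#'   `calibration` attribute recording the constraint and the achieved
#'   relative error.
#' @export
calibrate_chr2 <- function(target_peak = -0.45, irradiance = 13.6,
                           v_hold = -75.4, pulse_ms = 20,
                           params = chr2_params()) {
  if (!(target_peak < 0)) stop("target_peak must be negative (inward)")
  if (!(irradiance > 0)) stop("irradiance must be positive")
  rect <- chr2_rectification(v_hold, params)
  if (abs(rect) < 1e-12)
    stop("calibration failure: zero rectification drive at v_hold")
  if (rect > 0)
    stop("calibration failure: drive is outward at v_hold, ",
         "cannot match an inward target")
  unit <- params
  unit$g_chr2 <- 1
  seg <- data.frame(t0 = 0, t1 = pulse_ms, irr = irradiance)
  sol <- chr2_integrate(c(0, 0, 0, 0), seg, function(t) v_hold, unit,
                        dt_out = 0.05)
  i_unit <- rect * (sol$states[, 1L] + unit$gamma * sol$states[, 2L])
  peak_unit <- i_unit[which.max(abs(i_unit))]
  if (abs(peak_unit) < 1e-15)
    stop("calibration failure: no photocurrent at unit conductance")
  out <- params
  out$g_chr2 <- target_peak / peak_unit
  if (out$g_chr2 <= 0)
    stop("calibration failure: target sign incompatible with drive")
  attr(out, "calibration") <- list(
    target_peak = target_peak, irradiance = irradiance, v_hold = v_hold,
    pulse_ms = pulse_ms, achieved_peak = out$g_chr2 * peak_unit,
    rel_error = abs(out$g_chr2 * peak_unit - target_peak) /
      abs(target_peak))
  out
}

#' ChR2 current along a membrane-potential trace
#'
#' Integrates the calibrated photocycle driven by a recorded (or averaged)
#' membrane-potential cycle, reproducing the experimental computation of
#' the injected ChR2 current: the photocycle is first conditioned by
#' pre-pacing (the same cycle without the subthreshold pulse, with the
#' pacing light applied, repeated for `prepace_s` seconds of the protocol)
#' so that peak-current desensitization is reflected, then the cycle of
#' interest is simulated and the current returned in pA using the membrane
#' capacitance `c_m`.
#'
#' @param v_trace data.frame with columns `time_ms` and `v_mV`, covering
#'   one stimulation cycle at a sampling interval of at most 0.1 ms.
#' @param protocol a [light_protocol()]; its pulses with role `"pace"`
#'   drive the pre-pacing cycles, all pulses drive the cycle of interest.
#' @param params calibrated [chr2_params()].
#' @param c_m membrane capacitance (pF) used for the pA conversion.
#' @param prepace_trace optional data.frame like `v_trace` holding the
#'   cycle used during pre-pacing (the averaged AP without the
#'   subthreshold pulse); defaults to `v_trace`.
#' @return data.frame with columns `time_ms` and `i_pA` for the cycle of
#'   interest; the final photocycle state is attached as attribute
#'   `state`.
#' @export
current_along_trace <- function(v_trace, protocol, params, c_m = 100,
                                prepace_trace = NULL) {
  stopifnot(is.data.frame(v_trace),
            all(c("time_ms", "v_mV") %in% names(v_trace)))
  dt <- diff(v_trace$time_ms)
  if (any(dt > 0.1 + 1e-9))
    stop("v_trace sampling interval must be <= 0.1 ms")
  cl <- protocol$cycle_length_ms
  if (max(v_trace$time_ms) - min(v_trace$time_ms) < cl - 0.5)
    stop("v_trace must cover at least one full cycle")
  if (is.null(prepace_trace)) prepace_trace <- v_trace
  t0 <- min(v_trace$time_ms)
  vfun_cycle <- approxfun(v_trace$time_ms - t0, v_trace$v_mV, rule = 2)
  vfun_pre <- approxfun(prepace_trace$time_ms - min(prepace_trace$time_ms),
                        prepace_trace$v_mV, rule = 2)

  pace <- protocol$pulses[protocol$pulses$role == "pace", , drop = FALSE]
  seg_pre <- cycle_segments(pace, cl)
  y <- c(0, 0, 0, 0)
  n_pre <- floor(protocol$prepace_s * 1000 / cl)
  for (k in seq_len(n_pre)) {
    y <- chr2_integrate(y, seg_pre, vfun_pre, params)$y
  }
  seg_cycle <- cycle_segments(protocol$pulses, cl)
  sol <- chr2_integrate(y, seg_cycle, vfun_cycle, params, dt_out = 0.1)
  v_at <- vfun_cycle(sol$t)
  i_pa <- params$g_chr2 * chr2_rectification(v_at, params) *
    (sol$states[, 1L] + params$gamma * sol$states[, 2L]) * c_m
  out <- data.frame(time_ms = sol$t, i_pA = i_pa)
  attr(out, "state") <- c(o1 = sol$y[1L], o2 = sol$y[2L],
                          c1 = 1 - sum(sol$y[1:3]), c2 = sol$y[3L],
                          p = sol$y[4L])
  out
}

# split one cycle [0, cl] into constant-irradiance segments given a pulse
# table (start_ms, duration_ms, irradiance_uW_mm2)
cycle_segments <- function(pulses, cl) {
  edges <- sort(unique(c(0, cl,
                         pulses$start_ms,
                         pmin(pulses$start_ms + pulses$duration_ms, cl))))
  edges <- edges[edges >= 0 & edges <= cl]
  seg <- data.frame(t0 = edges[-length(edges)], t1 = edges[-1L])
  seg$irr <- vapply(seq_len(nrow(seg)), function(i) {
    mid <- (seg$t0[i] + seg$t1[i]) / 2
    on <- pulses$start_ms <= mid & mid < pulses$start_ms + pulses$duration_ms
    if (any(on)) sum(pulses$irradiance_uW_mm2[on]) else 0
  }, numeric(1))
  seg
}
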