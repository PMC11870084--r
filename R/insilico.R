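# Virtual-experiment protocols: RMP, input resistance via subthreshold
# light pulses, optical pacing threshold by bisection, leak and
# rectification calibration, modifier sweeps, drug response curves and
# intervention classification.

#' Options for the in-silico measurement protocols
#'
#' @param cycle_length_ms pacing cycle length (ms).
#' @param n_prepace number of paced conditioning cycles before any
#'   measurement (the measurement happens in cycle `n_prepace + 1`).
#' @param pace_irr irradiance (uW/mm^2) of the pacing light pulses, or
#'   `NULL` (default) to set it per condition to `pace_factor` times the
#'   condition's own single-pulse capture threshold. The adaptive default
#'   keeps the stimulus reliably suprathreshold while staying below the
#'   intensity range in which sustained illumination inactivates so much
#'   repolarizing current that the cell fails to return to rest.
#' @param pace_factor safety factor applied to the scanned capture
#'   threshold when `pace_irr` is `NULL`.
#' @param pace_ms pacing pulse duration (ms).
#' @param pace_start_ms pulse onset within the cycle (ms).
#' @param sub_irr,sub_ms,sub_delay_ms irradiance, duration and onset
#'   (relative to the pacing pulse onset) of the subthreshold probe pulse
#'   used for R_m; the default 20-ms, 15-uW/mm^2 pulse at 240 ms falls in
#'   deep diastole.
#' @param de_window_ms length of the window after probe-pulse onset over
#'   which the maximal membrane-potential difference is taken (pulse
#'   duration plus 100 ms by default).
#' @param capture_v threshold potential (mV) defining a triggered AP.
#' @param capture_window_ms time after pulse onset within which the AP
#'   must occur.
#' @param thr_bracket_uW bisection bracket for the pacing threshold
#'   (uW/mm^2); the upper bound mirrors the maximum technically available
#'   light intensity.
#' @param thr_rel_tol relative tolerance of the threshold bisection.
#' @param n_capture number of consecutive test pulses that must all
#'   trigger APs ("10 of 10").
#' @param c_m membrane capacitance (pF) for pA conversions.
#' @param stability_tol allowed diastolic drift between consecutive
#'   cycles (mV).
#' @return a list of class `protocol_options`.
#' @export
protocol_options <- function(cycle_length_ms = 275,
                             n_prepace = 10,
                             pace_irr = NULL, pace_factor = 1.2,
                             pace_ms = 10,
                             pace_start_ms = 10,
                             sub_irr = 15, sub_ms = 20,
                             sub_delay_ms = 240,
                             de_window_ms = NULL,
                             capture_v = 0, capture_window_ms = 50,
                             thr_bracket_uW = c(0.1, 800),
                             thr_rel_tol = 0.01,
                             n_capture = 10,
                             c_m = 100,
                             stability_tol = 1) {
  if (is.null(de_window_ms)) de_window_ms <- sub_ms + 100
  out <- list(cycle_length_ms = cycle_length_ms, n_prepace = n_prepace,
              pace_irr = pace_irr, pace_factor = pace_factor,
              pace_ms = pace_ms,
              pace_start_ms = pace_start_ms,
              sub_irr = sub_irr, sub_ms = sub_ms,
              sub_delay_ms = sub_delay_ms, de_window_ms = de_window_ms,
              capture_v = capture_v,
              capture_window_ms = capture_window_ms,
              thr_bracket_uW = thr_bracket_uW, thr_rel_tol = thr_rel_tol,
              n_capture = n_capture, c_m = c_m,
              stability_tol = stability_tol)
  class(out) <- "protocol_options"
  out
}

# simulation cache: conditioning runs keyed by modifiers + options
.sim_cache <- new.env(parent = emptyenv())

mods_key <- function(mods, chr2, opts) {
  paste(collapse = "|", c(
    format(unlist(mods[c("s_K1", "s_NaK", "s_Nab", "s_Na", "ir",
                         "g_leak")]), digits = 15),
    format(unlist(mods$drug_blocks), digits = 15),
    names(mods$drug_blocks),
    format(c(chr2$g_chr2, chr2$gamma), digits = 15),
    format(unlist(opts[c("cycle_length_ms", "n_prepace", "pace_factor",
                         "pace_ms", "pace_start_ms")]), digits = 15),
    format(opts$pace_irr %||% -1, digits = 15)))
}

# approximate sustained capture threshold from rest: upward geometric
# scan with a short train (all pulses must capture), then a coarse
# bisection; used to place the pacing intensity
scan_capture_threshold <- function(mods, chr2, opts, n_train = 5) {
  y0 <- myocyte_initial_state()
  lo <- opts$thr_bracket_uW[1]; hi_max <- opts$thr_bracket_uW[2]
  ok <- function(irr)
    capture_test(mods, chr2, opts, y0, irr, n = n_train)$capture
  irr <- max(lo, 25)
  if (ok(irr)) {
    hi <- irr
    while (irr > lo) {
      irr <- irr / 2
      if (!ok(irr)) { lo <- irr; break }
      hi <- irr
    }
  } else {
    lo <- irr
    repeat {
      irr <- irr * 2
      if (irr > hi_max)
        stop("no capture at the maximum available light intensity")
      if (ok(irr)) { hi <- irr; break }
      lo <- irr
    }
  }
  while (hi / lo > 1.1) {
    mid <- sqrt(lo * hi)
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

# run (and cache) the conditioning cycles; returns list(rec, y,
# pace_irr), verifying capture on every cycle.
#
# Conditioning is two-phase: the pacing rhythm is first established for
# three cycles without the background leak, then the leak is switched on
# for the n_prepace conditioning cycles.  This mirrors the experimental
# sequence (depolarizing illumination added during ongoing pacing) and
# avoids the model's metastable depolarized state, which a first AP fired
# from rest into a strong leak can otherwise fall into.  The pacing
# intensity is scanned on the leak-free reference so that paired
# conditions are paced identically.
condition_cycles <- function(mods, chr2, opts) {
  key <- mods_key(mods, chr2, opts)
  hit <- .sim_cache[[key]]
  if (!is.null(hit)) return(hit)
  mods0 <- mods; mods0$g_leak <- 0
  auto <- is.null(opts$pace_irr)
  base_irr <- if (auto) scan_capture_threshold(mods0, chr2, opts)
              else opts$pace_irr
  factors <- if (auto) opts$pace_factor * c(1, 1.2) else 1
  err <- NULL
  for (f in factors) {
    pace_irr <- f * base_irr
    pulse <- data.frame(start_ms = opts$pace_start_ms,
                        duration_ms = opts$pace_ms,
                        irradiance_uW_mm2 = pace_irr, role = "pace")
    protA <- light_protocol(pulse,
                            cycle_length_ms = opts$cycle_length_ms,
                            n_cycles = 3, prepace_s = 0)
    recA <- simulate_myocyte(mods0, protA, chr2, record = FALSE)
    protB <- light_protocol(pulse,
                            cycle_length_ms = opts$cycle_length_ms,
                            n_cycles = opts$n_prepace, prepace_s = 0)
    rec <- simulate_myocyte(mods, protB, chr2, init = recA$state)
    t <- rec$time_ms
    peaks <- vapply(seq_len(opts$n_prepace) - 1L, function(k) {
      w <- t >= k * opts$cycle_length_ms + opts$pace_start_ms &
        t <= k * opts$cycle_length_ms + opts$pace_start_ms +
          opts$capture_window_ms
      max(rec$v_mV[w])
    }, numeric(1))
    if (all(peaks > opts$capture_v)) {
      out <- list(rec = rec, y = rec$state, pace_irr = pace_irr)
      .sim_cache[[key]] <- out
      return(out)
    }
    err <- paste("model is not stable under pacing: capture lost during",
                 "conditioning (cycle",
                 paste(which(peaks <= opts$capture_v), collapse = ", "),
                 ")")
  }
  stop(err)
}

# resolve the adaptive pacing intensity for a reference condition and
# freeze it in the options, so that a family of paired measurements
# (e.g. with and without leak, or across root-finder iterates) is paced
# identically
resolve_pace_opts <- function(mods, chr2, opts) {
  if (!is.null(opts$pace_irr)) return(opts)
  opts$pace_irr <- opts$pace_factor *
    scan_capture_threshold(mods, chr2, opts)
  opts
}

#' Clear the cached conditioning simulations
#' @return invisibly, the number of entries removed.
#' @export
clear_sim_cache <- function() {
  n <- length(ls(.sim_cache))
  rm(list = ls(.sim_cache), envir = .sim_cache)
  invisible(n)
}

# simulate one extra cycle from the conditioned state, with optional
# extra pulses (start relative to cycle onset); returns opto_recording
# with time relative to cycle onset
measurement_cycle <- function(mods, chr2, opts, y0, pace_irr,
                              extra_pulses = NULL, n_cycles = 1) {
  pulses <- data.frame(start_ms = opts$pace_start_ms,
                       duration_ms = opts$pace_ms,
                       irradiance_uW_mm2 = pace_irr, role = "pace")
  if (!is.null(extra_pulses)) pulses <- rbind(pulses, extra_pulses)
  prot <- light_protocol(pulses, cycle_length_ms = opts$cycle_length_ms,
                         n_cycles = n_cycles, prepace_s = 0)
  simulate_myocyte(mods, prot, chr2, init = y0)
}

check_stable <- function(rec, opts, what) {
  # judge stability on the equilibrated tail of the conditioning train
  # (last 5 cycles), after the settling transient
  from <- max(0, (opts$n_prepace - 5)) * opts$cycle_length_ms
  if (!is_stable(rec, tolerance = opts$stability_tol, from_ms = from))
    stop("model is not stable under pacing; ", what,
         " was not measured (diastolic drift or spontaneous activity)")
  invisible(TRUE)
}

#' Resting membrane potential under pacing
#'
#' RMP is the minimum membrane potential after `n_prepace` paced cycles,
#' taken over one unpaced cycle length following the train (keeping the
#' statistic free of direct stimulus artifacts); it is only reported if
#' the paced model is stable (returns to the same diastolic potential
#' after each AP).
#'
#' @param modifiers a [model_modifiers()].
#' @param chr2 calibrated [chr2_params()].
#' @param opts a [protocol_options()].
#' @return RMP in mV.
#' @export
measure_rmp <- function(modifiers = model_modifiers(),
                        chr2 = calibrate_chr2(),
                        opts = protocol_options()) {
  cond <- condition_cycles(modifiers, chr2, opts)
  check_stable(cond$rec, opts, "RMP")
  quiet <- light_protocol(
    data.frame(start_ms = 0, duration_ms = 0, irradiance_uW_mm2 = 0),
    cycle_length_ms = opts$cycle_length_ms, n_cycles = 1, prepace_s = 0)
  rec <- simulate_myocyte(modifiers, quiet, chr2, init = cond$y)
  min(rec$v_mV)
}

#' Input resistance from a subthreshold light pulse
#'
#' Reproduces the in-silico R_m protocol: after the conditioning paced
#' cycles, one cycle is simulated with and one without the subthreshold
#' probe pulse. The maximal difference between the two membrane-potential
#' traces within the probe window is divided by the peak ChR2 photocurrent
#' of the probe pulse (Ohm's law); the current is converted to pA with the
#' membrane capacitance `c_m`.
#'
#' @inheritParams measure_rmp
#' @return list with `r_m_mohm` (megohms), `delta_e_mV`, `t_delta_e_ms`
#'   (time of the maximal difference, relative to probe onset),
#'   `i_peak_pApF`, `i_peak_pA`, and `r_m_rel` (mV per pA/pF, the
#'   capacitance-free form used for percentage changes).
#' @export
measure_rm <- function(modifiers = model_modifiers(),
                       chr2 = calibrate_chr2(),
                       opts = protocol_options()) {
  cond <- condition_cycles(modifiers, chr2, opts)
  check_stable(cond$rec, opts, "R_m")
  t_on <- opts$pace_start_ms + opts$sub_delay_ms
  if (t_on + opts$sub_ms > opts$cycle_length_ms)
    stop("subthreshold pulse does not fit in the cycle")
  sub <- data.frame(start_ms = t_on, duration_ms = opts$sub_ms,
                    irradiance_uW_mm2 = opts$sub_irr, role = "sub")
  rec0 <- measurement_cycle(modifiers, chr2, opts, cond$y, cond$pace_irr)
  rec1 <- measurement_cycle(modifiers, chr2, opts, cond$y, cond$pace_irr,
                            extra_pulses = sub)
  t <- rec1$time_ms
  win <- t >= t_on & t <= min(t_on + opts$de_window_ms,
                              opts$cycle_length_ms)
  if (any(rec1$v_mV[win] > opts$capture_v))
    stop("protocol error: probe pulse is not subthreshold ",
         "(an AP was triggered)")
  dv <- rec1$v_mV - rec0$v_mV
  i_max <- which.max(dv[win])
  delta_e <- dv[win][i_max]
  t_de <- t[win][i_max] - t_on
  pw <- t >= t_on & t <= t_on + opts$sub_ms + 20
  ip <- rec1$i_chr2_pApF[pw] - rec0$i_chr2_pApF[pw]
  i_peak <- ip[which.max(abs(ip))]      # inward, negative
  if (abs(i_peak) < 1e-12) stop("no probe photocurrent")
  r_rel <- delta_e / abs(i_peak)        # mV per pA/pF
  list(r_m_mohm = 1000 * delta_e / (abs(i_peak) * opts$c_m),
       delta_e_mV = delta_e, t_delta_e_ms = t_de,
       i_peak_pApF = i_peak, i_peak_pA = i_peak * opts$c_m,
       r_m_rel = r_rel)
}

# does a train of n test pulses at `irr` capture on every pulse?
# Returns list(capture, i_peak_pApF of the last pulse, rec) -- stops
# early at the first failed cycle.
capture_test <- function(mods, chr2, opts, y0, irr, n = opts$n_capture,
                         s2_delay = NULL) {
  offset <- if (is.null(s2_delay)) opts$pace_start_ms else s2_delay
  y <- y0
  i_peak <- NA_real_
  for (k in seq_len(n)) {
    pulses <- data.frame(start_ms = offset, duration_ms = opts$pace_ms,
                         irradiance_uW_mm2 = irr, role = "pace")
    prot <- light_protocol(pulses, cycle_length_ms = opts$cycle_length_ms,
                           n_cycles = 1, prepace_s = 0)
    rec <- simulate_myocyte(mods, prot, chr2, init = y)
    t <- rec$time_ms
    w <- t >= offset & t <= offset + opts$capture_window_ms
    if (max(rec$v_mV[w]) <= opts$capture_v)
      return(list(capture = FALSE, i_peak_pApF = NA_real_))
    pw <- t >= offset & t <= offset + opts$pace_ms + 20
    i_peak <- rec$i_chr2_pApF[pw][which.max(abs(rec$i_chr2_pApF[pw]))]
    y <- rec$state
  }
  list(capture = TRUE, i_peak_pApF = i_peak)
}

#' Optical pacing threshold
#'
#' The lowest light intensity at which `n_capture` consecutive light
#' pulses (duration `pace_ms`) each trigger an action potential, found by
#' an upward geometric scan followed by bisection to `thr_rel_tol`
#' relative tolerance. The threshold is also expressed as the peak ChR2
#' photocurrent density of the last threshold pulse (I_thr, pA/pF), the
#' scale on which percentage changes are computed.
#'
#' @inheritParams measure_rmp
#' @param s2_delay optional onset (ms after cycle start) of the test
#'   pulses, e.g. to probe a diastolic delay; by default test pulses are
#'   delivered at the pacing phase.
#' @return list with `irradiance_uW_mm2`, `i_thr_pApF` (positive
#'   magnitude), `capped` (TRUE if no capture at the bracket maximum) and
#'   `n_capture`.
#' @export
measure_pacing_threshold <- function(modifiers = model_modifiers(),
                                     chr2 = calibrate_chr2(),
                                     opts = protocol_options(),
                                     s2_delay = NULL) {
  cond <- condition_cycles(modifiers, chr2, opts)
  check_stable(cond$rec, opts, "pacing threshold")
  y0 <- cond$y
  lo <- opts$thr_bracket_uW[1]; hi_max <- opts$thr_bracket_uW[2]
  test <- function(irr) capture_test(modifiers, chr2, opts, y0, irr,
                                     s2_delay = s2_delay)
  # upward geometric scan for the first capturing intensity
  irr <- lo
  res <- test(irr)
  if (!res$capture) {
    repeat {
      irr_next <- min(irr * 2, hi_max)
      res <- test(irr_next)
      if (res$capture) { lo <- irr; irr <- irr_next; break }
      if (irr_next >= hi_max)
        return(list(irradiance_uW_mm2 = hi_max,
                    i_thr_pApF = NA_real_, capped = TRUE,
                    n_capture = opts$n_capture))
      lo <- irr_next; irr <- irr_next
    }
  }
  hi <- irr; res_hi <- res
  # bisection: lo fails, hi captures
  while (hi / lo > 1 + opts$thr_rel_tol) {
    mid <- sqrt(lo * hi)
    r <- test(mid)
    if (r$capture) { hi <- mid; res_hi <- r } else lo <- mid
  }
  list(irradiance_uW_mm2 = hi, i_thr_pApF = abs(res_hi$i_peak_pApF),
       capped = FALSE, n_capture = opts$n_capture)
}

#' Calibrate the background leak to a target RMP depolarization
#'
#' Root-finds the leak conductance scale `g_leak` so that the paced RMP is
#' depolarized by `target_drmp` millivolts relative to the same modifier
#' set without leak.
#'
#' @param target_drmp target RMP depolarization (mV), >= 0.
#' @inheritParams measure_rmp
#' @param tol_mV accepted deviation of the achieved shift (mV).
#' @return list with `g_leak`, `rmp_base`, `rmp_leak`, `drmp`.
#' @export
calibrate_leak <- function(target_drmp, modifiers = model_modifiers(),
                           chr2 = calibrate_chr2(),
                           opts = protocol_options(), tol_mV = 0.02) {
  stopifnot(target_drmp >= 0)
  mods0 <- modifiers; mods0$g_leak <- 0
  opts <- resolve_pace_opts(mods0, chr2, opts)
  rmp0 <- measure_rmp(mods0, chr2, opts)
  if (target_drmp == 0)
    return(list(g_leak = 0, rmp_base = rmp0, rmp_leak = rmp0, drmp = 0))
  # shift above target, or +Inf where the depolarized model loses
  # stability (treated as overshooting the target)
  f <- function(g) {
    m <- modifiers; m$g_leak <- g
    rmp <- try(measure_rmp(m, chr2, opts), silent = TRUE)
    if (inherits(rmp, "try-error")) return(Inf)
    rmp - rmp0 - target_drmp
  }
  # bracket: expand upward until the shift exceeds the target
  lo <- 0; flo <- -target_drmp
  hi <- 0.002
  fhi <- f(hi)
  while (is.finite(fhi) && fhi < 0) {
    lo <- hi; flo <- fhi
    hi <- hi * 2
    if (hi > 1) stop("leak calibration failure: target RMP shift ",
                     "not attainable before instability")
    fhi <- f(hi)
  }
  # bisection tolerant of unstable (Inf) upper evaluations
  while (hi - lo > max(1e-9, 1e-6 * hi)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (is.finite(fm) && abs(fm) < tol_mV / 4) { lo <- mid; flo <- fm; break }
    if (fm < 0) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
  if (!is.finite(flo) || abs(flo) > tol_mV)
    stop(sprintf(
      "leak calibration failure: achieved shift %.3f mV, target %.3f mV",
      flo + target_drmp, target_drmp))
  list(g_leak = lo, rmp_base = rmp0,
       rmp_leak = rmp0 + target_drmp + flo, drmp = target_drmp + flo)
}

#' Calibrate the I_K1 rectification exponent to a target R_m increase
#'
#' Root-finds the inward-rectification exponent `ir` such that a
#' leak-induced RMP depolarization of `at_drmp` millivolts raises the
#' diastolic input resistance by `target_drm_percent` percent. The leak
#' conductance is re-calibrated for every `ir` iterate, and the R_m change
#' is computed as a paired difference (same modifier set with and without
#' the calibrated leak) on the pA/pF scale.
#'
#' @param target_drm_percent target relative R_m increase (percent).
#' @param at_drmp RMP depolarization (mV) at which the increase is
#'   evaluated.
#' @inheritParams measure_rmp
#' @param interval search interval for `ir` (1/mV).
#' @param tol absolute tolerance on `ir`.
#' @return list with `ir`, the achieved `drm_percent`, the calibrated
#'   `g_leak`, and the number of outer iterations.
#' @export
calibrate_ir <- function(target_drm_percent = 8.7, at_drmp = 3.5,
                         modifiers = model_modifiers(),
                         chr2 = calibrate_chr2(),
                         opts = protocol_options(),
                         interval = c(0.01, 0.15), tol = 1e-4) {
  n_eval <- 0L
  last <- new.env(parent = emptyenv())
  f <- function(ir) {
    n_eval <<- n_eval + 1L
    m <- modifiers; m$ir <- ir
    d <- rm_change_at_drmp(at_drmp, m, chr2, opts)
    last$g_leak <- d$g_leak
    last$drm <- d$drm_percent
    d$drm_percent - target_drm_percent
  }
  flo <- f(interval[1]); fhi <- f(interval[2])
  if (flo * fhi > 0)
    stop(sprintf(paste0(
      "ir calibration failure: target %.3g%% not bracketed on [%g, %g] ",
      "(endpoint changes: %.3g%%, %.3g%%)"), target_drm_percent,
      interval[1], interval[2], flo + target_drm_percent,
      fhi + target_drm_percent))
  root <- uniroot(f, interval, f.lower = flo, f.upper = fhi, tol = tol)
  list(ir = root$root, drm_percent = last$drm + 0 * root$f.root,
       g_leak = last$g_leak, n_eval = n_eval)
}

# paired R_m change (%) induced by a leak depolarizing RMP by `drmp` mV;
# both legs and the inner leak calibration are paced at the intensity
# resolved for the leak-free reference
rm_change_at_drmp <- function(drmp, modifiers, chr2, opts) {
  m0 <- modifiers; m0$g_leak <- 0
  opts <- resolve_pace_opts(m0, chr2, opts)
  cal <- calibrate_leak(drmp, modifiers, chr2, opts)
  m1 <- modifiers; m1$g_leak <- cal$g_leak
  rm0 <- measure_rm(m0, chr2, opts)
  rm1 <- measure_rm(m1, chr2, opts)
  list(drm_percent = 100 * (rm1$r_m_rel / rm0$r_m_rel - 1),
       g_leak = cal$g_leak, rm_base = rm0, rm_leak = rm1,
       drmp = cal$drmp)
}

#' Sweep a modifier and record RMP, R_m and I_thr changes
#'
#' @param name modifier to sweep: one of `"s_K1"`, `"s_NaK"`, `"s_Nab"`,
#'   `"s_Na"`, `"ir"`, `"g_leak"`.
#' @param grid strictly monotone numeric grid of modifier values.
#' @inheritParams measure_rmp
#' @param metrics which quantities to measure (subset of `"rmp"`, `"rm"`,
#'   `"ithr"`); the pacing threshold is by far the most expensive.
#' @return data.frame of class `sweep_curve` with the raw values and the
#'   deltas relative to the default modifier set (`d_rmp_mV`,
#'   `d_rm_percent`, `d_ithr_percent`); unstable grid points are flagged
#'   and their values set to `NA`.
#' @export
sweep_modifier <- function(name, grid,
                           modifiers = model_modifiers(),
                           chr2 = calibrate_chr2(),
                           opts = protocol_options(),
                           metrics = c("rmp", "rm", "ithr")) {
  stopifnot(name %in% c("s_K1", "s_NaK", "s_Nab", "s_Na", "ir", "g_leak"))
  if (any(diff(grid) <= 0) && any(diff(grid) >= 0))
    stop("grid must be strictly monotone")
  metrics <- match.arg(metrics, several.ok = TRUE)
  eval_point <- function(value) {
    m <- modifiers
    m[[name]] <- value
    out <- list(rmp = NA_real_, rm = NA_real_, ithr = NA_real_,
                stable = TRUE)
    res <- try({
      if ("rmp" %in% metrics) out$rmp <- measure_rmp(m, chr2, opts)
      if ("rm" %in% metrics) out$rm <- measure_rm(m, chr2, opts)$r_m_rel
      if ("ithr" %in% metrics)
        out$ithr <- measure_pacing_threshold(m, chr2, opts)$i_thr_pApF
    }, silent = TRUE)
    if (inherits(res, "try-error")) out$stable <- FALSE
    out
  }
  base <- eval_point(modifiers[[name]])
  rows <- lapply(grid, eval_point)
  out <- data.frame(
    value = grid,
    rmp_mV = vapply(rows, `[[`, numeric(1), "rmp"),
    rm_rel = vapply(rows, `[[`, numeric(1), "rm"),
    ithr_pApF = vapply(rows, `[[`, numeric(1), "ithr"),
    stable = vapply(rows, `[[`, logical(1), "stable"))
  out$d_rmp_mV <- out$rmp_mV - base$rmp
  out$d_rm_percent <- 100 * (out$rm_rel / base$rm - 1)
  out$d_ithr_percent <- 100 * (out$ithr_pApF / base$ithr - 1)
  attr(out, "modifier") <- name
  attr(out, "baseline") <- base
  class(out) <- c("sweep_curve", "data.frame")
  out
}

#' Drug concentration-response of pacing threshold and input resistance
#'
#' Applies a multichannel [drug_profile()] at increasing concentrations
#' and reports the relative changes in I_thr and R_m together with the
#' fractional I_Na block, the axis on which multichannel blockers are
#' compared with isolated Na-channel block.
#'
#' @param profile a [drug_profile()].
#' @param concentrations numeric vector of concentrations (uM).
#' @inheritParams measure_rmp
#' @param metrics subset of `"rm"`, `"ithr"`.
#' @return data.frame with columns `concentration_uM`, `ina_block`,
#'   `d_rm_percent`, `d_ithr_percent`, `stable`.
#' @export
drug_response <- function(profile, concentrations,
                          modifiers = model_modifiers(),
                          chr2 = calibrate_chr2(),
                          opts = protocol_options(),
                          metrics = c("rm", "ithr")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  base_rm <- if ("rm" %in% metrics)
    measure_rm(modifiers, chr2, opts)$r_m_rel else NA_real_
  base_thr <- if ("ithr" %in% metrics)
    measure_pacing_threshold(modifiers, chr2, opts)$i_thr_pApF
    else NA_real_
  rows <- lapply(concentrations, function(conc) {
    p <- profile; p$concentration <- conc
    m <- apply_drug(modifiers, p)
    ina <- m$drug_blocks[["INa"]] %||% 0
    out <- list(ina = ina, rm = NA_real_, thr = NA_real_, stable = TRUE)
    res <- try({
      if ("rm" %in% metrics)
        out$rm <- measure_rm(m, chr2, opts)$r_m_rel
      if ("ithr" %in% metrics)
        out$thr <- measure_pacing_threshold(m, chr2, opts)$i_thr_pApF
    }, silent = TRUE)
    if (inherits(res, "try-error")) out$stable <- FALSE
    out
  })
  data.frame(
    concentration_uM = concentrations,
    ina_block = vapply(rows, `[[`, numeric(1), "ina"),
    d_rm_percent = 100 * (vapply(rows, `[[`, numeric(1), "rm") /
                            base_rm - 1),
    d_ithr_percent = 100 * (vapply(rows, `[[`, numeric(1), "thr") /
                              base_thr - 1),
    stable = vapply(rows, `[[`, logical(1), "stable"))
}

#' Classify an intervention by its R_m / I_thr signature
#'
#' Quadrant I: I_thr and R_m both increased (multichannel Na+/K+ blockers);
#' II: I_thr decreased, R_m increased (pro-arrhythmic conditions such as
#' reduced I_K1); III: both decreased; IV: I_thr increased, R_m decreased
#' (anti-arrhythmic conditions such as reduced I_K1 rectification).
#' Changes with magnitude at or below `tol` are labeled `"boundary"`.
#'
#' @param d_rm relative change in R_m (percent).
#' @param d_ithr relative change in I_thr (percent).
#' @param tol tie tolerance (percentage points).
#' @return character vector of labels among `"I"`, `"II"`, `"III"`,
#'   `"IV"`, `"boundary"`.
#' @export
classify_intervention <- function(d_rm, d_ithr, tol = 1e-8) {
  stopifnot(length(d_rm) == length(d_ithr))
  vapply(seq_along(d_rm), function(i) {
    r <- d_rm[i]; s <- d_ithr[i]
    if (is.na(r) || is.na(s)) return(NA_character_)
    if (abs(r) <= tol || abs(s) <= tol) return("boundary")
    if (s > 0 && r > 0) "I"
    else if (s < 0 && r > 0) "II"
    else if (s < 0 && r < 0) "III"
    else "IV"
  }, character(1))
}
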