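# Analysis pipeline for sharp-microelectrode membrane-potential
# recordings: cycle averaging, subthreshold depolarization (delta-E), AP
# phase detection, offset correction, Ohm's-law input resistance,
# upstroke velocity, DAD detection and quality-control filters.

#' Construct a membrane-potential recording
#'
#' Container for a sampled membrane-potential trace with pulse annotations
#' and acquisition metadata, as produced by the simulator, the synthetic
#' generators, or [read_recording()].
#'
#' @param time_ms,v_mV numeric vectors (uniform sampling required).
#' @param pulses data.frame with `start_ms`, `duration_ms`,
#'   `irradiance_uW_mm2`, `role` (`"pace"` or `"sub"`).
#' @param cycle_length_ms pacing cycle length (ms).
#' @param metadata named list; recognized fields include
#'   `ap_amplitude_mV`, `depth_um`, `electrode_r_initial_mohm`,
#'   `electrode_r_final_mohm`, `id`.
#' @return an object of class `opto_recording`.
#' @export
opto_recording <- function(time_ms, v_mV, pulses = NULL,
                           cycle_length_ms = NA_real_,
                           metadata = list()) {
  stopifnot(length(time_ms) == length(v_mV), length(time_ms) >= 2L)
  dt <- diff(time_ms)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("recording must be uniformly sampled")
  if (!is.null(pulses) && nrow(pulses)) {
    if (any(pulses$start_ms < min(time_ms) - 1e-9 |
            pulses$start_ms + pulses$duration_ms > max(time_ms) + 1e-9))
      stop("pulse annotations must lie within the trace span")
    if (is.null(pulses$role)) pulses$role <- "pace"
  }
  rec <- list(time_ms = time_ms, v_mV = v_mV,
              i_chr2_pApF = rep(NA_real_, length(time_ms)),
              pulses = pulses, cycle_length_ms = cycle_length_ms,
              modifiers = NULL, metadata = metadata, state = NULL)
  class(rec) <- "opto_recording"
  rec
}

# cycles aligned on pacing-pulse onsets; returns list of index windows
cycle_windows <- function(recording) {
  pace <- recording$pulses[recording$pulses$role == "pace", ,
                           drop = FALSE]
  if (is.null(pace) || nrow(pace) < 1L)
    stop("recording has no pacing-pulse annotations")
  starts <- sort(pace$start_ms)
  cl <- recording$cycle_length_ms
  if (is.na(cl)) {
    if (length(starts) < 2L) stop("cannot infer cycle length")
    dcl <- diff(starts)
    if (max(dcl) - min(dcl) > 1e-6 * stats::median(dcl))
      stop("alignment error: pacing cycle lengths differ")
    cl <- stats::median(dcl)
  }
  t <- recording$time_ms
  dt <- t[2L] - t[1L]
  n_per <- round(cl / dt)
  lapply(starts, function(s) {
    i0 <- which.min(abs(t - s))
    if (i0 + n_per - 1L > length(t)) return(NULL)
    seq(i0, i0 + n_per - 1L)
  })
}

#' Average aligned stimulation cycles
#'
#' Cycles are aligned on the pacing-pulse onsets and averaged pointwise to
#' reduce recording noise, separately for cycles with and without the
#' subthreshold probe pulse.
#'
#' @param recording an [opto_recording()] with pulse annotations.
#' @param condition `"with"` (cycles containing a `"sub"` pulse),
#'   `"without"`, or `"all"`.
#' @return data.frame with `time_ms` (relative to the pacing-pulse onset)
#'   and `v_mV`; attributes `n_cycles` (number averaged) and `sub_pulse`
#'   (the probe-pulse annotation relative to cycle onset, if present).
#' @export
average_cycles <- function(recording,
                           condition = c("all", "with", "without")) {
  condition <- match.arg(condition)
  wins <- cycle_windows(recording)
  pace <- recording$pulses[recording$pulses$role == "pace", ,
                           drop = FALSE]
  starts <- sort(pace$start_ms)
  sub <- recording$pulses[recording$pulses$role == "sub", , drop = FALSE]
  cl <- if (!is.na(recording$cycle_length_ms)) recording$cycle_length_ms
        else stats::median(diff(starts))
  has_sub <- vapply(starts, function(s)
    any(sub$start_ms >= s & sub$start_ms < s + cl), logical(1))
  keep <- switch(condition, all = rep(TRUE, length(wins)),
                 with = has_sub, without = !has_sub)
  keep <- keep & !vapply(wins, is.null, logical(1))
  if (sum(keep) < 1L)
    stop("no complete cycles in condition '", condition, "'")
  mat <- do.call(cbind, lapply(wins[keep],
                               function(i) recording$v_mV[i]))
  dt <- recording$time_ms[2L] - recording$time_ms[1L]
  out <- data.frame(time_ms = (seq_len(nrow(mat)) - 1L) * dt,
                    v_mV = rowMeans(mat))
  attr(out, "n_cycles") <- sum(keep)
  if (condition %in% c("with", "all") && nrow(sub)) {
    s0 <- starts[which(has_sub)[1L]]
    sp <- sub[sub$start_ms >= s0 & sub$start_ms < s0 + cl, , drop = FALSE]
    if (nrow(sp)) {
      sp$start_ms <- sp$start_ms - s0
      attr(out, "sub_pulse") <- sp
    }
  }
  out
}

#' Subthreshold depolarization between paired averaged cycles
#'
#' The maximal membrane-potential difference between the averaged cycles
#' with and without the subthreshold light pulse, searched over the pulse
#' window extended by `window_ext_ms` to cover the passive relaxation.
#'
#' @param avg_with,avg_without averaged traces from [average_cycles()],
#'   equal length and alignment.
#' @param pulse probe-pulse annotation (`start_ms`, `duration_ms`,
#'   relative to cycle onset); defaults to the `sub_pulse` attribute of
#'   `avg_with`. If absent, the whole cycle is searched.
#' @param window_ext_ms search-window extension after pulse offset (ms).
#' @param smooth_ms moving-average width applied to the difference trace
#'   before taking the maximum (ms). Taking the maximum of a noisy
#'   difference is biased upward by the residual-noise envelope; a short
#'   smoother (default 10 ms, well below the passive response width)
#'   suppresses the bias at negligible cost in peak attenuation. Set to 0
#'   to disable.
#' @return list with `delta_e_mV` and `t_ms` (time of the maximum,
#'   relative to cycle onset).
#' @export
delta_e <- function(avg_with, avg_without, pulse = NULL,
                    window_ext_ms = 100, smooth_ms = 10) {
  stopifnot(nrow(avg_with) == nrow(avg_without))
  if (max(abs(avg_with$time_ms - avg_without$time_ms)) > 1e-9)
    stop("averaged traces are not aligned")
  if (is.null(pulse)) pulse <- attr(avg_with, "sub_pulse")
  dv <- avg_with$v_mV - avg_without$v_mV
  t <- avg_with$time_ms
  if (smooth_ms > 0 && length(t) > 3L)
    dv <- moving_average(dv, t[2L] - t[1L], smooth_ms)
  if (!is.null(pulse)) {
    w <- t >= pulse$start_ms[1L] &
      t <= pulse$start_ms[1L] + pulse$duration_ms[1L] + window_ext_ms
  } else w <- rep(TRUE, length(t))
  i <- which(w)[which.max(dv[w])]
  list(delta_e_mV = dv[i], t_ms = t[i])
}

#' Action-potential phase markers
#'
#' AP initiation is the time of maximal upstroke dV/dt; APD70 and APD90
#' are the times (from initiation) at which the potential has repolarized
#' 70% and 90% of the AP amplitude (peak minus diastolic baseline, the
#' mean over the diastole window 200-240 ms after initiation); the plateau
#' marker is 0.5 * APD70.
#'
#' @param avg averaged AP trace (data.frame `time_ms`, `v_mV`).
#' @param min_amplitude_mV minimal AP amplitude; smaller deflections
#'   raise a detection error.
#' @param diastole_ms diastole window relative to AP initiation (ms).
#' @return object of class `ap_markers`: list with `t_init_ms`,
#'   `apd70_ms`, `apd90_ms`, `t_plateau_ms`, `diastole_ms` (absolute
#'   window), `amplitude_mV`, `v_peak_mV`, `v_diastolic_mV`.
#' @export
detect_phases <- function(avg, min_amplitude_mV = 10,
                          diastole_ms = c(200, 240)) {
  t <- avg$time_ms; v <- avg$v_mV
  dvdt <- c(NA, diff(v) / diff(t))
  i_init <- which.max(dvdt)
  t_init <- t[i_init]
  dia_w <- t >= t_init + diastole_ms[1L] & t <= t_init + diastole_ms[2L]
  if (!any(dia_w))
    stop("detection error: diastole window outside the trace")
  v_dia <- mean(v[dia_w])
  post <- t >= t_init
  i_peak <- which(post)[which.max(v[post])]
  v_peak <- v[i_peak]
  amp <- v_peak - v_dia
  if (!is.finite(amp) || amp < min_amplitude_mV)
    stop("detection error: no AP found (amplitude ",
         sprintf("%.1f", amp), " mV)")
  apd_at <- function(frac) {
    target <- v_peak - frac * amp
    after <- seq(i_peak, length(v))
    j <- which(v[after] <= target)[1L]
    if (is.na(j)) return(NA_real_)
    # linear interpolation between the bracketing samples
    k <- after[j]
    if (k == i_peak) return(t[k] - t_init)
    t_cross <- t[k - 1L] + (t[k] - t[k - 1L]) *
      (v[k - 1L] - target) / (v[k - 1L] - v[k])
    t_cross - t_init
  }
  apd70 <- apd_at(0.7)
  apd90 <- apd_at(0.9)
  out <- list(t_init_ms = t_init, apd70_ms = apd70, apd90_ms = apd90,
              t_plateau_ms = 0.5 * apd70,
              diastole_ms = t_init + diastole_ms,
              amplitude_mV = amp, v_peak_mV = v_peak,
              v_diastolic_mV = v_dia)
  class(out) <- "ap_markers"
  out
}

#' @export
print.ap_markers <- function(x, ...) {
  cat(sprintf(
    "AP markers: init %.2f ms, APD70 %.2f ms, APD90 %.2f ms, plateau %.2f ms\n",
    x$t_init_ms, x$apd70_ms, x$apd90_ms, x$t_plateau_ms))
  cat(sprintf("  amplitude %.1f mV (peak %.1f, diastolic %.1f)\n",
              x$amplitude_mV, x$v_peak_mV, x$v_diastolic_mV))
  invisible(x)
}

#' Correct the recording offset to the reference diastolic potential
#'
#' Shifts the trace additively so that the mean diastolic potential equals
#' the control resting membrane potential plus any constant light-induced
#' depolarization, compensating electrode offset drift.
#'
#' @param recording an [opto_recording()].
#' @param optical_depol constant light-induced RMP depolarization (mV).
#' @param target_rmp control RMP (mV); default -75.4.
#' @param diastole_ms diastole window relative to each pacing-pulse onset
#'   used to estimate the current diastolic level.
#' @return the shifted recording; the applied shift is stored in
#'   `metadata$offset_shift_mV`.
#' @export
offset_correct <- function(recording, optical_depol = 0,
                           target_rmp = -75.4,
                           diastole_ms = c(200, 240)) {
  pace <- recording$pulses[recording$pulses$role == "pace", ,
                           drop = FALSE]
  t <- recording$time_ms
  if (!is.null(pace) && nrow(pace)) {
    in_dia <- rep(FALSE, length(t))
    for (s in pace$start_ms)
      in_dia <- in_dia | (t >= s + diastole_ms[1L] &
                            t <= s + diastole_ms[2L])
    if (!any(in_dia)) stop("diastole window not identifiable")
    v_dia <- mean(recording$v_mV[in_dia])
  } else {
    v_dia <- mean(recording$v_mV)
  }
  shift <- (target_rmp + optical_depol) - v_dia
  recording$v_mV <- recording$v_mV + shift
  recording$metadata$offset_shift_mV <- shift
  recording
}

#' Input resistance by Ohm's law
#'
#' `R_m = delta_e / i_chr2` with explicit unit handling: a potential in mV
#' divided by a current in pA gives gigaohms, reported in megohms.
#'
#' @param delta_e subthreshold depolarization (mV).
#' @param i_chr2 injected current (pA), e.g. the peak computed ChR2
#'   current from [current_along_trace()] with a 100-pF capacitance.
#' @return input resistance in megohms.
#' @export
compute_rm <- function(delta_e, i_chr2) {
  if (any(i_chr2 == 0)) stop("undefined: zero injected current")
  1000 * delta_e / abs(i_chr2)
}

#' Maximal upstroke velocity
#'
#' Maximum of the centered finite-difference dV/dt over the trace
#' (mV/ms = V/s). Apply to averaged traces: differentiating unaveraged
#' noisy recordings inflates the estimate.
#'
#' @param avg averaged AP trace (data.frame `time_ms`, `v_mV`).
#' @return maximal dV/dt in V/s, with attribute `t_ms` (time of maximum).
#' @export
max_upstroke <- function(avg) {
  t <- avg$time_ms; v <- avg$v_mV
  n <- length(v)
  dvdt <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  i <- which.max(dvdt)
  structure(dvdt[i], t_ms = t[i + 1L])
}

#' Moving-average filter
#'
#' Centered moving average over `width_ms`, the pre-processing applied to
#' membrane-potential traces before afterdepolarization analysis. Edges
#' are filled with partial-window means.
#'
#' @param v numeric trace.
#' @param dt_ms sampling interval (ms).
#' @param width_ms filter width (ms), default 100.
#' @return filtered trace, same length.
#' @export
moving_average <- function(v, dt_ms, width_ms = 100) {
  w <- max(1L, round(width_ms / dt_ms))
  if (w %% 2L == 0L) w <- w + 1L
  k <- rep(1 / w, w)
  out <- stats::filter(v, k, sides = 2)
  # partial windows at the edges
  half <- (w - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(v)
  for (i in seq_len(min(half, n))) {
    out[i] <- cs[min(n, i + half)] / min(n, i + half)
    j <- n - i + 1L
    lo <- max(1L, j - half)
    out[j] <- (cs[n] - if (lo > 1L) cs[lo - 1L] else 0) / (n - lo + 1L)
  }
  as.numeric(out)
}

#' Detect delayed afterdepolarizations in a pacing pause
#'
#' The trace is smoothed with a 100-ms moving average, then local maxima
#' exceeding the local diastolic baseline by at least `k_sd` times the
#' post-filter residual noise (or `min_amplitude_mV`, whichever is larger)
#' are reported. The amplitude of each event is its filtered peak minus
#' the flanking baseline (mean of the minima within `flank_ms` on either
#' side).
#'
#' @param recording an [opto_recording()] covering the pause, or a
#'   data.frame with `time_ms` and `v_mV`.
#' @param pause_ms optional `c(start, end)` restricting the analysis
#'   window (ms); default: whole trace.
#' @param filter_ms moving-average width (ms).
#' @param k_sd detection threshold in units of post-filter noise sd.
#' @param min_separation_ms minimal separation between events (ms).
#' @param flank_ms window on each side of a peak over which the flanking
#'   baseline is taken.
#' @param min_amplitude_mV absolute floor of the detection threshold.
#' @return data.frame with `time_ms` and `amplitude_mV`, one row per
#'   event (zero rows if none).
#' @export
detect_dads <- function(recording, pause_ms = NULL, filter_ms = 100,
                        k_sd = 3, min_separation_ms = 50,
                        flank_ms = 300, min_amplitude_mV = 0.05) {
  t <- recording$time_ms; v <- recording$v_mV
  if (!is.null(pause_ms)) {
    sel <- t >= pause_ms[1L] & t <= pause_ms[2L]
    t <- t[sel]; v <- v[sel]
  }
  if (length(t) < 10L) stop("pause segment too short")
  dt <- t[2L] - t[1L]
  vf <- moving_average(v, dt, filter_ms)
  # post-filter residual noise: raw high-frequency noise attenuated by
  # the moving-average window
  sd_raw <- stats::sd(diff(v)) / sqrt(2)
  w <- max(1L, round(filter_ms / dt))
  sd_post <- sd_raw / sqrt(w)
  thr <- max(k_sd * sd_post, min_amplitude_mV)
  dev <- vf - stats::median(vf)
  sep <- max(1L, round(min_separation_ms / dt))
  idx <- find_peaks(dev, min_height = thr, min_prominence = thr,
                    min_distance = sep)
  if (!length(idx))
    return(data.frame(time_ms = numeric(0), amplitude_mV = numeric(0)))
  n <- length(vf)
  fl <- round(flank_ms / dt)
  amp <- vapply(idx, function(i) {
    lo <- max(1L, i - fl)
    hi <- min(n, i + fl)
    base <- (min(vf[lo:i]) + min(vf[i:hi])) / 2
    vf[i] - base
  }, numeric(1))
  data.frame(time_ms = t[idx], amplitude_mV = amp)
}

# local maxima with a topographic-prominence and separation criterion
find_peaks <- function(x, min_height = -Inf, min_prominence = 0,
                       min_distance = 1L) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  prominence <- vapply(cand, function(i) {
    saddle <- function(dir) {
      j <- i; m <- x[i]
      repeat {
        j <- j + dir
        if (j < 1L || j > n) return(m)      # ran off the boundary
        if (x[j] > x[i]) return(m)          # found higher ground
        if (x[j] < m) m <- x[j]
      }
    }
    x[i] - max(saddle(-1L), saddle(1L))
  }, numeric(1))
  ok <- cand[prominence >= min_prominence]
  if (!length(ok)) return(integer(0))
  # greedy separation filter, tallest first
  ok <- ok[order(x[ok], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ok) {
    if (!length(kept) || all(abs(kept - i) >= min_distance))
      kept <- c(kept, i)
  }
  sort(kept)
}

#' Current underlying an afterdepolarization
#'
#' Ohm's law: `I = E / R_m`, with amplitude in mV and resistance in
#' megohms giving current in nA, reported in pA.
#'
#' @param amplitude afterdepolarization amplitude (mV).
#' @param r_m input resistance (megohms), > 0.
#' @return current in pA.
#' @export
dad_current <- function(amplitude, r_m) {
  stopifnot(all(r_m > 0))
  1000 * amplitude / r_m
}

#' Quality-control filter for recordings
#'
#' Applies the acquisition quality rules: AP amplitude at least 70 mV,
#' and electrode resistance change from its initial value at most
#' 10 megohms (a larger change indicates a broken or clotted tip).
#' Recordings with missing metadata are rejected with reason
#' `"missing metadata"` rather than silently passed.
#'
#' @param recordings list of [opto_recording()] objects with metadata
#'   fields `ap_amplitude_mV`, `electrode_r_initial_mohm`,
#'   `electrode_r_final_mohm` (and optionally `id`, `depth_um`).
#' @param min_amplitude_mV amplitude cutoff (mV).
#' @param max_r_change_mohm electrode-resistance drift cutoff (megohms).
#' @return list with `accepted` (sublist of recordings) and `log`
#'   (data.frame `id`, `accepted`, `reason`).
#' @export
qc_filter <- function(recordings, min_amplitude_mV = 70,
                      max_r_change_mohm = 10) {
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    md <- rec$metadata
    id <- md$id %||% i
    need <- c("ap_amplitude_mV", "electrode_r_initial_mohm",
              "electrode_r_final_mohm")
    if (any(!need %in% names(md)) ||
        any(!vapply(md[intersect(need, names(md))],
                    function(x) is.finite(as.numeric(x)), logical(1))))
      return(data.frame(id = as.character(id), accepted = FALSE,
                        reason = "missing metadata"))
    if (md$ap_amplitude_mV < min_amplitude_mV)
      return(data.frame(id = as.character(id), accepted = FALSE,
                        reason = sprintf("AP amplitude %.1f mV < %g mV",
                                         md$ap_amplitude_mV,
                                         min_amplitude_mV)))
    dr <- abs(md$electrode_r_final_mohm - md$electrode_r_initial_mohm)
    if (dr > max_r_change_mohm)
      return(data.frame(id = as.character(id), accepted = FALSE,
                        reason = sprintf(
                          "electrode resistance changed %.1f Mohm", dr)))
    data.frame(id = as.character(id), accepted = TRUE, reason = "")
  })
  log <- do.call(rbind, rows)
  list(accepted = recordings[log$accepted], log = log)
}

#' Pair eligibility by electrode penetration depth
#'
#' Paired comparisons are restricted to impalements whose microelectrode
#' penetration depths differ by less than `max_diff_um`.
#'
#' @param depth_a,depth_b penetration depths (um).
#' @param max_diff_um maximal allowed difference (um).
#' @return logical.
#' @export
pair_eligible <- function(depth_a, depth_b, max_diff_um = 80) {
  abs(depth_a - depth_b) < max_diff_um
}

#' Linear interpolation at a target coordinate
#'
#' Piecewise-linear interpolation used e.g. to read off R_m and I_thr
#' changes at 3.5- and 7-mV RMP depolarization; extrapolation beyond the
#' data range is refused.
#'
#' @param x,y coordinates (x need not be sorted; ties are not allowed).
#' @param x_target target coordinate(s), within `range(x)`.
#' @return interpolated value(s).
#' @export
interpolate_at <- function(x, y, x_target) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (any(x_target < min(x) | x_target > max(x)))
    stop("extrapolation refused: x_target outside the data range")
  approx(x, y, xout = x_target, ties = "error")$y
}
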