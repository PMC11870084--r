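# Murine ventricular cardiomyocyte model: modifier hooks, formula-level
# current definitions, drug block, and the coupled simulation wrapper
# around the compiled right-hand side.

# channels that accept a fractional conductance block
.block_channels <- c("INa", "ICaL", "IKr", "IKs", "IK1", "Ito",
                     "IKur", "IKss")

#' Modifiers perturbing the cardiomyocyte model
#'
#' Multiplicative scaling factors for selected currents, the I_K1 inward
#' rectification exponent, the cation background leak conductance, and
#' per-channel fractional drug block.
#'
#' @param s_K1,s_NaK,s_Nab,s_Na scale factors (dimensionless, default 1)
#'   for the inward-rectifier K+ current, the Na+/K+-ATPase current, the
#'   background Na+ current and the fast Na+ current.
#' @param ir inward-rectification exponent of I_K1 (1/mV); the source
#'   model's value is 0.0896.
#' @param g_leak conductance scale of the cation background leak
#'   (pA/pF per mV; default 0 = no leak). The leak has a K+ conductance of
#'   0.5 relative to its Na+ conductance.
#' @param drug_blocks named list mapping channel names (`r
#'   paste(.block_channels, collapse = ", ")`) to a blocked fraction in
#'   [0, 1].
#' @return an object of class `model_modifiers`.
#' @export
model_modifiers <- function(s_K1 = 1, s_NaK = 1, s_Nab = 1, s_Na = 1,
                            ir = 0.0896, g_leak = 0,
                            drug_blocks = list()) {
  stopifnot(s_K1 >= 0, s_NaK >= 0, s_Nab >= 0, s_Na >= 0,
            ir >= 0, g_leak >= 0)
  if (length(drug_blocks)) {
    if (is.null(names(drug_blocks)) ||
        !all(names(drug_blocks) %in% .block_channels))
      stop("drug_blocks must be named with channels among: ",
           paste(.block_channels, collapse = ", "))
    if (any(unlist(drug_blocks) < 0 | unlist(drug_blocks) > 1))
      stop("block fractions must lie in [0, 1]")
  }
  structure(list(s_K1 = s_K1, s_NaK = s_NaK, s_Nab = s_Nab, s_Na = s_Na,
                 ir = ir, g_leak = g_leak, drug_blocks = drug_blocks),
            class = "model_modifiers")
}

#' @export
print.model_modifiers <- function(x, ...) {
  cat("Cardiomyocyte model modifiers\n")
  cat(sprintf("  s_K1 = %g, s_NaK = %g, s_Nab = %g, s_Na = %g\n",
              x$s_K1, x$s_NaK, x$s_Nab, x$s_Na))
  cat(sprintf("  ir = %g /mV, g_leak = %g\n", x$ir, x$g_leak))
  if (length(x$drug_blocks))
    cat("  blocks:",
        paste(sprintf("%s %.1f%%", names(x$drug_blocks),
                      100 * unlist(x$drug_blocks)), collapse = ", "), "\n")
  invisible(x)
}

# modifiers -> compiled-parameter vector (irradiance filled per segment)
mods_to_parms <- function(mods, chr2) {
  blk <- function(ch) 1 - (mods$drug_blocks[[ch]] %||% 0)
  c(mods$s_K1, mods$s_NaK, mods$s_Nab, mods$s_Na, mods$ir, mods$g_leak,
    blk("INa"), blk("ICaL"), blk("IKr"), blk("IKs"), blk("IK1"),
    blk("Ito"), blk("IKur"), blk("IKss"),
    chr2$g_chr2, chr2$gamma, 0)
}

#' Inward-rectifier potassium current I_K1
#'
#' Direct evaluation of the model's I_K1 with a parameterized
#' rectification exponent:
#' `s_K1 * 0.2938 * ko / (ko + 210) * (v - e_k) / (1 + exp(ir * (v - e_k)))`.
#' Outward current is positive. `ko` and the binding constant 210 must be
#' in the same units; the cell model evaluates it in uM (`ko = 5400`).
#'
#' @param v membrane potential (mV).
#' @param ko extracellular K+ concentration.
#' @param e_k K+ reversal potential (mV).
#' @param ir rectification exponent (1/mV).
#' @param s_K1 scale factor.
#' @return current density (pA/pF).
#' @export
i_k1 <- function(v, ko = 5400, e_k, ir = 0.0896, s_K1 = 1) {
  stopifnot(ko > 0)
  x <- v - e_k
  s_K1 * 0.2938 * (ko / (ko + 210.0)) * x / (1 + exp(ir * x))
}

#' Cation background leak current
#'
#' `g_leak * ((v - e_na) - 0.5 * (v - e_k))`: a nonselective cation leak
#' with a K+ conductance of 0.5 relative to the Na+ conductance, used to
#' depolarize the resting membrane potential like a constant ChR2-like
#' current.
#'
#' @param v membrane potential (mV).
#' @param g_leak conductance scale (pA/pF per mV).
#' @param e_na,e_k Na+ and K+ reversal potentials (mV).
#' @return current density (pA/pF).
#' @export
i_leak <- function(v, g_leak, e_na, e_k) {
  g_leak * ((v - e_na) - 0.5 * (v - e_k))
}

#' Fractional conductance remaining under drug block
#'
#' Hill-type block: `1 / (1 + (concentration / ic50)^hill)`, the
#' multiplicative conductance scale remaining at the given drug
#' concentration.
#'
#' @param concentration drug concentration (same units as `ic50`), >= 0.
#' @param ic50 half-maximal inhibitory concentration, > 0.
#' @param hill Hill coefficient, > 0.
#' @return fraction in (0, 1].
#' @export
block_factor <- function(concentration, ic50, hill) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  stopifnot(all(ic50 > 0), all(hill > 0))
  1 / (1 + (concentration / ic50)^hill)
}

#' Multichannel drug profiles
#'
#' A drug profile maps channels to (IC50, Hill coefficient) pairs. The
#' bundled defaults describe the qualitative multichannel signatures of
#' amiodarone (Na+ channel block accompanied by substantial K+ current
#' block including I_K1), dronedarone (Na+ channel block with strong
#' I_Kr block but little effect on I_K1) and lidocaine (pure fractional
#' I_Na block); they are configuration data, not measurements, and can be
#' replaced via the `channels` argument or a JSON config file.
#'
#' @param name drug name; `"amiodarone"`, `"dronedarone"` and
#'   `"lidocaine"` select bundled channel tables.
#' @param concentration drug concentration (uM).
#' @param channels optional data.frame with columns `channel`, `ic50_uM`,
#'   `hill`, overriding the bundled table.
#' @return an object of class `drug_profile`.
#' @export
drug_profile <- function(name, concentration = 0, channels = NULL) {
  if (is.null(channels)) {
    channels <- switch(
      name,
      amiodarone = data.frame(
        channel = c("INa", "ICaL", "IKr", "IKs", "IK1", "Ito"),
        ic50_uM = c(10, 5.8, 2.8, 20, 30, 8),
        hill = c(1, 1, 1, 1, 1, 1)),
      dronedarone = data.frame(
        channel = c("INa", "ICaL", "IKr", "IKs", "IK1"),
        ic50_uM = c(3, 1.8, 0.1, 10, 120),
        hill = c(1, 1, 1, 1, 1)),
      lidocaine = data.frame(
        channel = "INa", ic50_uM = 40, hill = 1),
      stop("no bundled channel table for drug '", name,
           "'; supply `channels`"))
  }
  stopifnot(all(c("channel", "ic50_uM", "hill") %in% names(channels)),
            all(channels$ic50_uM > 0), all(channels$hill > 0),
            concentration >= 0)
  channels <- channels[channels$channel %in% .block_channels, ,
                       drop = FALSE]
  structure(list(name = name, concentration = concentration,
                 channels = channels),
            class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat(sprintf("Drug profile: %s at %g uM\n", x$name, x$concentration))
  print(x$channels, row.names = FALSE)
  invisible(x)
}

#' Read a drug profile from a JSON configuration file
#' @param path file path to a JSON object with fields `name`,
#'   `concentration` and `channels` (array of channel/ic50_uM/hill).
#' @return a [drug_profile()].
#' @export
read_drug_profile <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  drug_profile(cfg$name, concentration = cfg$concentration %||% 0,
               channels = as.data.frame(cfg$channels))
}

#' Apply a drug profile to model modifiers
#'
#' Converts the profile's per-channel Hill block at its concentration into
#' fractional blocks on the modifier set (only channels present in the
#' murine model are affected).
#'
#' @param modifiers a [model_modifiers()] object.
#' @param profile a [drug_profile()].
#' @return modified `model_modifiers`.
#' @export
apply_drug <- function(modifiers, profile) {
  stopifnot(inherits(modifiers, "model_modifiers"),
            inherits(profile, "drug_profile"))
  blocks <- modifiers$drug_blocks
  for (i in seq_len(nrow(profile$channels))) {
    ch <- profile$channels$channel[i]
    keep <- block_factor(profile$concentration,
                         profile$channels$ic50_uM[i],
                         profile$channels$hill[i])
    prev <- blocks[[ch]] %||% 0
    blocks[[ch]] <- 1 - (1 - prev) * keep
  }
  modifiers$drug_blocks <- blocks
  modifiers
}

#' Resting-state initial conditions of the cardiomyocyte model
#'
#' The source model's quiescent resting state (apex parameter set), with
#' the ChR2 photocycle dark-adapted.
#'
#' @return named numeric vector of all 43 state variables.
#' @export
myocyte_initial_state <- function() {
  c(v = -82.4202,
    cai = 0.115001, cass = 0.115001, cajsr = 1299.5, cansr = 1299.5,
    ltrpn = 11.2684, htrpn = 125.29,
    po1 = 1.49102e-5, po2 = 9.51726e-11, pc2 = 1.6774e-4,
    o_l = 9.30308e-19, c2_l = 1.24216e-4, c3_l = 5.78679e-9,
    c4_l = 1.19816e-13, i1_l = 4.97923e-19, i2_l = 3.45847e-14,
    i3_l = 1.85106e-14,
    pryr = 0,
    nai = 14237.1, ki = 143720.0,
    cna2 = 0.020752, cna1 = 2.79132e-4, ona = 7.13483e-7,
    ifna = 1.53176e-4, i1na = 6.73345e-7, i2na = 1.55787e-9,
    icna2 = 0.0113879, icna3 = 0.34278,
    atof = 2.65563e-3, itof = 0.999977,
    nks = 2.62753e-4,
    aur = 4.17069e-4, iur = 0.998543,
    akss = 4.17069e-4, ikss = 1.0,
    ck1 = 9.92513e-4, ck2 = 6.41229e-4, ok = 1.75298e-4, ik = 3.19129e-5,
    o1c = 0, o2c = 0, c2c = 0, pc = 0)
}

# per-state absolute tolerances for the stiff solver
myocyte_atol <- function() {
  y <- myocyte_initial_state()
  atol <- rep(1e-10, length(y))
  names(atol) <- names(y)
  atol[c("v")] <- 1e-6
  atol[c("cai", "cass")] <- 1e-9
  atol[c("cajsr", "cansr", "nai", "ki")] <- 1e-3
  atol[c("ltrpn", "htrpn")] <- 1e-6
  atol
}

# integrate the coupled model over constant-irradiance segments.
# segments: data.frame(t0, t1, irr) in ms. Returns list(trace, y).
run_segments <- function(y0, segments, parms, dt_out = 0.1,
                         record = TRUE) {
  y <- y0
  atol <- myocyte_atol()
  ts <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    t0 <- segments$t0[i]; t1 <- segments$t1[i]
    if (t1 <= t0 + 1e-12) next
    parms[17L] <- segments$irr[i]
    times <- if (record) {
      grid <- seq(ceiling((t0 - 1e-9) / dt_out) * dt_out, t1 + 1e-9,
                  by = dt_out)
      grid <- grid[grid >= t0 - 1e-9 & grid <= t1 + 1e-9]
      sort(unique(c(t0, grid, t1)))
    } else c(t0, t1)
    sol <- deSolve::lsoda(y = y, times = times, func = "cell_derivs",
                          parms = parms, dllname = "optoclamp",
                          initfunc = "cell_init", nout = 2,
                          outnames = c("i_chr2", "i_k1"),
                          rtol = 1e-6, atol = unname(atol),
                          maxsteps = 200000)
    if (attr(sol, "istate")[1L] < 0)
      stop("simulation failure: stiff solver did not converge in segment [",
           t0, ", ", t1, "] ms")
    y <- as.numeric(sol[nrow(sol), 1L + seq_along(y)])
    names(y) <- names(y0)
    if (any(!is.finite(y)))
      stop("simulation failure: non-finite state at t = ", t1, " ms")
    if (record) {
      on_grid <- abs(sol[, "time"] / dt_out -
                       round(sol[, "time"] / dt_out)) < 1e-6
      keep <- sol[on_grid, c("time", "v", "i_chr2", "i_k1"), drop = FALSE]
      ts[[i]] <- keep
    }
  }
  trace <- NULL
  if (record) {
    trace <- do.call(rbind, ts)
    trace <- trace[!duplicated(round(trace[, "time"] / dt_out)), ,
                   drop = FALSE]
  }
  list(trace = trace, y = y)
}

# build the absolute-time pulse table for n cycles of a protocol,
# optionally appending extra pulses (absolute start times)
protocol_pulse_table <- function(protocol, n_cycles,
                                 roles = c("pace", "sub"),
                                 extra = NULL, t_offset = 0) {
  p <- protocol$pulses[protocol$pulses$role %in% roles, , drop = FALSE]
  cl <- protocol$cycle_length_ms
  tab <- NULL
  if (nrow(p) && n_cycles > 0) {
    tab <- do.call(rbind, lapply(seq_len(n_cycles) - 1L, function(k) {
      q <- p
      q$start_ms <- q$start_ms + k * cl + t_offset
      q
    }))
  }
  rbind(tab, extra)
}

# absolute pulse table -> constant-irradiance segments over [t0, t1]
pulses_to_segments <- function(pulses, t0, t1) {
  if (is.null(pulses) || nrow(pulses) == 0)
    return(data.frame(t0 = t0, t1 = t1, irr = 0))
  edges <- sort(unique(c(t0, t1,
                         pulses$start_ms,
                         pulses$start_ms + pulses$duration_ms)))
  edges <- edges[edges >= t0 - 1e-9 & edges <= t1 + 1e-9]
  seg <- data.frame(t0 = edges[-length(edges)], t1 = edges[-1L])
  seg$irr <- vapply(seq_len(nrow(seg)), function(i) {
    mid <- (seg$t0[i] + seg$t1[i]) / 2
    on <- pulses$start_ms <= mid &
      mid < pulses$start_ms + pulses$duration_ms
    if (any(on)) sum(pulses$irradiance_uW_mm2[on]) else 0
  }, numeric(1))
  seg
}

#' Simulate the coupled cardiomyocyte / ChR2 model
#'
#' Integrates the murine ventricular cardiomyocyte model with the coupled
#' ChR2 photocurrent under a light protocol, using an adaptive stiff
#' solver (relative tolerance 1e-6, per-state absolute tolerances),
#' resampled to a 10-kHz output grid.
#'
#' @param modifiers a [model_modifiers()] object.
#' @param protocol a [light_protocol()]; `n_cycles` cycles are simulated,
#'   all pulses applied every cycle unless their role is `"sub"`, which is
#'   applied only in the final cycle.
#' @param chr2 a [chr2_params()] object (normally calibrated).
#' @param init optional initial state (default [myocyte_initial_state()]).
#' @param dt_out output sampling interval (ms), default 0.1 (10 kHz).
#' @param record if `FALSE`, only the final state is returned.
#' @return an object of class `opto_recording`: a list with `time_ms`,
#'   `v_mV`, `i_chr2_pApF`, the pulse annotation table, metadata, and the
#'   final model state in `state`.
#' @export
simulate_myocyte <- function(modifiers = model_modifiers(),
                             protocol,
                             chr2 = chr2_params(),
                             init = NULL, dt_out = 0.1, record = TRUE) {
  stopifnot(inherits(modifiers, "model_modifiers"),
            inherits(protocol, "light_protocol"))
  if (is.null(init)) init <- myocyte_initial_state()
  n <- protocol$n_cycles
  cl <- protocol$cycle_length_ms
  pace <- protocol_pulse_table(protocol, n, roles = "pace")
  sub <- protocol$pulses[protocol$pulses$role == "sub", , drop = FALSE]
  if (nrow(sub)) {
    sub$start_ms <- sub$start_ms + (n - 1L) * cl
    pace <- rbind(pace, sub)
  }
  seg <- pulses_to_segments(pace, 0, n * cl)
  parms <- mods_to_parms(modifiers, chr2)
  res <- run_segments(init, seg, parms, dt_out = dt_out, record = record)
  new_opto_recording(res, pulses = pace, cycle_length_ms = cl,
                     modifiers = modifiers)
}

new_opto_recording <- function(res, pulses, cycle_length_ms, modifiers,
                               metadata = list()) {
  rec <- list(
    time_ms = if (!is.null(res$trace)) res$trace[, "time"] else numeric(0),
    v_mV = if (!is.null(res$trace)) res$trace[, "v"] else numeric(0),
    i_chr2_pApF = if (!is.null(res$trace)) res$trace[, "i_chr2"]
                  else numeric(0),
    pulses = pulses,
    cycle_length_ms = cycle_length_ms,
    modifiers = modifiers,
    metadata = metadata,
    state = res$y)
  class(rec) <- "opto_recording"
  rec
}

#' @export
print.opto_recording <- function(x, ...) {
  cat(sprintf("Membrane-potential recording: %d samples (%.1f ms at %g kHz), %d pulse(s)\n",
              length(x$time_ms),
              if (length(x$time_ms)) diff(range(x$time_ms)) else 0,
              if (length(x$time_ms) > 1)
                1 / diff(x$time_ms[1:2]) else NA_real_,
              if (!is.null(x$pulses)) nrow(x$pulses) else 0L))
  if (length(x$v_mV))
    cat(sprintf("  V range: [%.1f, %.1f] mV\n", min(x$v_mV), max(x$v_mV)))
  invisible(x)
}

#' @export
plot.opto_recording <- function(x, ...) {
  graphics::plot(x$time_ms, x$v_mV, type = "l", xlab = "time (ms)",
                 ylab = "membrane potential (mV)", ...)
  if (!is.null(x$pulses) && nrow(x$pulses)) {
    usr <- graphics::par("usr")
    graphics::rect(x$pulses$start_ms, usr[4] - 0.03 * (usr[4] - usr[3]),
                   x$pulses$start_ms + x$pulses$duration_ms, usr[4],
                   col = "#3c8dff80", border = NA)
  }
  invisible(x)
}

#' Stability check for paced recordings
#'
#' A paced recording is stable if the pre-stimulus diastolic potential of
#' consecutive cycles agrees within `tolerance` for every consecutive
#' pair, and no spontaneous action potentials occur between pacing pulses
#' (the cell returns to rest after each AP).
#'
#' @param recording an `opto_recording` holding at least two paced cycles.
#' @param tolerance allowed diastolic drift per consecutive cycle pair
#'   (mV), default 1.
#' @param ap_threshold potential (mV) above which a deflection counts as
#'   an AP, default 0.
#' @param from_ms ignore pulses starting before this time (used to skip
#'   the settling transient at the start of a run).
#' @return logical flag.
#' @export
is_stable <- function(recording, tolerance = 1, ap_threshold = 0,
                      from_ms = -Inf) {
  stopifnot(inherits(recording, "opto_recording"))
  pace <- recording$pulses[recording$pulses$role %in% "pace", ,
                           drop = FALSE]
  starts <- sort(pace$start_ms)
  starts <- starts[starts >= from_ms]
  if (length(starts) < 2L) stop("recording must hold >= 2 paced cycles")
  all_starts <- sort(pace$start_ms)
  sel <- recording$time_ms >= from_ms
  t <- recording$time_ms[sel]; v <- recording$v_mV[sel]
  # pre-stimulus diastolic potential: mean over the 5 ms before each pulse
  dia <- vapply(starts, function(s) {
    w <- t >= s - 5 & t < s
    if (!any(w)) NA_real_ else mean(v[w])
  }, numeric(1))
  dia <- dia[is.finite(dia)]
  if (length(dia) >= 2L && any(abs(diff(dia)) > tolerance)) return(FALSE)
  # spontaneous APs: V crossing threshold upward outside pulse-evoked
  # windows (50 ms after each pacing pulse onset)
  above <- v > ap_threshold
  up <- which(diff(as.integer(above)) == 1L)
  if (length(up)) {
    tup <- t[up + 1L]
    evoked <- vapply(tup, function(tt)
      any(tt >= all_starts & tt <= all_starts + 50), logical(1))
    if (any(!evoked)) return(FALSE)
  }
  TRUE
}
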