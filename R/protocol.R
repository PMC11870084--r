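# Light-stimulation protocols: square pulses within a repeating pacing
# cycle, plus a pre-pacing duration used to reach steady state.

#' Define a light-stimulation protocol
#'
#' A protocol is a set of square light pulses within one pacing cycle,
#' repeated for `n_cycles` cycles, optionally preceded by pre-pacing.
#' Pulses carry a `role`: `"pace"` pulses are applied in every cycle
#' (including pre-pacing), `"sub"` (subthreshold probe) pulses only in the
#' cycle of interest.
#'
#' @param pulses data.frame with columns `start_ms`, `duration_ms`,
#'   `irradiance_uW_mm2` and optionally `role` (default `"pace"`). Starts
#'   are relative to cycle onset; pulses must not overlap within a cycle.
#' @param cycle_length_ms pacing cycle length (ms), default 275.
#' @param n_cycles number of cycles simulated.
#' @param prepace_s pre-pacing duration in seconds (default 15 for
#'   trace-driven photocurrent computation).
#' @return an object of class `light_protocol`.
#' @export
light_protocol <- function(pulses, cycle_length_ms = 275, n_cycles = 1,
                           prepace_s = 15) {
  stopifnot(is.data.frame(pulses),
            all(c("start_ms", "duration_ms", "irradiance_uW_mm2") %in%
                  names(pulses)))
  if (is.null(pulses$role)) pulses$role <- "pace"
  if (!(cycle_length_ms > 0)) stop("cycle_length_ms must be > 0")
  if (any(pulses$irradiance_uW_mm2 < 0)) stop("irradiance must be >= 0")
  if (any(pulses$start_ms < 0 |
          pulses$start_ms + pulses$duration_ms > cycle_length_ms))
    stop("pulses must lie within the cycle")
  o <- order(pulses$start_ms)
  pulses <- pulses[o, , drop = FALSE]
  if (nrow(pulses) > 1L) {
    ends <- pulses$start_ms + pulses$duration_ms
    if (any(pulses$start_ms[-1L] < ends[-nrow(pulses)]))
      stop("pulses must not overlap within a cycle")
  }
  structure(list(pulses = pulses, cycle_length_ms = cycle_length_ms,
                 n_cycles = n_cycles, prepace_s = prepace_s),
            class = "light_protocol")
}

#' @export
print.light_protocol <- function(x, ...) {
  cat(sprintf("Light protocol: %d pulse(s)/cycle, cycle length %g ms, %d cycle(s), %g s pre-pacing\n",
              nrow(x$pulses), x$cycle_length_ms, x$n_cycles, x$prepace_s))
  print(x$pulses, row.names = FALSE)
  invisible(x)
}

#' Read / write a light protocol as a JSON configuration file
#'
#' @param path file path.
#' @param protocol a [light_protocol()].
#' @return `read_light_protocol` returns a `light_protocol`;
#'   `write_light_protocol` returns `path` invisibly.
#' @export
read_light_protocol <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  light_protocol(as.data.frame(cfg$pulses),
                 cycle_length_ms = cfg$cycle_length_ms,
                 n_cycles = cfg$n_cycles %||% 1,
                 prepace_s = cfg$prepace_s %||% 15)
}

#' @rdname read_light_protocol
#' @export
write_light_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
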