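# Plain-text container for membrane-potential recordings: '#'-prefixed
# header lines carrying JSON metadata and pulse annotations, followed by
# two tab-separated columns (time_ms, v_mV).

#' Write / read a recording as delimited text
#'
#' The container is a tab-separated two-column table (`time_ms`, `v_mV`)
#' preceded by comment lines holding the cycle length, the pulse
#' annotation table and the metadata as JSON.
#'
#' @param recording an [opto_recording()].
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `opto_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "opto_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# optoclamp recording v1", con)
  writeLines(sprintf("# cycle_length_ms: %s",
                     jsonlite::toJSON(recording$cycle_length_ms,
                                      auto_unbox = TRUE, digits = NA,
                                      na = "null")), con)
  pulses <- recording$pulses
  writeLines(sprintf("# pulses: %s",
                     if (is.null(pulses)) "null"
                     else jsonlite::toJSON(pulses, digits = NA)), con)
  writeLines(sprintf("# metadata: %s",
                     jsonlite::toJSON(recording$metadata,
                                      auto_unbox = TRUE, digits = NA)),
             con)
  writeLines("time_ms\tv_mV", con)
  utils::write.table(
    data.frame(time_ms = recording$time_ms, v_mV = recording$v_mV),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    ln <- grep(paste0("^# ", name, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    jsonlite::fromJSON(sub(paste0("^# ", name, ": "), "", ln[1L]))
  }
  cl <- get_field("cycle_length_ms")
  pulses <- get_field("pulses")
  metadata <- get_field("metadata")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  opto_recording(tab$time_ms, tab$v_mV,
                 pulses = if (is.null(pulses) ||
                              (is.logical(pulses) && is.na(pulses)))
                   NULL else as.data.frame(pulses),
                 cycle_length_ms = if (is.null(cl)) NA_real_ else cl,
                 metadata = if (is.null(metadata)) list()
                            else as.list(metadata))
}
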