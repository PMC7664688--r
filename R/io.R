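#' Write / read a recording as plain text plus JSON sidecar
#'
#' The signal matrix is written as whitespace-separated numbers (one row per
#' channel, `%.10g`) and a JSON sidecar carries channel names, sampling
#' rate, stage and labels — a text-only interchange layout for the
#' generator's output.
#'
#' @param rec an `eeg_recording`. @param path base path; writes
#'   `<path>.txt` and `<path>.json`.
#' @return base path invisibly (`write_recording`); the rebuilt
#'   `eeg_recording` (`read_recording`).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(format(rec$signal, digits = 10, scientific = TRUE,
                            trim = TRUE),
                     paste0(path, ".txt"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(channels = rec$channels, fs = rec$fs, subject = rec$subject,
         question = rec$question, scenario_type = rec$scenario_type,
         answer = rec$answer, stage = rec$stage,
         interpolated = rec$interpolated),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sig <- as.matrix(utils::read.table(paste0(path, ".txt")))
  dimnames(sig) <- list(meta$channels, NULL)
  rec <- raw_recording(sig, meta$fs, meta$channels, meta$subject,
                       meta$question, meta$scenario_type, meta$answer)
  rec$stage <- meta$stage
  rec$interpolated <- meta$interpolated %||% character(0)
  rec
}
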