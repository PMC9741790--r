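#' Write a recording to CSV (with optional JSON side-car)
#'
#' Writes one row per sample with header `time,copap,copml,vgrf` (seconds,
#' mm, mm, N). When `sidecar = TRUE`, a JSON file next to the CSV stores the
#' sampling rate and, for synthetic recordings, the ground-truth stride
#' onsets.
#'
#' @param recording A `gait_recording`.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` with metadata? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, sidecar = TRUE) {
  stopifnot(inherits(recording, "gait_recording"))
  n <- recording_length(recording)
  df <- data.frame(
    time = (seq_len(n) - 1) / recording$sampling_rate,
    copap = recording$copap,
    copml = recording$copml,
    vgrf = recording$vgrf
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    meta <- list(sampling_rate = recording$sampling_rate)
    if (!is.null(recording$true_boundaries)) {
      meta$true_boundaries <- recording$true_boundaries
    }
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a recording from CSV
#'
#' Reads a `time,copap,copml,vgrf` CSV written by [write_recording()] (or by
#' any acquisition export following that layout). The sampling rate is taken
#' from the JSON side-car when present, otherwise inferred from the median
#' time step.
#'
#' @param path CSV path.
#' @return A `gait_recording`.
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  required <- c("time", "copap", "copml", "vgrf")
  if (!all(required %in% names(df))) {
    stop("recording CSV must have columns time, copap, copml, vgrf",
         call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  tb <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    rate <- meta$sampling_rate
    if (!is.null(meta$true_boundaries)) tb <- as.integer(meta$true_boundaries)
  } else {
    rate <- 1 / median(diff(df$time))
  }
  new_gait_recording(rate, df$copap, df$copml, df$vgrf, tb)
}
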