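#' Write / read a recording as CSV plus JSON sidecar
#'
#' The time series go to a CSV with columns `time_s`, `test_arm`,
#' `control_arm`; metadata (sampling rate, units, polarity, timeline and,
#' for synthetic sessions, the ground truth) go to a JSON sidecar next to
#' it. Values are written with 17 significant digits so the round trip is
#' exact for double precision.
#'
#' @param recording a `ppg_recording`.
#' @param csv_path path of the CSV file; the sidecar is written to the same
#'   path with extension `.json` unless `json_path` is given.
#' @param json_path optional sidecar path.
#' @return `write_recording` invisibly returns `csv_path`; `read_recording`
#'   returns the reconstructed `ppg_recording`.
#' @export
write_recording <- function(recording, csv_path, json_path = NULL) {
  stopifnot(inherits(recording, "ppg_recording"))
  if (is.null(json_path)) json_path <- sidecar_path(csv_path)
  sig <- recording$signals
  out <- data.frame(lapply(sig, function(col) sprintf("%.17g", col)))
  names(out) <- names(sig)
  data.table::fwrite(out, csv_path, quote = FALSE)
  meta <- list(
    sampling_rate = recording$sampling_rate,
    units = recording$units,
    polarity = recording$polarity,
    timeline = timeline_to_list(recording$timeline),
    ground_truth = recording$ground_truth
  )
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(csv_path)
}

#' @rdname write_recording
#' @export
read_recording <- function(csv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sidecar_path(csv_path)
  sig <- data.table::fread(csv_path, colClasses = "numeric", data.table = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(
    sampling_rate = meta$sampling_rate,
    signals = sig,
    units = meta$units,
    polarity = meta$polarity,
    timeline = timeline_from_list(meta$timeline),
    ground_truth = meta$ground_truth
  ), class = "ppg_recording")
}

sidecar_path <- function(csv_path) {
  sub("\\.csv$", ".json", csv_path, ignore.case = TRUE)
}
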