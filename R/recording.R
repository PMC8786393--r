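#' Channel recording container
#'
#' Multi-channel optical time series with its measurement list, sampling rate,
#' stimulus paradigm, and good-measurement mask. Data are stored time x
#' measurement; the unit tag tracks whether columns are raw intensities or
#' optical density.
#'
#' @param data Numeric time x measurement matrix.
#' @param fs Sampling rate, Hz.
#' @param measurements A [measurement_list()] with one row per data column.
#' @param paradigm Data frame with columns `onset_s` and `condition` (may have
#'   zero rows).
#' @param unit `"intensity"` or `"od"`.
#' @param good_meas Logical mask over measurements.
#' @export
channel_recording <- function(data, fs, measurements,
                              paradigm = data.frame(onset_s = numeric(0),
                                                    condition = character(0)),
                              unit = c("intensity", "od"),
                              good_meas = rep(TRUE, ncol(data))) {
  unit <- match.arg(unit)
  data <- as.matrix(data)
  stopifnot(fs > 0, ncol(data) == nrow(measurements),
            length(good_meas) == ncol(data),
            all(c("onset_s", "condition") %in% names(paradigm)))
  dur <- nrow(data) / fs
  if (nrow(paradigm) && (any(paradigm$onset_s < 0) || any(paradigm$onset_s >= dur)))
    stop_fnirsdot("trigger times must fall within the recording", "paradigm_invalid")
  structure(list(data = data, fs = fs, measurements = measurements,
                 paradigm = paradigm, unit = unit,
                 good_meas = as.logical(good_meas)),
            class = "channel_recording")
}

#' @export
print.channel_recording <- function(x, ...) {
  cat(sprintf("<channel_recording> %d frames x %d measurements @ %g Hz (%s), %d good, %d trigger(s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$unit, sum(x$good_meas),
              nrow(x$paradigm)))
  invisible(x)
}

#' Write / read a channel recording in the CSV dialect
#'
#' The on-disk form is a set of plain-text files sharing a stem:
#' `<stem>_data.csv` (one column per measurement, one row per frame),
#' `<stem>_measurements.csv` (the measurement list), `<stem>_paradigm.csv`
#' (trigger onsets and condition labels) and `<stem>_meta.json` (fs, unit,
#' good-measurement mask).
#'
#' @param rec A [channel_recording()].
#' @param stem Path stem (no extension).
#' @return `write_channel_csv` the stem, invisibly; `read_channel_csv` a
#'   recording.
#' @export
write_channel_csv <- function(rec, stem) {
  stopifnot(inherits(rec, "channel_recording"))
  utils::write.csv(rec$data, paste0(stem, "_data.csv"), row.names = FALSE)
  utils::write.csv(rec$measurements, paste0(stem, "_measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$paradigm, paste0(stem, "_paradigm.csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, unit = rec$unit,
                            good_meas = rec$good_meas),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_channel_csv
#' @export
read_channel_csv <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.csv(paste0(stem, "_data.csv")))
  meas <- utils::read.csv(paste0(stem, "_measurements.csv"))
  par <- utils::read.csv(paste0(stem, "_paradigm.csv"),
                         colClasses = c(onset_s = "numeric", condition = "character"))
  channel_recording(data, meta$fs, meas, par, unit = meta$unit,
                    good_meas = meta$good_meas)
}
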