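#' Multi-channel sEMG recording with synchronized force
#'
#' Lightweight container for one trial: named sEMG channels in mV, a force
#' trace in N on the same sampling grid, the sampling rate, and free-form
#' metadata (subject/trial/phase labels).
#'
#' @param fs Sampling rate, Hz.
#' @param channels Named list of equal-length numeric sEMG series (mV).
#' @param force Numeric force series (N), same length as the channels.
#' @param meta List of labels (trial id, seed, phase, ...).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(fs, channels, force, meta = list()) {
  stopifnot(fs > 0, is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  lens <- vapply(channels, length, integer(1))
  if (length(unique(c(lens, length(force)))) != 1)
    stop("all channels and the force series must have equal length")
  structure(list(fs = fs, channels = channels, force = as.numeric(force),
                 meta = meta),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  n <- length(x$force)
  cat(sprintf("<emg_recording> %d samples @ %g Hz (%.2f s), channels: %s\n",
              n, x$fs, n / x$fs, paste(names(x$channels), collapse = ", ")))
  if (length(x$meta)) {
    keys <- vapply(x$meta, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  meta:", paste(names(x$meta), keys, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Read / write one trial as columnar text
#'
#' Trials are stored as plain CSV with columns
#' `time_s, biceps_mv, triceps_mv, force_n`.
#'
#' @param recording An [emg_recording()] with `biceps` and `triceps` channels.
#' @param path CSV file path.
#' @return `write_trial_csv()` returns `path` invisibly; `read_trial_csv()`
#'   returns an [emg_recording()].
#' @export
write_trial_csv <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  n <- length(recording$force)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$fs,
                   biceps_mv = recording$channels$biceps,
                   triceps_mv = recording$channels$triceps,
                   force_n = recording$force)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @param fs Sampling rate override; by default inferred from the time column.
#' @param meta Metadata attached to the recording.
#' @export
read_trial_csv <- function(path, fs = NULL, meta = list(file = path)) {
  df <- utils::read.csv(path)
  need <- c("time_s", "biceps_mv", "triceps_mv", "force_n")
  if (!all(need %in% names(df)))
    stop("trial CSV must have columns ", paste(need, collapse = ", "))
  if (is.null(fs)) {
    dt <- stats::median(diff(df$time_s))
    fs <- round(1 / dt)
  }
  emg_recording(fs = fs,
                channels = list(biceps = df$biceps_mv, triceps = df$triceps_mv),
                force = df$force_n, meta = meta)
}
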