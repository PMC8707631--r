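#' Sliding-window specification
#'
#' Real-time feature extraction uses a 0.2 s window; the step (update
#' interval) defaults to 0.1 s, i.e. half-overlapping windows. Window
#' timestamps follow the window-end convention (a causal estimator can only
#' report once the window has filled).
#'
#' @param win_s Window length, s.
#' @param step_s Step between successive windows, s.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(win_s = 0.2, step_s = 0.1) {
  stopifnot(win_s > 0, step_s > 0, step_s <= win_s)
  structure(list(win_s = win_s, step_s = step_s, alignment = "window-end"),
            class = "window_spec")
}

#' Cut a signal into sliding windows
#'
#' Windows of exactly `win_s * fs` samples advancing by `step_s * fs`; a final
#' partial window is discarded. The number of windows is
#' `floor((n - win) / step) + 1`.
#'
#' @param signal Numeric series.
#' @param fs Sampling rate, Hz.
#' @param spec A [window_spec()].
#' @return List with `windows` (matrix, one row per window) and `t` (window
#'   end times, s).
#' @export
sliding_windows <- function(signal, fs, spec = window_spec()) {
  win <- as.integer(round(spec$win_s * fs))
  step <- as.integer(round(spec$step_s * fs))
  if (win < 2) stop("window must span at least 2 samples")
  n <- length(signal)
  if (n < win) stop("signal shorter than one window")
  starts <- seq.int(1L, n - win + 1L, by = step)
  mat <- t(vapply(starts, function(s) signal[s:(s + win - 1L)], numeric(win)))
  list(windows = mat, t = (starts + win - 1L) / fs)
}

#' Time-domain window features: MAV, RMS, DASDV, WL
#'
#' The four per-window statistics forming the estimator's input vector:
#' * `mav(x)` -- mean absolute value, \eqn{\frac1n \sum |x_i|};
#' * `rms(x)` -- root mean square, \eqn{\sqrt{\frac1n \sum x_i^2}};
#' * `dasdv(x)` -- difference absolute standard deviation value,
#'   \eqn{\sqrt{\frac{1}{n-1}\sum (x_{i+1}-x_i)^2}};
#' * `wl(x)` -- waveform length, \eqn{\sum |x_{i+1}-x_i|}.
#'
#' All four are nonnegative; `mav(x) <= rms(x)` and
#' `wl(x) <= (n-1) * dasdv(x)` by Cauchy--Schwarz.
#'
#' @param window Numeric vector of samples (one window).
#' @return Scalar feature value.
#' @export
mav <- function(window) {
  if (length(window) < 1) stop("empty window")
  mean(abs(window))
}

#' @rdname mav
#' @export
rms <- function(window) {
  if (length(window) < 1) stop("empty window")
  sqrt(mean(window^2))
}

#' @rdname mav
#' @export
dasdv <- function(window) {
  n <- length(window)
  if (n < 2) stop("dasdv needs at least 2 samples")
  sqrt(sum(diff(window)^2) / (n - 1))
}

#' @rdname mav
#' @export
wl <- function(window) {
  if (length(window) < 2) stop("wl needs at least 2 samples")
  sum(abs(diff(window)))
}

feature_names <- function() {
  as.vector(t(outer(c("b", "t"), c("mav", "rms", "dasdv", "wl"), paste,
                    sep = "_")))
}

window_features <- function(mat) {
  cbind(mav = rowMeans(abs(mat)),
        rms = sqrt(rowMeans(mat^2)),
        dasdv = apply(mat, 1, dasdv),
        wl = apply(mat, 1, wl))
}

#' Assemble the 8-dimensional multi-feature matrix with force labels
#'
#' For every 0.2 s window the four time-domain features are computed on each
#' channel and stacked in the frozen ordering
#' `biceps[MAV, RMS, DASDV, WL], triceps[MAV, RMS, DASDV, WL]` -- the eight
#' inputs of the force estimator. The per-window force label is the mean force
#' over the window. By default features are computed on the MVC-scaled,
#' band-passed signal (`processed$scaled`); set `signal = "normalized"` to use
#' the rectified clamped envelope instead.
#'
#' @param processed A [preprocess_chain()] result with `biceps` and `triceps`.
#' @param force Force series synchronized with the signals; defaults to the
#'   one carried in `processed`.
#' @param spec A [window_spec()].
#' @param signal Which conditioned view feeds the features.
#' @return An object of class `feature_series`: `t` (window end times), `X`
#'   (n x 8 feature matrix), `y` (force labels, N), `trial` (label).
#' @export
feature_matrix <- function(processed, force = processed$force,
                           spec = window_spec(),
                           signal = c("scaled", "normalized")) {
  stopifnot(inherits(processed, "processed_emg"))
  signal <- match.arg(signal)
  src <- processed[[signal]]
  for (ch in c("biceps", "triceps"))
    if (is.null(src[[ch]])) stop("missing channel: ", ch)
  if (length(force) != length(src$biceps))
    stop("force series not synchronized with the sEMG channels")
  wb <- sliding_windows(src$biceps, processed$fs, spec)
  wt <- sliding_windows(src$triceps, processed$fs, spec)
  wf <- sliding_windows(force, processed$fs, spec)
  X <- cbind(window_features(wb$windows), window_features(wt$windows))
  colnames(X) <- feature_names()
  structure(list(t = wb$t, X = X, y = rowMeans(wf$windows),
                 trial = processed$meta$trial %||% NA),
            class = "feature_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d windows x %d features; force %.2f-%.2f N\n",
              nrow(x$X), ncol(x$X), min(x$y), max(x$y)))
  invisible(x)
}

#' Pool feature series from several trials
#'
#' Row-binds the feature matrices and labels, keeping a per-window trial id so
#' splits and per-trial metrics can be stratified.
#'
#' @param series_list List of [feature_matrix()] results.
#' @return A `feature_series` whose `trial` field is a per-window vector.
#' @export
bind_features <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  X <- do.call(rbind, lapply(series_list, `[[`, "X"))
  y <- unlist(lapply(series_list, `[[`, "y"))
  t <- unlist(lapply(series_list, `[[`, "t"))
  trial <- unlist(lapply(seq_along(series_list), function(k) {
    s <- series_list[[k]]
    id <- if (length(s$trial) == 1 && !is.na(s$trial)) s$trial else k
    rep(id, nrow(s$X))
  }))
  structure(list(t = t, X = X, y = y, trial = trial),
            class = "feature_series")
}

#' Write a feature series as CSV
#'
#' Columns `t_s, b_mav, b_rms, b_dasdv, b_wl, t_mav, t_rms, t_dasdv, t_wl,
#' force_n`.
#'
#' @param features A `feature_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(t_s = features$t, features$X, force_n = features$y,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
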