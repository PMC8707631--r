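#' Filter specification for the sEMG conditioning chain
#'
#' Parameters of the two IIR stages: a second-order mains notch and a
#' Butterworth band-pass. `bp_order` is the order of the low-pass prototype;
#' the resulting band-pass has twice that many poles. The printed upper cut of
#' 500 Hz equals the Nyquist frequency at the 1000 Hz sampling rate and is not
#' realizable digitally; at design time the high edge is clamped to
#' `0.99 * fs/2` (495 Hz at 1000 Hz) and a message is emitted.
#'
#' @param notch_hz Mains frequency to reject, Hz.
#' @param notch_q Quality factor of the notch (bandwidth = notch_hz / Q).
#' @param bp_order Butterworth prototype order (even).
#' @param bp_low,bp_high Band edges, Hz.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_hz = 50, notch_q = 30, bp_order = 4,
                        bp_low = 10, bp_high = 500) {
  stopifnot(notch_hz > 0, notch_q > 0, bp_order >= 2, bp_order %% 2 == 0,
            bp_low > 0, bp_high > bp_low)
  structure(list(notch_hz = notch_hz, notch_q = notch_q, bp_order = bp_order,
                 bp_low = bp_low, bp_high = bp_high),
            class = "filter_spec")
}

# ---- IIR design -----------------------------------------------------------
# No filter-design library ships with this R stack, so the classical designs
# are implemented directly: analog Butterworth prototype -> low-pass-to-
# band-pass transform -> bilinear transform with pre-warping, emitted as
# second-order sections; the notch is the standard constrained biquad.

# Digital Butterworth band-pass as a K x 6 second-order-section matrix.
# order = prototype order (number of pole pairs in the band-pass).
butter_bandpass_sos <- function(order, lo, hi, fs) {
  stopifnot(order >= 1, 0 < lo, lo < hi, hi < fs / 2)
  fs2 <- 2 * fs
  wlo <- fs2 * tan(pi * lo / fs)          # pre-warped analog edges
  whi <- fs2 * tan(pi * hi / fs)
  w0 <- sqrt(wlo * whi)
  bw <- whi - wlo
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit LP poles
  # low-pass -> band-pass: each prototype pole maps to a pole pair
  b2 <- proto * bw / 2
  disc <- sqrt(b2^2 - w0^2)
  s_poles <- c(b2 + disc, b2 - disc)
  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)     # bilinear transform
  # band-pass zeros: `order` at z = +1 and `order` at z = -1
  up <- z_poles[Im(z_poles) >= 0]
  stopifnot(length(up) == order)
  sos <- t(vapply(up, function(p) {
    c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2)           # (z-1)(z+1) over pole pair
  }, numeric(6)))
  # normalize to unit gain at the (warped) center frequency
  fc <- fs / pi * atan(w0 / fs2)
  g <- Mod(sos_response(sos, fc, fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  sos
}

# Constrained biquad notch at f0 with quality factor q.
notch_sos <- function(f0, q, fs) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  matrix(c(1 / a0, -2 * cos(w0) / a0, 1 / a0,
           1, -2 * cos(w0) / a0, (1 - alpha) / a0), nrow = 1)
}

#' Frequency response of a second-order-section cascade
#'
#' Evaluates the complex transfer function \eqn{H(e^{i 2\pi f / fs})} of a
#' cascade of biquads, the quantity the filter contracts (notch depth,
#' pass-band flatness) are stated in.
#'
#' @param sos K x 6 matrix of sections (`b0 b1 b2 a0 a1 a2`).
#' @param f Frequencies at which to evaluate, Hz.
#' @param fs Sampling rate, Hz.
#' @return Complex vector of responses, one per frequency.
#' @export
sos_response <- function(sos, f, fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z1 + sos[s, 3] * z1^2
    den <- sos[s, 4] + sos[s, 5] * z1 + sos[s, 6] * z1^2
    h <- h * num / den
  }
  h
}

# Apply a SOS cascade; zero_phase runs it forward then backward (offline use).
apply_sos <- function(sos, x, zero_phase = FALSE) {
  y <- .sosfilt_cpp(sos, as.numeric(x))
  if (zero_phase) y <- rev(.sosfilt_cpp(sos, rev(y)))
  y
}

# ---- conditioning stages --------------------------------------------------

#' Remove the DC offset of a signal
#'
#' Subtracts the series mean (the function of the hardware filter box in the
#' acquisition chain).
#'
#' @param signal Numeric series.
#' @return The zero-mean series.
#' @export
remove_dc <- function(signal) {
  if (length(signal) < 1) stop("empty signal")
  signal - mean(signal)
}

#' Mains notch filter
#'
#' Second-order IIR notch at `spec$notch_hz` (50 Hz) rejecting the power-line
#' interference by >= 20 dB while passing 100 Hz within 10%.
#'
#' @param signal Numeric series.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @param zero_phase Apply forward-backward for zero phase (offline analysis);
#'   default is causal, honoring real-time use.
#' @return Filtered series, same length.
#' @export
notch_50hz <- function(signal, fs, spec = filter_spec(), zero_phase = FALSE) {
  if (fs <= 2 * spec$notch_hz)
    stop("sampling rate too low for the notch frequency")
  apply_sos(notch_sos(spec$notch_hz, spec$notch_q, fs), signal, zero_phase)
}

# Clamp the band-pass high edge below Nyquist; message once per call site.
clamp_bp_high <- function(spec, fs, quiet = FALSE) {
  hi <- spec$bp_high
  lim <- 0.99 * fs / 2
  if (hi > lim) {
    if (!quiet)
      message(sprintf(
        "band-pass high edge %g Hz clamped to %g Hz (0.99 x Nyquist at fs = %g Hz)",
        hi, lim, fs))
    hi <- lim
  }
  if (!(spec$bp_low > 0 && spec$bp_low < hi && hi < fs / 2))
    stop("invalid band edges after clamping: need 0 < low < high < fs/2")
  hi
}

#' Butterworth band-pass filter
#'
#' Fourth-order (prototype) Butterworth band-pass with 10--500 Hz nominal
#' edges; the high edge is clamped to 0.99 x Nyquist when the nominal value is
#' unrealizable at the given sampling rate (see [filter_spec()]).
#'
#' @inheritParams notch_50hz
#' @param quiet Suppress the clamping message.
#' @return Filtered series, same length.
#' @export
butterworth_bandpass <- function(signal, fs, spec = filter_spec(),
                                 zero_phase = FALSE, quiet = FALSE) {
  hi <- clamp_bp_high(spec, fs, quiet)
  sos <- butter_bandpass_sos(spec$bp_order, spec$bp_low, hi, fs)
  apply_sos(sos, signal, zero_phase)
}

#' Full-wave rectification
#'
#' @param signal Numeric series.
#' @return Elementwise absolute value.
#' @export
full_wave_rectify <- function(signal) abs(signal)

#' Maximum voluntary contraction reference of one channel
#'
#' The MVC is the maximum of the conditioned (DC-removed, notched,
#' band-passed), rectified channel after smoothing with a 0.2 s moving
#' average -- the amplitude reference that maps sEMG to the `[0, 1]` scale.
#' The recording must contain a maximal-effort segment.
#'
#' @param recording An [emg_recording()].
#' @param channel Channel name.
#' @param spec A [filter_spec()].
#' @param smooth_s Moving-average length, s.
#' @return Positive scalar MVC in mV.
#' @export
compute_mvc <- function(recording, channel, spec = filter_spec(),
                        smooth_s = 0.2) {
  stopifnot(inherits(recording, "emg_recording"))
  if (!channel %in% names(recording$channels))
    stop("unknown channel: ", channel)
  x <- recording$channels[[channel]]
  if (all(x == 0)) stop("MVC undefined for an all-zero channel")
  fs <- recording$fs
  y <- remove_dc(x)
  y <- notch_50hz(y, fs, spec)
  y <- butterworth_bandpass(y, fs, spec, quiet = TRUE)
  env <- .movavg_cpp(abs(y), max(2L, as.integer(round(smooth_s * fs))))
  mvc <- max(env)
  if (mvc <= 0) stop("MVC undefined (non-positive envelope)")
  mvc
}

#' Normalize a series by its MVC reference
#'
#' Divides by the MVC and clamps to `[0, 1]`.
#'
#' @param signal Numeric series (typically rectified sEMG, mV).
#' @param mvc Positive MVC scalar, mV.
#' @return Unitless series in `[0, 1]`.
#' @export
mvc_normalize <- function(signal, mvc) {
  if (!is.numeric(mvc) || length(mvc) != 1 || mvc <= 0)
    stop("mvc must be a positive scalar")
  pmin(1, pmax(0, signal / mvc))
}

#' Run the full sEMG conditioning chain on a recording
#'
#' DC removal, 50 Hz notch, Butterworth band-pass (producing `filtered`),
#' full-wave rectification (`rectified`), and MVC normalization. Two
#' MVC-referenced views are produced: `normalized` is the rectified signal
#' divided by MVC and clamped to `[0, 1]`; `scaled` is the band-passed
#' (signed, pre-rectification) signal divided by MVC without clamping -- the
#' default input of the sliding-window feature extractor, which needs the
#' oscillating waveform (DASDV and WL collapse on a rectified envelope's
#' clamped version).
#'
#' @param recording An [emg_recording()].
#' @param spec A [filter_spec()].
#' @param mvc Named numeric vector of per-channel MVC values in mV; when
#'   `NULL` each channel's MVC is computed from this recording.
#' @param zero_phase Use forward-backward filtering (offline analysis mode).
#' @return An object of class `processed_emg` with per-channel lists
#'   `filtered`, `rectified`, `scaled`, `normalized`, the `mvc` vector, `fs`,
#'   and the synchronized `force` series carried through.
#' @export
preprocess_chain <- function(recording, spec = filter_spec(), mvc = NULL,
                             zero_phase = FALSE) {
  stopifnot(inherits(recording, "emg_recording"))
  fs <- recording$fs
  chans <- names(recording$channels)
  if (is.null(mvc))
    mvc <- vapply(chans, function(ch) compute_mvc(recording, ch, spec),
                  numeric(1))
  if (!all(chans %in% names(mvc)))
    stop("mvc must supply a value for every channel")
  if (any(mvc[chans] <= 0)) stop("mvc values must be positive")
  hi <- clamp_bp_high(spec, fs)        # validate and log the clamp once
  bp <- butter_bandpass_sos(spec$bp_order, spec$bp_low, hi, fs)
  nt <- notch_sos(spec$notch_hz, spec$notch_q, fs)
  filtered <- lapply(recording$channels, function(x) {
    apply_sos(bp, apply_sos(nt, remove_dc(x), zero_phase), zero_phase)
  })
  rectified <- lapply(filtered, full_wave_rectify)
  scaled <- mapply(function(x, m) x / m, filtered, mvc[chans],
                   SIMPLIFY = FALSE)
  normalized <- mapply(mvc_normalize, rectified, mvc[chans], SIMPLIFY = FALSE)
  structure(list(fs = fs, filtered = filtered, rectified = rectified,
                 scaled = scaled, normalized = normalized,
                 mvc = mvc[chans], force = recording$force,
                 meta = recording$meta),
            class = "processed_emg")
}

#' @export
print.processed_emg <- function(x, ...) {
  cat(sprintf("<processed_emg> %d samples @ %g Hz; channels: %s\n",
              length(x$force), x$fs,
              paste(names(x$filtered), collapse = ", ")))
  cat("  MVC (mV):", paste(sprintf("%s=%.4g", names(x$mvc), x$mvc),
                           collapse = " "), "\n")
  invisible(x)
}
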