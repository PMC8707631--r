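#' Configuration for the synthetic sEMG/force generator
#'
#' Bundles every knob of the paired sEMG/force trial generator. The stochastic
#' model is amplitude-modulated, band-limited Gaussian noise: a unitless
#' activation profile \eqn{a(t) \in [0,1]} modulates the envelope of a
#' zero-mean, unit-RMS Gaussian carrier restricted to `emg_band`, so the
#' envelope RMS rises from `A_rest` at rest to `A_mvc` at maximal effort on
#' the biceps channel. The triceps channel receives the same profile scaled by
#' `cocontraction` (elbow flexion is biceps-dominated). Fingertip force follows
#' a mildly nonlinear power law of activation with additive Gaussian noise.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Trial duration in seconds (>= 1).
#' @param A_rest Envelope RMS at rest, mV.
#' @param A_mvc Envelope RMS at maximal voluntary effort, mV.
#' @param cocontraction Triceps co-contraction gain in `[0, 1]` applied to the
#'   activation profile.
#' @param F_max Force at full activation, N.
#' @param force_noise_sd Standard deviation of additive force noise, N.
#' @param mains_amp Amplitude of the injected 50 Hz mains component, mV.
#' @param emg_band Two-element band (Hz) of the Gaussian carrier; must satisfy
#'   `fs > 2 * emg_band[2]`.
#' @param nonlinearity_p Exponent of the force--activation power law.
#' @param seed Master seed; every random draw in the generator flows from it.
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(duration_s = 2, seed = 1)
#' rec <- make_dataset(1, cfg)[[1]]
#' str(rec$channels$biceps[1:5])
synth_config <- function(fs = 1000, duration_s = 10, A_rest = 0.2,
                         A_mvc = 0.6, cocontraction = 0.15, F_max = 30,
                         force_noise_sd = 0.5, mains_amp = 0.05,
                         emg_band = c(20, 450), nonlinearity_p = 1.2,
                         seed = 42L) {
  stopifnot(fs > 0, duration_s >= 1, length(emg_band) == 2)
  if (!(A_mvc > A_rest && A_rest > 0))
    stop("require A_mvc > A_rest > 0")
  if (cocontraction < 0 || cocontraction > 1)
    stop("cocontraction must lie in [0, 1]")
  if (F_max <= 0) stop("F_max must be positive")
  if (fs <= 2 * emg_band[2])
    stop("fs must exceed twice the upper EMG band edge (Nyquist)")
  structure(list(fs = fs, duration_s = duration_s, A_rest = A_rest,
                 A_mvc = A_mvc, cocontraction = cocontraction, F_max = F_max,
                 force_noise_sd = force_noise_sd, mains_amp = mains_amp,
                 emg_band = as.numeric(emg_band),
                 nonlinearity_p = nonlinearity_p, seed = as.integer(seed)),
            class = "synth_config")
}

#' Activation profile of one effort trial
#'
#' Builds the unitless activation time course \eqn{a(t) \in [0,1]} on the
#' uniform sampling grid. The default `"trapezoid"` emulates one isometric
#' effort from rest to maximal voluntary output and back: a linear rise over
#' the first 40\% of the trial, a plateau at 1 for 20\%, and a linear fall
#' over the final 40\%. `"ramp"` rises linearly over the whole trial;
#' `"hold"` stays at 1 throughout (an MVC-style effort).
#'
#' @param config A [synth_config()].
#' @param pattern One of `"trapezoid"`, `"ramp"`, `"hold"`.
#' @return An object of class `activation_profile` with fields `time`, `a`,
#'   `pattern`.
#' @export
activation_profile <- function(config, pattern = c("trapezoid", "ramp", "hold")) {
  stopifnot(inherits(config, "synth_config"))
  pattern <- match.arg(pattern)
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  T <- config$duration_s
  a <- switch(pattern,
    trapezoid = {
      rise <- 0.4 * T; hold <- 0.2 * T
      ifelse(t < rise, t / rise,
             ifelse(t < rise + hold, 1, pmax(0, (T - t) / (0.4 * T))))
    },
    ramp = t / T,
    hold = rep(1, n)
  )
  structure(list(time = t, a = pmin(1, pmax(0, a)), pattern = pattern),
            class = "activation_profile")
}

# Zero-mean Gaussian noise band-limited to [lo, hi] Hz by FFT masking,
# rescaled to unit RMS. Draws n iid normals from the current RNG stream.
band_limited_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)           # two-sided (aliased) frequency
  W[freqs < lo | freqs > hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Synthesize one sEMG channel from an activation profile
#'
#' Implements `envelope(t) * w(t) + mains`: the envelope is
#' `A_rest + (A_mvc - A_rest) * a_ch(t)` where the biceps uses the profile
#' directly and the triceps uses `cocontraction * a(t)`; `w(t)` is zero-mean,
#' unit-RMS Gaussian noise band-limited to `config$emg_band`; mains is
#' `mains_amp * sin(2 pi 50 t)`.
#'
#' @param profile An [activation_profile()].
#' @param channel `"biceps"` or `"triceps"`.
#' @param config A [synth_config()].
#' @param seed Seed applied before drawing the carrier noise; `NULL` uses the
#'   current RNG state (as inside [make_dataset()]).
#' @return Numeric vector of sEMG samples in mV.
#' @export
synth_emg <- function(profile, channel = c("biceps", "triceps"), config,
                      seed = config$seed) {
  stopifnot(inherits(profile, "activation_profile"),
            inherits(config, "synth_config"))
  channel <- match.arg(channel)
  if (config$fs <= 2 * config$emg_band[2])
    stop("fs must exceed twice the upper EMG band edge (Nyquist)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  a_ch <- if (channel == "biceps") profile$a else config$cocontraction * profile$a
  env <- config$A_rest + (config$A_mvc - config$A_rest) * a_ch
  w <- band_limited_noise(length(profile$a), config$fs,
                          config$emg_band[1], config$emg_band[2])
  env * w + config$mains_amp * sin(2 * pi * 50 * profile$time)
}

#' Synthesize the isometric force trace for an activation profile
#'
#' `F(t) = F_max * a(t)^p + eps(t)` with iid Gaussian noise of standard
#' deviation `force_noise_sd`, clamped at zero from below (the sensor cannot
#' read negative pressing force).
#'
#' @inheritParams synth_emg
#' @return Numeric vector of force samples in N.
#' @export
synth_force <- function(profile, config, seed = NULL) {
  stopifnot(inherits(profile, "activation_profile"),
            inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- config$F_max * profile$a^config$nonlinearity_p
  if (config$force_noise_sd > 0)
    f <- f + stats::rnorm(length(f), sd = config$force_noise_sd)
  pmax(f, 0)
}

#' Generate a dataset of paired sEMG/force trials
#'
#' Each trial is a two-channel (biceps, triceps) recording with a synchronized
#' force trace, generated under a per-trial seed derived deterministically from
#' the master seed (`config$seed + trial index`), so any single trial can be
#' regenerated in isolation. Within a trial the draws happen in the fixed
#' order biceps, triceps, force.
#'
#' @param n_trials Number of trials (default 5, one offline training session).
#' @param config A [synth_config()].
#' @param pattern Activation pattern passed to [activation_profile()].
#' @return List of [emg_recording()] objects.
#' @export
make_dataset <- function(n_trials = 5, config = synth_config(),
                         pattern = "trapezoid") {
  stopifnot(inherits(config, "synth_config"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  profile <- activation_profile(config, pattern)
  lapply(seq_len(n_trials), function(k) {
    set.seed(config$seed + k)
    biceps  <- synth_emg(profile, "biceps",  config, seed = NULL)
    triceps <- synth_emg(profile, "triceps", config, seed = NULL)
    force   <- synth_force(profile, config, seed = NULL)
    emg_recording(fs = config$fs,
                  channels = list(biceps = biceps, triceps = triceps),
                  force = force,
                  meta = list(trial = k, seed = config$seed + k,
                              pattern = pattern))
  })
}

#' Write a dataset as per-trial CSV files plus a JSON config sidecar
#'
#' One file `trial_<k>.csv` per recording with columns
#' `time_s, biceps_mv, triceps_mv, force_n`, and `synth_config.json` echoing
#' the generator configuration.
#'
#' @param dataset List of recordings from [make_dataset()].
#' @param dir Output directory (created if missing).
#' @param config Optional [synth_config()] echoed to the sidecar.
#' @return Invisibly, the written trial file paths.
#' @export
write_trials <- function(dataset, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(dataset), function(k) {
    path <- file.path(dir, sprintf("trial_%02d.csv", k))
    write_trial_csv(dataset[[k]], path)
    path
  }, character(1))
  if (!is.null(config))
    jsonlite::write_json(unclass(config), file.path(dir, "synth_config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
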