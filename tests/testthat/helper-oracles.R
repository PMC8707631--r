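# Shared fixtures and independent oracles. Everything here is written
# against the stated formulas, not against the package's code paths, so the
# tests compare two independent routes.

# Short trials keep the suite fast; all other generator settings are the
# package defaults (the stated experimental conditions).
quick_synth <- function(duration_s = 4, seed = 7, ...) {
  synth_config(duration_s = duration_s, seed = seed, ...)
}

# Steady-state amplitude of a (possibly transient) sinusoidal response:
# peak-to-peak over the second half of the series.
steady_amp <- function(y) {
  tail_part <- y[seq.int(floor(length(y) / 2), length(y))]
  (max(tail_part) - min(tail_part)) / 2
}

# Independent evaluation of a biquad cascade's magnitude response, written
# directly from the transfer-function definition.
oracle_sos_gain <- function(sos, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  h <- 1 + 0i
  for (s in seq_len(nrow(sos))) {
    h <- h * (sos[s, 1] + sos[s, 2] / z + sos[s, 3] / z^2) /
      (sos[s, 4] + sos[s, 5] / z + sos[s, 6] / z^2)
  }
  Mod(h)
}

# Brute-force single-window feature formulas, written out literally.
oracle_features <- function(x) {
  n <- length(x)
  d <- x[-1] - x[-n]
  c(mav = sum(abs(x)) / n,
    rms = sqrt(sum(x^2) / n),
    dasdv = sqrt(sum(d^2) / (n - 1)),
    wl = sum(abs(d)))
}

# Independent 8-3-1 forward pass: explicit loops, symmetric sigmoid written
# as 2/(1+exp(-2z)) - 1 (not tanh), separate denormalization.
oracle_forward <- function(model, x) {
  n_h <- nrow(model$w_in)
  xn <- (x - model$feat_norm$min) /
    (model$feat_norm$max - model$feat_norm$min)
  h <- numeric(n_h)
  for (j in seq_len(n_h)) {
    z <- sum(model$w_in[j, ] * xn) - model$t[j]
    h[j] <- 2 / (1 + exp(-2 * z)) - 1
  }
  yn <- sum(model$w_out * h) + model$b_out
  yn * (model$force_norm$max - model$force_norm$min) + model$force_norm$min
}

# Classical RK4 integration of the mainframe ODE
#   J1 th'' + B1 th' + K (th - th_j)/gamma = km1 i(t)
# under zero-order-hold current, as an oracle for the simulator's
# semi-implicit Euler trajectory.
oracle_rk4_theta <- function(i_cmd, plant, dt, theta0, omega0 = 0,
                             substeps = 10) {
  f <- function(th, om, i) {
    acc <- (plant$km1 * i - plant$B1 * om -
              plant$K * (th - plant$theta_j0) / plant$gamma) / plant$J1
    c(om, acc)
  }
  th <- theta0; om <- omega0
  out <- numeric(length(i_cmd))
  h <- dt / substeps
  for (k in seq_along(i_cmd)) {
    for (s in seq_len(substeps)) {
      k1 <- f(th, om, i_cmd[k])
      k2 <- f(th + h / 2 * k1[1], om + h / 2 * k1[2], i_cmd[k])
      k3 <- f(th + h / 2 * k2[1], om + h / 2 * k2[2], i_cmd[k])
      k4 <- f(th + h * k3[1], om + h * k3[2], i_cmd[k])
      th <- th + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      om <- om + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    }
    out[k] <- th
  }
  out
}

# A processed_emg stub for feature tests that bypasses the filter chain.
fake_processed <- function(biceps, triceps, force, fs = 1000) {
  structure(list(fs = fs,
                 filtered = list(biceps = biceps, triceps = triceps),
                 rectified = list(biceps = abs(biceps), triceps = abs(triceps)),
                 scaled = list(biceps = biceps, triceps = triceps),
                 normalized = list(biceps = pmin(1, abs(biceps)),
                                   triceps = pmin(1, abs(triceps))),
                 mvc = c(biceps = 1, triceps = 1),
                 force = force, meta = list()),
            class = "processed_emg")
}
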