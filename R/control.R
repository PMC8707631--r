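#' Plant parameters of the series-elastic elbow actuator
#'
#' Minimal model of the assist device under the isometric constraint: the
#' output link (forearm cuff) is kinematically frozen at `theta_j0`, so only
#' the motor-driven mainframe moves, winding the joint spring of stiffness
#' `K` (high-stiffness mode, 118.49 N m/rad). The mainframe obeys
#' \deqn{J_1 \ddot\theta_1 + B_1 \dot\theta_1 + K(\theta_1-\theta_j)/\gamma
#'   = k_{m1} i} and the spring torque delivered to the link is
#' \eqn{K(\theta_1-\theta_j)}. Measured hand force is joint torque divided by
#' the lever arm (elbow-to-sensor distance), with the gravity moment of
#' forearm + device (`grav_mgl * cos(theta_j)`) as preload. `Jm`/`Bm`
#' describe the output link and are unused while it is frozen.
#'
#' All numeric defaults except `K` are design values of this simulation, not
#' measured device constants; each is config-exposed.
#'
#' @param J1 Mainframe inertia, kg m^2.
#' @param B1 Mainframe damping, N m s/rad.
#' @param Jm,Bm Output-link inertia and damping (unused under the isometric
#'   constraint; kept for completeness).
#' @param gamma Transmission ratio motor-to-spring.
#' @param km1 Motor torque constant, N m/A.
#' @param K Joint stiffness, N m/rad.
#' @param lever_arm Elbow-to-force-sensor distance, m.
#' @param grav_mgl Combined m g l_c of forearm + device, N m.
#' @param theta_j0 Fixed joint angle, rad (0 = horizontal forearm).
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(J1 = 5e-4, B1 = 0.2, Jm = 0.01, Bm = 0.05,
                         gamma = 10, km1 = 0.1, K = 118.49,
                         lever_arm = 0.25, grav_mgl = 1.5, theta_j0 = 0) {
  stopifnot(J1 > 0, B1 > 0, Jm > 0, Bm > 0, gamma > 0, km1 > 0, K > 0,
            lever_arm > 0, grav_mgl >= 0)
  structure(list(J1 = J1, B1 = B1, Jm = Jm, Bm = Bm, gamma = gamma,
                 km1 = km1, K = K, lever_arm = lever_arm,
                 grav_mgl = grav_mgl, theta_j0 = theta_j0),
            class = "plant_params")
}

#' PID controller gains for force tracking
#'
#' Deliberately low gains: in rehabilitation use the force-tracking loop is
#' tuned soft so that human--robot interaction stays safe, at the cost of
#' tracking speed.
#'
#' @param kp Proportional gain, A/N.
#' @param ki Integral gain, A/(N s).
#' @param kd Derivative gain, A s/N.
#' @param i_max Motor current saturation, A.
#' @param dt Control step, s.
#' @return An object of class `controller_gains`.
#' @export
controller_gains <- function(kp = 0.5, ki = 2, kd = 0, i_max = 6,
                             dt = 0.001) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0, i_max > 0, dt > 0)
  structure(list(kp = kp, ki = ki, kd = kd, i_max = i_max, dt = dt),
            class = "controller_gains")
}

#' Bilateral force error
#'
#' `F_error = F_health - F_affected`, the assist metric: the healthy-side
#' force is the reference the affected side is assisted to track.
#'
#' @param f_health,f_affected Forces in N (vectorized).
#' @return Signed error in N.
#' @export
force_error <- function(f_health, f_affected) f_health - f_affected

#' Spring torque of the variable-stiffness joint
#'
#' `tau = K * (theta_j - theta_1)`: stiffness times the deflection between
#' output link and mainframe.
#'
#' @param theta_j Output-link angle, rad.
#' @param theta_1 Mainframe angle, rad.
#' @param K Stiffness, N m/rad.
#' @return Torque, N m.
#' @export
vsa_torque <- function(theta_j, theta_1, K = 118.49) K * (theta_j - theta_1)

#' Motor torque from current
#'
#' @param i Motor current, A.
#' @param km1 Torque constant, N m/A.
#' @return Torque `km1 * i`, N m.
#' @export
motor_torque <- function(i, km1) km1 * i

#' Gravity moment of forearm + device
#'
#' `grav_mgl * cos(theta_j)` with `theta_j = 0` at horizontal forearm
#' (maximal moment) and zero when vertical.
#'
#' @param theta_j Joint angle, rad.
#' @param grav_mgl Combined m g l_c, N m.
#' @return Moment, N m.
#' @export
gravity_torque <- function(theta_j, grav_mgl) grav_mgl * cos(theta_j)

#' One step of the discrete PID law
#'
#' `u = kp e + ki * I + kd * de/dt` with a trapezoid integral (no area is
#' accumulated until a second sample exists), a backward-difference
#' derivative, output clamping to `[-i_max, i_max]`, and conditional
#' anti-windup: the integral is frozen while the output is saturated in the
#' direction the error would push it further.
#'
#' @param state Controller memory from the previous call, or `NULL` to start.
#' @param error Current force error, N.
#' @param gains A [controller_gains()].
#' @param feedforward Additive feed-forward current included before clamping.
#' @return List with `u` (clamped command, A) and `state` (pass back next
#'   call).
#' @export
pid_step <- function(state, error, gains, feedforward = 0) {
  if (is.null(state))
    state <- list(integral = 0, prev_error = NA_real_)
  dt <- gains$dt
  first <- is.na(state$prev_error)
  integral_cand <- if (first) state$integral
                   else state$integral + dt * (error + state$prev_error) / 2
  deriv <- if (first) 0 else (error - state$prev_error) / dt
  u_raw <- gains$kp * error + gains$ki * integral_cand + gains$kd * deriv +
    feedforward
  u <- max(-gains$i_max, min(gains$i_max, u_raw))
  saturating <- (u_raw > gains$i_max && error > 0) ||
                (u_raw < -gains$i_max && error < 0)
  if (!saturating) state$integral <- integral_cand
  state$prev_error <- error
  list(u = u, state = state)
}

#' Closed-loop mirror-assist simulation
#'
#' Simulates the real-time assist phase: a PID force-tracking loop drives the
#' motor current so that the measured affected-side force follows the
#' healthy-side reference. Per step the controller acts on
#' `F_err = F_ref - F_aff` (plus a gravity feed-forward current
#' `grav_mgl cos(theta_j) / (gamma km1)` that pre-loads the spring against
#' the limb weight); the mainframe ODE is integrated by semi-implicit Euler
#' at `gains$dt`; the measured force is
#' `max(0, (tau_spring + tau_human - tau_gravity) / lever_arm)`.
#'
#' @param F_ref Healthy-side reference force series, N.
#' @param human_torque Active torque of the affected limb, N m (scalar or
#'   series; what the impaired side still contributes).
#' @param plant A [plant_params()].
#' @param gains A [controller_gains()].
#' @param theta1_0,omega1_0 Initial mainframe angle (rad) and angular
#'   velocity (rad/s); defaults start at rest with a relaxed spring.
#' @return An object of class `assist_sim` with series `t`, `F_ref`, `F_aff`,
#'   `F_err`, `i_cmd`, `theta1`.
#' @export
simulate_assist <- function(F_ref, human_torque = 0,
                            plant = plant_params(),
                            gains = controller_gains(),
                            theta1_0 = plant$theta_j0, omega1_0 = 0) {
  n <- length(F_ref)
  tau_h <- rep_len(human_torque, n)
  dt <- gains$dt
  th_j <- plant$theta_j0
  tau_g <- gravity_torque(th_j, plant$grav_mgl)
  i_ff <- tau_g / (plant$gamma * plant$km1)
  theta1 <- numeric(n); F_aff <- numeric(n)
  F_err <- numeric(n); i_cmd <- numeric(n)
  th <- theta1_0; om <- omega1_0
  state <- NULL
  for (k in seq_len(n)) {
    tau_spring <- plant$K * (th - th_j)
    F_aff[k] <- max(0, (tau_spring + tau_h[k] - tau_g) / plant$lever_arm)
    F_err[k] <- force_error(F_ref[k], F_aff[k])
    step <- pid_step(state, F_err[k], gains, feedforward = i_ff)
    state <- step$state
    i_cmd[k] <- step$u
    # mainframe: J1 th'' + B1 th' + K (th - th_j) / gamma = km1 i
    acc <- (motor_torque(i_cmd[k], plant$km1) - plant$B1 * om -
              tau_spring / plant$gamma) / plant$J1
    om <- om + dt * acc
    th <- th + dt * om
    theta1[k] <- th
    if (!is.finite(th) || !is.finite(om))
      stop(sprintf("simulation diverged at step %d (t = %.3f s)", k, k * dt))
  }
  structure(list(t = (seq_len(n) - 1) * dt, F_ref = F_ref, F_aff = F_aff,
                 F_err = F_err, i_cmd = i_cmd, theta1 = theta1,
                 plant = plant, gains = gains),
            class = "assist_sim")
}

#' @export
print.assist_sim <- function(x, ...) {
  n <- length(x$t)
  tail_idx <- seq.int(max(1, floor(0.8 * n)), n)
  cat(sprintf(
    "<assist_sim> %d steps (%.2f s); final-20%% |F_err|: mean %.3g N, max %.3g N\n",
    n, n * x$gains$dt, mean(abs(x$F_err[tail_idx])),
    max(abs(x$F_err[tail_idx]))))
  cat(sprintf("  current: max |i| = %.3g A (limit %.3g A)\n",
              max(abs(x$i_cmd)), x$gains$i_max))
  invisible(x)
}

#' Write an assist simulation result as CSV
#'
#' Columns `t_s, f_ref_n, f_aff_n, f_err_n, i_cmd_a, theta1_rad`.
#'
#' @param result An `assist_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assist_csv <- function(result, path) {
  df <- data.frame(t_s = result$t, f_ref_n = result$F_ref,
                   f_aff_n = result$F_aff, f_err_n = result$F_err,
                   i_cmd_a = result$i_cmd, theta1_rad = result$theta1)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
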