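test_that("algebraic plant relations match their definitions", {
  expect_equal(force_error(10, 4), 6)
  expect_equal(force_error(7, 7), 0)
  expect_equal(force_error(4, 10), -6)
  expect_equal(vsa_torque(0.3, 0.3, 118.49), 0)
  expect_equal(vsa_torque(0.1, 0, 118.49), 11.849)
  expect_equal(vsa_torque(0.2, 0, 118.49), 2 * vsa_torque(0.1, 0, 118.49))
  expect_equal(motor_torque(0, 0.03), 0)
  expect_equal(motor_torque(2, 0.03), 0.06)
  expect_equal(sign(motor_torque(-3, 0.1)), -1)
  expect_equal(gravity_torque(pi / 2, 2), 0, tolerance = 1e-12)
  expect_equal(gravity_torque(0, 2), 2)
  expect_equal(gravity_torque(pi / 3, 2), 1, tolerance = 1e-12)
})

test_that("the discrete PID law matches hand-computed steps", {
  g <- controller_gains(kp = 0, ki = 1, kd = 0, i_max = 100, dt = 1)
  s1 <- pid_step(NULL, 0, g)
  expect_equal(s1$u, 0)
  # trapezoid integral: no area after one sample, 1.0 after the second
  s2 <- pid_step(NULL, 1, g)
  expect_equal(s2$u, 0)
  s3 <- pid_step(s2$state, 1, g)
  expect_equal(s3$u, 1)
  gp <- controller_gains(kp = 0.7, ki = 0, kd = 0, i_max = 100, dt = 0.01)
  st <- NULL
  for (k in 1:5) { r <- pid_step(st, 2, gp); st <- r$state }
  expect_equal(r$u, 1.4)                       # pure proportional
  # derivative: backward difference
  gd <- controller_gains(kp = 0, ki = 0, kd = 0.1, i_max = 100, dt = 0.1)
  r1 <- pid_step(NULL, 1, gd)
  r2 <- pid_step(r1$state, 2, gd)
  expect_equal(r2$u, 0.1 * (2 - 1) / 0.1)
  # clamping and anti-windup: integral frozen while saturated
  gs <- controller_gains(kp = 0, ki = 1, kd = 0, i_max = 0.5, dt = 1)
  st <- NULL
  for (k in 1:50) { r <- pid_step(st, 1, gs); st <- r$state }
  expect_equal(r$u, 0.5)
  r_down <- pid_step(st, -1, gs)               # must react immediately
  expect_lt(r_down$state$integral, 2)          # no runaway accumulation
})

test_that("zero reference with zero human torque is an equilibrium", {
  plant <- plant_params()
  sim <- simulate_assist(rep(0, 2000), 0, plant, controller_gains())
  expect_true(all(sim$F_aff == 0))
  i_ff <- plant$grav_mgl * cos(plant$theta_j0) / (plant$gamma * plant$km1)
  expect_equal(sim$i_cmd, rep(i_ff, 2000), tolerance = 1e-9)
  expect_equal(sim$F_err, sim$F_ref - sim$F_aff)
})

test_that("integral action drives a 10 N step to <= 0.1 N steady error", {
  sim <- simulate_assist(rep(10, 5000), 0, plant_params(),
                         controller_gains())
  expect_lte(max(abs(sim$F_err[4000:5000])), 0.1)
  expect_true(all(abs(sim$i_cmd) <= sim$gains$i_max))   # hard safety bound
})

test_that("with a negligible current budget the assist is inert", {
  plant <- plant_params(grav_mgl = 1e-9)     # no gravity preload either
  gains <- controller_gains(i_max = 1e-9)
  tau_h <- rep(0.5, 3000)                    # human torque only
  sim <- simulate_assist(rep(10, 3000), tau_h, plant, gains)
  expect_equal(sim$F_aff, rep(0.5 / plant$lever_arm, 3000), tolerance = 1e-3)
})

test_that("the spring relaxes to the joint angle without drive", {
  plant <- plant_params(grav_mgl = 1e-9)
  gains <- controller_gains(kp = 0, ki = 0, kd = 0, i_max = 1e-12)
  sim <- simulate_assist(rep(0, 3000), 0, plant, gains,
                         theta1_0 = plant$theta_j0 + 0.2)
  expect_lt(abs(sim$theta1[3000] - plant$theta_j0), 1e-4)
  expect_lt(sim$F_aff[3000], 1e-3)
})

test_that("semi-implicit Euler agrees with an RK4 oracle and finer steps", {
  plant <- plant_params()
  gains <- controller_gains()
  ref <- c(seq(0, 8, length.out = 1500), rep(8, 1500))
  sim <- simulate_assist(ref, 0.3, plant, gains)
  # oracle: integrate the mainframe ODE by RK4 under the recorded currents
  th_oracle <- oracle_rk4_theta(sim$i_cmd, plant, gains$dt,
                                theta0 = plant$theta_j0)
  rel_rms <- sqrt(mean((sim$theta1 - th_oracle)^2)) /
    sqrt(mean(th_oracle^2))
  expect_lt(rel_rms, 0.01)
  # step-size robustness: rerun the whole closed loop at dt/10
  g_fine <- gains; g_fine$dt <- gains$dt / 10
  ref_fine <- rep(ref, each = 10)
  fine <- simulate_assist(ref_fine, 0.3, plant, g_fine)
  f_sub <- fine$F_aff[seq(10, length(ref_fine), by = 10)]
  rel <- sqrt(mean((sim$F_aff - f_sub)^2)) / sqrt(mean(f_sub^2))
  expect_lt(rel, 0.01)
})

test_that("assist results serialize to the documented CSV layout", {
  sim <- simulate_assist(rep(1, 100), 0, plant_params(), controller_gains())
  path <- withr::local_tempfile(fileext = ".csv")
  write_assist_csv(sim, path)
  df <- read.csv(path)
  expect_named(df, c("t_s", "f_ref_n", "f_aff_n", "f_err_n", "i_cmd_a",
                     "theta1_rad"))
  expect_equal(df$f_err_n, df$f_ref_n - df$f_aff_n, tolerance = 1e-9)
})
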