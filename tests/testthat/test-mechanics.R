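test_that("Hill force reproduces its anchor points exactly", {
  m <- default_muscle_set()$TRL
  expect_equal(hill_force(1, 1, 0, m), m$F0m * cos(m$phi0))
  expect_equal(hill_force(0, 1, 0, m), 0)
  expect_equal(fv_hill(0), 1)
  expect_equal(fv_hill(-1), 0)
  expect_lt(fv_hill(100), 1.4)
  expect_error(hill_force(0.5, -0.1, 0, m), "positive")
})

test_that("Hill force matches hand-composed curve formulas", {
  m <- muscle_params("X", F0m = 500, l0 = 0.1, phi0 = 0,
                     moment_arms = list(el_fe = c(0.03, 0, 0)))
  a <- 0.5; l <- 1.1; v <- -0.2
  fl <- exp(-(l - 1)^2 / 0.45)
  fv <- (1 + v) / (1 - v / 0.35)
  fp <- (exp(8 * (l - 1)) - 1) / (exp(8 * 0.7) - 1)
  expect_equal(hill_force(a, l, v, m), 500 * (a * fl * fv + fp),
               tolerance = 1e-12)
  # monotone nondecreasing in activation at fixed state
  aa <- seq(0, 1, by = 0.1)
  expect_true(all(diff(hill_force(aa, 1.1, -0.2, m)) > 0))
})

test_that("fiber kinematics: excursion integral and velocity by differences", {
  fs <- 400
  m <- muscle_params("X", F0m = 100, l0 = 0.1, phi0 = 0,
                     moment_arms = list(el_fe = c(0.03, 0, 0)))
  base <- c(sh_fe = 0, sh_aa = 0, sh_erir = 0, el_fe = pi / 2)
  const <- as.data.frame(as.list(base))[rep(1, 200), ]
  fk <- fiber_kinematics(const, m, fs)
  expect_true(all(abs(fk$vm_norm) < 1e-12))
  expect_true(all(fk$lm_norm == 1))

  # ramp of 0.5 rad with constant moment arm r: fiber shortens by r * 0.5
  ramp <- const
  ramp$el_fe <- seq(pi / 2, pi / 2 + 0.5, length.out = 200)
  fk2 <- fiber_kinematics(ramp, m, fs)
  expect_equal(fk2$lm_norm[200] * m$l0 - m$l0, -0.03 * 0.5, tolerance = 1e-12)

  # sinusoidal angle: velocity matches the analytic derivative to O(dt^2)
  t <- seq(0, 1, by = 1 / fs)
  sine <- data.frame(sh_fe = 0, sh_aa = 0, sh_erir = 0,
                     el_fe = pi / 2 + 0.3 * sin(2 * pi * t))
  fk3 <- fiber_kinematics(sine, m, fs)
  v_analytic <- -0.03 * 0.3 * 2 * pi * cos(2 * pi * t) / (10 * m$l0)
  mid <- 10:(length(t) - 10)
  expect_lt(max(abs(fk3$vm_norm[mid] - v_analytic[mid])), 1e-3)
})

test_that("muscle and net joint torques follow the moment-arm algebra", {
  m <- muscle_params("X", F0m = 100, l0 = 0.1, phi0 = 0,
                     moment_arms = list(el_fe = c(0.03, 0, 0)))
  expect_equal(muscle_torque(rep(100, 5), rep(1, 5), m), rep(3, 5))
  expect_equal(muscle_torque(rep(0, 5), rep(1, 5), m), rep(0, 5))
  mp <- muscle_params("Y", F0m = 100, l0 = 0.1, phi0 = 0,
                      moment_arms = list(el_fe = c(0.02, 0.01, 0)))
  expect_equal(muscle_torque(50, 0.5, mp), 1.25)

  expect_equal(net_joint_torque(list(c(2, 2), c(-2, -2))), c(0, 0))
  expect_equal(net_joint_torque(list(1:3)), 1:3)
  r1 <- seq(0, 1, length.out = 7); r2 <- seq(2, 0, length.out = 7)
  expect_equal(net_joint_torque(list(r1, r2, r1)), r1 + r2 + r1)
  expect_error(net_joint_torque(list()), "no contributing")
  expect_error(net_joint_torque(list(1:3, 1:4)), "aligned")
})

test_that("two-link inverse dynamics: statics, zero gravity, energy balance", {
  fs <- 400
  n <- 400
  arm <- arm_model(body_mass = 70, m2 = 1.5, c2 = 0.15)
  # static horizontal forearm: elbow torque = m2 g c2
  idt <- inverse_dynamics_2link(rep(0, n), rep(pi / 2, n), fs, arm)
  expect_equal(mean(idt$el_fe[50:350]), 1.5 * 9.81 * 0.15, tolerance = 1e-6)
  expect_equal(mean(idt$el_fe[50:350]), 2.2073, tolerance = 1e-4)

  arm0 <- arm_model(g = 1e-12)
  idt0 <- inverse_dynamics_2link(rep(0.3, n), rep(1, n), fs, arm0)
  expect_true(all(abs(idt0$el_fe) < 1e-9))
  expect_error(inverse_dynamics_2link(1:3, 1:3, fs), "shorter")

  # energy oracle: power of the applied torques equals dE/dt, with E built
  # independently from link centre-of-mass kinematics
  arm <- arm_model()
  t <- seq(0, 2, by = 1 / fs)
  q1 <- 0.4 * sin(2 * pi * 0.7 * t)
  q2 <- 1.2 + 0.3 * cos(2 * pi * 0.5 * t)
  idt <- inverse_dynamics_2link(q1, q2, fs, arm)
  q1d <- pracma::gradient(q1, 1 / fs); q2d <- pracma::gradient(q2, 1 / fs)
  # centre-of-mass positions (x, z), angles from the downward vertical
  a2 <- q1 + q2
  c1x <- arm$c1 * sin(q1); c1z <- -arm$c1 * cos(q1)
  c2x <- arm$upper_arm * sin(q1) + arm$c2 * sin(a2)
  c2z <- -arm$upper_arm * cos(q1) - arm$c2 * cos(a2)
  vsq <- function(x, z) pracma::gradient(x, 1 / fs)^2 +
    pracma::gradient(z, 1 / fs)^2
  E <- 0.5 * arm$m1 * vsq(c1x, c1z) + 0.5 * arm$I1 * q1d^2 +
    0.5 * arm$m2 * vsq(c2x, c2z) + 0.5 * arm$I2 * (q1d + q2d)^2 +
    arm$m1 * arm$g * c1z + arm$m2 * arm$g * c2z
  dE <- pracma::gradient(E, 1 / fs)
  P <- idt$sh_fe * q1d + idt$el_fe * q2d
  mid <- 20:(length(t) - 20)
  rel <- sqrt(mean((dE[mid] - P[mid])^2)) / sqrt(mean(P[mid]^2))
  expect_lt(rel, 0.01)
})

test_that("rate alignment decimates exactly", {
  a <- rep(0.3, 2000)
  expect_equal(align_rates(a), rep(0.3, 400))
  x <- sin(2 * pi * 1 * seq(0, 1 - 5e-4, by = 5e-4))
  x400 <- align_rates(x)
  expect_length(x400, 400)
  ref <- sin(2 * pi * 1 * seq(0, 1 - 2.5e-3, by = 2.5e-3))
  expect_lt(max(abs(x400 - ref)), 1e-3)
  expect_error(align_rates(rep(1, 7)), "misaligned")
})
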