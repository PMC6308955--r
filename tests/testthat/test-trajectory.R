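test_that("quaternion integration matches closed-form constant-rate rotations", {
  # 90 degrees about z in 1 s at 200 Hz
  n <- 201
  g <- matrix(rep(c(0, 0, pi / 2), each = n), n, 3)
  q <- integrate_orientation(g, c(1, 0, 0, 0), 200)
  q_true <- c(cos(pi / 4), 0, 0, sin(pi / 4))  # half-angle of a 90 deg turn
  expect_lt(max(abs(q[n, ] - q_true)), 1e-4)
  # norm preserved to 1e-9 across > 400 steps of random rates
  set.seed(4)
  g2 <- matrix(rnorm(3 * 500, sd = 3), 500, 3)
  q2 <- integrate_orientation(g2, quat_normalize(c(0.6, 0.4, -0.2, 0.1)), 200)
  expect_lt(max(abs(sqrt(rowSums(q2^2)) - 1)), 1e-9)
  # rotations about a shared axis compose additively in angle
  ga <- matrix(rep(c(0, 1.3, 0), each = 101), 101, 3)
  qa <- integrate_orientation(ga, c(1, 0, 0, 0), 200)[101, ]
  qb <- integrate_orientation(ga, qa, 200)[101, ]
  ang <- 2 * acos(pmin(qb[1], 1))
  expect_equal(ang, 2 * 1.3 * 0.5, tolerance = 1e-6)
  # constant zero rate keeps the initial orientation
  q0 <- quat_normalize(c(1, 2, 3, 4))
  qc <- integrate_orientation(matrix(0, 50, 3), q0, 200)
  expect_equal(qc[50, ], q0)
})

test_that("gravity alignment returns the minimal rotation onto world +z", {
  g <- 9.81
  expect_equal(initial_orientation_from_gravity(c(0, 0, g)), c(1, 0, 0, 0))
  for (a_ms in list(c(g, 0, 0), c(0, g, 0), c(3, -4, 8), c(0, 0, -g))) {
    q <- if (a_ms[3] < 0 && a_ms[1] == 0 && a_ms[2] == 0) {
      expect_silent(initial_orientation_from_gravity(a_ms))
    } else initial_orientation_from_gravity(a_ms)
    rotated <- quat_rotate(q, a_ms)
    expect_equal(rotated, c(0, 0, sqrt(sum(a_ms^2))), tolerance = 1e-9)
    expect_equal(sqrt(sum(q^2)), 1, tolerance = 1e-12)
  }
  expect_warning(initial_orientation_from_gravity(c(0, 0, 2)), "quasi-static")
})

test_that("gravity removal is consistent with the gravity-based initialization", {
  n <- 10
  q_id <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  a_static <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  expect_equal(remove_gravity(a_static, q_id), matrix(0, n, 3),
               ignore_attr = TRUE)
  # sensor tilted 90 degrees: initialization + removal cancel exactly
  a_tilt <- matrix(rep(c(9.81, 0, 0), each = n), n, 3)
  q0 <- initial_orientation_from_gravity(c(9.81, 0, 0))
  q_seq <- matrix(rep(q0, each = n), n, 4)
  expect_lt(max(abs(remove_gravity(a_tilt, q_seq))), 1e-9)
  # free fall reads zero specific force
  ff <- remove_gravity(matrix(0, n, 3), q_id)
  expect_equal(ff[, 3], rep(-9.81, n))
  expect_error(remove_gravity(a_static, q_id[1:5, ]), "equal lengths")
})

test_that("dedrifting subtracts the endpoint line and zeroes both midstances", {
  # acceleration chosen so the raw trapezoidal velocity is [0, 0.3, 0.4]
  a <- cbind(c(0.2, 0.4, -0.2), 0, 0)
  v <- integrate_velocity_dedrifted(a, fs = 1)
  expect_equal(v[, 1], c(0, 0.1, 0))
  expect_equal(integrate_velocity_dedrifted(matrix(0, 10, 3), 200),
               matrix(0, 10, 3), ignore_attr = TRUE)
  # constant drift acceleration dedrifts to exactly zero
  drift <- matrix(rep(c(0.05, -0.02, 0.08), each = 100), 100, 3)
  expect_lt(max(abs(integrate_velocity_dedrifted(drift, 200))), 1e-12)
})

test_that("position integration reproduces closed-form displacements", {
  expect_equal(integrate_position(matrix(0, 20, 3), 200), matrix(0, 20, 3),
               ignore_attr = TRUE)
  # triangular velocity pulse peaking at 1 m/s over 1 s covers 0.5 m
  n <- 201
  vx <- 1 - abs(seq(-1, 1, length.out = n))
  v <- cbind(vx, 0, 0)
  p <- integrate_position(v, fs = (n - 1))
  expect_equal(unname(p[n, 1]), 0.5, tolerance = 1e-9)
  expect_equal(integrate_position(2 * v, (n - 1))[, 1], 2 * p[, 1])
})

test_that("midstance detection minimizes windowed gyroscopic energy", {
  # constructed minimum at n_ic + 20
  n <- 400
  e <- 2 + abs((1:n) - 120) * 0.05
  g <- cbind(sqrt(e), 0, 0)
  rec <- imu_recording(a = cbind(0, 0, rep(9.81, n)), g = g, fs = 200)
  expect_equal(detect_midstance(rec, 100L), 120L)
  # all-zero gyro: tie broken toward the earliest sample
  rec0 <- imu_recording(a = cbind(0, 0, rep(9.81, n)), g = matrix(0, n, 3), fs = 200)
  expect_equal(detect_midstance(rec0, 100L), 100L)
  expect_error(detect_midstance(rec0, 390L), "exceeds")
  # simulated strides: within 5 samples of the true zero-velocity instant
  ses <- quick_session(3.0, 4)
  ics <- detect_initial_contacts(ses$recording)
  ms <- vapply(ics, function(ic) detect_midstance(ses$recording, ic), integer(1))
  expect_true(all(abs(ms - ses$ground_truth$midstance) <= 5))
})

test_that("dedrifted velocity is exactly zero at both midstances of every stride", {
  ses <- quick_session(4.0, 5, accel_noise_sd = 0.3, gyro_noise_sd = 0.02,
                       seed = 13L)
  ics <- detect_initial_contacts(ses$recording)
  ms <- vapply(ics, function(ic) detect_midstance(ses$recording, ic), integer(1))
  for (i in seq_len(length(ms) - 1L)) {
    traj <- reconstruct_stride_trajectory(ses$recording, ms[i], ms[i + 1L])
    n <- nrow(traj$velocity)
    expect_true(all(abs(traj$velocity[c(1, n), ]) <= 1e-12))
    expect_equal(traj$position[1, ], c(0, 0, 0), ignore_attr = TRUE)
  }
})

test_that("trajectory estimates recover simulated stride length", {
  # noise-free: within 2% per stride
  cfg <- simulation_config(velocity = 3.58)  # true length ~2.40 m
  ses <- simulate_session(cfg, 5)
  est <- estimate_strides_trajectory(ses$recording)
  expect_gt(nrow(est), 0)
  expect_true(all(abs(est$stride_length - cfg$stride_length) /
                    cfg$stride_length < 0.02))
  # a perfectly static segment yields zero length and velocity
  n <- 300
  rec0 <- imu_recording(a = cbind(0, 0, rep(9.81, n)),
                        g = matrix(0, n, 3), fs = 200)
  traj <- reconstruct_stride_trajectory(rec0, 50L, 250L)
  est0 <- trajectory_estimate(traj)
  expect_lt(est0$stride_length, 1e-9)
  expect_lt(est0$velocity, 1e-9)
})

test_that("stride-length accuracy degrades gracefully with sensor noise", {
  mae_at <- function(sd_a, sd_g) {
    errs <- c()
    for (i in 1:5) {
      ses <- quick_session(3.0 + 0.3 * i, 5, accel_noise_sd = sd_a,
                           gyro_noise_sd = sd_g, seed = 50L + i)
      est <- estimate_strides_trajectory(ses$recording)
      errs <- c(errs, abs(est$stride_length - ses$config$stride_length))
    }
    mean(errs)
  }
  m0 <- mae_at(0, 0)
  m1 <- mae_at(0.3, 0.02)
  m2 <- mae_at(1.5, 0.10)
  expect_lte(m0, m1)
  expect_lte(m1, m2)
})

test_that("stride length is invariant to sensor yaw (heading unobservability)", {
  ses <- quick_session(3.2, 4)
  rec <- ses$recording
  est <- estimate_strides_trajectory(rec)
  # re-mount the sensor rotated about its craniocaudal axis
  psi <- 0.7
  Rz <- rbind(c(cos(psi), -sin(psi), 0), c(sin(psi), cos(psi), 0), c(0, 0, 1))
  rec_rot <- imu_recording(a = rec$a %*% Rz, g = rec$g %*% Rz, fs = rec$fs)
  est_rot <- estimate_strides_trajectory(rec_rot)
  expect_equal(est_rot$stride_length, est$stride_length, tolerance = 1e-6)
})
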