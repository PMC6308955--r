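test_that("stride kinematics honour the configured velocity and zero-velocity midstance", {
  cfg <- simulation_config(velocity = 3.0)
  kin <- simulate_stride_kinematics(cfg)
  expect_equal(kin$stride_length / kin$stride_time, 3.0, tolerance = 1e-6)
  ms <- kin$events$midstance
  expect_lt(sqrt(sum(kin$velocity[ms, ]^2)), 1e-6)
  # stride length equals the displacement to the next initial contact
  expect_equal(sqrt(sum((kin$p_end - kin$position[1, ])^2)),
               kin$stride_length, tolerance = 1e-9)
  expect_error(simulation_config(velocity = 10), "config error")
  expect_error(simulation_config(velocity = 1.0), "config error")
  expect_error(simulation_config(velocity = 3, fs = 20), "config error")
})

test_that("static kinematics produce gravity-only accelerometer readings", {
  n <- 100
  kin <- list(accel_world = matrix(0, n, 3), theta = rep(0, n),
              theta_dot = rep(0, n), fs = 200)
  cfg <- simulation_config(velocity = 3.0)
  rec <- kinematics_to_imu(kin, cfg)
  expect_equal(rec$a, cbind(0, 0, rep(9.81, n)), ignore_attr = TRUE)
  expect_equal(rec$g, matrix(0, n, 3), ignore_attr = TRUE)
})

test_that("the same seed reproduces a bit-identical recording", {
  cfg <- simulation_config(velocity = 3.5, accel_noise_sd = 0.3,
                           gyro_noise_sd = 0.02, seed = 77L)
  r1 <- simulate_session(cfg, 3)$recording
  r2 <- simulate_session(cfg, 3)$recording
  expect_identical(r1$a, r2$a)
  expect_identical(r1$g, r2$g)
  r3 <- simulate_session(simulation_config(velocity = 3.5, accel_noise_sd = 0.3,
                                           gyro_noise_sd = 0.02, seed = 78L),
                         3)$recording
  expect_false(identical(r1$a, r3$a))
})

test_that("sessions satisfy the reference-velocity identity and telescoping distance", {
  ses <- quick_session(3.5, 10)
  gt <- ses$ground_truth
  expect_equal(nrow(gt), 10)
  expect_true(all(abs(gt$vref - 3.5) < 1e-6))
  expect_equal(gt$vref, gt$dref * 200 / gt$n_stride)  # exact identity
  # displacement between first and last initial contact telescopes
  p <- ses$kinematics$position
  ic <- gt$ic
  total <- unname(p[ic[10] + gt$n_stride[10], 2] - p[ic[1], 2])
  expect_equal(total, sum(gt$dref), tolerance = 1e-6)
  # segmentation of the noise-free output finds exactly the 10 contacts
  ics <- detect_initial_contacts(ses$recording)
  expect_length(ics, 10)
})

test_that("simulated position and accelerometer are analytically consistent", {
  ses <- quick_session(3.2, 4)
  kin <- ses$kinematics
  fs <- kin$fs
  n <- nrow(kin$position)
  # second central difference of position vs world acceleration
  d2 <- (kin$position[3:n, ] - 2 * kin$position[2:(n - 1), ] +
           kin$position[1:(n - 2), ]) * fs^2
  err <- abs(d2 - kin$accel_world[2:(n - 1), ])
  # guard band: the impact transient is deliberately near-Nyquist, and the
  # phase boundaries are only C1, so the O(dt^2) bound applies elsewhere
  guard <- rep(FALSE, n - 2)
  N <- ses$config$n_stride
  cycle_starts <- seq(1, n, by = N)  # lead-in, strides, phantom tail cycle
  for (cs in cycle_starts) {
    lo <- max(1, cs - 4); hi <- min(n - 2, cs + round(0.06 * fs) + 2)
    guard[lo:hi] <- TRUE               # impact transient is near-Nyquist
    for (b in cs + round(c(0.05, 0.25) * fs))  # C1 phase boundaries
      guard[max(1, b - 3):min(n - 2, b + 3)] <- TRUE
  }
  expect_lt(max(err[!guard, ]), 0.2)
})

test_that("cohorts draw plausible anthropometrics and fill the velocity bins", {
  cohort <- simulate_cohort(4, strides_per_bin = c(4, 4, 4, 4), seed = 5,
                            strides_per_session = 4L)
  expect_length(cohort, 4)
  heights <- vapply(cohort, function(s) s$subject$height, numeric(1))
  expect_true(all(heights > 1.5 & heights < 2.1))
  bins <- rbind(c(2, 3), c(3, 4), c(4, 5), c(5, 6))
  for (sub in cohort) {
    per_bin <- integer(4)
    for (ses in sub$sessions) {
      b <- attr(ses, "bin")
      v <- ses$ground_truth$vref
      expect_true(all(v >= bins[b, 1] & v <= bins[b, 2]))
      per_bin[b] <- per_bin[b] + nrow(ses$ground_truth)
    }
    expect_equal(per_bin, c(4L, 4L, 4L, 4L))
  }
  # reproducibility
  cohort2 <- simulate_cohort(4, strides_per_bin = c(4, 4, 4, 4), seed = 5,
                             strides_per_session = 4L)
  expect_identical(heights,
                   vapply(cohort2, function(s) s$subject$height, numeric(1)))
  expect_identical(cohort[[2]]$sessions[[1]]$recording$a,
                   cohort2[[2]]$sessions[[1]]$recording$a)
})
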