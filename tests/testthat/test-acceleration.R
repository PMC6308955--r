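test_that("channel smoothing is a centered moving average with shrinking edges", {
  a <- cbind(rep(2, 50), rep(-1, 50), rep(9.81, 50))
  expect_equal(smooth_signals(a, 200, 0.05), a, ignore_attr = TRUE)
  # unit impulse with a 5-sample window becomes a 0.2 plateau
  imp <- rep(0, 21); imp[11] <- 1
  sm <- smooth_signals(cbind(imp, 0, 0), 100, 0.05)  # 5-sample window
  expect_equal(unname(sm[9:13, 1]), rep(0.2, 5))
  expect_equal(unname(sm[7, 1]), 0)
  # 1-sample window is the identity
  x <- cbind(rnorm(30), rnorm(30), rnorm(30))
  expect_equal(smooth_signals(x, 200, 0.004), x, ignore_attr = TRUE)
})

test_that("integration value averages absolute channels over the trailing window", {
  s <- cbind(rep(1, 10), rep(-2, 10), rep(0, 10))
  expect_equal(integration_value(s, n = 3, l_samples = 2), 3.0)
  expect_equal(integration_value(matrix(0, 10, 3), 5, 2), 0)
  expect_equal(integration_value(-s, 3, 2), integration_value(s, 3, 2))
  expect_error(integration_value(s, 2, 2), "L < n")
  # linear in the input amplitude
  s2 <- cbind(rnorm(50), rnorm(50), rnorm(50))
  expect_equal(integration_value(3.5 * s2, 40, 20),
               3.5 * integration_value(s2, 40, 20))
})

test_that("smoothed-peak step detection finds one step per simulated stride", {
  ses <- quick_session(3.0, 5)
  s <- smooth_signals(ses$recording$a, 200)
  steps <- detect_steps_smoothed(s[, 2], 200)
  # lead-in stride plus 5 counted strides and the tail each carry one swing
  expect_gte(length(steps), 5)
  expect_true(all(diff(steps) >= 0.25 * 200))

  expect_identical(detect_steps_smoothed(rep(0, 500), 200), integer(0))

  # two peaks 0.1 s apart: the refractory rule keeps the larger
  y <- rep(0, 400); y[100] <- 40; y[120] <- 55
  kept <- detect_steps_smoothed(y, 200)
  expect_identical(kept, 120L)
})

test_that("quadratic regression recovers generating coefficients", {
  iota <- c(1, 2, 3, 4)
  m <- fit_velocity_regression(iota, 1 + 2 * iota + 0.5 * iota^2)
  expect_equal(c(m$A, m$B, m$C), c(1, 2, 0.5), tolerance = 1e-8)
  expect_lt(m$fit_rmse, 1e-8)

  ident <- fit_velocity_regression(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(c(ident$A, ident$B, ident$C), c(0, 1, 0), tolerance = 1e-8)
  expect_equal(ident$fit_rmse, 0, tolerance = 1e-10)

  set.seed(3)
  iota_n <- runif(500, 1, 8)
  v_n <- 0.5 + 0.8 * iota_n + 0.05 * iota_n^2 + rnorm(500, sd = 0.1)
  mn <- fit_velocity_regression(iota_n, v_n)
  expect_lt(max(abs(c(mn$A - 0.5, mn$B - 0.8, mn$C - 0.05))), 0.05)

  expect_error(fit_velocity_regression(rep(2, 5), 1:5), "distinct")
  # JSON round trip
  f <- tempfile(fileext = ".json")
  write_quadratic_model(mn, f)
  back <- read_quadratic_model(f)
  expect_equal(back$A, mn$A)
  expect_equal(back$n_train, 500)
})

test_that("acceleration estimates apply the quadratic model at each step", {
  ses <- quick_session(3.5, 5)
  # identity model: velocity equals the integration value itself
  ident <- structure(list(A = 0, B = 1, C = 0, fit_rmse = 0, n_train = 3),
                     class = "quadratic_model")
  est <- estimate_strides_acceleration(ses$recording, ident)
  expect_gt(nrow(est), 0)
  s <- smooth_signals(ses$recording$a, 200)
  iota1 <- integration_value(s, est$step[1], round(0.3 * 200))
  expect_equal(est$velocity[1], iota1)
  expect_equal(est$stride_length[1], iota1 * est$stride_time[1])

  const <- structure(list(A = 1, B = 0, C = 0, fit_rmse = 0, n_train = 3),
                     class = "quadratic_model")
  est2 <- estimate_strides_acceleration(ses$recording, const)
  expect_true(all(est2$velocity == 1))

  neg <- structure(list(A = -5, B = 0, C = 0, fit_rmse = 0, n_train = 3),
                   class = "quadratic_model")
  expect_warning(est3 <- estimate_strides_acceleration(ses$recording, neg),
                 "clamped")
  expect_true(all(est3$velocity == 0))
  expect_error(estimate_strides_acceleration(ses$recording, list(A = 1)),
               "state error")
})

test_that("a model trained on the simulator family predicts velocity within 10% MAPE", {
  set.seed(21)
  train_sessions <- lapply(1:10, function(i) {
    quick_session(runif(1, 2.5, 5.5), 5, seed = 300L + i)
  })
  model <- train_acceleration_model(train_sessions)
  ref <- c(); est <- c()
  for (i in 1:6) {
    v <- runif(1, 2.6, 5.0)
    ses <- quick_session(v, 5, seed = 700L + i)
    e <- estimate_strides_acceleration(ses$recording, model)
    ref <- c(ref, rep(v, nrow(e))); est <- c(est, e$velocity)
  }
  expect_gt(length(ref), 20)
  expect_lt(error_summary(ref, est, "velocity")$mape, 10)
})

test_that("accuracy is preserved at a 60 Hz sampling rate", {
  set.seed(22)
  vels <- runif(8, 2.6, 5.2)
  mape_at <- function(fs) {
    sessions <- lapply(seq_along(vels), function(i) {
      simulate_session(simulation_config(velocity = vels[i], fs = fs,
                                         seed = 40L + i), 5)
    })
    model <- train_acceleration_model(sessions[1:5])
    ref <- c(); est <- c()
    for (ses in sessions[6:8]) {
      e <- estimate_strides_acceleration(ses$recording, model)
      ref <- c(ref, rep(ses$config$velocity, nrow(e)))
      est <- c(est, e$velocity)
    }
    error_summary(ref, est, "velocity")$mape
  }
  m200 <- mape_at(200)
  m60 <- mape_at(60)
  expect_lt(m60, m200 + 2)  # degradation under 2 percentage points
})
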