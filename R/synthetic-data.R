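# Synthetic running strides: closed-form foot kinematics and the exact IMU
# signals they imply. Serves as ground truth for every estimator.
#
# One stride cycle [0, T), anchored at initial ground contact (IC), in a
# world frame with x lateral, y forward, z up:
#   * braking [0, T_brk): the foot lands with residual forward velocity
#     v_land (still decelerating at a_land < 0) and is brought to rest by a
#     C1 Hermite velocity ramp;
#   * plateau [T_brk, T_st): the foot is stationary (true zero-velocity
#     phase); a small sinusoidal pitch wiggle gives the gyroscopic energy a
#     unique minimum at midstance t = T_st/2;
#   * swing [T_st, T): smooth polynomial velocity bump carrying the foot
#     forward by the remaining stride length, a vertical arc of height
#     h_max, and a pitch excursion; the swing ends at (v_land, a_land) so
#     acceleration is continuous through the next IC.
# At each IC a high-frequency impact oscillation (Hann-windowed 40 Hz
# sinusoid plus a smoothstep correction) is added to the forward position;
# its analytic velocity and displacement return to exactly zero after 50 ms,
# so ground truth is unaffected. All sensor channels follow analytically:
# specific force = R(pitch)^T (world accel + g e_z), gyro = pitch rate about
# the lateral axis. Noise and gyro bias are added last.

#' Simulation configuration
#'
#' @param velocity Target mean stride velocity in m/s, within `[1.5, 7]`.
#' @param fs Sampling rate in Hz (>= 50). Default 200.
#' @param stance_time Ground-contact duration in seconds. Default 0.25.
#' @param impact_amplitude Peak acceleration of the impact oscillation at
#'   initial contact, m/s^2. Default 80 (enough to trip the segmentation
#'   threshold at the default sampling rate).
#' @param cadence_intercept,cadence_slope Linear cadence model
#'   `stride_time = intercept - slope * velocity` (s). Defaults 0.85 and
#'   0.05, giving 0.75 s at 2 m/s down to 0.55 s at 6 m/s.
#' @param strike_type `"rearfoot"` (flat foot at stance) or
#'   `"forefoot_midfoot"` (constant pitch offset).
#' @param accel_noise_sd,gyro_noise_sd Gaussian sensor noise, m/s^2 and
#'   rad/s. Defaults 0.
#' @param gyro_bias Constant gyroscope bias, rad/s (scalar or length 3).
#'   Default 0.
#' @param seed Integer seed for the noise draw.
#' @return List of class `simulation_config` including derived quantities
#'   (`stride_time`, `n_stride`, `stride_length`, swing/brake parameters).
#' @export
simulation_config <- function(velocity = 3.5, fs = 200, stance_time = 0.25,
                              impact_amplitude = 80,
                              cadence_intercept = 0.85, cadence_slope = 0.05,
                              strike_type = c("rearfoot", "forefoot_midfoot"),
                              accel_noise_sd = 0, gyro_noise_sd = 0,
                              gyro_bias = 0, seed = 1L) {
  strike_type <- match.arg(strike_type)
  if (!is.finite(velocity) || velocity < 1.5 || velocity > 7.0)
    stop("config error: 'velocity' must lie in [1.5, 7] m/s")
  if (fs < 50) stop("config error: 'fs' must be >= 50 Hz")
  if (stance_time <= 0.1 || stance_time >= 0.4)
    stop("config error: 'stance_time' must lie in (0.1, 0.4) s")
  t_raw <- cadence_intercept - cadence_slope * velocity
  n_stride <- round(t_raw * fs)
  stride_time <- n_stride / fs         # stride boundaries fall on samples
  t_swing <- stride_time - stance_time
  if (t_swing < 0.15)
    stop("config error: cadence model and stance time leave < 0.15 s of swing")
  if (length(gyro_bias) == 1L) gyro_bias <- rep(gyro_bias, 3L)
  structure(list(velocity = velocity, fs = fs, stance_time = stance_time,
                 impact_amplitude = impact_amplitude,
                 cadence_intercept = cadence_intercept,
                 cadence_slope = cadence_slope,
                 strike_type = strike_type,
                 accel_noise_sd = accel_noise_sd,
                 gyro_noise_sd = gyro_noise_sd, gyro_bias = gyro_bias,
                 seed = as.integer(seed),
                 # derived
                 stride_time = stride_time, n_stride = n_stride,
                 stride_length = velocity * stride_time,
                 t_swing = t_swing, t_brake = 0.05,
                 v_land = 0.4 * velocity, a_land = -8 * velocity,
                 swing_height = 0.12, pitch_amplitude = 0.5,
                 stance_pitch_rate = 0.3,
                 pitch_offset = if (strike_type == "forefoot_midfoot") 0.35 else 0,
                 gravity = 9.81,
                 impact_freq = 40, impact_duration = 0.05),
            class = "simulation_config")
}

# ---- closed-form phase pieces ------------------------------------------------
# Everything below evaluates position/velocity/acceleration and pitch
# analytically at arbitrary times within one cycle [0, T).

# impact oscillation: displacement delta(t) on [0, T_r] along world y with
# delta(0) = delta(T_r) = 0, delta'(T_r) = 0 and zero net displacement
ring_eval <- function(tau, cfg) {
  A <- cfg$impact_amplitude
  Tr <- cfg$impact_duration
  w1 <- 2 * pi * cfg$impact_freq          # 40 Hz
  w2 <- 2 * pi / Tr                       # 20 Hz for Tr = 0.05; w1 = 2 w2
  inside <- tau >= 0 & tau <= Tr
  tt <- ifelse(inside, tau, 0)
  # acceleration r = -A sin(w1 t) * (1 - cos(w2 t))/2
  #             = -A/2 sin(w1 t) + A/4 [sin((w1+w2)t) + sin((w1-w2)t)]
  acc <- -A / 2 * sin(w1 * tt) +
    A / 4 * (sin((w1 + w2) * tt) + sin((w1 - w2) * tt))
  vel <- -A / 2 * (1 - cos(w1 * tt)) / w1 +
    A / 4 * ((1 - cos((w1 + w2) * tt)) / (w1 + w2) +
             (1 - cos((w1 - w2) * tt)) / (w1 - w2))
  dis <- -A / 2 * (tt - sin(w1 * tt) / w1) / w1 +
    A / 4 * ((tt - sin((w1 + w2) * tt) / (w1 + w2)) / (w1 + w2) +
             (tt - sin((w1 - w2) * tt) / (w1 - w2)) / (w1 - w2))
  # net displacement of the sinusoid alone (nonzero); cancel it with a C2
  # smoothstep so the ring leaves no trace after T_r
  C <- -A / 2 * Tr / w1 + A / 4 * (Tr / (w1 + w2) + Tr / (w1 - w2))
  u <- tt / Tr
  s <- 10 * u^3 - 15 * u^4 + 6 * u^5
  s1 <- (30 * u^2 - 60 * u^3 + 30 * u^4) / Tr
  s2 <- (60 * u - 180 * u^2 + 120 * u^3) / Tr^2
  acc <- acc - C * s2
  vel <- vel - C * s1
  dis <- dis - C * s
  after <- tau > Tr
  acc[after] <- 0; vel[after] <- 0; dis[after] <- 0
  before <- tau < 0
  acc[before] <- 0; vel[before] <- 0; dis[before] <- 0
  list(acc = acc, vel = vel, dis = dis)
}

# base cycle (without the impact ring) at cycle times tc in [0, T)
cycle_eval <- function(tc, cfg) {
  T_st <- cfg$stance_time; T_br <- cfg$t_brake; T_sw <- cfg$t_swing
  d <- cfg$stride_length
  vl <- cfg$v_land; al <- cfg$a_land
  # brake displacement over [0, T_br]
  i_brk <- T_br * vl / 2 + T_br^2 * al / 12
  # swing bump coefficient so the full cycle advances exactly d
  P <- 30 * ((d - i_brk) / T_sw - vl / 2 + al * T_sw / 12)
  n <- length(tc)
  y <- vy <- ay <- z <- vz <- az <- th <- thd <- numeric(n)

  brk <- tc < T_br
  if (any(brk)) {
    s <- tc[brk] / T_br
    h00 <- 2 * s^3 - 3 * s^2 + 1; h10 <- s^3 - 2 * s^2 + s
    h00i <- s^4 / 2 - s^3 + s;    h10i <- s^4 / 4 - 2 * s^3 / 3 + s^2 / 2
    h00d <- 6 * s^2 - 6 * s;      h10d <- 3 * s^2 - 4 * s + 1
    vy[brk] <- vl * h00 + al * T_br * h10
    ay[brk] <- (vl * h00d + al * T_br * h10d) / T_br
    y[brk] <- T_br * (vl * h00i + al * T_br * h10i)
  }
  plat <- tc >= T_br & tc < T_st
  y[plat] <- i_brk
  st <- tc < T_st
  if (any(st)) {
    # stance pitch wiggle: rate eps*cos(pi t/T_st), zero exactly at midstance
    eps <- cfg$stance_pitch_rate
    th[st] <- eps * T_st / pi * sin(pi * tc[st] / T_st)
    thd[st] <- eps * cos(pi * tc[st] / T_st)
  }
  sw <- !st
  if (any(sw)) {
    u <- (tc[sw] - T_st) / T_sw
    b <- u^2 * (1 - u)^2
    bd <- 2 * u * (1 - u) * (1 - 2 * u)
    bdd <- 2 - 12 * u + 12 * u^2
    bi <- u^3 / 3 - u^4 / 2 + u^5 / 5
    h01 <- 3 * u^2 - 2 * u^3; h01d <- 6 * u - 6 * u^2; h01i <- u^3 - u^4 / 2
    h11 <- u^3 - u^2; h11d <- 3 * u^2 - 2 * u; h11i <- u^4 / 4 - u^3 / 3
    vy[sw] <- P * b + vl * h01 + al * T_sw * h11
    ay[sw] <- (P * bd + vl * h01d + al * T_sw * h11d) / T_sw
    y[sw] <- i_brk + T_sw * (P * bi + vl * h01i + al * T_sw * h11i)
    hm <- cfg$swing_height
    z[sw] <- 16 * hm * b
    vz[sw] <- 16 * hm * bd / T_sw
    az[sw] <- 16 * hm * bdd / T_sw^2
    # swing pitch excursion, zero value and rate at both ends
    aa <- 2 * pi * u
    thA <- cfg$pitch_amplitude
    th[sw] <- thA * sin(aa) * (1 - cos(aa)) / 2
    thd[sw] <- thA * pi / T_sw * (cos(aa) * (1 - cos(aa)) + sin(aa)^2)
  }
  list(y = y, vy = vy, ay = ay, z = z, vz = vz, az = az,
       theta = th + cfg$pitch_offset, theta_dot = thd)
}

# Assemble continuous kinematics for `blocks` whole strides plus `tail`
# extra seconds of the following cycle, with impact rings at the given cycle
# starts. Returns sample-aligned arrays.
assemble_kinematics <- function(cfg, n_cycles, tail_s = 0, ring_at = seq_len(n_cycles + 1L)) {
  fs <- cfg$fs; N <- cfg$n_stride; T <- cfg$stride_time
  n_tail <- round(tail_s * fs)
  n_tot <- n_cycles * N + n_tail
  k <- 0:(n_tot - 1L)
  t <- k / fs
  cyc <- pmin(k %/% N, n_cycles - 0L)           # cycle index (tail continues the next cycle)
  tc <- t - cyc * T
  base <- cycle_eval(tc, cfg)
  y <- base$y + cyc * cfg$stride_length
  vy <- base$vy; ay <- base$ay
  for (r in ring_at) {
    tau <- t - (r - 1L) * T
    rng <- ring_eval(tau, cfg)
    y <- y + rng$dis; vy <- vy + rng$vel; ay <- ay + rng$acc
  }
  pos <- cbind(x = numeric(n_tot), y = y, z = base$z)
  vel <- cbind(x = numeric(n_tot), y = vy, z = base$vz)
  acc <- cbind(x = numeric(n_tot), y = ay, z = base$az)
  q <- cbind(cos(base$theta / 2), sin(base$theta / 2), 0, 0)
  list(t = t, position = pos, velocity = vel, accel_world = acc,
       orientation = q, theta = base$theta, theta_dot = base$theta_dot,
       fs = fs, n_stride = N)
}

#' Simulate ground-truth kinematics for one stride
#'
#' Produces the continuous foot pose over one stride cycle (initial contact
#' to the next initial contact, exclusive) together with event indices and
#' the true stride length and time. Foot velocity is exactly zero during the
#' stance plateau, in particular at midstance.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `stride_kinematics` with per-sample `t`, `position`,
#'   `velocity`, `accel_world` (n x 3 world-frame), `orientation` (n x 4
#'   sensor-to-world quaternions), `theta`/`theta_dot` (pitch about the
#'   lateral axis), `events` (`ic`, `midstance`), `stride_length`,
#'   `stride_time`, `fs`, and `p_end` (exact position at the next initial
#'   contact).
#' @export
simulate_stride_kinematics <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  kin <- assemble_kinematics(cfg, 1L, tail_s = 0, ring_at = 1L)
  structure(c(kin,
              list(events = list(ic = 1L,
                                 midstance = 1L + round(cfg$stance_time / 2 * cfg$fs)),
                   stride_length = cfg$stride_length,
                   stride_time = cfg$stride_time,
                   p_end = c(0, cfg$stride_length, 0))),
            class = "stride_kinematics")
}

#' Convert kinematics to the IMU signals they imply
#'
#' The accelerometer reports specific force in the sensor frame,
#' `R(q)^T (p_ddot + (0, 0, g))`, so a static level segment reads
#' `(0, 0, +9.81)`; the gyroscope reports the sensor-frame angular rate.
#' Gaussian noise and a constant gyro bias are added last, seeded from
#' `cfg$seed` (the same seed gives a bit-identical recording).
#'
#' @param kin A `stride_kinematics` (or the kinematics part of a session).
#' @param cfg The [simulation_config()] used to generate it.
#' @return An [imu_recording()].
#' @export
kinematics_to_imu <- function(kin, cfg) {
  g <- cfg$gravity
  wy <- kin$accel_world[, 2]
  wz <- kin$accel_world[, 3] + g
  ct <- cos(kin$theta); st <- sin(kin$theta)
  # sensor = Rx(-theta) %*% world
  a <- cbind(x = kin$accel_world[, 1],
             y = ct * wy + st * wz,
             z = -st * wy + ct * wz)
  gy <- cbind(x = kin$theta_dot, y = 0, z = 0)
  n <- nrow(a)
  set.seed(cfg$seed)
  if (cfg$accel_noise_sd > 0)
    a <- a + matrix(rnorm(3 * n, sd = cfg$accel_noise_sd), n, 3)
  gy <- sweep(gy, 2L, cfg$gyro_bias, "+")
  if (cfg$gyro_noise_sd > 0)
    gy <- gy + matrix(rnorm(3 * n, sd = cfg$gyro_noise_sd), n, 3)
  imu_recording(a = a, g = gy, fs = kin$fs)
}

#' Simulate a running session with ground truth
#'
#' Concatenates a lead-in stride (so the first counted initial contact has a
#' preceding swing phase), `n_strides` identical strides at the configured
#' velocity, and a short stance tail. Impact transients are injected at the
#' initial contacts of the counted strides only, so segmentation of a
#' noise-free session detects exactly `n_strides` contacts.
#'
#' @param cfg A [simulation_config()].
#' @param n_strides Number of ground-truth strides (>= 1).
#' @return List with `recording` (an [imu_recording()]), `ground_truth`
#'   (data frame with per-stride `ic`, `midstance`, `n_stride`, `dref`,
#'   `tref`, `vref` satisfying `vref = dref * fs / n_stride`), and
#'   `kinematics` (the assembled sample-aligned truth).
#' @export
simulate_session <- function(cfg, n_strides) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (n_strides < 1L) stop("'n_strides' must be >= 1")
  n_cycles <- n_strides + 1L            # one uncounted lead-in stride
  # rings at the ICs of counted strides: cycle starts 2 .. n_strides + 1
  kin <- assemble_kinematics(cfg, n_cycles, tail_s = 0.3,
                             ring_at = 2:(n_strides + 1L))
  rec <- kinematics_to_imu(kin, cfg)
  N <- cfg$n_stride
  ic <- N * (1:n_strides) + 1L          # 1-based stride-start samples
  gt <- ground_truth_strides(dref = rep(cfg$stride_length, n_strides),
                             n_stride = rep(N, n_strides), fs = cfg$fs)
  gt <- cbind(ic = ic,
              midstance = ic + round(cfg$stance_time / 2 * cfg$fs), gt)
  list(recording = rec, ground_truth = gt, kinematics = kin, config = cfg)
}

#' Simulate a cohort of subjects across velocity bins
#'
#' Draws subject metadata (heights from a 178.6 +/- 8.0 cm normal
#' distribution truncated to (1.5, 2.1) m; mixed genders) and, per subject,
#' sessions that populate the velocity bins 2-3, 3-4, 4-5 and 5-6 m/s with
#' the requested number of strides. Session velocities are drawn uniformly
#' within each bin and each subject gets a small cadence-intercept offset so
#' stride time carries subject-level signal.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param strides_per_bin Strides per velocity bin per subject (length 4).
#'   Default `c(10, 10, 15, 15)`.
#' @param seed Integer seed.
#' @param strides_per_session Ground-truth strides per simulated trial.
#' @param ... Further arguments passed to [simulation_config()] (e.g. noise
#'   levels).
#' @return List of subjects; each has `subject` (a [subject_info()]) and
#'   `sessions` (list of [simulate_session()] results, each with a `bin`
#'   attribute).
#' @export
simulate_cohort <- function(n_subjects, strides_per_bin = c(10, 10, 15, 15),
                            seed = 1L, strides_per_session = 5L, ...) {
  if (n_subjects < 2L) stop("'n_subjects' must be >= 2")
  if (length(strides_per_bin) != 4L)
    stop("'strides_per_bin' must give counts for the 4 bins 2-3, 3-4, 4-5, 5-6 m/s")
  set.seed(seed)
  bins <- rbind(c(2, 3), c(3, 4), c(4, 5), c(5, 6))
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    repeat {
      h <- rnorm(1, 1.786, 0.08)
      if (h > 1.5 && h < 2.1) break
    }
    gender <- if (runif(1) < 21 / 27) "male" else "female"
    strike <- if (runif(1) < 6 / 27) "forefoot_midfoot" else "rearfoot"
    cad0 <- 0.85 + rnorm(1, 0, 0.02)
    subj <- subject_info(sprintf("S%02d", i), gender, h, strike_type = strike)
    sessions <- list()
    for (b in 1:4) {
      remaining <- strides_per_bin[b]
      while (remaining > 0L) {
        k <- min(strides_per_session, remaining)
        v <- runif(1, bins[b, 1], bins[b, 2])
        cfg <- simulation_config(velocity = v, cadence_intercept = cad0,
                                 strike_type = subj$strike_type,
                                 seed = sample.int(.Machine$integer.max / 2, 1),
                                 ...)
        ses <- simulate_session(cfg, k)
        attr(ses, "bin") <- b
        sessions[[length(sessions) + 1L]] <- ses
        remaining <- remaining - k
      }
    }
    out[[i]] <- list(subject = subj, sessions = sessions)
  }
  out
}
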