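# Strapdown trajectory reconstruction per stride with zero-velocity updates:
# midstance detection from gyroscopic energy, gravity-aligned orientation
# initialization, quaternion integration of angular rate, gravity removal in
# the world frame, dedrifted double integration, and stride length as the
# L2-norm of the final position.

# ---- quaternion algebra ----------------------------------------------------
# Quaternions are length-4 numeric vectors c(w, x, y, z), unit norm, mapping
# SENSOR to WORLD coordinates: v_world = R(q) v_sensor.

#' Quaternion utilities
#'
#' Hamilton-convention quaternion algebra on length-4 vectors `c(w, x, y, z)`.
#' `quat_multiply()` composes rotations, `quat_normalize()` rescales to unit
#' norm, and `quat_rotate()` applies the rotation (sensor to world) to one
#' 3-vector or to the rows of an n x 3 matrix.
#'
#' @param p,q Quaternions as length-4 numeric vectors.
#' @param v Numeric 3-vector, or n x 3 matrix when `q` is an n x 4 matrix of
#'   per-sample quaternions.
#' @return `quat_multiply()` and `quat_normalize()` return quaternions;
#'   `quat_rotate()` returns a rotated vector or matrix.
#' @export
quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' @rdname quat_multiply
#' @export
quat_normalize <- function(q) {
  nrm <- sqrt(sum(q * q))
  if (nrm == 0) stop("cannot normalize a zero quaternion")
  q / nrm
}

#' @rdname quat_multiply
#' @export
quat_rotate <- function(q, v) {
  if (is.matrix(q)) {
    stopifnot(is.matrix(v), nrow(q) == nrow(v))
    return(t(vapply(seq_len(nrow(q)),
                    function(i) quat_rotate(q[i, ], v[i, ]),
                    numeric(3))))
  }
  w <- q[1]; u <- q[2:4]
  # v' = v + 2 w (u x v) + 2 u x (u x v)
  uv <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  uuv <- c(u[2] * uv[3] - u[3] * uv[2],
           u[3] * uv[1] - u[1] * uv[3],
           u[1] * uv[2] - u[2] * uv[1])
  v + 2 * w * uv + 2 * uuv
}

# Exponential map: rotation vector (axis * angle) -> quaternion.
quat_exp_map <- function(rotvec) {
  angle <- sqrt(sum(rotvec * rotvec))
  if (angle < 1e-12) {
    q <- c(1, rotvec / 2)  # first-order expansion
    return(quat_normalize(q))
  }
  axis <- rotvec / angle
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# ---- parameters and containers ---------------------------------------------

#' Trajectory-method parameters
#'
#' @param midstance_search Search interval after initial contact in seconds
#'   (the average stance duration for velocities up to 6 m/s). Default 0.250.
#' @param energy_window Moving-average window for the gyroscopic energy and
#'   for the static-orientation accelerometer mean, seconds. Default 0.05.
#' @param gravity Gravitational acceleration, m/s^2. Default 9.81.
#' @return List of class `trajectory_params`.
#' @export
trajectory_params <- function(midstance_search = 0.250, energy_window = 0.05,
                              gravity = 9.81) {
  vals <- c(midstance_search, energy_window, gravity)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all trajectory parameters must be positive")
  structure(list(midstance_search = midstance_search,
                 energy_window = energy_window, gravity = gravity),
            class = "trajectory_params")
}

# ---- algorithm steps -------------------------------------------------------

#' Detect midstance after an initial contact
#'
#' Midstance is the sample of minimum windowed gyroscopic energy
#' (`gx^2 + gy^2 + gz^2`, smoothed with a centered moving average of
#' `energy_window`) within `midstance_search` seconds after the initial
#' contact. Ties break toward the earliest sample.
#'
#' @param rec An [imu_recording()].
#' @param n_ic Initial-contact sample index (1-based).
#' @param params A [trajectory_params()].
#' @return Midstance sample index.
#' @export
detect_midstance <- function(rec, n_ic, params = trajectory_params()) {
  fs <- rec$fs
  w <- round(params$midstance_search * fs)
  if (n_ic < 1L || n_ic + w - 1L > n_samples(rec))
    stop("midstance search window exceeds the recording")
  energy <- rowSums(rec$g^2)
  energy <- moving_average(energy, round(params$energy_window * fs))
  idx <- n_ic:(n_ic + w - 1L)
  idx[which.min(energy[idx])]
}

#' Initial orientation from the static accelerometer reading
#'
#' During midstance the sensor is quasi-static, so the measured specific
#' force is (rotated) gravity. Returns the minimal (shortest-arc) rotation
#' mapping the measured direction to world +z; heading (yaw) is left at zero,
#' which is irrelevant for stride length (a norm). Warns when the magnitude
#' is far from g (sensor not quasi-static) but proceeds.
#'
#' @param a_ms Mean acceleration 3-vector around midstance (m/s^2).
#' @param gravity Gravitational acceleration, m/s^2.
#' @return Unit quaternion (sensor to world).
#' @examples
#' initial_orientation_from_gravity(c(0, 0, 9.81))  # identity
#' @export
initial_orientation_from_gravity <- function(a_ms, gravity = 9.81) {
  nrm <- sqrt(sum(a_ms^2))
  if (nrm < 0.5 * gravity || nrm > 1.5 * gravity)
    warning(sprintf("specific force magnitude %.2f m/s^2 is far from g: sensor may not be quasi-static",
                    nrm))
  if (nrm == 0) stop("zero acceleration cannot define an orientation")
  v <- a_ms / nrm
  z <- c(0, 0, 1)
  d <- sum(v * z)
  if (d <= -1 + 1e-12) {
    # antipodal: 180 degrees about a deterministic axis orthogonal to z
    return(c(0, 1, 0, 0))
  }
  axis <- c(v[2] * z[3] - v[3] * z[2],
            v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  q <- quat_normalize(c(1 + d, axis))
  q
}

#' Integrate angular rate into an orientation sequence
#'
#' Exponential-map strapdown update
#' `q[n+1] = q[n] * exp_map(omega[n] * dt)`, renormalized every step.
#'
#' @param g n x 3 angular-rate series over one stride (rad/s, sensor frame).
#' @param q0 Initial unit quaternion (sensor to world).
#' @param fs Sampling rate in Hz.
#' @return n x 4 matrix of unit quaternions, row 1 equal to `q0`.
#' @export
integrate_orientation <- function(g, q0, fs) {
  g <- as_triplet_matrix(g, "g")
  if (abs(sqrt(sum(q0^2)) - 1) > 1e-9) stop("'q0' must be unit norm")
  n <- nrow(g)
  q <- matrix(0, n, 4)
  q[1, ] <- q0
  dt <- 1 / fs
  for (i in seq_len(n - 1L)) {
    dq <- quat_exp_map(g[i, ] * dt)
    q[i + 1L, ] <- quat_normalize(quat_multiply(q[i, ], dq))
  }
  q
}

#' Rotate specific force to the world frame and remove gravity
#'
#' `a_world[n] = R(q[n]) a[n] - (0, 0, gravity)`.
#'
#' @param a n x 3 specific-force series (sensor frame, m/s^2).
#' @param q n x 4 orientation sequence (sensor to world).
#' @param gravity Gravitational acceleration, m/s^2.
#' @return n x 3 world-frame linear acceleration.
#' @export
remove_gravity <- function(a, q, gravity = 9.81) {
  a <- as_triplet_matrix(a, "a")
  if (!is.matrix(q) || nrow(q) != nrow(a) || ncol(q) != 4L)
    stop("'a' and 'q' must have equal lengths")
  aw <- quat_rotate(q, a)
  aw[, 3] <- aw[, 3] - gravity
  aw
}

#' Dedrifted velocity by trapezoidal integration
#'
#' Integrates world acceleration from zero with the cumulative trapezoidal
#' rule, then subtracts per axis the line through the first and last raw
#' velocity values (the zero-velocity update): the returned velocity is
#' exactly zero at both ends.
#'
#' @param a_world n x 3 world linear acceleration (n >= 2).
#' @param fs Sampling rate in Hz.
#' @return n x 3 dedrifted velocity (m/s).
#' @export
integrate_velocity_dedrifted <- function(a_world, fs) {
  a_world <- as_triplet_matrix(a_world, "a_world")
  n <- nrow(a_world)
  if (n < 2L) stop("need at least 2 samples")
  v_raw <- pracma::cumtrapz((seq_len(n) - 1) / fs, a_world)
  frac <- (seq_len(n) - 1) / (n - 1)
  line <- outer(1 - frac, v_raw[1, ]) + outer(frac, v_raw[n, ])
  v <- v_raw - line
  v[c(1L, n), ] <- 0  # the zero-velocity update is exact by definition
  dimnames(v) <- list(NULL, c("x", "y", "z"))
  v
}

#' Position by trapezoidal integration of velocity
#'
#' @param v n x 3 velocity series with `v[1, ] = 0`.
#' @param fs Sampling rate in Hz.
#' @return n x 3 position starting at the origin (m).
#' @export
integrate_position <- function(v, fs) {
  v <- as_triplet_matrix(v, "v")
  p <- pracma::cumtrapz((seq_len(nrow(v)) - 1) / fs, v)
  dimnames(p) <- list(NULL, c("x", "y", "z"))
  p
}

#' Reconstruct the foot trajectory over one midstance-to-midstance stride
#'
#' Chains the four algorithm steps: orientation initialization from the mean
#' specific force around the opening midstance, quaternion integration of the
#' gyroscope, gravity removal, and dedrifted double integration.
#'
#' @param rec An [imu_recording()].
#' @param ms_start,ms_end Midstance sample indices of consecutive strides.
#' @param params A [trajectory_params()].
#' @return List of class `stride_trajectory` with `velocity` and `position`
#'   (n x 3 world-frame matrices over `ms_start:ms_end`), `orientation`
#'   (n x 4), and the midstance indices.
#' @export
reconstruct_stride_trajectory <- function(rec, ms_start, ms_end,
                                          params = trajectory_params()) {
  if (ms_start >= ms_end) stop("'ms_start' must precede 'ms_end'")
  fs <- rec$fs
  half <- round(params$energy_window * fs)
  win <- max(1L, ms_start - half):min(n_samples(rec), ms_start + half)
  a_ms <- colMeans(rec$a[win, , drop = FALSE])
  q0 <- initial_orientation_from_gravity(a_ms, params$gravity)
  idx <- ms_start:ms_end
  q <- integrate_orientation(rec$g[idx, , drop = FALSE], q0, fs)
  a_world <- remove_gravity(rec$a[idx, , drop = FALSE], q, params$gravity)
  v <- integrate_velocity_dedrifted(a_world, fs)
  p <- integrate_position(v, fs)
  structure(list(velocity = v, position = p, orientation = q,
                 ms_start = ms_start, ms_end = ms_end, fs = fs),
            class = "stride_trajectory")
}

#' Trajectory stride estimate from a reconstructed trajectory
#'
#' `dstride` is the L2-norm of the position at the closing midstance,
#' `tstride` the midstance-to-midstance duration, `vstride` their ratio.
#'
#' @param traj A `stride_trajectory`.
#' @return A one-row [stride_estimates()] data frame (algorithm
#'   `"trajectory"`).
#' @export
trajectory_estimate <- function(traj) {
  stopifnot(inherits(traj, "stride_trajectory"))
  n <- nrow(traj$position)
  d <- sqrt(sum(traj$position[n, ]^2))
  tstride <- (traj$ms_end - traj$ms_start) / traj$fs
  stride_estimates(d, tstride, algorithm = "trajectory")
}

#' Trajectory-method stride estimates for a full recording
#'
#' Detects initial contacts, finds the midstance after each, re-segments the
#' recording midstance-to-midstance (the first and last partial strides are
#' dropped), and reconstructs each stride.
#'
#' @param rec An [imu_recording()].
#' @param params A [trajectory_params()].
#' @param seg_params A [segmentation_params()].
#' @return A [stride_estimates()] data frame (algorithm `"trajectory"`) with
#'   extra columns `ms_start`, `ms_end` and `ic` (the initial contact opening
#'   each stride).
#' @export
estimate_strides_trajectory <- function(rec, params = trajectory_params(),
                                        seg_params = segmentation_params()) {
  ics <- detect_initial_contacts(rec, seg_params)
  w <- round(params$midstance_search * rec$fs)
  ics <- ics[ics + w - 1L <= n_samples(rec)]
  if (length(ics) < 2L) {
    out <- stride_estimates(numeric(0), numeric(0), algorithm = "trajectory")
    out$ms_start <- out$ms_end <- out$ic <- integer(0)
    return(out)
  }
  ms <- vapply(ics, function(ic) detect_midstance(rec, ic, params), integer(1))
  n_str <- length(ms) - 1L
  lengths <- numeric(n_str); times <- numeric(n_str)
  for (i in seq_len(n_str)) {
    traj <- reconstruct_stride_trajectory(rec, ms[i], ms[i + 1L], params)
    est <- trajectory_estimate(traj)
    lengths[i] <- est$stride_length
    times[i] <- est$stride_time
  }
  out <- stride_estimates(lengths, times, algorithm = "trajectory")
  out$ms_start <- ms[-length(ms)]
  out$ms_end <- ms[-1]
  out$ic <- ics[-length(ics)]
  out
}
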