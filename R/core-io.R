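# Domain types (S3) and file formats shared by all estimators.

#' Construct a validated IMU recording
#'
#' Bundles synchronized triaxial accelerometer and gyroscope series sampled
#' on a uniform time grid. The accelerometer stores specific force (gravity
#' included): a static, level sensor reads `(0, 0, +9.81)` m/s^2. Gyroscope
#' units are rad/s internally.
#'
#' @param a n x 3 numeric matrix of accelerations (m/s^2), columns x
#'   (lateral), y (dorsoventral), z (craniocaudal).
#' @param g n x 3 numeric matrix of angular rates (rad/s), same column order.
#' @param fs Sampling rate in Hz (> 0).
#' @param t Optional numeric vector of sample times in seconds. If omitted it
#'   is generated as `(0:(n-1))/fs`; if given, spacing must equal `1/fs`
#'   within `1e-9` s.
#' @return An object of class `imu_recording`: a list with elements `t`,
#'   `a`, `g`, `fs` and `axis_convention`.
#' @examples
#' rec <- imu_recording(a = cbind(0, 0, rep(9.81, 100)),
#'                      g = matrix(0, 100, 3), fs = 200)
#' nrow(rec$a)
#' @export
imu_recording <- function(a, g, fs, t = NULL) {
  a <- as_triplet_matrix(a, "a")
  g <- as_triplet_matrix(g, "g")
  if (nrow(a) != nrow(g))
    stop("accelerometer and gyroscope series must have identical length")
  n <- nrow(a)
  if (n < 2L)
    stop("an IMU recording needs at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive sampling rate in Hz")
  if (is.null(t)) {
    t <- (seq_len(n) - 1) / fs
  } else {
    if (length(t) != n)
      stop("'t' must have one entry per sample")
    dt <- diff(t)
    if (any(abs(dt - 1 / fs) > 1e-9))
      stop("non-uniform sampling: 't' spacing deviates from 1/fs by more than 1e-9 s")
  }
  structure(
    list(t = as.numeric(t), a = a, g = g, fs = fs,
         axis_convention = "x_lateral_y_dorsoventral_z_craniocaudal"),
    class = "imu_recording"
  )
}

as_triplet_matrix <- function(x, name) {
  x <- as.matrix(x)
  if (ncol(x) != 3L)
    stop(sprintf("'%s' must have 3 columns (x, y, z)", name))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", name))
  storage.mode(x) <- "double"
  dimnames(x) <- list(NULL, c("x", "y", "z"))
  x
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("IMU recording: %d samples at %g Hz (%.2f s)\n",
              nrow(x$a), x$fs, nrow(x$a) / x$fs))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An [imu_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$a)

#' Subject metadata
#'
#' @param subject_id Character identifier.
#' @param gender `"male"` or `"female"` (the step-function tables are
#'   gender-specific; no imputation is done).
#' @param height Body height in meters, must lie in (1.0, 2.5).
#' @param strike_type `"rearfoot"`, `"forefoot_midfoot"` or `"unknown"`.
#' @return An object of class `subject_info`.
#' @export
subject_info <- function(subject_id, gender, height,
                         strike_type = c("unknown", "rearfoot", "forefoot_midfoot")) {
  gender <- match.arg(gender, c("male", "female"))
  strike_type <- match.arg(strike_type)
  if (!is.numeric(height) || length(height) != 1L ||
      !is.finite(height) || height <= 1.0 || height >= 2.5)
    stop("'height' must be in (1.0, 2.5) meters")
  structure(list(subject_id = as.character(subject_id), gender = gender,
                 height = height, strike_type = strike_type),
            class = "subject_info")
}

#' Stride windows
#'
#' A stride window is a half-open sample interval `[start, end)` (1-based
#' indices) delimiting one stride, anchored either at initial ground contact
#' or at midstance. The stride duration `(end - start)/fs` must lie in
#' (0.2, 2.0) s.
#'
#' @param start,end Integer vectors of window bounds, `start < end`.
#' @param fs Sampling rate in Hz (used to validate durations).
#' @param rec_len Recording length in samples (upper bound for `end`).
#' @param anchor `"initial_contact"` or `"midstance"`.
#' @return A data frame of class `stride_windows` with columns `start`,
#'   `end`, `anchor`.
#' @export
stride_windows <- function(start, end, fs, rec_len,
                           anchor = c("initial_contact", "midstance")) {
  anchor <- match.arg(anchor)
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop("'start' and 'end' lengths differ")
  if (length(start)) {
    if (any(start < 1L) || any(start >= end) || any(end > rec_len + 1L))
      stop("stride windows must satisfy 1 <= start < end <= recording length + 1")
    dur <- (end - start) / fs
    if (any(dur <= 0.2 | dur >= 2.0))
      stop("stride duration out of the plausible (0.2, 2.0) s range")
  }
  structure(data.frame(start = start, end = end,
                       anchor = rep(anchor, length.out = length(start)),
                       stringsAsFactors = FALSE),
            class = c("stride_windows", "data.frame"))
}

#' Per-stride estimates
#'
#' @param stride_length Stride lengths in m (>= 0).
#' @param stride_time Stride durations in s (> 0).
#' @param algorithm One of `"stride_time"`, `"acceleration"`, `"trajectory"`,
#'   `"deep_learning"`.
#' @return A data frame of class `stride_estimates` with columns
#'   `stride_length`, `stride_time`, `velocity` (derived as length/time) and
#'   `algorithm`.
#' @export
stride_estimates <- function(stride_length, stride_time, algorithm) {
  algorithm <- match.arg(algorithm,
    c("stride_time", "acceleration", "trajectory", "deep_learning"))
  if (length(stride_length) != length(stride_time))
    stop("'stride_length' and 'stride_time' lengths differ")
  if (any(stride_length < 0)) stop("stride lengths must be >= 0")
  if (any(stride_time <= 0)) stop("stride times must be > 0")
  structure(data.frame(stride_length = as.numeric(stride_length),
                       stride_time = as.numeric(stride_time),
                       velocity = as.numeric(stride_length) / as.numeric(stride_time),
                       algorithm = rep(algorithm, length.out = length(stride_length)),
                       stringsAsFactors = FALSE),
            class = c("stride_estimates", "data.frame"))
}

#' Per-stride ground truth
#'
#' Reference stride length and velocity, e.g. from motion capture or from the
#' simulator. The identity `vref = dref * fs / Nstride` is enforced.
#'
#' @param dref Reference stride lengths (m).
#' @param n_stride Samples per stride (between consecutive initial contacts).
#' @param fs Sampling rate (Hz).
#' @return Data frame with columns `dref`, `n_stride`, `tref`, `vref`.
#' @export
ground_truth_strides <- function(dref, n_stride, fs) {
  if (length(dref) != length(n_stride)) stop("length mismatch")
  if (any(n_stride < 1)) stop("'n_stride' must be >= 1 sample")
  data.frame(dref = as.numeric(dref), n_stride = as.integer(n_stride),
             tref = n_stride / fs, vref = as.numeric(dref) * fs / n_stride)
}

# ---- readers / writers -----------------------------------------------------

#' Read an IMU recording from CSV
#'
#' Expects a header with columns `ax, ay, az, gx, gy, gz` and optionally `t`
#' (seconds). If `t` is absent, `fs` must be supplied; if present, `fs` is
#' inferred from the median spacing (unless given) and the grid is validated.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz; optional when the file has a `t` column.
#' @param gyro_unit `"rad_s"` (default) or `"deg_s"`; degrees are converted
#'   to rad/s on load.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, fs = NULL, gyro_unit = c("rad_s", "deg_s")) {
  gyro_unit <- match.arg(gyro_unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE)
  need <- c("ax", "ay", "az", "gx", "gy", "gz")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("IMU CSV format error: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  t <- if ("t" %in% names(df)) as.numeric(df$t) else NULL
  if (is.null(t) && is.null(fs))
    stop("'fs' is required when the CSV has no 't' column")
  if (is.null(fs)) {
    dt <- diff(t)
    fs <- 1 / stats::median(dt)
    fs <- round(fs, 6)
  }
  g <- as.matrix(df[need[4:6]])
  if (gyro_unit == "deg_s") g <- g * pi / 180
  imu_recording(a = as.matrix(df[need[1:3]]), g = g, fs = fs, t = t)
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_imu_csv()]; writes `t,ax,ay,az,gx,gy,gz` at full double
#' precision so a round trip is lossless to 1e-9.
#'
#' @param rec An [imu_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(t = rec$t,
                   ax = rec$a[, 1], ay = rec$a[, 2], az = rec$a[, 3],
                   gx = rec$g[, 1], gy = rec$g[, 2], gz = rec$g[, 3])
  write_csv_precise(df, path)
  invisible(path)
}

write_csv_precise <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("I/O error writing %s: %s", path,
                                conditionMessage(ok)))
  invisible(path)
}

#' Write stride estimates to CSV
#'
#' One row per stride with columns `stride_index, algorithm, stride_length_m,
#' stride_time_s, velocity_mps`. The numeric fields round-trip through
#' [read_estimates_csv()] to 1e-9.
#'
#' @param estimates A [stride_estimates()] data frame (non-empty).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_estimates_csv <- function(estimates, path) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0L)
    stop("'estimates' must be a non-empty stride_estimates data frame")
  df <- data.frame(stride_index = seq_len(nrow(estimates)),
                   algorithm = estimates$algorithm,
                   stride_length_m = estimates$stride_length,
                   stride_time_s = estimates$stride_time,
                   velocity_mps = estimates$velocity)
  write_csv_precise(df, path)
}

#' Read stride estimates written by [write_estimates_csv()]
#' @param path CSV file path.
#' @return A [stride_estimates()] data frame.
#' @export
read_estimates_csv <- function(path) {
  df <- read.csv(path)
  need <- c("stride_index", "algorithm", "stride_length_m", "stride_time_s",
            "velocity_mps")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("estimates CSV format error: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  out <- stride_estimates(df$stride_length_m, df$stride_time_s,
                          algorithm = df$algorithm[1])
  out$algorithm <- df$algorithm
  out
}

#' Read subject metadata from JSON
#'
#' Expects keys `subject_id`, `gender`, `height_m` and optionally
#' `strike_type`.
#'
#' @param path JSON file path.
#' @return A [subject_info()].
#' @export
read_subject_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  subject_info(x$subject_id, x$gender, x$height_m,
               strike_type = if (is.null(x$strike_type)) "unknown" else x$strike_type)
}

#' Write subject metadata to JSON
#' @param subject A [subject_info()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_subject_json <- function(subject, path) {
  stopifnot(inherits(subject, "subject_info"))
  jsonlite::write_json(list(subject_id = subject$subject_id,
                            gender = subject$gender,
                            height_m = subject$height,
                            strike_type = subject$strike_type),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

#' Default configuration
#'
#' All tunables in one flat list: sampling rate, the two empirical
#' segmentation thresholds, the midstance search interval, the network pad
#' length, and the sub-module parameter defaults.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    fs = 200,                  # Hz
    h_threshold = 1000,        # (m/s^2)^2, on squared per-sample differences
    s_threshold = -3,          # m/s, swing-phase backward integral
    refractory = 0.25,         # s, minimum spacing between initial contacts
    midstance_search = 0.250,  # s, search interval after initial contact
    energy_window = 0.05,      # s, gyroscopic-energy smoothing window
    gravity = 9.81,            # m/s^2
    smooth_window = 0.05,      # s, acceleration-method moving average
    l_window = 0.30,           # s, integration-value window (swing duration)
    peak_threshold = 30,       # m/s^2, smoothed-peak step detector
    pad_length = 200,          # samples, network input length
    gyro_unit = "rad_s",
    seed = 1L
  )
}

#' Load a YAML configuration, filling defaults
#'
#' Absent keys take the values of [default_config()]; unknown keys are
#' ignored with a warning.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Named list with the full configuration.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop(sprintf("config parse error: %s",
                                                    conditionMessage(e))))
  if (is.null(user)) return(cfg)
  if (!is.list(user)) stop("config parse error: top level must be a mapping")
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    warning(sprintf("ignoring unknown config key(s): %s",
                    paste(unknown, collapse = ", ")))
    user <- user[setdiff(names(user), unknown)]
  }
  modifyList(cfg, user)
}
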