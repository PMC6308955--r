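# Accelerometer-only estimator: a sliding-window absolute integration value
# computed across all three acceleration channels correlates with running
# velocity and is mapped to m/s by a trained quadratic regression.

#' Acceleration-method parameters
#'
#' @param smooth_window Moving-average window in seconds applied to each
#'   acceleration channel before everything else. Default 0.05.
#' @param l_window Integration window in seconds; should match the swing
#'   phase duration. Default 0.30.
#' @param peak_threshold Step-detection threshold on the smoothed
#'   dorsoventral channel, m/s^2. Default 30.
#' @param refractory Minimum spacing between detected steps, seconds.
#'   Default 0.25.
#' @return List of class `accel_params`.
#' @export
accel_params <- function(smooth_window = 0.05, l_window = 0.30,
                         peak_threshold = 30, refractory = 0.25) {
  vals <- c(smooth_window, l_window, peak_threshold, refractory)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all acceleration parameters must be positive")
  structure(list(smooth_window = smooth_window, l_window = l_window,
                 peak_threshold = peak_threshold, refractory = refractory),
            class = "accel_params")
}

# Centered moving average with shrinking windows at the edges; the window is
# an odd sample count, so a 1-sample window is the identity.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth acceleration channels
#'
#' Centered moving average per channel with the window shrinking at the
#' edges; signal length is preserved.
#'
#' @param a n x 3 acceleration matrix (m/s^2).
#' @param fs Sampling rate in Hz.
#' @param smooth_window Window length in seconds.
#' @return n x 3 matrix of smoothed channels.
#' @export
smooth_signals <- function(a, fs, smooth_window = 0.05) {
  a <- as_triplet_matrix(a, "a")
  width <- round(smooth_window * fs)
  apply(a, 2L, moving_average, width = width)
}

#' Integration value at one sample
#'
#' `iota[n] = (1/(L+1)) * sum_{i=0..L} sum_d |s_d[n-i]|`: the trailing
#' average of the summed absolute smoothed accelerations over an L-sample
#' window. Invariant to sign flips and linear in the input amplitude.
#'
#' @param s n x 3 matrix of smoothed acceleration channels.
#' @param n Sample index (1-based); requires `n > L`.
#' @param l_samples Window length L in samples.
#' @return Scalar integration value (m/s^2).
#' @export
integration_value <- function(s, n, l_samples) {
  s <- as_triplet_matrix(s, "s")
  if (n <= l_samples || n > nrow(s))
    stop("'n' must satisfy L < n <= nrow(s)")
  idx <- (n - l_samples):n
  sum(abs(s[idx, ])) / (l_samples + 1)
}

# Full iota series (NA where the trailing window is incomplete).
integration_series <- function(s, l_samples) {
  tot <- rowSums(abs(s))
  cs <- cumsum(c(0, tot))
  n <- length(tot)
  out <- rep(NA_real_, n)
  valid <- (l_samples + 1):n
  out[valid] <- (cs[valid + 1] - cs[valid - l_samples]) / (l_samples + 1)
  out
}

#' Detect steps in the smoothed dorsoventral channel
#'
#' Local maxima of the smoothed dorsoventral acceleration above
#' `peak_threshold`, separated by at least one refractory period (when two
#' peaks collide, the larger is kept).
#'
#' @param s_y Smoothed dorsoventral series (m/s^2).
#' @param fs Sampling rate in Hz.
#' @param params An [accel_params()].
#' @return Ascending integer vector of step indices (possibly empty).
#' @export
detect_steps_smoothed <- function(s_y, fs, params = accel_params()) {
  n <- length(s_y)
  if (n < 3L) return(integer(0))
  core <- s_y[2:(n - 1)]
  is_peak <- core > params$peak_threshold &
    core >= s_y[1:(n - 2)] & core > s_y[3:n]
  cand <- which(is_peak) + 1L
  if (!length(cand)) return(integer(0))
  refr <- params$refractory * fs
  # greedy by amplitude: keep the largest peak, suppress neighbours within
  # the refractory distance
  ord <- cand[order(s_y[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= refr)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Fit the quadratic velocity regression
#'
#' Least-squares fit of `v = A + B * iota + C * iota^2` on training pairs of
#' integration value and reference velocity.
#'
#' @param iota Integration values at detected steps.
#' @param vref Reference velocities (m/s), same length.
#' @return List of class `quadratic_model` with elements `A`, `B`, `C`,
#'   `fit_rmse` and `n_train`.
#' @examples
#' iota <- 1:4
#' fit_velocity_regression(iota, 1 + 2 * iota + 0.5 * iota^2)
#' @export
fit_velocity_regression <- function(iota, vref) {
  if (length(iota) != length(vref)) stop("'iota' and 'vref' lengths differ")
  if (length(iota) < 3L || length(unique(iota)) < 3L)
    stop("fit error: need >= 3 pairs with >= 3 distinct integration values")
  fit <- lm(vref ~ iota + I(iota^2))
  cf <- unname(coef(fit))
  if (any(!is.finite(cf))) stop("fit error: degenerate design")
  structure(list(A = cf[1], B = cf[2], C = cf[3],
                 fit_rmse = sqrt(mean(fit$residuals^2)),
                 n_train = length(iota)),
            class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("quadratic velocity model: v = %.4g + %.4g*iota + %.4g*iota^2 (rmse %.3f m/s, n = %d)\n",
              x$A, x$B, x$C, x$fit_rmse, x$n_train))
  invisible(x)
}

#' Serialize / restore a quadratic model as JSON
#' @param model A `quadratic_model`.
#' @param path JSON file path.
#' @return `write_quadratic_model()` returns `path` invisibly;
#'   `read_quadratic_model()` returns the model.
#' @export
write_quadratic_model <- function(model, path) {
  stopifnot(inherits(model, "quadratic_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_quadratic_model
#' @export
read_quadratic_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("A", "B", "C", "fit_rmse", "n_train")], class = "quadratic_model")
}

# iota evaluated at each detected step of a recording, with the step indices.
step_integration_values <- function(rec, params = accel_params()) {
  s <- smooth_signals(rec$a, rec$fs, params$smooth_window)
  steps <- detect_steps_smoothed(s[, 2], rec$fs, params)
  l_samples <- round(params$l_window * rec$fs)
  steps <- steps[steps > l_samples]
  iota <- vapply(steps, function(n) integration_value(s, n, l_samples),
                 numeric(1))
  list(steps = steps, iota = iota)
}

#' Train the acceleration model on simulated or labelled sessions
#'
#' For each session, steps are detected, each detected step is matched to the
#' ground-truth stride containing it, and the (integration value, reference
#' velocity) pairs are pooled into one quadratic fit.
#'
#' @param sessions List of sessions as returned by [simulate_session()]:
#'   each a list with `recording` (an [imu_recording()]) and `ground_truth`
#'   (with columns `ic`, `n_stride`, `vref`).
#' @param params An [accel_params()].
#' @return A `quadratic_model`.
#' @export
train_acceleration_model <- function(sessions, params = accel_params()) {
  iota <- numeric(0); vref <- numeric(0)
  for (ses in sessions) {
    si <- step_integration_values(ses$recording, params)
    gt <- ses$ground_truth
    for (k in seq_along(si$steps)) {
      j <- which(gt$ic <= si$steps[k] & si$steps[k] < gt$ic + gt$n_stride)
      if (length(j) == 1L) {
        iota <- c(iota, si$iota[k])
        vref <- c(vref, gt$vref[j])
      }
    }
  }
  fit_velocity_regression(iota, vref)
}

#' Acceleration-method stride estimates
#'
#' Detects steps in the smoothed dorsoventral channel, evaluates the
#' integration value at each step, maps it to velocity with the trained
#' quadratic model, and forms per-stride estimates between consecutive
#' steps: `stride_time` from the step spacing and
#' `stride_length = v * stride_time`. Negative predicted velocities are
#' clamped to zero with a warning.
#'
#' @param rec An [imu_recording()].
#' @param model A trained `quadratic_model`.
#' @param params An [accel_params()].
#' @return A [stride_estimates()] data frame (algorithm `"acceleration"`)
#'   with an extra column `step` giving the detected step index opening each
#'   stride.
#' @export
estimate_strides_acceleration <- function(rec, model, params = accel_params()) {
  if (!inherits(model, "quadratic_model"))
    stop("state error: 'model' must be a trained quadratic_model")
  si <- step_integration_values(rec, params)
  if (length(si$steps) < 2L) {
    out <- stride_estimates(numeric(0), numeric(0), algorithm = "acceleration")
    out$step <- integer(0)
    return(out)
  }
  k <- seq_len(length(si$steps) - 1L)
  v <- model$A + model$B * si$iota[k] + model$C * si$iota[k]^2
  if (any(v < 0)) {
    warning(sprintf("%d negative predicted velocity value(s) clamped to 0",
                    sum(v < 0)))
    v <- pmax(v, 0)
  }
  tstride <- diff(si$steps) / rec$fs
  out <- stride_estimates(v * tstride, tstride, algorithm = "acceleration")
  out$step <- si$steps[k]
  out
}
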