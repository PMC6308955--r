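# Threshold-based stride segmentation from the dorsoventral acceleration.
#
# Initial ground contact produces a sharp transient in ay. Squared
# per-sample differences amplify it (H), and a backward integral of ay from
# the candidate to the previous zero crossing (S) confirms that a swing-phase
# deceleration preceded the impact, rejecting spurious spikes.

#' Segmentation parameters
#'
#' @param h_threshold Threshold on the amplified difference signal, in
#'   (m/s^2)^2 at 200 Hz (per-sample differences are rescaled by `fs/200`
#'   before squaring at other rates so the value keeps its meaning).
#'   Default 1000.
#' @param s_threshold Threshold on the backward swing integral in m/s; a
#'   candidate is kept only if the integral falls below it. Default -3.
#' @param refractory Minimum spacing between initial contacts in seconds,
#'   roughly one ground-contact duration. Default 0.25.
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(h_threshold = 1000, s_threshold = -3,
                                refractory = 0.25) {
  if (h_threshold <= 0) stop("'h_threshold' must be > 0")
  if (s_threshold >= 0) stop("'s_threshold' must be < 0")
  if (refractory <= 0) stop("'refractory' must be > 0")
  structure(list(h_threshold = h_threshold, s_threshold = s_threshold,
                 refractory = refractory), class = "segmentation_params")
}

#' Amplified difference signal H
#'
#' `H[n] = (ay[n] - ay[n-1])^2` with `H[1] = 0`. An optional rescaling of the
#' difference by `fs/200` keeps the companion threshold calibrated at rates
#' other than 200 Hz.
#'
#' @param ay Dorsoventral acceleration series (m/s^2), length >= 2.
#' @param fs Sampling rate in Hz; differences are scaled by `fs/200`.
#' @return Nonnegative numeric vector, same length as `ay`.
#' @examples
#' amplified_difference_signal(c(0, 0, 50, 0))
#' @export
amplified_difference_signal <- function(ay, fs = 200) {
  if (length(ay) < 2L) stop("'ay' must have length >= 2")
  d <- c(0, diff(ay)) * (fs / 200)
  d * d
}

#' Backward swing-phase integral S
#'
#' Integrates `ay` backwards from the initial-contact candidate `n_ic` to the
#' nearest zero crossing at or before it (the first sample with `ay >= 0`
#' scanning backwards): `S = sum(ay[n_zc:n_ic]) / fs`. A markedly negative
#' value indicates the foot decelerated through late swing, confirming the
#' candidate.
#'
#' @param ay Dorsoventral acceleration series (m/s^2).
#' @param n_ic Candidate sample index (1-based), `1 < n_ic <= length(ay)`.
#' @param fs Sampling rate in Hz.
#' @return List with `s` (m/s), `n_zc` (index of the zero crossing) and
#'   `truncated` (`TRUE` when no zero crossing exists before `n_ic` and the
#'   integral covers the full available prefix).
#' @examples
#' ay <- c(5, rep(-10, 70))
#' swing_integral(ay, n_ic = 71, fs = 200)$s  # ~ -3.5
#' @export
swing_integral <- function(ay, n_ic, fs) {
  n <- length(ay)
  if (n_ic <= 1L || n_ic > n) stop("'n_ic' must satisfy 1 < n_ic <= length(ay)")
  nonneg <- which(ay[seq_len(n_ic)] >= 0)
  if (length(nonneg)) {
    n_zc <- max(nonneg)
    truncated <- FALSE
  } else {
    n_zc <- 1L
    truncated <- TRUE
  }
  list(s = sum(ay[n_zc:n_ic]) / fs, n_zc = n_zc, truncated = truncated)
}

#' Detect initial ground contacts
#'
#' Finds contiguous runs of the amplified difference signal above
#' `h_threshold`; each run contributes one candidate, placed at the sample
#' immediately before the run (the onset of the rise, where the impact has
#' not yet corrupted `ay`). Candidates whose backward swing integral does not
#' fall below `s_threshold` are rejected, and accepted contacts are enforced
#' to be at least one refractory period apart.
#'
#' @param rec An [imu_recording()].
#' @param params A [segmentation_params()].
#' @return Sorted integer vector of initial-contact sample indices (possibly
#'   empty).
#' @export
detect_initial_contacts <- function(rec, params = segmentation_params()) {
  stopifnot(inherits(rec, "imu_recording"))
  ay <- rec$a[, 2]
  fs <- rec$fs
  h <- amplified_difference_signal(ay, fs)
  above <- h > params$h_threshold
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_starts <- starts[r$values]
  ics <- integer(0)
  refr <- params$refractory * fs
  for (a0 in run_starts) {
    cand <- a0 - 1L
    if (cand <= 1L) next
    si <- swing_integral(ay, cand, fs)
    if (si$s >= params$s_threshold) next
    if (length(ics) && (cand - ics[length(ics)]) < refr) next
    ics <- c(ics, cand)
  }
  ics
}

#' Cut consecutive initial contacts into stride windows
#'
#' Window `i` is the half-open interval `[ics[i], ics[i+1])`. Windows whose
#' duration falls outside (0.2, 2.0) s are dropped with a warning.
#'
#' @param ics Sorted integer vector of initial-contact indices.
#' @param rec_len Recording length in samples.
#' @param fs Sampling rate in Hz.
#' @return A [stride_windows()] data frame (zero rows when fewer than two
#'   contacts survive).
#' @export
segment_strides <- function(ics, rec_len, fs) {
  if (is.unsorted(ics)) stop("'ics' must be sorted ascending")
  if (length(ics) < 2L)
    return(stride_windows(integer(0), integer(0), fs, rec_len))
  start <- ics[-length(ics)]
  end <- ics[-1]
  dur <- (end - start) / fs
  ok <- dur > 0.2 & dur < 2.0
  if (any(!ok))
    warning(sprintf("dropped %d stride window(s) outside the (0.2, 2.0) s duration bound",
                    sum(!ok)))
  stride_windows(start[ok], end[ok], fs, rec_len, anchor = "initial_contact")
}
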