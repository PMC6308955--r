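# Agreement statistics between reference and estimated stride parameters.
# The error sign convention is reference minus estimate throughout.

#' Reference velocity from positional ground truth
#'
#' `vref = dref * fs / Nstride`: stride length over stride time, with the
#' stride time expressed as a sample count.
#'
#' @param dref Reference stride length(s), m.
#' @param n_stride Samples between the two initial contacts (>= 1).
#' @param fs Sampling rate, Hz.
#' @return Reference velocity(ies), m/s.
#' @examples
#' reference_velocity(2.0, 160, 200)  # 2.5
#' @export
reference_velocity <- function(dref, n_stride, fs) {
  if (any(n_stride < 1)) stop("input error: 'n_stride' must be >= 1")
  dref * fs / n_stride
}

#' Error summary statistics
#'
#' Errors are `e_i = ref_i - est_i`. Reports the mean error (ME), its sample
#' standard deviation (n - 1 denominator; 0 when n = 1), the mean absolute
#' error (MAE) and the mean absolute percentage error
#' (`100 * mean(|e_i| / ref_i)`), which requires strictly nonzero references.
#'
#' @param ref,est Equal-length numeric vectors of reference and estimated
#'   values.
#' @param parameter Label, `"velocity"` or `"stride_length"`.
#' @return List of class `error_summary` with `me`, `std`, `mape`, `mae`,
#'   `n`, `parameter`.
#' @examples
#' error_summary(c(2, 2), c(2.1, 1.9))  # ME 0, MAE 0.1, MAPE 5
#' @export
error_summary <- function(ref, est, parameter = c("velocity", "stride_length")) {
  parameter <- match.arg(parameter)
  if (length(ref) != length(est)) stop("'ref' and 'est' lengths differ")
  n <- length(ref)
  if (n < 1L) stop("need at least one pair")
  if (any(ref == 0)) stop("metric error: MAPE undefined for zero reference values")
  e <- ref - est
  structure(list(me = mean(e),
                 std = if (n > 1L) sd(e) else 0,
                 mape = 100 * mean(abs(e) / abs(ref)),
                 mae = mean(abs(e)),
                 n = n, parameter = parameter),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("%s: ME %.4f +/- %.4f, MAPE %.2f%%, MAE %.4f (n = %d)\n",
              x$parameter, x$me, x$std, x$mape, x$mae, x$n))
  invisible(x)
}

#' Bland-Altman agreement data
#'
#' Pairwise means `(ref + est)/2` and differences `ref - est`, the bias
#' (mean difference) and the 95% limits of agreement
#' `bias +/- 1.96 * sd(diff)`.
#'
#' @param ref,est Equal-length numeric vectors, n >= 2.
#' @return List of class `bland_altman` with `means`, `diffs`, `bias`,
#'   `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(ref, est) {
  if (length(ref) != length(est)) stop("'ref' and 'est' lengths differ")
  if (length(ref) < 2L) stop("input error: Bland-Altman needs n >= 2")
  diffs <- ref - est
  bias <- mean(diffs)
  half <- 1.96 * sd(diffs)
  structure(list(means = (ref + est) / 2, diffs = diffs, bias = bias,
                 loa_lower = bias - half, loa_upper = bias + half),
            class = "bland_altman")
}

#' Leave-one-subject-out folds
#'
#' One fold per distinct subject: that subject forms the test set and all
#' others the training set, so no fold ever trains on its test subject and
#' the test sets cover every subject exactly once.
#'
#' @param subject_ids Vector of subject identifiers (>= 2 distinct).
#' @return List of folds, each a list with `train` (character vector) and
#'   `test` (single id).
#' @export
loso_folds <- function(subject_ids) {
  ids <- unique(as.character(subject_ids))
  if (length(ids) < 2L) stop("input error: need >= 2 distinct subjects")
  lapply(ids, function(id) list(train = setdiff(ids, id), test = id))
}

#' Cumulative-distance mean absolute error
#'
#' Per session, the estimated total distance is the sum of the estimated
#' stride lengths; the result is the mean absolute deviation from the true
#' distance over sessions.
#'
#' @param estimates_per_session List of numeric vectors of stride lengths
#'   (or of [stride_estimates()] data frames).
#' @param true_distance True session distance(s) in m (scalar or one per
#'   session).
#' @return Mean absolute error in m.
#' @examples
#' total_distance_error(list(rep(2, 5)), 10.5)  # 0.5
#' @export
total_distance_error <- function(estimates_per_session, true_distance) {
  if (!length(estimates_per_session)) stop("need at least one session")
  dist <- vapply(estimates_per_session, function(e) {
    if (is.data.frame(e)) sum(e$stride_length) else sum(e)
  }, numeric(1))
  true_distance <- rep_len(true_distance, length(dist))
  mean(abs(dist - true_distance))
}

#' Velocity-bin summaries
#'
#' Convenience wrapper: [error_summary()] per reference-velocity bin with
#' edges `[2,3), [3,4), [4,5), [5,6]`.
#'
#' @param ref,est Reference and estimated values.
#' @param vref Reference velocities used for binning (defaults to `ref`).
#' @param parameter Passed to [error_summary()].
#' @return Named list of `error_summary` objects (bins with no data are
#'   dropped).
#' @export
binned_error_summary <- function(ref, est, vref = ref,
                                 parameter = c("velocity", "stride_length")) {
  parameter <- match.arg(parameter)
  edges <- list(`2-3` = c(2, 3), `3-4` = c(3, 4), `4-5` = c(4, 5), `5-6` = c(5, 6))
  out <- list()
  for (nm in names(edges)) {
    e <- edges[[nm]]
    sel <- if (nm == "5-6") vref >= e[1] & vref <= e[2] else vref >= e[1] & vref < e[2]
    if (any(sel)) out[[nm]] <- error_summary(ref[sel], est[sel], parameter)
  }
  out
}
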