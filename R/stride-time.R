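# Stride-time estimator: gender-specific step functions of relative stride
# length (stride length / body height) over stride duration, taken from the
# running-biomechanics literature. Velocity follows as length / time.

.stridekit_env <- new.env(parent = emptyenv())

#' Step-function table of relative stride length
#'
#' Returns the packaged step function relating stride time (s) to relative
#' stride length (stride lengths per body height) for one gender. Rows are
#' half-open intervals `(t_lower, t_upper]` that partition (0, Inf); relative
#' stride length is non-increasing in stride time (faster cadence, longer
#' relative stride).
#'
#' @param gender `"male"` (13 rows) or `"female"` (9 rows).
#' @return Data frame with columns `t_lower`, `t_upper`, `d_rel`.
#' @export
stride_length_table <- function(gender = c("male", "female")) {
  gender <- match.arg(gender)
  if (is.null(.stridekit_env$step_table)) {
    path <- system.file("extdata", "stride_length_steps.csv",
                        package = "stridekit", mustWork = TRUE)
    .stridekit_env$step_table <- read.csv(path, stringsAsFactors = FALSE)
  }
  tab <- .stridekit_env$step_table
  tab <- tab[tab$gender == gender, c("t_lower", "t_upper", "d_rel")]
  tab <- tab[order(tab$t_lower), ]
  rownames(tab) <- NULL
  validate_step_table(tab, gender)
  tab
}

validate_step_table <- function(tab, gender) {
  expected_rows <- if (gender == "male") 13L else 9L
  if (nrow(tab) != expected_rows)
    stop(sprintf("step table for %s must have %d rows", gender, expected_rows))
  if (tab$t_lower[1] != 0 || !is.infinite(tab$t_upper[nrow(tab)]) ||
      any(tab$t_upper[-nrow(tab)] != tab$t_lower[-1]))
    stop("step-table intervals must partition (0, Inf) without gaps or overlaps")
  if (is.unsorted(rev(tab$d_rel)))
    stop("relative stride length must be non-increasing in stride time")
  invisible(tab)
}

#' Stride time from a stride window
#'
#' `(end - start) / fs`, i.e. the sample count between two consecutive
#' initial ground contacts divided by the sampling rate.
#'
#' @param windows A [stride_windows()] data frame (or any data frame with
#'   `start`/`end` columns).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of stride durations in seconds.
#' @export
stride_time_from_window <- function(windows, fs) {
  (windows$end - windows$start) / fs
}

#' Relative stride length lookup
#'
#' Looks up the gender-specific step function at the given stride time using
#' the half-open convention `(t_lower, t_upper]`.
#'
#' @param tstride Stride time(s) in seconds, > 0.
#' @param gender `"male"` or `"female"`.
#' @return Relative stride length(s) (dimensionless).
#' @examples
#' relative_stride_length(0.75, "male")   # 1.080
#' relative_stride_length(0.65, "female") # 1.720
#' @export
relative_stride_length <- function(tstride, gender) {
  gender <- match.arg(gender, c("male", "female"))
  if (any(!is.finite(tstride)) || any(tstride <= 0))
    stop("'tstride' must be positive and finite")
  tab <- stride_length_table(gender)
  # interval i is (t_lower[i], t_upper[i]]: the first row with tstride <= t_upper
  idx <- vapply(tstride, function(t) which(t <= tab$t_upper)[1], integer(1))
  tab$d_rel[idx]
}

#' Stride-time estimator
#'
#' Per stride: `dstride = height * d_rel(tstride, gender)` and
#' `vstride = dstride / tstride`.
#'
#' @param windows A [stride_windows()] data frame (initial-contact anchored).
#' @param subject A [subject_info()] (gender and height are required).
#' @param fs Sampling rate in Hz.
#' @return A [stride_estimates()] data frame with algorithm tag
#'   `"stride_time"`.
#' @examples
#' w <- stride_windows(1, 151, fs = 200, rec_len = 200)
#' s <- subject_info("s1", "male", 1.80)
#' estimate_strides_stride_time(w, s, fs = 200)
#' @export
estimate_strides_stride_time <- function(windows, subject, fs) {
  stopifnot(inherits(subject, "subject_info"))
  tstride <- stride_time_from_window(windows, fs)
  d_rel <- relative_stride_length(tstride, subject$gender)
  stride_estimates(subject$height * d_rel, tstride, algorithm = "stride_time")
}
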