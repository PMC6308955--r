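# Shared fixtures: all simulated in code, nothing stored on disk.

quick_session <- function(velocity = 3.0, n_strides = 6L, ...) {
  simulate_session(simulation_config(velocity = velocity, ...), n_strides)
}

# padded stride windows + targets + subject metadata from a simulated cohort
cohort_training_set <- function(cohort, input_len = 200L) {
  xs <- list(); ys <- numeric(0); tref <- numeric(0); subjects <- list()
  for (sub in cohort) {
    for (ses in sub$sessions) {
      gt <- ses$ground_truth
      sig <- cbind(ses$recording$a, ses$recording$g)
      for (i in seq_len(nrow(gt))) {
        if (gt$n_stride[i] > input_len) next
        seg <- sig[gt$ic[i]:(gt$ic[i] + gt$n_stride[i] - 1L), , drop = FALSE]
        xs[[length(xs) + 1L]] <- pad_stride_to_fixed_length(seg, input_len)
        ys <- c(ys, gt$dref[i])
        tref <- c(tref, gt$tref[i])
        subjects[[length(subjects) + 1L]] <- sub$subject
      }
    }
  }
  list(x = array(unlist(xs), c(input_len, 6L, length(xs))),
       y = ys, tref = tref, subjects = subjects)
}

# write a small IMU CSV and return its path
write_temp_imu <- function(rec) {
  f <- tempfile(fileext = ".csv")
  write_imu_csv(rec, f)
  f
}
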