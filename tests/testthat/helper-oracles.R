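# Independent oracle for tolerance-window matching: dynamic program over
# the two sorted sequences computing the maximum number of one-to-one
# pairs with |d - r| <= tol. On a line with a uniform window an optimal
# matching can always be taken non-crossing (exchange argument), so the
# DP explores the full optimum while sharing no code with the greedy
# implementation under test.
oracle_max_matching <- function(det, ref, tol) {
  nd <- length(det)
  nr <- length(ref)
  if (nd == 0L || nr == 0L) return(0L)
  M <- matrix(0L, nd + 1L, nr + 1L)
  for (i in nd:1) {
    for (j in nr:1) {
      best <- max(M[i + 1L, j], M[i, j + 1L])
      if (abs(det[i] - ref[j]) <= tol) {
        best <- max(best, 1L + M[i + 1L, j + 1L])
      }
      M[i, j] <- best
    }
  }
  M[1L, 1L]
}

# recording with a prescribed vertical (z) acceleration signal on top of
# gravity; x/y axes zero
make_rec <- function(z_dyn, rate = 100, gyro = NULL) {
  n <- length(z_dyn)
  t <- (0:(n - 1)) / rate
  imu_recording(t, cbind(0, 0, 9.80665 + z_dyn), gyro = gyro,
                sampling_rate = rate)
}

# quick F1 against a ground truth at the standard tolerance
recovery_f1 <- function(result, truth, tol = 0.3) {
  match_steps(result$step_times, truth$step_times, tolerance_s = tol)$f1
}
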