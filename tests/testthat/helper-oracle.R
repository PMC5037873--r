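# Independent brute-force oracles used across the test files.
#
# rk4_fd_oracle integrates the full six-component arm with a fixed-step
# classical Runge-Kutta scheme and method-of-steps handling of the pure
# transport delay.  It shares no code with the package's solver path: the
# gut/enterocyte pair is integrated numerically (the package uses their
# closed form) and the delayed enterocyte history is read from a stored
# half-step grid, so the step is chosen to make the delay an exact
# multiple of the half-step.

rk4_fd_oracle <- function(params, arm, t_max, h_target = 2.5e-4) {
  k <- retikin:::arm_coefficients(params, arm)
  a <- k$k_in + k$k_loss
  b <- k$k_chain + k$k_direct
  # half-step grid aligned with the delay
  h2 <- if (k$dt > 0) k$dt / max(1, round(k$dt / (h_target / 2)))
        else h_target / 2
  h <- 2 * h2
  n2 <- ceiling(t_max / h2)
  lag <- if (k$dt > 0) as.integer(round(k$dt / h2)) else 0L

  # phase 1: gut + enterocyte on the half-step grid
  q2hist <- numeric(n2 + 1)
  q1 <- 1; q2 <- 0
  f12 <- function(q1, q2) c(-a * q1, k$k_in * q1 - b * q2)
  for (i in seq_len(n2)) {
    k1 <- f12(q1, q2)
    k2 <- f12(q1 + h2 / 2 * k1[1], q2 + h2 / 2 * k1[2])
    k3 <- f12(q1 + h2 / 2 * k2[1], q2 + h2 / 2 * k2[2])
    k4 <- f12(q1 + h2 * k3[1], q2 + h2 * k3[2])
    q1 <- q1 + h2 / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    q2 <- q2 + h2 / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    q2hist[i + 1] <- q2
  }
  o3_at <- function(j2) {        # delayed inflow at half-step index j2
    jj <- j2 - lag
    if (jj < 0) 0 else k$k_chain * q2hist[jj + 1]
  }

  # phase 2: liver + plasma + stores on the full-step grid
  n <- floor(n2 / 2)
  times <- h * (0:n)
  out <- matrix(0, n + 1, 3)
  y <- c(0, 0, 0)
  f456 <- function(y, o3, q2v)
    c(o3 - k$k_liver * y[1],
      k$k_liver * y[1] + k$k_direct * q2v + k$L56 * y[3] - k$L65 * y[2],
      k$L65 * y[2] - (k$L56 + k$L106) * y[3])
  for (i in seq_len(n)) {
    j0 <- 2L * (i - 1L)         # half-step index of t_i
    k1 <- f456(y, o3_at(j0), q2hist[j0 + 1])
    k2 <- f456(y + h / 2 * k1, o3_at(j0 + 1L), q2hist[j0 + 2])
    k3 <- f456(y + h / 2 * k2, o3_at(j0 + 1L), q2hist[j0 + 2])
    k4 <- f456(y + h * k3, o3_at(j0 + 2L), q2hist[j0 + 3])
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- y
  }
  data.frame(time = times, q4 = out[, 1], q5 = out[, 2], q6 = out[, 3])
}

# Random valid subject parameters (for property-style tests).
random_subject_params <- function() {
  r <- function(m) m * exp(stats::rnorm(1, 0, 0.5))
  subject_params(
    retinol_arm_params(L21 = r(24.2), L52 = r(0.114),
                       DT3 = min(r(0.113), 0.9), L54 = r(2.98),
                       L65 = r(5.5), L56 = r(0.169), L106 = r(0.0599)),
    carotene_arm_params(P11 = r(10.9), L1512 = r(0.11),
                        DT13 = min(r(0.152), 0.9), L1514 = r(1.43))
  )
}

# Clean simulated observation pair at the study schedule.
clean_observed_pair <- function(params = reference_mean_params(),
                                schedule = default_schedule()) {
  mk <- function(arm) {
    cv <- simulate_fd(params, arm, schedule)
    tracer_curve(arm, cv$time, cv$fd, observed = TRUE)
  }
  list(C10 = mk("C10"), C5 = mk("C5"))
}
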