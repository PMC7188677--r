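# Independent oracles used across tests.

# global (whole-frame) speckle variance, population moments
global_k2 <- function(frame) {
  m <- mean(frame)
  mean((frame - m)^2) / m^2
}

# time-integrated contrast of an exponentially decorrelating field, by
# numerical quadrature: K^2 = 2 * int_0^1 (1-u) * |g1(T u)|^2 du with
# g1(t) = exp(-t/tau_c), plus the heterodyne cross term for rho < 1.
oracle_k2_dynamic <- function(x) {
  2 * integrate(function(u) (1 - u) * exp(-2 * x * u), 0, 1,
                rel.tol = 1e-12)$value
}

oracle_k2_cross <- function(x) {
  integrate(function(u) (1 - u) * exp(-x * u), 0, 1, rel.tol = 1e-12)$value
}

oracle_k2_model <- function(x, beta = 1, rho = 1, upsilon_n = 0) {
  beta * rho^2 * sapply(x, oracle_k2_dynamic) +
    4 * beta * rho * (1 - rho) * sapply(x, oracle_k2_cross) + upsilon_n
}

# brute-force windowed contrast: per-pixel double loop, shrink-to-bounds,
# population sigma, valid-pixel restriction
brute_spatial_k <- function(frame, window, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(frame), ncol(frame))
  h <- window %/% 2
  K <- matrix(NA_real_, nrow(frame), ncol(frame))
  cnt <- matrix(0L, nrow(frame), ncol(frame))
  for (j in seq_len(ncol(frame))) {
    for (i in seq_len(nrow(frame))) {
      ii <- max(1, i - h):min(nrow(frame), i + h)
      jj <- max(1, j - h):min(ncol(frame), j + h)
      block <- frame[ii, jj]
      ok <- valid[ii, jj]
      v <- block[ok]
      cnt[i, j] <- length(v)
      if (length(v) == 0) next
      m <- mean(v)
      if (m > 0) K[i, j] <- sqrt(mean((v - m)^2)) / m
    }
  }
  list(K = K, count = cnt)
}

# per-frame mean K^2 of a simulated uniform stack, with its standard error
stack_k2_stats <- function(stack) {
  k2 <- apply(stack$frames, 3, global_k2)
  list(mean = mean(k2), se = sd(k2) / sqrt(length(k2)))
}

quiet <- function(expr) withCallingHandlers(
  expr, warning = function(w) invokeRestart("muffleWarning"))

# Effective speckle-averaging factor of the windowed contrast estimator,
# calibrated once from an ergodic (rho = 1) uniform-tau simulation: the
# small-sample bias of the 5x5 window is multiplicative in K^2 and plays the
# role of beta, exactly as a baseline fit would absorb it.
calibrate_window_beta <- function(window = 5, x_cal = 2, tau = 1e-3,
                                  n_frames = 40, seed = 777) {
  st <- simulate_stack(matrix(tau, 64, 64),
                       sim_config(x_cal * tau, n_frames = n_frames, rho = 1,
                                  noise_floor = 0, quantize = FALSE,
                                  seed = seed))
  nr <- quiet(noise_reduced_contrast(st, window))
  trim <- (window %/% 2) + 1
  inner <- nr$K_squared[trim:(64 - trim), trim:(64 - trim)]
  mean(inner) / model_k_squared(x_cal * tau, tau)
}
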