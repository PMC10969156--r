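# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately naive (scalar loops, closed forms) so it
# stays independent of the vectorized implementation paths it checks.

# scalar, per-trajectory transcription of the first-order oscillator system
scalar_drift_oracle <- function(state, p) {
  out <- matrix(0, nrow(state), 4)
  for (i in seq_len(nrow(state))) {
    x1 <- state[i, 1]; x2 <- state[i, 2]; x3 <- state[i, 3]; x4 <- state[i, 4]
    out[i, 1] <- x3
    out[i, 2] <- x4
    out[i, 3] <- -(p$k1 + p$k2) * x1 + p$k2 * x2 - p$b1 * x1^3 -
      p$b2 * (x1 - x2)^3 + p$eps1 * x3 * (1 - x1^2)
    out[i, 4] <- p$k2 * x1 - p$k2 * x2 + p$b2 * (x1 - x2)^3 +
      p$eps2 * x4 * (1 - x2^2)
  }
  out
}

# hist_pdf with analytic Gaussian bin masses (CDF differences)
gaussian_pdf_on_grid <- function(mean, sd, grid, t = NA_real_) {
  mass <- diff(pnorm(grid$edges, mean, sd))
  mass <- mass / sum(mass)
  structure(list(grid = grid, mass = mass, t = t, n_samples = NA_integer_),
            class = "hist_pdf")
}

# instantaneous information rate of a Gaussian family: (mu'^2 + 2 sd'^2)/sd^2
gaussian_gamma <- function(mu_dot, sigma, sigma_dot = 0) {
  sqrt((mu_dot^2 + 2 * sigma_dot^2) / sigma^2)
}

# forward-difference information rate between two Gaussians, from the
# Bhattacharyya coefficient closed form (same functional as the estimator,
# evaluated on the exact continuous densities)
gaussian_gamma_fd <- function(m1, s1, m2, s2, dt) {
  bc <- sqrt(2 * s1 * s2 / (s1^2 + s2^2)) *
    exp(-(m1 - m2)^2 / (4 * (s1^2 + s2^2)))
  (2 / dt) * sqrt(2 - 2 * bc)
}

# Ornstein-Uhlenbeck closed forms: dX = -theta X dt + q dW
ou_mean <- function(t, mean0, theta) mean0 * exp(-theta * t)
ou_var <- function(t, sd0, theta, q) {
  q^2 / (2 * theta) + (sd0^2 - q^2 / (2 * theta)) * exp(-2 * theta * t)
}

# joint_hist whose mass is an exact outer product of 1-D mass vectors
product_joint <- function(mass_list, grids, times = NULL) {
  m <- Reduce(function(a, b) outer(a, b), mass_list)
  if (is.null(times)) times <- rep(NA_real_, length(mass_list))
  structure(list(grids = grids, mass = array(m, dim = vapply(mass_list,
                                                             length, 0L)),
                 times = times, n_samples = NA_integer_),
            class = "joint_hist")
}

# quick measure_series over a uniform time base
make_series <- function(values, delta_t = 1e-4, t0 = 0, name = "m") {
  measure_series(name, t0 + (seq_along(values) - 1) * delta_t, values,
                 delta_t)
}

# slice collector consumer: records every emitted (t, x1, x2[, x3, x4])
slice_collector <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- list(); e$x1 <- list(); e$x2 <- list(); e$x3 <- list()
  e$x4 <- list()
  list(
    consumer = function(t, x1, x2, x3 = NULL, x4 = NULL) {
      k <- length(e$t) + 1L
      e$t[[k]] <- t; e$x1[[k]] <- x1; e$x2[[k]] <- x2
      if (!is.null(x3)) { e$x3[[k]] <- x3; e$x4[[k]] <- x4 }
    },
    env = e)
}
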