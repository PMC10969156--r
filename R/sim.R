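#' Simulation configuration
#'
#' @param dt integrator step size in model time units (published runs use
#'   1e-6 to cope with the large stiffness coefficients).
#' @param record_dt recording cadence; must be an integer multiple of `dt`
#'   (published runs use 1e-4, the interval at which densities are
#'   estimated).
#' @param t_end final time (published runs use 10).
#' @param t_start initial time, default 0.
#' @return An object of class `simulation_config` with derived fields
#'   `steps_per_record`, `n_steps` and `n_records`.
#' @export
#' @examples
#' cfg <- simulation_config(dt = 1e-3, record_dt = 1e-3, t_end = 1e-2)
#' n_slices(cfg)  # 11
simulation_config <- function(dt = 1e-6, record_dt = 1e-4, t_end = 10,
                              t_start = 0) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(record_dt) || record_dt <= 0) stop("record_dt must be > 0")
  if (!is.finite(t_end) || t_end <= t_start)
    stop("t_end must exceed t_start")
  spr <- record_dt / dt
  if (abs(spr - round(spr)) > 1e-6 * spr)
    stop("record_dt must be an integer multiple of dt")
  n_rec <- (t_end - t_start) / record_dt
  if (abs(n_rec - round(n_rec)) > 1e-6)
    stop("(t_end - t_start) must be an integer multiple of record_dt")
  structure(list(dt = dt, record_dt = record_dt, t_end = t_end,
                 t_start = t_start,
                 steps_per_record = as.integer(round(spr)),
                 n_records = as.integer(round(n_rec)),
                 n_steps = round(spr) * round(n_rec)),
            class = "simulation_config")
}

#' Number of recorded state slices for a configuration
#'
#' Recording includes the initial state at `t_start`, so a run emits
#' `n_records + 1` slices at times `t_start + m * record_dt`,
#' `m = 0..n_records`.
#'
#' @param config a [simulation_config()].
#' @return integer slice count.
#' @export
n_slices <- function(config) config$n_records + 1L

#' Deterministic drift field of the coupled oscillator
#'
#' Evaluates the deterministic right-hand side of the first-order system
#' \deqn{\dot x_1 = x_3,\quad \dot x_2 = x_4,}
#' \deqn{\dot x_3 = -(k_1+k_2)x_1 + k_2 x_2 - b_1 x_1^3 - b_2 (x_1-x_2)^3
#'   + \epsilon_1 x_3 (1 - x_1^2),}
#' \deqn{\dot x_4 = k_2 x_1 - k_2 x_2 + b_2 (x_1-x_2)^3
#'   + \epsilon_2 x_4 (1 - x_2^2),}
#' noise excluded. Pure function of the state.
#'
#' @param state n x 4 numeric matrix of (x1, x2, x3, x4) rows, or a
#'   length-4 vector for a single trajectory.
#' @param params an [oscillator_params()].
#' @return n x 4 matrix of time derivatives.
#' @export
drift_field <- function(state, params) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  stopifnot(ncol(state) == 4L)
  x1 <- state[, 1]; x2 <- state[, 2]; x3 <- state[, 3]; x4 <- state[, 4]
  d3 <- (x1 - x2)^3
  f3 <- -(params$k1 + params$k2) * x1 + params$k2 * x2 -
    params$b1 * x1^3 - params$b2 * d3 + params$eps1 * x3 * (1 - x1^2)
  f4 <- params$k2 * x1 - params$k2 * x2 + params$b2 * d3 +
    params$eps2 * x4 * (1 - x2^2)
  cbind(x3, x4, f3, f4, deparse.level = 0)
}

#' One Euler-Maruyama step
#'
#' Advances every trajectory by `x + drift * dt`, then adds the stochastic
#' increment `mu_noise * sqrt(dt) * noise` to the fourth component only
#' (white noise enters the model solely through the second oscillator's
#' velocity equation).
#'
#' @param state n x 4 state matrix.
#' @param params an [oscillator_params()].
#' @param dt step size (> 0).
#' @param noise length-n vector of standard-normal draws.
#' @return the advanced n x 4 state matrix.
#' @export
em_step <- function(state, params, dt, noise) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (length(noise) != nrow(state))
    stop("noise must supply one draw per trajectory")
  out <- state + drift_field(state, params) * dt
  out[, 4] <- out[, 4] + params$mu_noise * sqrt(dt) * noise
  if (any(!is.finite(out)))
    stop("integration blow-up: non-finite state after an Euler-Maruyama step")
  out
}

#' Draw the initial ensemble
#'
#' Four independent Gaussian columns with the specified means and common
#' standard deviation, reproducible from `spec$seed` (drawn with R's RNG;
#' the integrator's per-step noise uses a separate internal stream seeded
#' from the same value).
#'
#' @param spec an [initial_ensemble_spec()].
#' @return `n_traj` x 4 numeric matrix.
#' @export
sample_initial_ensemble <- function(spec) {
  stopifnot(inherits(spec, "initial_ensemble_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_traj
  matrix(rnorm(4L * n, mean = rep(spec$means, each = n), sd = spec$sigma),
         nrow = n, ncol = 4L)
}

#' Simulate a trajectory ensemble, streaming recorded slices to a consumer
#'
#' Integrates the coupled Duffing-van der Pol SDE with the Euler-Maruyama
#' scheme from `t_start` to `t_end`. At every recording time (multiples of
#' `record_dt`, including `t_start`) the consumer is called as
#' `consumer(t, x1, x2)` (or `consumer(t, x1, x2, x3, x4)` when
#' `record_vars = "all"`). The full per-step history is never retained:
#' memory stays proportional to the ensemble size, which is what makes
#' large-ensemble runs feasible. A non-finite state aborts with an error
#' naming the recording interval in which the blow-up occurred.
#'
#' @param params an [oscillator_params()].
#' @param spec an [initial_ensemble_spec()].
#' @param config a [simulation_config()].
#' @param consumer an R function receiving each recorded slice.
#' @param record_vars `"x1x2"` (default; the downstream estimators use only
#'   the two position signals) or `"all"`.
#' @return invisibly, the number of slices emitted.
#' @export
#' @examples
#' counter <- local({n <- 0L; function(t, x1, x2) n <<- n + 1L})
#' simulate_ensemble(preset_params("ctl_ec"), preset_ic(4, 100),
#'                   simulation_config(1e-5, 1e-4, t_end = 1e-3), counter)
simulate_ensemble <- function(params, spec, config, consumer,
                              record_vars = c("x1x2", "all")) {
  stopifnot(inherits(params, "oscillator_params"),
            inherits(spec, "initial_ensemble_spec"),
            inherits(config, "simulation_config"),
            is.function(consumer))
  record_vars <- match.arg(record_vars)
  state <- sample_initial_ensemble(spec)
  par <- c(params$k1, params$k2, params$b1, params$b2,
           params$eps1, params$eps2, params$mu_noise)
  # distinct 64-bit stream seed derived from the user's integer seed
  noise_seed <- abs(spec$seed) * 2654435761 + 1
  .sim_oscillator(state, par, config$t_start, config$dt, config$record_dt,
                  config$steps_per_record, config$n_records, noise_seed,
                  consumer, identical(record_vars, "all"))
  invisible(n_slices(config))
}

#' Simulate an Ornstein-Uhlenbeck ensemble (estimator-validation process)
#'
#' Evolves `dX = -theta X dt + q dW` for an ensemble of trajectories with
#' the same Euler-Maruyama machinery and noise stream as
#' [simulate_ensemble()]. The OU process has closed-form Gaussian marginals
#' \eqn{\mu(t) = \mu_0 e^{-\theta t}}, \eqn{\sigma^2(t) = q^2/(2\theta) +
#' (\sigma_0^2 - q^2/(2\theta)) e^{-2\theta t}}, making it the standard
#' analytic benchmark for the density and information-rate estimators.
#'
#' @param n_traj ensemble size.
#' @param theta relaxation rate (> 0).
#' @param q noise intensity.
#' @param mean0,sd0 initial Gaussian mean and standard deviation.
#' @param config a [simulation_config()].
#' @param consumer function called as `consumer(t, x)` per recorded slice.
#' @param seed integer seed.
#' @return invisibly, the number of slices emitted.
#' @export
simulate_ou_ensemble <- function(n_traj, theta, q, mean0, sd0, config,
                                 consumer, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"), is.function(consumer),
            theta > 0, n_traj >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x0 <- rnorm(n_traj, mean0, sd0)
  noise_seed <- abs(seed) * 2654435761 + 1
  .sim_ou(x0, theta, q, config$t_start, config$dt, config$record_dt,
          config$steps_per_record, config$n_records, noise_seed, consumer)
  invisible(n_slices(config))
}
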