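#' Streaming measure accumulator for recorded slices
#'
#' Builds the consumer used by [run_condition()]: at each recorded slice it
#' pairs the incoming slice with the previous one and evaluates, at the
#' earlier time, every requested measure on shared grids built from the
#' pooled pair. Only the previous slice and the scalar measure values are
#' retained, so memory stays fixed regardless of run length.
#'
#' Per evaluation time the accumulator computes: information rates
#' `gamma_x1`, `gamma_x2`; differential entropies `h_x1`, `h_x2` (nats, on
#' the current slice); causal information rates `gamma_x2_to_x1`,
#' `gamma_x1_to_x2` (joint-consistent marginals); transfer entropies
#' `te_x2_to_x1`, `te_x1_to_x2` (bits). Marginal grids use
#' `bin_policy(n, 1)` bins, 2-D lagged joints `bin_policy(n, 2)` per axis,
#' 3-D history joints `bin_policy(n, 3)` per axis.
#'
#' @param measures character subset of
#'   `c("gamma", "entropy", "causal", "te")`.
#' @param bin_policy `function(n_samples, n_dim)` giving per-axis bin
#'   counts; default [joint_bins()].
#' @return A list with `consumer` (pass to [simulate_ensemble()]) and
#'   `results()` (call after the run; returns a named list of
#'   [measure_series()]).
#' @export
#' @examples
#' acc <- measure_accumulator(measures = "gamma")
#' simulate_ensemble(preset_params("ad_ec"), preset_ic(4, 2000),
#'                   simulation_config(1e-5, 1e-4, t_end = 2e-3),
#'                   acc$consumer)
#' names(acc$results())
measure_accumulator <- function(measures = c("gamma", "entropy", "causal",
                                             "te"),
                                bin_policy = joint_bins) {
  measures <- match.arg(measures, several.ok = TRUE)
  e <- new.env(parent = emptyenv())
  e$prev_t <- NULL
  e$t <- numeric(0)
  keys <- c(
    if ("gamma" %in% measures) c("gamma_x1", "gamma_x2"),
    if ("entropy" %in% measures) c("h_x1", "h_x2"),
    if ("causal" %in% measures) c("gamma_x2_to_x1", "gamma_x1_to_x2"),
    if ("te" %in% measures) c("te_x2_to_x1", "te_x1_to_x2"))
  for (k in keys) e[[k]] <- numeric(0)
  e$k <- 0L
  e$cap <- 0L

  grow <- function(need) {
    if (need > e$cap) {
      newcap <- max(1024L, 2L * e$cap)
      pad <- numeric(newcap - e$cap)
      e$t <- c(e$t, pad)
      for (kk in keys) e[[kk]] <- c(e[[kk]], pad)
      e$cap <- newcap
    }
  }

  causal_pair <- function(b_now, b_next, a_now, t, t2, nb) {
    gb <- build_grid(list(b_now, b_next), nb)
    ga <- build_grid(a_now, nb)
    j0 <- estimate_joint(list(b_now, a_now), list(gb, ga), times = c(t, t))
    j1 <- estimate_joint(list(b_next, a_now), list(gb, ga),
                         times = c(t2, t))
    causal_information_rate(j0, j1)
  }

  te_pair <- function(b_now, b_next, a_now, t, t2, nb) {
    gb <- build_grid(list(b_now, b_next), nb)
    ga <- build_grid(a_now, nb)
    transfer_entropy(estimate_joint(list(b_next, b_now, a_now),
                                    list(gb, gb, ga),
                                    times = c(t2, t, t)))
  }

  consumer <- function(t, x1, x2) {
    if (!is.null(e$prev_t)) {
      t0 <- e$prev_t
      n <- length(x1)
      k <- e$k + 1L
      grow(k)
      e$t[k] <- t0
      if ("gamma" %in% measures || "entropy" %in% measures) {
        for (v in c("x1", "x2")) {
          prev <- if (v == "x1") e$prev_x1 else e$prev_x2
          cur <- if (v == "x1") x1 else x2
          g <- build_grid(list(prev, cur), bin_policy(n, 1L))
          p0 <- estimate_pdf(prev, g, t = t0)
          if ("gamma" %in% measures) {
            p1 <- estimate_pdf(cur, g, t = t)
            e[[paste0("gamma_", v)]][k] <- information_rate(p0, p1)
          }
          if ("entropy" %in% measures)
            e[[paste0("h_", v)]][k] <- differential_entropy(p0)
        }
      }
      if ("causal" %in% measures) {
        nb <- bin_policy(n, 2L)
        e$gamma_x2_to_x1[k] <- causal_pair(e$prev_x1, x1, e$prev_x2,
                                           t0, t, nb)
        e$gamma_x1_to_x2[k] <- causal_pair(e$prev_x2, x2, e$prev_x1,
                                           t0, t, nb)
      }
      if ("te" %in% measures) {
        nb <- bin_policy(n, 3L)
        e$te_x2_to_x1[k] <- te_pair(e$prev_x1, x1, e$prev_x2, t0, t, nb)
        e$te_x1_to_x2[k] <- te_pair(e$prev_x2, x2, e$prev_x1, t0, t, nb)
      }
      if (is.null(e$delta_t)) e$delta_t <- t - t0
      e$k <- k
    }
    e$prev_t <- t
    e$prev_x1 <- x1
    e$prev_x2 <- x2
    invisible(NULL)
  }

  results <- function() {
    if (e$k == 0L) stop("no measure evaluations accumulated")
    tt <- e$t[seq_len(e$k)]
    units <- c(gamma_x1 = "1/time", gamma_x2 = "1/time",
               h_x1 = "nats", h_x2 = "nats",
               gamma_x2_to_x1 = "1/time", gamma_x1_to_x2 = "1/time",
               te_x2_to_x1 = "bits", te_x1_to_x2 = "bits")
    out <- lapply(keys, function(kk)
      measure_series(kk, tt, e[[kk]][seq_len(e$k)], e$delta_t,
                     units = units[[kk]]))
    names(out) <- keys
    out
  }

  list(consumer = consumer, results = results)
}
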