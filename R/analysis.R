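# Stationary-window statistics, measure distributions, spectra and the
# end-to-end per-condition pipeline.

# Select the stationary evaluation times of a measure series: values whose
# defining slice pair (t, t + delta_t) lies inside [window_start, t_end).
# With the published cadence (delta_t = 1e-4, t_end = 10, window 7.5) this
# selects exactly 24,999 samples: 25,000 recorded densities in the window
# give 24,999 adjacent pairs.
.window_index <- function(series, window_start, t_end = NULL) {
  if (is.null(t_end)) t_end <- max(series$t) + series$delta_t
  tol <- 1e-9 * max(1, abs(t_end))
  which(series$t >= window_start - tol &
        series$t < (t_end - series$delta_t) - tol)
}

#' Stationary-window summary of a measure series
#'
#' Mean and sample standard deviation (n - 1 denominator) of the measure
#' over evaluation times in the stationary window `[window_start, t_end)`.
#' A value at time t consumes density slices at t and t + delta_t, so the
#' last admissible evaluation time is `t_end - 2 * delta_t`; for the
#' published configuration (window 7.5, t_end 10, delta_t 1e-4) the window
#' holds exactly 24,999 samples.
#'
#' @param series a [measure_series()].
#' @param window_start start of the stationary window (published runs
#'   use 7.5).
#' @param t_end end of the window; defaults to the series' natural end
#'   (last evaluation time + delta_t).
#' @return An object of class `stationary_summary`: list with `measure`,
#'   `window_start`, `n_samples`, `mean`, `sd`.
#' @export
stationary_summary <- function(series, window_start, t_end = NULL) {
  stopifnot(inherits(series, "measure_series"))
  sel <- .window_index(series, window_start, t_end)
  if (length(sel) < 2L)
    stop("empty stationary window: fewer than 2 evaluation times at t >= ",
         window_start)
  v <- series$value[sel]
  structure(list(measure = series$name, window_start = window_start,
                 n_samples = length(sel), mean = mean(v), sd = sd(v)),
            class = "stationary_summary")
}

#' @export
print.stationary_summary <- function(x, ...) {
  cat(sprintf("%s (t >= %g, n = %d): %.4g +/- %.4g\n",
              x$measure, x$window_start, x$n_samples, x$mean, x$sd))
  invisible(x)
}

#' Empirical distribution of a measure over the stationary window
#'
#' Histogram of the windowed measure values with Rice's-rule bin count on
#' the window sample size (58 bins for the published 24,999 samples), over
#' their min-max range.
#'
#' @inheritParams stationary_summary
#' @return An object of class `measure_distribution`: list with `measure`,
#'   `edges`, `mass`, `n_samples`.
#' @export
measure_distribution <- function(series, window_start, t_end = NULL) {
  stopifnot(inherits(series, "measure_series"))
  sel <- .window_index(series, window_start, t_end)
  if (length(sel) < 2L) stop("empty stationary window")
  v <- series$value[sel]
  if (max(v) <= min(v))
    stop("degenerate support: measure is constant over the window")
  g <- build_grid(v, rice_bins(length(v)))
  p <- estimate_pdf(v, g)
  structure(list(measure = series$name, edges = g$edges, mass = p$mass,
                 n_samples = length(v)),
            class = "measure_distribution")
}

#' One-sided amplitude spectrum of a stationary-window measure series
#'
#' Removes the window mean (so the DC term does not dominate log-log fits)
#' and returns the one-sided FFT amplitude `|X_k|` at frequencies
#' `k / (N * delta_t)`, `k = 1..floor(N/2)`. One model time unit is treated
#' as one second, so the published cadence delta_t = 1e-4 makes the series
#' a 10 kHz signal with 5 kHz Nyquist frequency.
#'
#' @inheritParams stationary_summary
#' @param fit_band default frequency band (Hz) for [power_law_fit()].
#' @return An object of class `spectrum_fit` with `frequency`, `amplitude`,
#'   `fit_band`, and unfilled `exponent`/`intercept`.
#' @export
power_spectrum <- function(series, window_start, t_end = NULL,
                           fit_band = c(100, 1000)) {
  stopifnot(inherits(series, "measure_series"))
  sel <- .window_index(series, window_start, t_end)
  if (length(sel) < 4L) stop("stationary window too short for a spectrum")
  if (any(diff(sel) != 1L)) stop("window must be uniformly sampled")
  x <- series$value[sel]
  x <- x - mean(x)
  n <- length(x)
  half <- seq_len(n %/% 2)
  amp <- Mod(fft(x))[half + 1L]
  structure(list(measure = series$name,
                 frequency = half / (n * series$delta_t),
                 amplitude = amp, fit_band = fit_band,
                 exponent = NA_real_, intercept = NA_real_, n = n),
            class = "spectrum_fit")
}

#' Power-law fit of an amplitude spectrum
#'
#' Ordinary least squares of `log10(amplitude)` on `log10(frequency)`
#' restricted to the fit band; the exponent is the slope, quantifying how
#' fast spectral amplitude falls with frequency.
#'
#' @param spectrum a [power_spectrum()] result.
#' @param band numeric `c(f_lo, f_hi)` in Hz; defaults to the spectrum's
#'   `fit_band`.
#' @return the `spectrum_fit` with `exponent` and `intercept` filled.
#' @export
#' @examples
#' s <- structure(list(frequency = 1:2000, amplitude = (1:2000)^-1.5,
#'                     fit_band = c(100, 1000)), class = "spectrum_fit")
#' power_law_fit(s)$exponent  # -1.5
power_law_fit <- function(spectrum, band = spectrum$fit_band) {
  stopifnot(inherits(spectrum, "spectrum_fit"))
  if (band[1] >= band[2]) stop("fit band must satisfy f_lo < f_hi")
  sel <- spectrum$frequency >= band[1] & spectrum$frequency <= band[2] &
    spectrum$amplitude > 0
  if (sum(sel) < 10L)
    stop("fewer than 10 spectrum points inside the fit band [",
         band[1], ", ", band[2], "] Hz")
  fit <- lm(y ~ x, data = data.frame(x = log10(spectrum$frequency[sel]),
                                     y = log10(spectrum$amplitude[sel])))
  spectrum$exponent <- unname(coef(fit)[2])
  spectrum$intercept <- unname(coef(fit)[1])
  spectrum$fit_band <- band
  spectrum
}

#' Run the full measure pipeline for one oscillator condition
#'
#' Simulates the ensemble for the requested condition and initial ensemble,
#' streaming recorded slices through a [measure_accumulator()], then
#' derives stationary summaries, empirical measure distributions, and
#' power spectra with power-law fits for the two information-rate series.
#' Net series (net causal information rate, net transfer entropy) are
#' added when both directions were computed.
#'
#' @param condition one of [condition_names()].
#' @param ic initial-ensemble preset 1..6 (4 is the conventional default).
#' @param n_traj ensemble size.
#' @param config a [simulation_config()].
#' @param seed integer seed for the run.
#' @param window_start stationary-window start (published runs use 7.5;
#'   scale it with `config$t_end` for shorter runs).
#' @param measures passed to [measure_accumulator()].
#' @param bin_policy passed to [measure_accumulator()].
#' @param fit_band power-law fit band in Hz.
#' @param out_dir optional directory; when given, per-measure CSVs with
#'   JSON sidecars, a summary table and a manifest are written there.
#' @return An object of class `condition_bundle`: list with `condition`,
#'   `ic`, `n_traj`, `config`, `seed`, `window_start`, `series`,
#'   `summaries` (data.frame), `distributions`, `spectra`, `manifest`.
#' @export
run_condition <- function(condition, ic = 4L, n_traj, config, seed = 1L,
                          window_start = 7.5,
                          measures = c("gamma", "entropy", "causal", "te"),
                          bin_policy = joint_bins,
                          fit_band = c(100, 1000), out_dir = NULL) {
  params <- preset_params(condition)
  spec <- preset_ic(ic, n_traj, seed)
  acc <- measure_accumulator(measures = measures, bin_policy = bin_policy)
  simulate_ensemble(params, spec, config, acc$consumer)
  series <- acc$results()

  if (all(c("gamma_x2_to_x1", "gamma_x1_to_x2") %in% names(series))) {
    series$net_causal <- net_causal_rate(series$gamma_x2_to_x1,
                                         series$gamma_x1_to_x2)
    series$net_causal$name <- "net_causal"
  }
  if (all(c("te_x2_to_x1", "te_x1_to_x2") %in% names(series))) {
    series$net_te <- net_causal_rate(series$te_x2_to_x1,
                                     series$te_x1_to_x2)
    series$net_te$name <- "net_te"
  }

  summaries <- do.call(rbind, lapply(series, function(s) {
    z <- stationary_summary(s, window_start, config$t_end)
    data.frame(measure = z$measure, condition = condition,
               window_start = z$window_start, n_samples = z$n_samples,
               mean = z$mean, sd = z$sd)
  }))
  rownames(summaries) <- NULL

  distributions <- lapply(series, measure_distribution, window_start,
                          config$t_end)
  # the power-law fit needs >= 10 in-band frequencies; short windows keep
  # the raw spectrum with an unfilled exponent
  spectra <- lapply(series[intersect(c("gamma_x1", "gamma_x2"),
                                     names(series))],
                    function(s) {
                      ps <- power_spectrum(s, window_start, config$t_end,
                                           fit_band)
                      tryCatch(power_law_fit(ps), error = function(e) ps)
                    })

  manifest <- list(
    package = "inforate",
    version = as.character(utils::packageVersion("inforate")),
    condition = condition, ic = ic, n_traj = n_traj, seed = seed,
    dt = config$dt, record_dt = config$record_dt,
    t_start = config$t_start, t_end = config$t_end,
    window_start = window_start, measures = measures,
    bin_policy = "floor(2 * n^(1/(d+2))) bins per axis (Rice at d = 1)",
    fit_band = fit_band, complete = TRUE)

  bundle <- structure(list(condition = condition, ic = ic, n_traj = n_traj,
                           config = config, seed = seed,
                           window_start = window_start, series = series,
                           summaries = summaries,
                           distributions = distributions, spectra = spectra,
                           manifest = manifest),
                      class = "condition_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a condition bundle to disk
#'
#' Per-measure CSVs (`t,value`) with JSON sidecars (name, units, delta_t,
#' binning policy, seed), a stationary-summary CSV, and a manifest JSON.
#'
#' @param bundle a [run_condition()] result.
#' @param out_dir output directory (created if missing).
#' @return invisibly, `out_dir`.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "condition_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in bundle$series) {
    base <- file.path(out_dir, paste0(bundle$condition, "_", s$name))
    write.csv(as.data.frame(s), paste0(base, ".csv"), row.names = FALSE)
    jsonlite::write_json(
      list(name = s$name, units = s$units, delta_t = s$delta_t,
           seed = bundle$seed, bin_policy = bundle$manifest$bin_policy),
      paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  write.csv(bundle$summaries,
            file.path(out_dir, paste0(bundle$condition, "_summary.csv")),
            row.names = FALSE)
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir,
                                 paste0(bundle$condition, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Combined report across the four oscillator conditions
#'
#' Mirrors the two published summary tables: information rate and
#' differential entropy per condition, and causal information rate /
#' net causal rate / transfer entropy per condition, each cell a
#' stationary-window mean and SD. Also reports the headline contrast flags:
#' for healthy controls the information rates drop on eye opening
#' (EO < EC), for AD patients they rise (EO > EC), and the net causal rate
#' increases from EC to EO in both groups. Bundles are matched by their
#' condition name, so argument order is irrelevant.
#'
#' @param bundles list of four [run_condition()] bundles (one per
#'   condition).
#' @param out_dir optional directory for `report.csv` / `report.json`.
#' @return A list with `table` (long data.frame: measure x condition),
#'   `rate_entropy_table` and `causal_te_table` (wide, mean +/- sd cells),
#'   and `contrasts` (named logicals).
#' @export
compare_conditions <- function(bundles, out_dir = NULL) {
  conds <- vapply(bundles, function(b) b$condition, "")
  if (!setequal(conds, condition_names()))
    stop("need one complete bundle per condition: ",
         paste(condition_names(), collapse = ", "))
  bundles <- bundles[match(condition_names(), conds)]
  long <- do.call(rbind, lapply(bundles, function(b) b$summaries))
  rownames(long) <- NULL

  cell <- function(measure, cond) {
    r <- long[long$measure == measure & long$condition == cond, ]
    if (nrow(r) != 1L) return(NA_character_)
    sprintf("%.4g +/- %.4g", r$mean, r$sd)
  }
  wide <- function(measures) {
    out <- data.frame(measure = measures)
    for (cond in condition_names())
      out[[cond]] <- vapply(measures, cell, "", cond = cond)
    out
  }
  mval <- function(measure, cond)
    long$mean[long$measure == measure & long$condition == cond]

  contrasts <- c(
    ctl_gamma_x1_eo_lt_ec = mval("gamma_x1", "ctl_eo") <
      mval("gamma_x1", "ctl_ec"),
    ctl_gamma_x2_eo_lt_ec = mval("gamma_x2", "ctl_eo") <
      mval("gamma_x2", "ctl_ec"),
    ad_gamma_x1_eo_gt_ec = mval("gamma_x1", "ad_eo") >
      mval("gamma_x1", "ad_ec"),
    ad_gamma_x2_eo_gt_ec = mval("gamma_x2", "ad_eo") >
      mval("gamma_x2", "ad_ec"))
  if ("net_causal" %in% long$measure) {
    contrasts <- c(contrasts,
      ctl_net_causal_increases_on_eo = mval("net_causal", "ctl_eo") >
        mval("net_causal", "ctl_ec"),
      ad_net_causal_increases_on_eo = mval("net_causal", "ad_eo") >
        mval("net_causal", "ad_ec"))
  }

  report <- list(
    table = long,
    rate_entropy_table = wide(intersect(
      c("gamma_x1", "gamma_x2", "h_x1", "h_x2"), unique(long$measure))),
    causal_te_table = wide(intersect(
      c("gamma_x2_to_x1", "gamma_x1_to_x2", "net_causal",
        "te_x2_to_x1", "te_x1_to_x2", "net_te"), unique(long$measure))),
    contrasts = contrasts)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(long, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}
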