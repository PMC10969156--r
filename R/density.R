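#' Rice's rule bin count
#'
#' Number of histogram bins for `n` samples: `floor(2 * n^(1/3))`, at least
#' one bin. Flooring (rather than rounding half-up) matches the published
#' counts: 542 bins for 2e7 samples (2 * (2e7)^(1/3) = 542.88) and 58 bins
#' for 24,999 samples.
#'
#' @param n_samples positive integer sample count.
#' @return integer bin count.
#' @export
#' @examples
#' rice_bins(2e7)    # 542
#' rice_bins(24999)  # 58
rice_bins <- function(n_samples) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L ||
      !is.finite(n_samples) || n_samples < 1)
    stop("n_samples must be a positive count")
  # tiny guard so exact cube roots (e.g. n = 8) are not floored down by
  # floating-point error; far below the 0.88 margin of the printed 542
  max(1L, as.integer(floor(2 * n_samples^(1 / 3) + 1e-8)))
}

#' Per-dimension bin count for d-dimensional joint histograms
#'
#' The default binning policy extends Rice's rule to joints:
#' `floor(2 * n^(1/(d+2)))` bins per axis, which recovers Rice's rule at
#' d = 1 and keeps per-cell occupancy under control as the dimension grows
#' (for n = 2e7: 133 per axis in 2-D, 57 in 3-D). The policy is a single
#' swappable function: pipeline entry points accept any
#' `function(n_samples, n_dim)` in its place.
#'
#' @param n_samples positive sample count.
#' @param n_dim histogram dimension (1, 2 or 3).
#' @return integer per-axis bin count.
#' @export
#' @examples
#' joint_bins(2e7, 1)  # 542, same as rice_bins
#' joint_bins(2e7, 2)  # 133
joint_bins <- function(n_samples, n_dim = 1L) {
  if (!n_dim %in% 1:3) stop("n_dim must be 1, 2 or 3")
  if (!is.numeric(n_samples) || length(n_samples) != 1L ||
      !is.finite(n_samples) || n_samples < 1)
    stop("n_samples must be a positive count")
  max(1L, as.integer(floor(2 * n_samples^(1 / (n_dim + 2)) + 1e-8)))
}

#' Build a shared one-dimensional bin grid from pooled samples
#'
#' Equal-width edges spanning the pooled range of all supplied sample
#' vectors, padded by a relative 1e-9 on each side so extreme samples fall
#' strictly inside. A grid used to compare two time slices must be built
#' once from both slices and shared - differencing densities is only
#' meaningful on a common support.
#'
#' @param samples_list a numeric vector or list of numeric vectors to pool.
#' @param n_bins number of bins.
#' @return An object of class `bin_grid` with fields `edges` (length
#'   `n_bins + 1`) and `n_bins`.
#' @export
#' @examples
#' g <- build_grid(list(0:1, c(0.5, 2)), 4)
#' range(g$edges)  # spans [0, 2] (padded)
build_grid <- function(samples_list, n_bins) {
  if (!is.list(samples_list)) samples_list <- list(samples_list)
  pooled_min <- min(vapply(samples_list, min, 0))
  pooled_max <- max(vapply(samples_list, max, 0))
  if (!is.finite(pooled_min) || !is.finite(pooled_max))
    stop("samples contain non-finite values")
  if (pooled_max <= pooled_min)
    stop("degenerate support: all pooled samples are identical")
  if (!is.finite(n_bins) || n_bins < 1) stop("n_bins must be >= 1")
  pad <- (pooled_max - pooled_min) * 1e-9
  edges <- seq(pooled_min - pad, pooled_max + pad, length.out = n_bins + 1L)
  structure(list(edges = edges, n_bins = as.integer(n_bins)),
            class = "bin_grid")
}

# bin index per sample; errors (rather than silently dropping) on samples
# outside the grid. Grids are equal-width by construction, so the index is
# arithmetic (no binary search); the right edge closes the last bin.
.bin_index <- function(samples, grid) {
  lo <- grid$edges[1L]
  hi <- grid$edges[grid$n_bins + 1L]
  bad <- samples < lo | samples > hi
  if (any(bad))
    stop(sprintf(
      "sample %g outside grid [%g, %g]: grids must be built from the pooled samples they bin",
      samples[which(bad)[1]], lo, hi))
  idx <- as.integer((samples - lo) * (grid$n_bins / (hi - lo))) + 1L
  idx[idx > grid$n_bins] <- grid$n_bins
  idx
}

#' Histogram density estimate of one sample slice
#'
#' Bin masses are counts/n; the density in bin i is `mass[i] / width[i]`.
#' Out-of-range samples are an error, never dropped.
#'
#' @param samples numeric sample vector.
#' @param grid a [build_grid()] result covering the samples.
#' @param t time stamp carried along for cadence checks (default `NA`).
#' @return An object of class `hist_pdf` with fields `grid`, `mass`, `t`,
#'   `n_samples`.
#' @export
estimate_pdf <- function(samples, grid, t = NA_real_) {
  stopifnot(inherits(grid, "bin_grid"))
  idx <- .bin_index(samples, grid)
  n <- length(samples)
  structure(list(grid = grid,
                 mass = tabulate(idx, nbins = grid$n_bins) / n,
                 t = t, n_samples = n),
            class = "hist_pdf")
}

#' Joint histogram of two or three aligned sample columns
#'
#' Columns may come from different recording times of the *same*
#' trajectories (row i of every column is one trajectory), which is what
#' makes time-lagged joints such as p(x2 at t+dt; x1 at t) meaningful.
#' Each axis uses its own shared 1-D grid, so marginalizing the joint
#' reproduces, cell for cell, the 1-D histogram of that variable on the
#' same grid.
#'
#' @param columns list of 2 or 3 equal-length numeric vectors.
#' @param grids list of [build_grid()] objects, one per column.
#' @param times numeric vector of per-axis time stamps (default `NA`).
#' @return An object of class `joint_hist` with fields `grids`, `mass`
#'   (array with one dimension per axis), `times`, `n_samples`.
#' @export
estimate_joint <- function(columns, grids, times = NULL) {
  d <- length(columns)
  if (!d %in% 2:3) stop("estimate_joint takes 2 or 3 columns")
  if (length(grids) != d) stop("one grid per column required")
  n <- length(columns[[1]])
  if (any(vapply(columns, length, 0L) != n))
    stop("alignment error: columns must have equal length (one row per trajectory)")
  if (is.null(times)) times <- rep(NA_real_, d)
  nb <- vapply(grids, function(g) g$n_bins, 0L)
  lin <- .bin_index(columns[[1]], grids[[1]])
  stride <- nb[1]
  for (j in 2:d) {
    lin <- lin + stride * (.bin_index(columns[[j]], grids[[j]]) - 1L)
    stride <- stride * nb[j]
  }
  mass <- array(tabulate(lin, nbins = prod(nb)) / n, dim = nb)
  structure(list(grids = grids, mass = mass, times = times, n_samples = n),
            class = "joint_hist")
}

# exact-equality check that two histograms share one grid object's edges
.same_grid <- function(g1, g2) {
  g1$n_bins == g2$n_bins &&
    (identical(g1$edges, g2$edges) || all(g1$edges == g2$edges))
}
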