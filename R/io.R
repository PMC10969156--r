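#' Read a flat key/value run configuration file
#'
#' Parses `key = value` lines (one per line, `#` comments allowed) with the
#' keys `condition`, `ic`, `n_traj`, `dt`, `record_dt`, `t_end`, `seed` and
#' optionally `record_vars`, returning the pieces ready for
#' [run_condition()] / [simulate_ensemble()].
#'
#' @param path file path.
#' @return A list with `condition`, `ic`, `n_traj`, `seed`, `record_vars`
#'   and a [simulation_config()] under `config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  need <- c("condition", "ic", "n_traj", "dt", "record_dt", "t_end", "seed")
  missing <- setdiff(need, names(vals))
  if (length(missing))
    stop("config is missing keys: ", paste(missing, collapse = ", "))
  if (!vals[["condition"]] %in% condition_names())
    stop("unknown condition '", vals[["condition"]], "' in config")
  list(condition = vals[["condition"]],
       ic = as.integer(vals[["ic"]]),
       n_traj = as.numeric(vals[["n_traj"]]),
       seed = as.integer(vals[["seed"]]),
       record_vars = if ("record_vars" %in% names(vals))
         vals[["record_vars"]] else "x1x2",
       config = simulation_config(dt = as.numeric(vals[["dt"]]),
                                  record_dt = as.numeric(vals[["record_dt"]]),
                                  t_end = as.numeric(vals[["t_end"]])))
}

#' Export a stack of density estimates as long-form CSV
#'
#' One row per (time, bin): columns `t`, `bin_center`, `density`, ready for
#' plotting the density time evolution.
#'
#' @param pdfs list of [estimate_pdf()] results (time-stamped).
#' @param file output CSV path, or `NULL` to return the data frame only.
#' @return invisibly, the long-form data frame.
#' @export
pdf_stack_csv <- function(pdfs, file = NULL) {
  rows <- lapply(pdfs, function(p) {
    stopifnot(inherits(p, "hist_pdf"))
    e <- p$grid$edges
    data.frame(t = p$t, bin_center = (e[-1] + e[-length(e)]) / 2,
               density = p$mass / diff(e))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  invisible(out)
}
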