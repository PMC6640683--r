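#' Construct a time series
#'
#' The common record for RMSD and hinge-angle traces: per-frame values on a
#' strictly increasing time axis, with explicit units.
#'
#' @param times numeric, ns, strictly increasing.
#' @param values numeric, same length.
#' @param label series label.
#' @param units `"A"` (Angstrom) or `"deg"`.
#' @return An object of class `md_timeseries`.
#' @export
md_timeseries <- function(times, values, label = "series", units = "A") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(label = label, times = times, values = values, units = units),
            class = "md_timeseries")
}

#' @export
print.md_timeseries <- function(x, ...) {
  cat("md_timeseries '", x$label, "' [", x$units, "]: ", length(x$times),
      " points, t = ", format(x$times[1]), "..",
      format(x$times[length(x$times)]), " ns\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.md_timeseries <- function(x, ...) {
  data.frame(time_ns = x$times, value = x$values)
}

#' Write a time series as CSV
#'
#' Columns `time_ns,value`; the label and units go in a leading `#` comment,
#' so the file stays self-describing.
#'
#' @param series an `md_timeseries` (or a named list of them, written as
#'   extra value columns sharing one time axis).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "md_timeseries")) series <- list(series)
  t0 <- series[[1]]$times
  for (s in series)
    if (!isTRUE(all.equal(s$times, t0)))
      stop("series share no common time axis; use overlay_table()")
  labels <- vapply(series, function(s) s$label, character(1))
  units <- vapply(series, function(s) s$units, character(1))
  df <- data.frame(time_ns = round(t0, 6))
  for (i in seq_along(series))
    df[[make.names(labels[i])]] <- round(series[[i]]$values, 4)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(labels, " [", units, "]",
                                sep = "", collapse = "; ")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Summary statistics over a time window
#'
#' Mean and sample (n-1) standard deviation of a series restricted to
#' `t_start <= t <= t_end`; used to characterize steady-state behaviour over
#' a trailing trajectory interval.
#'
#' @param series an `md_timeseries`.
#' @param t_start,t_end window bounds in ns, `t_start < t_end`.
#' @return A list (`window_stats`): `t_start`, `t_end`, `mean`, `sd`,
#'   `n_points`. A single-point window reports `sd = 0`.
#' @export
window_stats <- function(series, t_start, t_end) {
  stopifnot(inherits(series, "md_timeseries"))
  if (t_start >= t_end) stop("t_start must be < t_end")
  keep <- series$times >= t_start & series$times <= t_end
  if (!any(keep)) stop("window [", t_start, ", ", t_end,
                       "] contains no samples")
  v <- series$values[keep]
  structure(list(t_start = t_start, t_end = t_end,
                 mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 n_points = length(v)),
            class = "window_stats")
}

#' @export
print.window_stats <- function(x, ...) {
  cat(sprintf("window [%.4g, %.4g] ns: mean %.4g, sd %.4g (n = %d)\n",
              x$t_start, x$t_end, x$mean, x$sd, x$n_points))
  invisible(x)
}
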