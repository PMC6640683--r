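#' Find when a trajectory best matches a query conformation
#'
#' Scans all frames for the minimum superposed RMSD between the trajectory's
#' `calc_set` atoms and the query coordinates (same selection on both
#' systems, index-matched). The earliest minimizing time wins ties, so the
#' answer is the first moment the trajectory reaches the query conformation
#' — the quantity behind sampling-speedup estimates.
#'
#' @param query_coords coordinates of the query conformation over the same
#'   atoms as `calc_set` (or full-structure coordinates).
#' @param traj an `md_trajectory`.
#' @param calc_set `atom_set` defining the atom correspondence.
#' @return A list: `t_match` (ns), `match_rmsd` (Angstrom), `frame`.
#' @export
match_time <- function(query_coords, traj, calc_set) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(calc_set, "atom_set"))
  idx <- calc_set$indices
  q <- as_coord_matrix(query_coords)
  if (nrow(q) == dim(traj$coords)[2]) q <- q[idx, , drop = FALSE]
  if (nrow(q) != length(idx))
    stop("query atom count (", nrow(q), ") matches neither the selection (",
         length(idx), ") nor the structure")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    rmsd_pair(matrix(traj$coords[f, , ], ncol = 3L)[idx, , drop = FALSE],
              q, superpose = TRUE)
  }, numeric(1))
  best <- which.min(vals)   # which.min returns the earliest minimum
  list(t_match = traj$times[best], match_rmsd = vals[best],
       frame = best, rmsd_series = md_timeseries(
         traj$times, vals, label = "match_rmsd", units = "A"))
}

#' Sampling scale (speedup) factor between two trajectories
#'
#' Ratio of the reference trajectory's elapsed time to the time at which the
#' faster-sampling trajectory reaches the matched conformation. A factor of
#' 6 means the second trajectory explored in 1/6 of the nominal time what
#' the reference needed its full length for.
#'
#' @param reference_time elapsed time of the reference trajectory (ns).
#' @param t_match matched time in the compared trajectory (ns), > 0.
#' @param match_rmsd optional RMSD at the match (Angstrom), carried along.
#' @return A `scale_fit`: `t_match`, `reference_time`, `factor`
#'   (unrounded), `factor_rounded` (nearest integer), `match_rmsd`.
#' @export
estimate_scale_factor <- function(reference_time, t_match, match_rmsd = NA_real_) {
  if (!is.numeric(reference_time) || reference_time <= 0)
    stop("reference_time must be > 0")
  if (!is.numeric(t_match) || t_match <= 0)
    stop("t_match must be > 0")
  f <- reference_time / t_match
  structure(list(t_match = t_match, reference_time = reference_time,
                 factor = f, factor_rounded = round(f),
                 match_rmsd = match_rmsd),
            class = "scale_fit")
}

#' @export
print.scale_fit <- function(x, ...) {
  cat(sprintf(
    "scale_fit: %.4g ns (reference) / %.4g ns (matched) = factor %.4g (~%d)\n",
    x$reference_time, x$t_match, x$factor, x$factor_rounded))
  invisible(x)
}

#' Rescale a series' time axis
#'
#' Multiplies times by a conversion factor, leaving values untouched — the
#' operation used to overlay an implicit-solvent trace on explicit-solvent
#' time after estimating the sampling speedup.
#'
#' @param series an `md_timeseries`.
#' @param factor positive dimensionless conversion factor.
#' @return The rescaled `md_timeseries`, label annotated with the factor.
#' @export
rescale_time <- function(series, factor) {
  stopifnot(inherits(series, "md_timeseries"))
  if (!is.numeric(factor) || factor <= 0) stop("factor must be > 0")
  md_timeseries(series$times * factor, series$values,
                label = sprintf("%s (x%g)", series$label, factor),
                units = series$units)
}

#' Tabulate several series on a common time grid
#'
#' Linear interpolation within each series' support, never beyond it (cells
#' outside a series' span stay NA) — the table behind overlaid
#' explicit/rescaled-implicit plots.
#'
#' @param series_list named list of `md_timeseries`.
#' @param grid numeric vector of grid times (ns).
#' @return data.frame: `time_ns` plus one column per series.
#' @export
overlay_table <- function(series_list, grid) {
  if (length(grid) == 0L) stop("empty grid")
  if (is.null(names(series_list)) || any(names(series_list) == ""))
    names(series_list) <- vapply(series_list, function(s) s$label, character(1))
  out <- data.frame(time_ns = as.numeric(grid))
  for (nm in names(series_list)) {
    s <- series_list[[nm]]
    v <- stats::approx(s$times, s$values, xout = grid, rule = 1)$y
    out[[make.names(nm)]] <- v
  }
  out
}
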