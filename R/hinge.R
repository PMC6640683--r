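#' Position of an anchor residue in one frame
#'
#' Anchors mark the tips of the two Fabs and the Fc plus the CH1-CH2 linker
#' vertex; by default an anchor resolves to its residue's CA atom, or to the
#' residue centroid under the `"centroid"` rule.
#'
#' @param coords full-structure `n_atoms x 3` frame coordinates.
#' @param structure the `md_structure`.
#' @param map a `domain_map` with resolved anchors.
#' @param label anchor label in the map.
#' @return 3-vector position (Angstrom).
#' @export
anchor_point <- function(coords, structure, map, label) {
  coords <- as_coord_matrix(coords)
  an <- map$anchors[map$anchors$label == label, , drop = FALSE]
  if (nrow(an) != 1L) stop("anchor '", label, "' not defined in map")
  if (is.na(an$atom_index))
    stop("anchor '", label, "' is not resolved against a structure")
  if (an$rule == "centroid") {
    grp <- attr(map, "anchor_groups")[[label]]
    return(colMeans(coords[grp, , drop = FALSE]))
  }
  coords[an$atom_index, ]
}

#' Angle at a vertex between two endpoints
#'
#' Arc-cosine of the normalized dot product of the two vertex-to-endpoint
#' rays; the cosine is clamped to [-1, 1] so exactly straight or folded
#' geometries do not produce NaN.
#'
#' @param a,vertex,b 3-vector positions (Angstrom).
#' @return Angle in degrees, in [0, 180].
#' @export
triplet_angle <- function(a, vertex, b) {
  u <- as.numeric(a) - as.numeric(vertex)
  v <- as.numeric(b) - as.numeric(vertex)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu <= 1e-6 || nv <= 1e-6)
    stop("degenerate angle: endpoint coincides with vertex")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Fab/Fc hinge-angle time series
#'
#' The three interchain angles monitored across the CH1-CH2 linker, all
#' sharing the linker anchor as vertex: left = (Fab-left, linker, Fc),
#' right = (Fab-right, linker, Fc), top = (Fab-left, linker, Fab-right).
#' Angles are invariant under rigid motion of the whole frame, so no
#' alignment is applied.
#'
#' The map must define anchors labelled `fab_left`, `fab_right`, `fc` and
#' `hinge` (the linker vertex).
#'
#' @param traj an `md_trajectory`.
#' @param map a `domain_map` with the four anchors resolved.
#' @return Named list of three `md_timeseries` (`left`, `right`, `top`),
#'   degrees.
#' @export
angle_series <- function(traj, map) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(map, "domain_map"))
  need <- c("fab_left", "fab_right", "fc", "hinge")
  have <- map$anchors$label
  if (!all(need %in% have))
    stop("map lacks anchor(s): ", paste(setdiff(need, have), collapse = ", "))
  nf <- n_frames(traj)
  left <- right <- top <- numeric(nf)
  s <- traj$structure
  for (f in seq_len(nf)) {
    fr <- matrix(traj$coords[f, , ], ncol = 3L)
    pl <- anchor_point(fr, s, map, "fab_left")
    pr <- anchor_point(fr, s, map, "fab_right")
    pf <- anchor_point(fr, s, map, "fc")
    ph <- anchor_point(fr, s, map, "hinge")
    left[f] <- tryCatch(triplet_angle(pl, ph, pf), error = function(e)
      stop("frame ", f, ": ", conditionMessage(e)))
    right[f] <- triplet_angle(pr, ph, pf)
    top[f] <- triplet_angle(pl, ph, pr)
  }
  list(left = md_timeseries(traj$times, left, "left", "deg"),
       right = md_timeseries(traj$times, right, "right", "deg"),
       top = md_timeseries(traj$times, top, "top", "deg"))
}

#' Write hinge-angle series as CSV
#'
#' Columns `time_ns,left_deg,right_deg,top_deg`, with the anchor definitions
#' echoed in header comments.
#'
#' @param angles result of [angle_series()].
#' @param map the `domain_map` used (for the header echo); optional.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(angles, path, map = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# hinge angles [deg]: left(fab_left,hinge,fc) right(fab_right,hinge,fc) top(fab_left,hinge,fab_right)", con)
  if (!is.null(map) && !is.null(map$anchors)) {
    writeLines(sprintf("# anchor %s: chain %s resid %d (%s)",
                       map$anchors$label, map$anchors$chain,
                       map$anchors$resid, map$anchors$rule), con)
  }
  df <- data.frame(time_ns = round(angles$left$times, 6),
                   left_deg = round(angles$left$values, 4),
                   right_deg = round(angles$right$values, 4),
                   top_deg = round(angles$top$values, 4))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
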