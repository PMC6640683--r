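#' RMSD between two conformations
#'
#' Root-mean-square distance over index-matched atoms,
#' `sqrt(sum |r_i(t1) - r_i(t2)|^2 / N_atoms)`. With `superpose = TRUE` the
#' pair is first treated as rigid bodies and overlapped by the optimal
#' rotation + translation (`best_fit`), which is how trajectory RMSD is
#' conventionally reported.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices (Angstrom).
#' @param superpose align `coords_a` onto `coords_b` first (needs n >= 3
#'   non-collinear atoms).
#' @return RMSD in Angstrom.
#' @export
rmsd_pair <- function(coords_a, coords_b, superpose = FALSE) {
  A <- as_coord_matrix(coords_a)
  B <- as_coord_matrix(coords_b)
  if (nrow(A) != nrow(B)) stop("atom counts differ")
  if (nrow(A) < 1L) stop("empty coordinate set")
  if (superpose) return(best_fit(A, B)$fitted_rmsd)
  sqrt(mean(rowSums((A - B)^2)))
}

#' RMSD time series along a trajectory
#'
#' Per frame: superpose on `fit_set`, then evaluate the RMSD over `calc_set`
#' against the reference. With `fit_set = calc_set` (the default) this is the
#' usual whole-set fitted RMSD; fitting on a fragment while measuring another
#' isolates relative inter-domain motion.
#'
#' @param traj an `md_trajectory`.
#' @param reference frame index (default 1, the first production frame) or an
#'   external full-structure coordinate matrix.
#' @param calc_set `atom_set` the RMSD is evaluated over.
#' @param fit_set `atom_set` the superposition uses (default `calc_set`).
#' @return An `md_timeseries` in Angstrom.
#' @export
rmsd_series <- function(traj, reference = 1L, calc_set, fit_set = calc_set) {
  stopifnot(inherits(traj, "md_trajectory"),
            inherits(calc_set, "atom_set"), inherits(fit_set, "atom_set"))
  fi <- fit_set$indices
  ci <- calc_set$indices
  ref_fit <- reference_coords(traj, reference, fi)
  ref_calc <- reference_coords(traj, reference, ci)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- matrix(traj$coords[f, , ], ncol = 3L)
    fit <- tryCatch(best_fit(fr[fi, , drop = FALSE], ref_fit),
                    error = function(e)
                      stop("frame ", f, ": ", conditionMessage(e)))
    rmsd_pair(apply_fit(fr[ci, , drop = FALSE], fit), ref_calc)
  }, numeric(1))
  md_timeseries(traj$times, vals, label = calc_set$label, units = "A")
}

#' Iteratively converged mean structure
#'
#' The time-average conformation is alignment-dependent, so it is defined by
#' fixed-point iteration: align every frame to the running mean on `fit_set`,
#' recompute the mean over `atomset`, and repeat until the mean moves less
#' than `tol` (max per-coordinate shift, Angstrom) or `max_iter` is reached
#' (warning; last iterate returned).
#'
#' @param traj an `md_trajectory`.
#' @param atomset `atom_set` whose mean coordinates are returned.
#' @param fit_set `atom_set` used for the per-frame alignment
#'   (default `atomset`).
#' @param max_iter,tol convergence controls (defaults 10 and 1e-6 A).
#' @return Mean coordinates, `length(atomset) x 3`.
#' @export
mean_structure <- function(traj, atomset, fit_set = atomset,
                           max_iter = 10L, tol = 1e-6) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(atomset, "atom_set"))
  ai <- atomset$indices
  fi <- fit_set$indices
  nf <- n_frames(traj)
  # initialize from the plain (unaligned) frame average so the result is
  # anchored in the trajectory's own frame, not at frame 1
  mean_fit <- apply(traj$coords[, fi, , drop = FALSE], c(2, 3), mean)
  mean_all <- NULL
  for (it in seq_len(max_iter)) {
    acc_all <- matrix(0, length(ai), 3L)
    acc_fit <- matrix(0, length(fi), 3L)
    for (f in seq_len(nf)) {
      fr <- matrix(traj$coords[f, , ], ncol = 3L)
      fit <- best_fit(fr[fi, , drop = FALSE], mean_fit)
      acc_all <- acc_all + apply_fit(fr[ai, , drop = FALSE], fit)
      acc_fit <- acc_fit + apply_fit(fr[fi, , drop = FALSE], fit)
    }
    new_all <- acc_all / nf
    new_fit <- acc_fit / nf
    shift <- max(abs(new_fit - mean_fit))
    mean_fit <- new_fit
    converged <- shift < tol
    mean_all <- new_all
    if (converged) break
  }
  if (!converged)
    warning("mean structure not converged after ", max_iter,
            " iterations (last shift ", format(shift, digits = 3), " A)")
  mean_all
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each residue about its time-averaged
#' position: frames are aligned (on the fragment itself in `"local"` mode,
#' removing rigid-body drift of the fragment, or on a caller-given set), the
#' converged mean structure is taken as the reference, and per residue k the
#' time average of the residue-mean squared displacement
#' `sum_i |r_i(t) - <r_i>|^2 / N_k` is square-rooted.
#'
#' Local mode is the fragment-focused variant: aligning on the fragment
#' itself excludes the relative-orientation component that inflates RMSF
#' when rigid domains reorient about flexible linkers.
#'
#' @param traj an `md_trajectory` (needs >= 2 frames).
#' @param fragment `atom_set` analysed, grouped by residue internally.
#' @param fit_mode `"local"` (default) or `"global"`.
#' @param fit_set `atom_set` used for alignment when `fit_mode = "global"`.
#' @return An `rmsf_profile`: data.frame with `chain`, `resid`, `rmsf`
#'   (Angstrom); attributes `label` and `n_frames`.
#' @export
rmsf_profile <- function(traj, fragment, fit_mode = c("local", "global"),
                         fit_set = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(fragment, "atom_set"))
  fit_mode <- match.arg(fit_mode)
  if (n_frames(traj) < 2L)
    stop("RMSF is undefined for a single-frame trajectory")
  fset <- if (fit_mode == "local") fragment else {
    if (is.null(fit_set)) stop("global fit_mode requires fit_set")
    fit_set
  }
  mref <- mean_structure(traj, fragment, fset)      # mean over the fragment
  mfit <- if (identical(fset$indices, fragment$indices)) mref
          else mean_structure(traj, fset, fset)     # alignment target
  fi <- fset$indices
  ai <- fragment$indices
  nf <- n_frames(traj)
  # accumulate squared displacement from the mean, per atom
  ssd <- numeric(length(ai))
  for (f in seq_len(nf)) {
    fr <- matrix(traj$coords[f, , ], ncol = 3L)
    fit <- best_fit(fr[fi, , drop = FALSE], mfit)
    moved <- apply_fit(fr[ai, , drop = FALSE], fit)
    ssd <- ssd + rowSums((moved - mref)^2)
  }
  msd_atom <- ssd / nf
  grp <- group_by_residue(traj$structure, fragment)
  res_msd <- vapply(grp$groups, function(g) mean(msd_atom[match(g, ai)]),
                    numeric(1))
  out <- data.frame(chain = grp$chain, resid = grp$resid,
                    rmsf = sqrt(res_msd), stringsAsFactors = FALSE)
  attr(out, "label") <- fragment$label
  attr(out, "n_frames") <- nf
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Write an RMSF profile as CSV
#' @param profile an `rmsf_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmsf_csv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# RMSF [A], fragment '", attr(profile, "label"),
                    "', ", attr(profile, "n_frames"), " frames"), con)
  utils::write.csv(data.frame(chain = profile$chain, resid = profile$resid,
                              rmsf_A = round(profile$rmsf, 4)),
                   con, row.names = FALSE)
  invisible(path)
}
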