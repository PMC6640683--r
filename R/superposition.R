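#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimize the (optionally
#' weighted) RMSD between two index-matched point sets — the primitive under
#' every RMSD/RMSF computation here. The SVD-based solution carries a sign
#' correction on the smallest singular value so the returned rotation is
#' always proper (det = +1): mirror images are never matched by reflection.
#'
#' The transform maps mobile points (as rows) via
#' `aligned = mobile %*% rotation + translation`.
#'
#' @param mobile n x 3 coordinates to move (Angstrom).
#' @param reference n x 3 target coordinates.
#' @param weights optional non-negative per-atom weights (not all zero);
#'   default uniform. Mass weighting can be had by passing masses.
#' @return An object of class `superposition_fit`: `rotation` (3 x 3,
#'   orthonormal, det +1), `translation` (length-3), `fitted_rmsd` (Angstrom,
#'   the minimized weighted RMSD).
#' @export
best_fit <- function(mobile, reference, weights = NULL) {
  X <- as_coord_matrix(mobile)
  Y <- as_coord_matrix(reference)
  n <- nrow(X)
  if (nrow(Y) != n) stop("mobile and reference atom counts differ")
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite coordinates")
  if (n < 3L) stop("degenerate geometry: need >= 3 points for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length mismatch")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero")
  w <- weights / sum(weights)

  cm <- colSums(X * w)
  cr <- colSums(Y * w)
  Xc <- sweep(X, 2L, cm)
  Yc <- sweep(Y, 2L, cr)

  # collinear clouds leave the rotation about the common axis undetermined
  if (is_collinear(Xc) || is_collinear(Yc))
    stop("degenerate geometry: points are collinear")

  H <- crossprod(Xc * w, Yc)          # 3x3 weighted covariance
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)   # row convention: x %*% R
  resid <- Xc %*% R - Yc
  msd <- sum(w * rowSums(resid^2))
  fit <- list(rotation = R,
              translation = as.numeric(cr - cm %*% R),
              fitted_rmsd = sqrt(max(msd, 0)))
  class(fit) <- "superposition_fit"
  fit
}

#' @export
print.superposition_fit <- function(x, ...) {
  cat(sprintf("superposition_fit: fitted RMSD %.6g A\n", x$fitted_rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix.
#' @param fit a `superposition_fit`.
#' @return Transformed n x 3 matrix.
#' @export
apply_fit <- function(coords, fit) {
  stopifnot(inherits(fit, "superposition_fit"))
  sweep(as_coord_matrix(coords) %*% fit$rotation, 2L, -fit$translation)
}

#' Export a transform as a homogeneous 4 x 4 matrix
#' @param fit a `superposition_fit`.
#' @param path optional plain-text output file.
#' @return The 4 x 4 matrix (row-vector convention), invisibly if written.
#' @export
fit_matrix <- function(fit, path = NULL) {
  m <- rbind(cbind(fit$rotation, 0), c(fit$translation, 1))
  if (!is.null(path)) {
    utils::write.table(format(m, digits = 17), path, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(m))
  }
  m
}

is_collinear <- function(Xc, tol = 1e-8) {
  sv <- svd(Xc, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1e-300)
}

#' Rigid-body alignment of every trajectory frame
#'
#' Each frame gets its own `best_fit` on the fit set against the reference,
#' and the resulting rigid transform is applied to all atoms, so internal
#' frame geometry is untouched.
#'
#' @param traj an `md_trajectory`.
#' @param fit_set `atom_set` used to compute each frame's transform.
#' @param reference frame index into `traj` (default 1), or an external
#'   coordinate matrix over the fit-set atoms (or the whole structure).
#' @return A new, aligned `md_trajectory`.
#' @export
align_trajectory <- function(traj, fit_set, reference = 1L) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(fit_set, "atom_set"))
  idx <- fit_set$indices
  ref <- reference_coords(traj, reference, idx)
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    fr <- matrix(traj$coords[f, , ], ncol = 3L)
    fit <- tryCatch(best_fit(fr[idx, , drop = FALSE], ref),
                    error = function(e)
                      stop("frame ", f, ": ", conditionMessage(e)))
    out[f, , ] <- apply_fit(fr, fit)
  }
  md_trajectory(traj$structure, out, traj$times)
}

# resolve a reference argument to fit-set coordinates
reference_coords <- function(traj, reference, idx) {
  if (is.numeric(reference) && length(reference) == 1L) {
    frame_coords(traj, as.integer(reference))[idx, , drop = FALSE]
  } else {
    ref <- as_coord_matrix(reference)
    if (nrow(ref) == dim(traj$coords)[2]) ref[idx, , drop = FALSE]
    else if (nrow(ref) == length(idx)) ref
    else stop("reference coordinates match neither the structure nor the fit set")
  }
}
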