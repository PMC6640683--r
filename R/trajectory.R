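#' Construct a trajectory
#'
#' Time-ordered coordinate frames bound to a structure; houses the atomic
#' positions r_i(t) that every RMSD/RMSF/angle analysis consumes.
#'
#' @param structure the `md_structure` the frames belong to.
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom), or a
#'   single `n_atoms x 3` matrix for a one-frame trajectory.
#' @param times numeric vector of per-frame times in ns, strictly increasing.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(structure, coords, times) {
  stopifnot(inherits(structure, "md_structure"))
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(1L, dim(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[1] < 1L) stop("zero frames")
  if (dim(coords)[2] != n_atoms(structure))
    stop("frame atom count (", dim(coords)[2],
         ") does not match structure (", n_atoms(structure),
         "): wrong structure/trajectory pairing?")
  times <- as.numeric(times)
  if (length(times) != dim(coords)[1])
    stop("times length does not match frame count")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(structure = structure, coords = coords, times = times),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_frames(x), "frames x", dim(x$coords)[2], "atoms,",
      sprintf("t = %.4g..%.4g ns\n", x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  dim(traj$coords)[1]
}

#' Extract one frame's coordinates
#' @param traj an `md_trajectory`.
#' @param frame frame index (1-based).
#' @return `n_atoms x 3` coordinate matrix.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (frame < 1L || frame > n_frames(traj)) stop("frame index out of range")
  matrix(traj$coords[frame, , ], ncol = 3L)
}

#' Read a trajectory from disk
#'
#' Supports multi-model PDB (MODEL/ENDMDL) and CHARMM/NAMD-dialect DCD,
#' dispatched on file extension. Neither format carries absolute time, so
#' frame times are `(frame index) * dt`.
#'
#' @param path trajectory file (`.pdb` multi-model or `.dcd`).
#' @param structure the matching `md_structure`; frame atom counts must agree.
#' @param dt time per frame in ns (default 0.1).
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, structure, dt = 0.1) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  stopifnot(inherits(structure, "md_structure"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    m <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    m <- pdb$xyz
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  }
  nf <- nrow(m)
  if (nf < 1L) stop("zero frames")
  na <- ncol(m) / 3L
  if (na != n_atoms(structure))
    stop("frame atom count (", na, ") does not match structure (",
         n_atoms(structure), "): wrong structure/trajectory pairing?")
  coords <- array(0, dim = c(nf, na, 3L))
  for (f in seq_len(nf)) coords[f, , ] <- matrix(m[f, ], ncol = 3L, byrow = TRUE)
  md_trajectory(structure, coords, times = seq_len(nf) * dt)
}

#' Restrict a trajectory to a subset of frames
#' @param traj an `md_trajectory`.
#' @param frames increasing vector of frame indices.
#' @return An `md_trajectory` over the chosen frames.
#' @export
subset_frames <- function(traj, frames) {
  stopifnot(inherits(traj, "md_trajectory"))
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > n_frames(traj))) stop("frame index out of range")
  md_trajectory(traj$structure,
                traj$coords[frames, , , drop = FALSE],
                traj$times[frames])
}
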