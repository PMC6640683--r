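# Shared fixtures and independent oracles, all built in code.

# small protein-like structure: n_res residues on chain(s), 4 heavy atoms each
mini_structure <- function(n_res = 10L, chains = "A",
                           atom_names = c("N", "CA", "C", "O")) {
  rows <- list()
  xyz <- list()
  aid <- 0L
  for (ch in chains) {
    for (r in seq_len(n_res)) {
      for (k in seq_along(atom_names)) {
        aid <- aid + 1L
        rows[[aid]] <- data.frame(
          atom_id = aid, atom_name = atom_names[k], resid = r,
          resname = "GLY", chain = ch, element = substr(atom_names[k], 1, 1),
          insert = "", stringsAsFactors = FALSE)
        # a gentle helix so nothing is collinear
        t <- r + k / 10
        xyz[[aid]] <- c(3 * cos(t) + match(ch, chains) * 30,
                        3 * sin(t), 1.5 * t)
      }
    }
  }
  md_structure(do.call(rbind, rows), do.call(rbind, xyz))
}

# rigid tumble of a base conformation: each frame a random rotation + shift
rigid_tumble <- function(structure, n_frames = 5L, seed = 1L) {
  set.seed(seed)
  x0 <- structure$xyz
  coords <- array(0, dim = c(n_frames, nrow(x0), 3L))
  coords[1, , ] <- x0
  for (f in seq_len(n_frames)[-1]) {
    ax <- stats::rnorm(3)
    r <- rotation_matrix(ax, stats::runif(1, 0, 180))
    coords[f, , ] <- sweep(x0 %*% t(r), 2L, -stats::rnorm(3, sd = 10))
  }
  md_trajectory(structure, coords, times = seq_len(n_frames) * 0.1)
}

# independent superposition oracle: minimum RMSD over n_rot random proper
# rotations (uniform via unit quaternions), each followed by the optimal
# translation (centroid matching), evaluated through the trace identity
rotation_sampling_min <- function(mobile, reference, n_rot = 10000L,
                                  seed = 1L) {
  set.seed(seed)
  Xc <- scale(mobile, scale = FALSE)
  Yc <- scale(reference, scale = FALSE)
  q <- matrix(stats::rnorm(4L * n_rot), 4L)
  q <- q / rep(sqrt(colSums(q^2)), each = 4L)
  w <- q[1, ]; x <- q[2, ]; y <- q[3, ]; z <- q[4, ]
  rmats <- rbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                 2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                 2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
  m <- crossprod(Xc, Yc)
  ss <- sum(Xc^2) + sum(Yc^2) - 2 * colSums(rmats * as.vector(t(m)))
  sqrt(max(min(ss), 0) / nrow(mobile))
}

# direct per-residue RMSF (time average of residue-mean squared displacement
# from the per-atom time mean, square-rooted) on an aligned coordinate array
direct_rmsf <- function(coords, groups) {
  nf <- dim(coords)[1]
  mean_xyz <- apply(coords, c(2, 3), mean)
  msd_atom <- rowSums(apply(coords, 1, function(fr)
    rowSums((matrix(fr, ncol = 3L) - mean_xyz)^2))) / nf
  vapply(groups, function(g) sqrt(mean(msd_atom[g])), numeric(1))
}

# alignment by an independent engine (bio3d) for dual-route RMSD checks
bio3d_fitted_rmsd <- function(mobile, reference) {
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(reference)),
                           mobile = as.vector(t(mobile)),
                           fixed.inds = seq_len(3 * nrow(reference)),
                           mobile.inds = seq_len(3 * nrow(mobile)))
  sqrt(mean(rowSums((matrix(fitted, ncol = 3L, byrow = TRUE) - reference)^2)))
}
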