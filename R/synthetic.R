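#' Build a toy Y-shaped antibody and its domain map
#'
#' Constructs a four-chain immunoglobulin mimic: two heavy chains (B left,
#' D right) running tip-to-tip from a Fab arm through a 10-residue central
#' linker into the Fc stem, and two light chains (A, C) paired along the
#' arms, giving the canonical 12-domain decomposition (VL/CL per light
#' chain; VH/CH1/CH2/CH3 per heavy chain). Residues are laid out as CA-only
#' beads (optionally 4 atoms per residue) along smooth per-domain curves
#' whose lateral wiggle vanishes at domain ends, so the four anchors —
#' Fab-left and Fab-right tips, Fc tip, and the linker midpoint — sit
#' exactly on the construction axes.
#'
#' The two Fab arms subtend `arm_angle` (so the top hinge angle of frame 0
#' is the construction value), and the molecule is planar by default, which
#' makes the three hinge angles sum to exactly 360 degrees; `fc_tilt` lifts
#' the Fc axis out of plane to break that.
#'
#' @param n_res_per_domain residues per domain (>= 4; default 8).
#' @param atoms_per_residue 1 (CA-only, default) or 4 (N, CA, C, O at fixed
#'   offsets), exercising multi-atom residues in the RMSF formula.
#' @param arm_angle angle between the Fab arms, degrees (default 110).
#' @param fc_tilt out-of-plane tilt of the Fc axis, degrees (default 0).
#' @param spacing along-curve residue spacing, Angstrom (default 3.8, the
#'   CA-CA virtual bond length).
#' @param wiggle lateral curve amplitude, Angstrom (default 1.2; keeps every
#'   domain non-collinear so local superposition is well-posed).
#' @return List with `structure` (`md_structure`) and `map` (`domain_map`
#'   with regions `fab_left`, `fab_right`, `fc` and anchors `fab_left`,
#'   `fab_right`, `fc`, `hinge` resolved).
#' @export
make_toy_antibody <- function(n_res_per_domain = 8L, atoms_per_residue = 1L,
                              arm_angle = 110, fc_tilt = 0, spacing = 3.8,
                              wiggle = 1.2) {
  n <- as.integer(n_res_per_domain)
  if (n < 4L) stop("n_res_per_domain must be >= 4")
  if (!atoms_per_residue %in% c(1L, 4L))
    stop("atoms_per_residue must be 1 or 4")
  half <- arm_angle / 2 * pi / 180
  tilt <- fc_tilt * pi / 180
  u_l <- c(-sin(half), cos(half), 0)
  u_r <- c(sin(half), cos(half), 0)
  u_f <- c(0, -cos(tilt), sin(tilt))
  l_arm <- 2 * n * spacing
  n_link <- 10L

  # residues j = 1..m from arc positions `arc` along u from the origin,
  # with lateral wiggle zeroed at both domain ends
  domain_curve <- function(u, arc, offset = c(0, 0, 0), amp = wiggle,
                           phase = 0) {
    m <- length(arc)
    t <- if (m > 1L) (seq_len(m) - 1) / (m - 1) else 0
    p <- c(-u[2], u[1], 0)
    p <- p / sqrt(sum(p^2))
    lat <- amp * sin(2 * pi * 1.5 * t + phase) * sin(pi * t)
    outer(arc, u) + outer(lat, p) +
      matrix(offset, m, 3L, byrow = TRUE)
  }

  heavy_chain <- function(u_arm, fc_offset) {
    arm_arc <- l_arm - (seq_len(2 * n) - 1) * spacing   # tip inward
    vh <- domain_curve(u_arm, arm_arc[seq_len(n)])
    ch1 <- domain_curve(u_arm, arm_arc[n + seq_len(n)], phase = 1)
    link <- t(vapply(seq_len(n_link), function(k) {
      if (k <= 5L) u_arm * 0.5 * spacing * (5 - k) / 4
      else u_f * 0.5 * spacing * (k - 5) / 5
    }, numeric(3)))
    fc_arc <- (0.5 + seq_len(2 * n)) * spacing
    ch2 <- domain_curve(u_f, fc_arc[seq_len(n)], offset = fc_offset)
    ch3 <- domain_curve(u_f, fc_arc[n + seq_len(n)], offset = fc_offset,
                        phase = 2)
    rbind(vh, ch1, link, ch2, ch3)
  }
  light_chain <- function(u_arm) {
    arm_arc <- l_arm - (seq_len(2 * n) - 1) * spacing
    vl <- domain_curve(u_arm, arm_arc[seq_len(n)], offset = c(0, 0, 5),
                       phase = 2)
    cl <- domain_curve(u_arm, arm_arc[n + seq_len(n)], offset = c(0, 0, 5),
                       phase = 3)
    rbind(vl, cl)
  }

  # Fc stems of the two heavy chains run parallel, offset to either side
  p_f <- c(1, 0, 0)
  chains <- list(
    A = light_chain(u_l),
    B = heavy_chain(u_l, fc_offset = 1.0 * p_f),
    C = light_chain(u_r),
    D = heavy_chain(u_r, fc_offset = -1.0 * p_f)
  )

  atom_rows <- list()
  xyz_rows <- list()
  aid <- 0L
  for (ch in names(chains)) {
    ca <- chains[[ch]]
    nres <- nrow(ca)
    for (j in seq_len(nres)) {
      if (atoms_per_residue == 1L) {
        names_j <- "CA"
        off <- matrix(0, 1L, 3L)
      } else {
        names_j <- c("N", "CA", "C", "O")
        off <- rbind(c(-1.2, 0.4, 0.3), c(0, 0, 0),
                     c(1.2, 0.4, -0.3), c(1.8, 1.5, -0.3))
      }
      for (k in seq_along(names_j)) {
        aid <- aid + 1L
        atom_rows[[aid]] <- data.frame(
          atom_id = aid, atom_name = names_j[k], resid = j,
          resname = "ALA", chain = ch,
          element = substr(names_j[k], 1, 1), insert = "",
          stringsAsFactors = FALSE)
        xyz_rows[[aid]] <- ca[j, ] + off[k, ]
      }
    }
  }
  structure_ <- md_structure(do.call(rbind, atom_rows),
                             do.call(rbind, xyz_rows))

  frag <- function(label, chain, start, end)
    data.frame(label = label, chain = chain, start = start, end = end,
               stringsAsFactors = FALSE)
  fragments <- rbind(
    frag("VL_A", "A", 1L, n), frag("CL_A", "A", n + 1L, 2L * n),
    frag("VL_C", "C", 1L, n), frag("CL_C", "C", n + 1L, 2L * n),
    frag("VH_B", "B", 1L, n), frag("CH1_B", "B", n + 1L, 2L * n),
    frag("linker_B", "B", 2L * n + 1L, 2L * n + n_link),
    frag("CH2_B", "B", 2L * n + n_link + 1L, 3L * n + n_link),
    frag("CH3_B", "B", 3L * n + n_link + 1L, 4L * n + n_link),
    frag("VH_D", "D", 1L, n), frag("CH1_D", "D", n + 1L, 2L * n),
    frag("linker_D", "D", 2L * n + 1L, 2L * n + n_link),
    frag("CH2_D", "D", 2L * n + n_link + 1L, 3L * n + n_link),
    frag("CH3_D", "D", 3L * n + n_link + 1L, 4L * n + n_link))
  regions <- list(
    fab_left = c("VH_B", "CH1_B", "VL_A", "CL_A"),
    fab_right = c("VH_D", "CH1_D", "VL_C", "CL_C"),
    fc = c("CH2_B", "CH3_B", "CH2_D", "CH3_D"))
  anchors <- data.frame(
    label = c("fab_left", "fab_right", "hinge", "fc"),
    chain = c("B", "D", "B", "B"),
    resid = c(1L, 1L, 2L * n + 5L, 4L * n + n_link),
    rule = "CA", stringsAsFactors = FALSE)
  map <- domain_map(fragments, regions, anchors, structure = structure_)
  list(structure = structure_, map = map)
}

#' Hinge angle schedule
#'
#' Angle (degrees) as a function of frame index, used by [hinge_program()].
#'
#' @param type `"constant"`, `"linear"` or `"sinusoid"`.
#' @param value constant angle (constant type), degrees.
#' @param from,to ramp endpoints (linear type), degrees.
#' @param amp,period,phase sinusoid amplitude (deg), period (frames) and
#'   phase (rad).
#' @return A `hinge_schedule`.
#' @export
hinge_schedule <- function(type = c("constant", "linear", "sinusoid"),
                           value = 0, from = 0, to = 0,
                           amp = 0, period = 100, phase = 0) {
  type <- match.arg(type)
  structure(list(type = type, value = value, from = from, to = to,
                 amp = amp, period = period, phase = phase),
            class = "hinge_schedule")
}

#' Evaluate a schedule over frames
#' @param schedule a `hinge_schedule`.
#' @param n_frames number of frames it must cover.
#' @return Numeric vector of angles (degrees), length `n_frames`.
#' @export
schedule_angles <- function(schedule, n_frames) {
  stopifnot(inherits(schedule, "hinge_schedule"))
  switch(schedule$type,
         constant = rep(schedule$value, n_frames),
         linear = seq(schedule$from, schedule$to, length.out = n_frames),
         sinusoid = schedule$amp *
           sin(2 * pi * (seq_len(n_frames) - 1) / schedule$period +
               schedule$phase))
}

#' One hinge of the kinematic program
#'
#' @param region region label in the domain map whose atoms rotate rigidly.
#' @param schedule a `hinge_schedule` giving the rotation angle per frame.
#' @param axis rotation axis (normalized internally; default +z, the normal
#'   of the default planar construction).
#' @param pivot anchor label used as the pivot point (default `"hinge"`).
#' @return A `hinge` specification.
#' @export
hinge_program <- function(region, schedule, axis = c(0, 0, 1),
                          pivot = "hinge") {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("zero hinge axis")
  structure(list(region = region, schedule = schedule, axis = axis / nrm,
                 pivot = pivot), class = "hinge")
}

#' Per-residue fluctuation amplitudes
#'
#' Isotropic Gaussian noise amplitude per residue (`sigma`, Angstrom per
#' coordinate), with optional terminal ramps that scale amplitudes linearly
#' up to `peak` x sigma at a chain terminus — emulating the elevated
#' C-terminal mobility of partially unfolding loops.
#'
#' @param sigma base amplitude, Angstrom per coordinate (scalar).
#' @param ramps list of ramps, each
#'   `list(chain =, terminal = "C" or "N", length =, peak =)`.
#' @return A `fluctuation_spec`.
#' @export
fluctuation_spec <- function(sigma = 0.3, ramps = list()) {
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(sigma = sigma, ramps = ramps), class = "fluctuation_spec")
}

# per-atom sigma vector for a structure
expand_sigma <- function(structure, spec) {
  a <- structure$atoms
  sig_res <- rep(spec$sigma, nrow(a))
  for (rmp in spec$ramps) {
    in_chain <- a$chain == rmp$chain
    resids <- a$resid[in_chain]
    if (length(resids) == 0L) stop("ramp chain '", rmp$chain, "' not found")
    rmax <- max(resids)
    rmin <- min(resids)
    if (rmp$length > (rmax - rmin + 1L))
      stop("ramp longer than chain ", rmp$chain)
    if (identical(rmp$terminal, "C")) {
      d <- rmax - a$resid          # 0 at the C terminus
    } else {
      d <- a$resid - rmin
    }
    scale <- 1 + (rmp$peak - 1) * pmax(0, 1 - d / rmp$length)
    sig_res[in_chain] <- sig_res[in_chain] * scale[in_chain]
  }
  sig_res
}

#' Ground truth for a synthetic trajectory
#'
#' Fully determines a generated trajectory given the template structure:
#' the hinge program, the fluctuation spec, an optional global rigid-body
#' motion (steady tumble + drift along a seeded random axis/direction), the
#' seed and the frame spacing. The single seed expands to fixed per-stream
#' seeds (noise: seed+1000, global motion: seed+2000, ion placement:
#' seed+3000) so streams stay independent and reproducible.
#'
#' @param hinges list of [hinge_program()] specifications.
#' @param fluct a [fluctuation_spec()].
#' @param global `NULL` for no global motion, or
#'   `list(rot_deg_per_frame =, drift_A_per_frame =)`.
#' @param seed integer RNG seed.
#' @param dt frame spacing, ns (default 0.1).
#' @return A `ground_truth`.
#' @export
ground_truth <- function(hinges = list(), fluct = fluctuation_spec(0),
                         global = NULL, seed = 1L, dt = 0.1) {
  if (dt <= 0) stop("dt must be > 0")
  structure(list(hinges = hinges, fluct = fluct, global = global,
                 seed = as.integer(seed), dt = dt), class = "ground_truth")
}

#' Generate a synthetic trajectory
#'
#' Per frame, in order: each hinge region is rotated rigidly about its pivot
#' by the programmed angle; iid isotropic Gaussian noise (per-residue sigma,
#' per coordinate, uncorrelated between frames) is added; an optional global
#' rigid tumble-and-drift is applied. Deterministic given
#' (structure, truth, n_frames).
#'
#' @param structure template `md_structure`.
#' @param map `domain_map` resolving hinge regions and pivots.
#' @param truth a [ground_truth()].
#' @param n_frames number of frames to generate.
#' @return An `md_trajectory` carrying `truth` in attribute
#'   `"ground_truth"`.
#' @export
simulate_trajectory <- function(structure, map, truth, n_frames) {
  stopifnot(inherits(structure, "md_structure"),
            inherits(map, "domain_map"), inherits(truth, "ground_truth"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  x0 <- structure$xyz
  na <- nrow(x0)

  hinge_data <- lapply(truth$hinges, function(h) {
    sched <- schedule_angles(h$schedule, n_frames)
    if (length(sched) < n_frames) stop("schedule shorter than n_frames")
    pivot <- anchor_point(x0, structure, map, h$pivot)
    idx <- region_atoms(structure, map, h$region)$indices
    list(idx = idx, pivot = pivot, axis = h$axis, sched = sched)
  })

  sig_atom <- expand_sigma(structure, truth$fluct)

  if (!is.null(truth$global)) {
    set.seed(truth$seed + 2000L)
    g_axis <- stats::rnorm(3)
    g_axis <- g_axis / sqrt(sum(g_axis^2))
    g_dir <- stats::rnorm(3)
    g_dir <- g_dir / sqrt(sum(g_dir^2))
    g_center <- colMeans(x0)
  }

  set.seed(truth$seed + 1000L)
  coords <- array(0, dim = c(n_frames, na, 3L))
  for (f in seq_len(n_frames)) {
    x <- x0
    for (h in hinge_data) {
      r <- rotation_matrix(h$axis, h$sched[f])
      x[h$idx, ] <- sweep(sweep(x[h$idx, , drop = FALSE], 2L, h$pivot) %*%
                            t(r), 2L, -h$pivot)
    }
    if (any(sig_atom > 0))
      x <- x + matrix(stats::rnorm(na * 3L, sd = sig_atom), na, 3L)
    if (!is.null(truth$global)) {
      rg <- rotation_matrix(g_axis, truth$global$rot_deg_per_frame * f)
      x <- sweep(sweep(x, 2L, g_center) %*% t(rg), 2L, -g_center)
      x <- sweep(x, 2L, -g_dir * truth$global$drift_A_per_frame * f)
    }
    coords[f, , ] <- x
  }
  traj <- md_trajectory(structure, coords, times = seq_len(n_frames) * truth$dt)
  attr(traj, "ground_truth") <- truth
  traj
}

#' Programmed (noise-free) hinge-angle series
#'
#' Runs the kinematic program of a ground truth with noise and global motion
#' switched off — the reference the recovery tests compare measured angle
#' series against.
#'
#' @inheritParams simulate_trajectory
#' @return Named list of three `md_timeseries` as from [angle_series()].
#' @export
programmed_angle_series <- function(structure, map, truth, n_frames) {
  quiet <- ground_truth(hinges = truth$hinges, fluct = fluctuation_spec(0),
                        global = NULL, seed = truth$seed, dt = truth$dt)
  angle_series(simulate_trajectory(structure, map, quiet, n_frames), map)
}

#' Rotation matrix about an axis (Rodrigues)
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation angle, degrees (right-handed).
#' @return 3 x 3 rotation matrix (column convention, `x' = R %*% x`).
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- as.numeric(axis)
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3L) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' Write a ground-truth sidecar
#'
#' JSON record of the hinge program, fluctuation spec, global-motion
#' schedule, seed and dt, for test harnesses consuming generated
#' trajectories from disk.
#'
#' @param truth a `ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  ser <- list(
    hinges = lapply(truth$hinges, function(h)
      list(region = h$region, axis = h$axis, pivot = h$pivot,
           schedule = unclass(h$schedule))),
    fluct = unclass(truth$fluct),
    global = truth$global, seed = truth$seed, dt = truth$dt)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a ground-truth sidecar
#' @param path JSON file written by [write_ground_truth()].
#' @return A `ground_truth`.
#' @export
read_ground_truth <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  hinges <- lapply(y$hinges, function(h)
    hinge_program(h$region,
                  do.call(hinge_schedule, h$schedule),
                  axis = h$axis, pivot = h$pivot))
  ground_truth(hinges = hinges,
               fluct = fluctuation_spec(y$fluct$sigma,
                                        y$fluct$ramps %||% list()),
               global = y$global, seed = y$seed, dt = y$dt)
}
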