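#' Run the full analysis pipeline
#'
#' Drives the standard battery over one trajectory: total RMSD
#' (whole-molecule fit), per-chain and per-domain RMSD (each fragment fit on
#' itself), per-chain RMSF profiles (local fit), hinge-angle series, and
#' steady-state window statistics, writing one CSV per analysis plus a run
#' log. Outputs are deterministic: re-running the same config and seed
#' reproduces the files byte for byte.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{structure}{`md_structure` or PDB path.}
#'     \item{trajectory}{`md_trajectory` or trajectory path.}
#'     \item{dt}{ns per frame when reading a trajectory file (default 0.1).}
#'     \item{domain_map}{`domain_map` or YAML path (required for domain /
#'       angle analyses).}
#'     \item{atom_class}{atom class for metrics (default `"heavy"`).}
#'     \item{analyses}{character subset of `c("rmsd_total", "rmsd_chain",
#'       "rmsd_domain", "rmsf", "angles")` (default: all).}
#'     \item{window}{length-2 steady-state window bounds in ns (default:
#'       trailing half of the trajectory).}
#'     \item{outdir}{output directory (created).}
#'     \item{seed}{integer recorded in the log (default 1).}
#'   }
#' @return Named list of written file paths (invisibly also the parsed
#'   config in attribute `"config"`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  cfg$atom_class <- cfg$atom_class %||% "heavy"
  cfg$analyses <- cfg$analyses %||%
    c("rmsd_total", "rmsd_chain", "rmsd_domain", "rmsf", "angles")
  cfg$seed <- cfg$seed %||% 1L
  cfg$dt <- cfg$dt %||% 0.1
  if (is.null(cfg$outdir)) stop("config requires an outdir")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  s <- stage("load structure",
             if (inherits(cfg$structure, "md_structure")) cfg$structure
             else read_structure(cfg$structure))
  traj <- stage("load trajectory",
                if (inherits(cfg$trajectory, "md_trajectory")) cfg$trajectory
                else read_trajectory(cfg$trajectory, s, dt = cfg$dt))
  map <- NULL
  if (!is.null(cfg$domain_map))
    map <- stage("load domain map",
                 if (inherits(cfg$domain_map, "domain_map")) cfg$domain_map
                 else read_domain_map(cfg$domain_map, s))
  needs_map <- intersect(cfg$analyses, c("rmsd_domain", "angles"))
  if (length(needs_map) > 0L && is.null(map))
    stop("analyses ", paste(needs_map, collapse = ", "),
         " require a domain_map")

  window <- cfg$window %||%
    c(traj$times[1] + diff(range(traj$times)) / 2, max(traj$times))
  if (window[1] >= window[2]) stop("window bounds must be ordered")

  out <- list()
  wstats <- list()
  chains <- sort(unique(s$atoms$chain))

  if ("rmsd_total" %in% cfg$analyses) {
    all_set <- select_atoms(s, class = cfg$atom_class, label = "all")
    ser <- stage("rmsd_total", rmsd_series(traj, 1L, all_set))
    ser$label <- "total"
    out$rmsd_total <- file.path(cfg$outdir, "rmsd_total.csv")
    write_series_csv(ser, out$rmsd_total)
    wstats$total <- window_stats(ser, window[1], window[2])
  }
  if ("rmsd_chain" %in% cfg$analyses) {
    sers <- stage("rmsd_chain", lapply(chains, function(ch) {
      set <- select_atoms(s, chain = ch, class = cfg$atom_class,
                          label = paste0("chain_", ch))
      rmsd_series(traj, 1L, set)
    }))
    names(sers) <- paste0("chain_", chains)
    out$rmsd_chain <- file.path(cfg$outdir, "rmsd_chains.csv")
    write_series_csv(sers, out$rmsd_chain)
    for (nm in names(sers))
      wstats[[nm]] <- window_stats(sers[[nm]], window[1], window[2])
  }
  if ("rmsd_domain" %in% cfg$analyses) {
    labs <- unique(map$fragments$label)
    sers <- stage("rmsd_domain", lapply(labs, function(lab) {
      set <- fragment_atoms(s, map, lab, class = cfg$atom_class)
      rmsd_series(traj, 1L, set)
    }))
    names(sers) <- labs
    out$rmsd_domain <- file.path(cfg$outdir, "rmsd_domains.csv")
    write_series_csv(sers, out$rmsd_domain)
  }
  if ("rmsf" %in% cfg$analyses) {
    profs <- stage("rmsf", lapply(chains, function(ch) {
      set <- select_atoms(s, chain = ch, class = cfg$atom_class,
                          label = paste0("chain_", ch))
      rmsf_profile(traj, set, fit_mode = "local")
    }))
    df <- do.call(rbind, lapply(profs, as.data.frame))
    out$rmsf <- file.path(cfg$outdir, "rmsf_chains.csv")
    con <- file(out$rmsf, "w")
    writeLines(paste0("# per-residue RMSF [A], local per-chain fit, ",
                      n_frames(traj), " frames"), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  if ("angles" %in% cfg$analyses) {
    ang <- stage("angles", angle_series(traj, map))
    out$angles <- file.path(cfg$outdir, "angles.csv")
    write_angles_csv(ang, out$angles, map = map)
  }

  if (length(wstats) > 0L) {
    wdf <- do.call(rbind, lapply(names(wstats), function(nm)
      data.frame(series = nm, t_start = wstats[[nm]]$t_start,
                 t_end = wstats[[nm]]$t_end, mean = wstats[[nm]]$mean,
                 sd = wstats[[nm]]$sd, n = wstats[[nm]]$n_points)))
    out$window_stats <- file.path(cfg$outdir, "window_stats.csv")
    utils::write.csv(wdf, out$window_stats, row.names = FALSE)
  }

  out$log <- file.path(cfg$outdir, "run_log.txt")
  writeLines(c(
    paste0("abtraj ", as.character(utils::packageVersion("abtraj"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("seed: ", cfg$seed),
    paste0("atom_class: ", cfg$atom_class),
    paste0("analyses: ", paste(cfg$analyses, collapse = ", ")),
    paste0("frames: ", n_frames(traj)),
    sprintf("window: %.6g..%.6g ns", window[1], window[2])
  ), out$log)
  attr(out, "config") <- cfg
  invisible(out)
}
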