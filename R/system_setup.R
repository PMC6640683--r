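#' Solvation box dimensions for a padded system
#'
#' Axis-aligned bounding box of all atoms plus twice the padding per axis —
#' the arithmetic behind "a water box extending at least d Angstrom from any
#' solute atom".
#'
#' @param structure an `md_structure`.
#' @param padding minimum solute-to-wall distance, Angstrom (default 30).
#' @return Numeric length-3 edge lengths (x, y, z), Angstrom.
#' @export
padded_box <- function(structure, padding = 30) {
  stopifnot(inherits(structure, "md_structure"))
  if (padding < 0) stop("padding must be >= 0")
  ext <- apply(structure$xyz, 2L, function(v) diff(range(v)))
  as.numeric(ext + 2 * padding)
}

AVOGADRO <- 6.02214076e23
WATER_MOLARITY <- 55.345   # mol/L, pure water at simulation conditions

#' Ion pairs for a 1:1 salt at a given ionic strength
#'
#' For a monovalent 1:1 salt the ionic strength equals the salt
#' concentration, so the pair count follows directly from either the box
#' volume (`n = round(c * N_A * V)`) or, as some solvation tools do, from
#' the water count (`n = round(c / 55.345 * n_waters)`). Both conventions
#' are offered because deposited systems rarely state which was used; an
#' equal number of cations and anions keeps the box electroneutral around a
#' neutral solute.
#'
#' @param box length-3 box edge lengths, Angstrom.
#' @param ionic_strength mol/L, >= 0.
#' @param convention `"volume"` (default) or `"water-ratio"`.
#' @param n_waters water molecule count, required for `"water-ratio"`.
#' @return Named list `n_cation`, `n_anion` (equal integers).
#' @export
ion_pairs <- function(box, ionic_strength,
                      convention = c("volume", "water-ratio"),
                      n_waters = NULL) {
  convention <- match.arg(convention)
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edges")
  if (ionic_strength < 0) stop("ionic_strength must be >= 0")
  n <- if (convention == "volume") {
    v_litre <- prod(box) * 1e-27          # A^3 -> L
    round(ionic_strength * AVOGADRO * v_litre)
  } else {
    if (is.null(n_waters) || n_waters < 0)
      stop("water-ratio convention requires n_waters >= 0")
    round(ionic_strength / WATER_MOLARITY * n_waters)
  }
  list(n_cation = as.integer(n), n_anion = as.integer(n))
}

#' Audit the composition of a solvated system
#'
#' Counts protein, water, cation, anion and other atoms by residue name —
#' the check run against a deposited solvated structure before trusting its
#' provenance. Water is HOH/TIP3/TIP3P/WAT/SPC; cations NA/SOD/POT/K;
#' anions CL/CLA. Unrecognized residues fall under `other` rather than
#' erroring.
#'
#' @param structure an `md_structure` (typically a solvated-system PDB).
#' @return A `system_audit` list: `protein_atoms`, `water_atoms`,
#'   `cations`, `anions`, `other_atoms`, `total_atoms`, `n_waters`
#'   (molecule count).
#' @export
audit_system <- function(structure) {
  stopifnot(inherits(structure, "md_structure"))
  a <- structure$atoms
  rn <- toupper(trimws(a$resname))
  rn[is.na(rn)] <- "NA"                      # string "NA" mangled upstream
  water <- rn %in% c("HOH", "TIP3", "TIP3P", "WAT", "SPC", "SOL")
  cation <- rn %in% c("NA", "SOD", "POT", "K")
  anion <- rn %in% c("CL", "CLA")
  amino <- rn %in% AMINO3
  other <- !(water | cation | anion | amino)
  wk <- paste(a$chain[water], a$resid[water], a$insert[water])
  structure(list(protein_atoms = sum(amino),
                 water_atoms = sum(water),
                 cations = sum(cation),
                 anions = sum(anion),
                 other_atoms = sum(other),
                 total_atoms = nrow(a),
                 n_waters = length(unique(wk))),
            class = "system_audit")
}

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
            "SER", "THR", "TRP", "TYR", "VAL")

#' @export
print.system_audit <- function(x, ...) {
  cat("system_audit:\n",
      sprintf("  protein atoms: %d\n", x$protein_atoms),
      sprintf("  water atoms:   %d (%d molecules)\n", x$water_atoms, x$n_waters),
      sprintf("  cations:       %d\n", x$cations),
      sprintf("  anions:        %d\n", x$anions),
      sprintf("  other:         %d\n", x$other_atoms),
      sprintf("  total:         %d\n", x$total_atoms), sep = "")
  invisible(x)
}

#' Write an audit report as JSON
#' @param audit a `system_audit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_audit_json <- function(audit, path) {
  jsonlite::write_json(unclass(audit), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Seeded random ion placement
#'
#' Uniform positions inside the box, rejecting candidates closer than
#' `min_dist` to any solute atom or previously placed ion. Plumbing for
#' synthetic solvated systems; makes no claim of reproducing any particular
#' solvation tool's placement.
#'
#' @param structure solute `md_structure` (assumed centered in the box).
#' @param n_cation,n_anion counts to place.
#' @param box length-3 edge lengths, Angstrom (origin at box center).
#' @param min_dist minimum separation, Angstrom (default 5).
#' @param seed integer RNG seed.
#' @param max_tries rejection-sampling cap per ion.
#' @return data.frame: `species` ("SOD"/"CLA"), `x`, `y`, `z`.
#' @export
place_ions <- function(structure, n_cation, n_anion, box, min_dist = 5,
                       seed = 1L, max_tries = 10000L) {
  set.seed(as.integer(seed) + 3000L)
  box <- as.numeric(box)
  solute <- structure$xyz
  center <- colMeans(solute)
  placed <- matrix(numeric(0), 0L, 3L)
  species <- character(0)
  for (sp in c(rep("SOD", n_cation), rep("CLA", n_anion))) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- center + (stats::runif(3) - 0.5) * box
      d_sol <- min(sqrt(rowSums(sweep(solute, 2L, p)^2)))
      d_ion <- if (nrow(placed) > 0L)
        min(sqrt(rowSums(sweep(placed, 2L, p)^2))) else Inf
      if (d_sol >= min_dist && d_ion >= min_dist) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place ion after ", max_tries, " tries")
    placed <- rbind(placed, p)
    species <- c(species, sp)
  }
  data.frame(species = species, x = placed[, 1], y = placed[, 2],
             z = placed[, 3], stringsAsFactors = FALSE)
}
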