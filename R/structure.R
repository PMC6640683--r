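#' Construct a molecular structure
#'
#' The static frame of reference for all trajectory analyses: an atom table
#' (identity) plus a coordinate matrix. Residue numbers follow PDB author
#' numbering, 1-based per chain; insertion codes, when present, are kept in
#' `insert` and appended to the residue key used for uniqueness checks.
#'
#' @param atoms data.frame with columns `atom_id` (integer), `atom_name`,
#'   `resid` (integer author residue number), `resname`, `chain`
#'   (single character), `element`, and optionally `insert`.
#' @param xyz numeric matrix, `nrow(atoms)` x 3, coordinates in Angstrom.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as_coord_matrix(xyz)
  needed <- c("atom_id", "atom_name", "resid", "resname", "chain", "element")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("no atoms")
  if (nrow(atoms) != nrow(xyz))
    stop("atom table (", nrow(atoms), ") and coordinates (", nrow(xyz),
         ") differ in length")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  key <- paste(atoms$chain, atoms$resid, atoms$insert, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom_name) identities: ",
         key[duplicated(key)][1L])
  structure(list(atoms = atoms, xyz = xyz), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s) [",
      paste(sort(unique(x$atoms$chain)), collapse = " "), "]\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure an `md_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) {
  stopifnot(inherits(structure, "md_structure"))
  nrow(structure$atoms)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (first MODEL only), preserving author residue
#' numbering and chain identifiers. Alternate locations are resolved to the
#' highest-occupancy conformer; ties keep the first listed.
#'
#' @param path path to a PDB file.
#' @return An `md_structure`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e)))
  atoms_from_bio3d(pdb)
}

atoms_from_bio3d <- function(pdb) {
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no atoms")
  # altloc resolution: per (chain,resid,insert,name) keep highest occupancy,
  # ties broken by file order
  alt <- a$alt
  alt[is.na(alt)] <- ""
  keep <- rep(TRUE, nrow(a))
  has_alt <- alt != "" & alt != " "
  if (any(has_alt)) {
    ins0 <- a$insert
    ins0[is.na(ins0)] <- ""
    key <- paste(a$chain, a$resno, ins0, a$elety)
    occ <- a$o
    occ[is.na(occ)] <- 1
    ord <- order(key, -occ, seq_len(nrow(a)))
    keep_idx <- ord[!duplicated(key[ord])]
    keep <- seq_len(nrow(a)) %in% keep_idx
  }
  a <- a[keep, , drop = FALSE]
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- " "
  elem <- a$elesy
  if (is.null(elem)) elem <- guess_element(a$elety)
  elem[is.na(elem) | elem == ""] <- guess_element(a$elety[is.na(elem) | elem == ""])
  ins <- a$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(
    atom_id = as.integer(a$eleno),
    atom_name = a$elety,
    resid = as.integer(a$resno),
    resname = a$resid,
    chain = chain,
    element = elem,
    insert = ins,
    stringsAsFactors = FALSE
  )
  xyz <- cbind(a$x, a$y, a$z)
  if (!all(is.finite(xyz))) stop("malformed coordinate fields")
  md_structure(atoms, xyz)
}

guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  # strip leading digits (e.g. "1HB"), take leading letter; two-letter ions
  nm <- sub("^[0-9]+", "", nm)
  two <- substr(nm, 1, 2)
  el <- substr(nm, 1, 1)
  el[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR", "CA ")] <-
    two[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR", "CA ")]
  el
}

#' Write a structure (or trajectory) to a PDB file
#'
#' Single structures produce plain ATOM records; trajectories are written as
#' multi-model PDB (MODEL/ENDMDL), the package's text trajectory format.
#'
#' @param x an `md_structure` or `md_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "md_trajectory")) {
    s <- x$structure
    con <- file(path, "w")
    on.exit(close(con))
    nf <- n_frames(x)
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(pdb_atom_lines(s$atoms, x$coords[f, , ]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  stopifnot(inherits(x, "md_structure"))
  writeLines(c(pdb_atom_lines(x$atoms, x$xyz), "END"), path)
  invisible(path)
}

pdb_atom_lines <- function(atoms, xyz) {
  xyz <- as_coord_matrix(xyz)
  name <- ifelse(nchar(atoms$atom_name) < 4,
                 sprintf(" %-3s", atoms$atom_name),
                 sprintf("%-4s", atoms$atom_name))
  sprintf("ATOM  %5d %s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$atom_id %% 100000L, name, substr(atoms$resname, 1, 4),
          substr(atoms$chain, 1, 1), atoms$resid %% 10000L,
          substr(paste0(atoms$insert, " "), 1, 1),
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, atoms$element)
}

# coerce to an n x 3 numeric matrix; a bare length-3 vector is one point
as_coord_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) == 3L) x <- matrix(as.numeric(x), 1L, 3L)
    else stop("coordinates must be an n x 3 matrix")
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must be an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}
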