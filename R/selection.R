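#' Select atoms from a structure
#'
#' Builds an `atom_set` (ordered, duplicate-free indices into the structure)
#' either from a small selection expression or from keyword arguments.
#' The expression grammar joins clauses with `and`:
#' `chain <id>`, `resid <a>-<b>` (or a single number), and an atom class
#' (`CA`, `backbone`, `heavy`, `all`), e.g. `"chain A and resid 1-30 and CA"`.
#'
#' @param structure an `md_structure`.
#' @param spec selection expression string, or `NULL` to use the keyword
#'   arguments.
#' @param chain chain id(s) to keep.
#' @param resid residue numbers to keep (vector; use `a:b` for a range).
#' @param class atom-name class: `"all"`, `"heavy"` (non-hydrogen, the
#'   default for metrics), `"backbone"` (N, CA, C, O), or `"CA"`.
#' @param label label recorded on the resulting set.
#' @param allow_empty return an empty set instead of erroring.
#' @return An object of class `atom_set`.
#' @export
select_atoms <- function(structure, spec = NULL, chain = NULL, resid = NULL,
                         class = "all", label = NULL, allow_empty = FALSE) {
  stopifnot(inherits(structure, "md_structure"))
  if (!is.null(spec)) {
    parsed <- parse_selection(spec)
    chain <- parsed$chain
    resid <- parsed$resid
    class <- parsed$class
    if (is.null(label)) label <- spec
  }
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid & a$insert == ""
  keep <- keep & atom_class_mask(a, class)
  idx <- which(keep)
  if (length(idx) == 0L && !allow_empty)
    stop("empty selection",
         if (!is.null(spec)) paste0(": '", spec, "'") else "")
  atom_set(idx, label = label %||% "selection", structure = structure)
}

parse_selection <- function(spec) {
  out <- list(chain = NULL, resid = NULL, class = "all")
  clauses <- trimws(strsplit(spec, "\\band\\b")[[1]])
  for (cl in clauses) {
    if (cl == "") next
    if (grepl("^chain\\s+", cl)) {
      out$chain <- strsplit(sub("^chain\\s+", "", cl), "\\s+")[[1]]
    } else if (grepl("^resid\\s+", cl)) {
      rng <- sub("^resid\\s+", "", cl)
      parts <- strsplit(rng, "-", fixed = TRUE)[[1]]
      if (length(parts) == 2L) {
        out$resid <- as.integer(parts[1]):as.integer(parts[2])
      } else {
        out$resid <- as.integer(parts[1])
      }
    } else if (cl %in% c("CA", "ca", "backbone", "heavy", "all")) {
      out$class <- if (cl == "ca") "CA" else cl
    } else {
      stop("cannot parse selection clause '", cl, "'")
    }
  }
  out
}

atom_class_mask <- function(atoms, class) {
  class <- match.arg(class, c("all", "heavy", "backbone", "CA"))
  switch(class,
         all = rep(TRUE, nrow(atoms)),
         heavy = !(toupper(atoms$element) %in% c("H", "D")),
         backbone = atoms$atom_name %in% c("N", "CA", "C", "O"),
         CA = atoms$atom_name == "CA")
}

#' Construct an atom set
#' @param indices integer atom indices into `structure`, in structure order.
#' @param label text label.
#' @param structure optionally, the `md_structure` the indices refer to
#'   (validates the indices and enables residue grouping).
#' @return An object of class `atom_set`.
#' @export
atom_set <- function(indices, label = "set", structure = NULL) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("duplicate atom indices")
  if (any(indices < 1L)) stop("atom indices must be positive")
  if (!is.null(structure) && length(indices) > 0 &&
      max(indices) > n_atoms(structure))
    stop("atom index exceeds structure size")
  structure(list(indices = indices, label = label), class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat("atom_set '", x$label, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

#' @export
length.atom_set <- function(x) length(x$indices)

#' Group an atom set by residue
#'
#' @param structure the `md_structure` the set indexes into.
#' @param set an `atom_set`.
#' @return A list with `chain`, `resid` (one entry per residue, in structure
#'   order) and `groups`, a list of atom-index vectors (the N_k atoms of each
#'   residue).
#' @export
group_by_residue <- function(structure, set) {
  stopifnot(inherits(structure, "md_structure"), inherits(set, "atom_set"))
  a <- structure$atoms[set$indices, , drop = FALSE]
  key <- paste(a$chain, a$resid, a$insert, sep = "\r")
  ukey <- unique(key)
  groups <- split(set$indices, factor(key, levels = ukey))
  first <- match(ukey, key)
  list(chain = a$chain[first], resid = a$resid[first], groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
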