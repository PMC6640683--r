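#' Construct a domain map
#'
#' Names the fragments (chains, immunoglobulin domains, linkers), the region
#' groups composed from them (the two Fabs and the Fc), and the anchor
#' residues used for hinge-angle triplets.
#'
#' @param fragments data.frame with columns `label`, `chain`, `start`, `end`
#'   (inclusive author residue numbers; a label may span several rows).
#' @param regions named list; each element a character vector of fragment
#'   labels.
#' @param anchors data.frame with columns `label`, `chain`, `resid` and
#'   optionally `rule` (`"CA"`, the default, or `"centroid"`).
#' @param structure optionally, an `md_structure` to validate/resolve against.
#' @return An object of class `domain_map`.
#' @export
domain_map <- function(fragments, regions = list(), anchors = NULL,
                       structure = NULL) {
  fragments <- as.data.frame(fragments, stringsAsFactors = FALSE)
  if (nrow(fragments) == 0L) stop("domain map declares zero fragments")
  stopifnot(all(c("label", "chain", "start", "end") %in% names(fragments)))
  if (any(fragments$end < fragments$start))
    stop("fragment residue range empty for '",
         fragments$label[fragments$end < fragments$start][1L], "'")
  # overlap within one label (same chain) is a config error
  for (lab in unique(fragments$label)) {
    rows <- fragments[fragments$label == lab, , drop = FALSE]
    for (ch in unique(rows$chain)) {
      r <- rows[rows$chain == ch, , drop = FALSE]
      if (nrow(r) > 1L) {
        r <- r[order(r$start), , drop = FALSE]
        if (any(r$start[-1L] <= r$end[-nrow(r)]))
          stop("overlapping residue ranges within fragment '", lab, "'")
      }
    }
  }
  for (rg in names(regions)) {
    bad <- setdiff(regions[[rg]], fragments$label)
    if (length(bad) > 0L)
      stop("region '", rg, "' references undefined fragment(s): ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(anchors)) {
    anchors <- as.data.frame(anchors, stringsAsFactors = FALSE)
    stopifnot(all(c("label", "chain", "resid") %in% names(anchors)))
    if (is.null(anchors$rule)) anchors$rule <- "CA"
    anchors$rule[is.na(anchors$rule)] <- "CA"
  }
  map <- structure(list(fragments = fragments, regions = regions,
                        anchors = anchors), class = "domain_map")
  if (!is.null(structure)) map <- resolve_anchors(map, structure)
  map
}

#' @export
print.domain_map <- function(x, ...) {
  cat("domain_map:", length(unique(x$fragments$label)), "fragments,",
      length(x$regions), "regions,",
      if (is.null(x$anchors)) 0L else nrow(x$anchors), "anchors\n")
  invisible(x)
}

#' Read a domain map from a YAML file
#'
#' The file declares `fragments` (list of label/chain/start/end entries, or
#' label/chain/ranges with a list of start/end pairs), `regions` (name ->
#' fragment-label list) and `anchors` (name -> chain/resid/rule). All anchors
#' are resolved against the structure; unresolvable anchors are an error.
#'
#' @param path YAML file.
#' @param structure `md_structure` to validate against.
#' @return A `domain_map` with anchors resolved to atom indices.
#' @export
read_domain_map <- function(path, structure) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  y <- yaml::read_yaml(path)
  if (is.null(y$fragments) || length(y$fragments) == 0L)
    stop("domain map declares zero fragments")
  frag_rows <- lapply(y$fragments, function(fr) {
    if (!is.null(fr$ranges)) {
      do.call(rbind, lapply(fr$ranges, function(r)
        data.frame(label = fr$label, chain = as.character(fr$chain),
                   start = as.integer(r$start), end = as.integer(r$end),
                   stringsAsFactors = FALSE)))
    } else {
      data.frame(label = fr$label, chain = as.character(fr$chain),
                 start = as.integer(fr$start), end = as.integer(fr$end),
                 stringsAsFactors = FALSE)
    }
  })
  fragments <- do.call(rbind, frag_rows)
  regions <- lapply(y$regions %||% list(), unlist)
  anchors <- NULL
  if (!is.null(y$anchors)) {
    anchors <- do.call(rbind, lapply(names(y$anchors), function(nm) {
      an <- y$anchors[[nm]]
      data.frame(label = nm, chain = as.character(an$chain),
                 resid = as.integer(an$resid),
                 rule = an$rule %||% "CA", stringsAsFactors = FALSE)
    }))
  }
  domain_map(fragments, regions, anchors, structure = structure)
}

# attach atom indices (or residue atom groups for centroid anchors)
resolve_anchors <- function(map, structure) {
  a <- structure$atoms
  # validate fragments touch the structure at all
  for (i in seq_len(nrow(map$fragments))) {
    fr <- map$fragments[i, ]
    hit <- a$chain == fr$chain & a$resid >= fr$start & a$resid <= fr$end
    if (!any(hit))
      stop("fragment '", fr$label, "' (chain ", fr$chain, " ", fr$start, "-",
           fr$end, ") matches no atoms in the structure")
  }
  if (!is.null(map$anchors)) {
    map$anchors$atom_index <- NA_integer_
    for (i in seq_len(nrow(map$anchors))) {
      an <- map$anchors[i, ]
      res_idx <- which(a$chain == an$chain & a$resid == an$resid &
                       a$insert == "")
      if (length(res_idx) == 0L)
        stop("anchor '", an$label, "': residue ", an$resid, " of chain ",
             an$chain, " absent from structure")
      if (an$rule == "CA") {
        ca <- res_idx[a$atom_name[res_idx] == "CA"]
        if (length(ca) != 1L)
          stop("anchor '", an$label, "': residue ", an$resid, " of chain ",
               an$chain, " has no unique CA atom")
        map$anchors$atom_index[i] <- ca
      } else if (an$rule == "centroid") {
        map$anchors$atom_index[i] <- res_idx[1L]
        attr(map, "anchor_groups") <-
          c(attr(map, "anchor_groups"), stats::setNames(list(res_idx), an$label))
      } else {
        stop("unknown anchor rule '", an$rule, "'")
      }
    }
  }
  map
}

#' Atoms of one named fragment
#'
#' @param structure an `md_structure`.
#' @param map a `domain_map`.
#' @param label fragment label.
#' @param class atom class filter (default `"all"`).
#' @return An `atom_set`.
#' @export
fragment_atoms <- function(structure, map, label, class = "all") {
  rows <- map$fragments[map$fragments$label == label, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown fragment '", label, "'")
  a <- structure$atoms
  keep <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(rows)))
    keep <- keep | (a$chain == rows$chain[i] & a$resid >= rows$start[i] &
                    a$resid <= rows$end[i] & a$insert == "")
  keep <- keep & atom_class_mask(a, class)
  idx <- which(keep)
  if (length(idx) == 0L) stop("fragment '", label, "' selects no atoms")
  atom_set(idx, label = label, structure = structure)
}

#' Atoms of one region group (e.g. a Fab or the Fc)
#'
#' @inheritParams fragment_atoms
#' @param region region name declared in the map.
#' @return An `atom_set` (union of the region's fragments, structure order).
#' @export
region_atoms <- function(structure, map, region, class = "all") {
  labs <- map$regions[[region]]
  if (is.null(labs)) stop("unknown region '", region, "'")
  idx <- sort(unique(unlist(lapply(labs, function(l)
    fragment_atoms(structure, map, l, class = class)$indices))))
  atom_set(idx, label = region, structure = structure)
}
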