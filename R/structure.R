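#' Parse a protein structure from PDB-format text
#'
#' Reads ATOM and HETATM records via bio3d after a light fixed-width
#' validation pass (so malformed records are reported with their line
#' number). Alternate locations are resolved by keeping, for each
#' (chain, residue, atom name), the altloc with the highest occupancy.
#'
#' @param pdb_text Character vector of PDB lines, a single string with
#'   embedded newlines, or a path to a PDB file.
#' @param cofactor Optional cofactor selector: either a HET residue name
#'   (e.g. `"ICS"`) or a list with `chain` and `resno` components.
#' @return Object of class `structure3d`: a list with `atoms` (data frame
#'   with serial, name, element, residue_name, residue_seq, chain, x, y, z,
#'   occupancy, record) and `cofactor` (the selector, possibly `NULL`).
#' @export
parse_structure <- function(pdb_text, cofactor = NULL) {
  if (length(pdb_text) == 1 && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    lines <- readLines(pdb_text)
  } else {
    lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE))
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records found in PDB input")
  atom_lines <- which(is_atom)
  for (ln in atom_lines) {
    line <- lines[ln]
    if (nchar(line) < 54) {
      stop("malformed PDB record at line ", ln, ": shorter than coordinate field")
    }
    coords <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                            substr(line, 39, 46),
                                            substr(line, 47, 54))))
    if (anyNA(coords) || any(!is.finite(coords))) {
      stop("malformed PDB record at line ", ln, ": non-numeric coordinates")
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  elem <- toupper(trimws(at$elesy))
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]

  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    element = elem,
    residue_name = trimws(at$resid),
    residue_seq = at$resno,
    chain = ifelse(is.na(at$chain), "", at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    record = at$type,
    stringsAsFactors = FALSE)

  # altloc resolution: highest occupancy per (chain, residue, atom name)
  key <- paste(atoms$chain, atoms$residue_seq, atoms$residue_name, atoms$name)
  ord <- order(key, -atoms$occupancy)
  atoms <- atoms[ord, ][!duplicated(key[ord]), ]
  atoms <- atoms[order(atoms$serial), ]
  rownames(atoms) <- NULL

  structure(list(atoms = atoms, cofactor = cofactor), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$residue_seq))), "residues\n")
  invisible(x)
}

water_names <- function() c("HOH", "WAT", "DOD", "H2O")

cofactor_atoms <- function(structure, cofactor = NULL) {
  sel <- if (is.null(cofactor)) structure$cofactor else cofactor
  if (is.null(sel)) stop("no cofactor selector set on this structure")
  at <- structure$atoms
  hit <- if (is.character(sel)) {
    at$residue_name == toupper(sel)
  } else {
    at$chain == sel$chain & at$residue_seq == sel$resno
  }
  if (!any(hit)) {
    hets <- unique(at$residue_name[at$record == "HETATM" &
                                     !(at$residue_name %in% water_names())])
    stop("cofactor selector matches no atoms; available het groups: ",
         if (length(hets)) paste(hets, collapse = ", ") else "(none)")
  }
  at[hit, , drop = FALSE]
}

#' Active-site extraction configuration
#'
#' @param cutoff Contact distance in Angstroms; a residue belongs to the
#'   active site when any of its atoms lies within `cutoff` of any cofactor
#'   atom. Default 5.
#' @param reference_sequence Optional protein sequence defining the
#'   reference numbering frame used by [map_positions()].
#' @return Object of class `active_site_config`.
#' @export
active_site_config <- function(cutoff = 5, reference_sequence = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0) {
    stop("'cutoff' must be a single non-negative number")
  }
  structure(list(cutoff = cutoff, reference_sequence = reference_sequence),
            class = "active_site_config")
}

#' Protein residues within a distance cutoff of the cofactor
#'
#' Returns every protein residue with at least one non-hydrogen atom whose
#' Euclidean distance to any cofactor atom is at most the cutoff. Cofactor
#' atoms themselves, waters, and other HETATM groups are excluded from the
#' candidate set; hydrogens are ignored in the distance test.
#'
#' @param structure A [parse_structure()] result with a cofactor selector.
#' @param config An [active_site_config()].
#' @param cofactor Optional selector overriding the one stored in
#'   `structure`.
#' @return Data frame with columns `chain`, `residue_seq`, `residue_name`,
#'   and `min_dist`, ordered by chain then residue number.
#' @export
residues_near_cofactor <- function(structure, config = active_site_config(),
                                   cofactor = NULL) {
  stopifnot(inherits(structure, "structure3d"),
            inherits(config, "active_site_config"))
  cof <- cofactor_atoms(structure, cofactor)
  at <- structure$atoms
  cand <- at$record == "ATOM" &
    !(at$residue_name %in% water_names()) &
    at$element != "H" &
    !(at$serial %in% cof$serial)
  at <- at[cand, , drop = FALSE]
  if (nrow(at) == 0) {
    return(data.frame(chain = character(), residue_seq = integer(),
                      residue_name = character(), min_dist = numeric()))
  }
  keep <- carve_keep_cpp(as.matrix(at[, c("x", "y", "z")]),
                         as.matrix(cof[, c("x", "y", "z")]),
                         rep(config$cutoff, nrow(cof)))
  # carve_keep_cpp drops points strictly inside the cutoff spheres; contacts
  # are exactly the dropped atoms plus boundary ties, so recompute min
  # distances for the reported residues explicitly.
  d2 <- min_sq_dist_cpp(as.matrix(at[, c("x", "y", "z")]),
                        as.matrix(cof[, c("x", "y", "z")]))
  at$min_dist <- sqrt(d2)
  hit <- at$min_dist <= config$cutoff
  if (!any(hit)) {
    return(data.frame(chain = character(), residue_seq = integer(),
                      residue_name = character(), min_dist = numeric()))
  }
  res <- at[hit, c("chain", "residue_seq", "residue_name", "min_dist")]
  agg <- stats::aggregate(min_dist ~ chain + residue_seq + residue_name,
                          data = res, FUN = min)
  agg <- agg[order(agg$chain, agg$residue_seq), ]
  rownames(agg) <- NULL
  agg
}

#' One-letter residue codes for a set of contacting residues
#'
#' @param residues Data frame from [residues_near_cofactor()].
#' @return Named character vector of one-letter codes (names are
#'   `chain:residue_seq`). Non-standard residues map to `X`.
#' @export
residue_one_letter <- function(residues) {
  codes <- bio3d::aa321(residues$residue_name)
  codes[is.na(codes)] <- "X"
  names(codes) <- paste0(residues$chain, ":", residues$residue_seq)
  codes
}
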