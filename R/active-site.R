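#' Labeled protein alignment
#'
#' Container for an aligned protein family with per-sequence metal-dependence
#' labels, matching the closed label set Nif / Vnf / Anf / unknown, plus an
#' optional reference row defining the numbering frame.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param labels Character vector of labels (recycled names of `seqs` order);
#'   each must be one of `"Nif"`, `"Vnf"`, `"Anf"`, `"unknown"`.
#' @param reference Name of the reference row, or `NULL`.
#' @return Object of class `labeled_alignment`.
#' @export
labeled_alignment <- function(seqs, labels = NULL, reference = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("'seqs' must be uniquely named")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) stop("aligned sequences must have equal length")
  if (is.null(labels)) labels <- rep("unknown", length(seqs))
  labels <- as.character(labels)
  ok <- labels %in% c("Nif", "Vnf", "Anf", "unknown")
  if (!all(ok)) stop("labels outside the closed set Nif/Vnf/Anf/unknown: ",
                     paste(unique(labels[!ok]), collapse = ", "))
  if (length(labels) != length(seqs)) stop("one label per sequence required")
  names(labels) <- names(seqs)
  if (!is.null(reference) && !(reference %in% names(seqs))) {
    stop("reference row '", reference, "' not present in the alignment")
  }
  structure(list(seqs = toupper(seqs), labels = labels, reference = reference),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("labeled_alignment:", length(x$seqs), "sequences x",
      nchar(x$seqs[[1]]), "columns\n")
  print(table(x$labels))
  invisible(x)
}

#' Alignment rows as a character matrix
#'
#' @param alignment A [labeled_alignment()].
#' @return Character matrix (sequences x columns) of single residues.
#' @export
alignment_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "labeled_alignment"))
  m <- do.call(rbind, strsplit(unname(alignment$seqs), ""))
  rownames(m) <- names(alignment$seqs)
  m
}

#' Read an aligned FASTA file with an optional label table
#'
#' @param fasta Path to an aligned protein FASTA file.
#' @param labels Optional path to a two-column TSV (name, label) or a named
#'   character vector.
#' @param reference Optional reference row name.
#' @return A [labeled_alignment()].
#' @export
read_labeled_alignment <- function(fasta, labels = NULL, reference = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lab <- rep("unknown", length(seqs))
  names(lab) <- names(seqs)
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
      tab <- utils::read.delim(labels, header = TRUE, stringsAsFactors = FALSE)
      labels <- stats::setNames(tab[[2]], tab[[1]])
    }
    lab[names(labels)] <- labels
  }
  labeled_alignment(seqs, lab, reference)
}

#' Write a labeled alignment to FASTA (and optionally a label TSV)
#'
#' @param alignment A [labeled_alignment()].
#' @param fasta Output FASTA path.
#' @param labels Optional output TSV path for the label table.
#' @return Invisibly, the FASTA path.
#' @export
write_labeled_alignment <- function(alignment, fasta, labels = NULL) {
  stopifnot(inherits(alignment, "labeled_alignment"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(alignment$seqs), fasta)
  if (!is.null(labels)) {
    utils::write.table(
      data.frame(name = names(alignment$labels), label = alignment$labels),
      labels, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' Map reference numbering onto a query sequence
#'
#' Aligns the query to the reference by global pairwise alignment (affine
#' gaps, BLOSUM62 scoring) and reads the induced position map off the
#' alignment: reference position `i` maps to the index of the query residue
#' aligned with it, or `NA` where the reference position falls in a query
#' gap.
#'
#' @param query_sequence,reference_sequence Ungapped protein sequences.
#' @return Object of class `site_map`: a data frame with columns
#'   `reference_position`, `query_index`, `query_residue`.
#' @export
map_positions <- function(query_sequence, reference_sequence) {
  q <- toupper(gsub("-", "", query_sequence))
  r <- toupper(gsub("-", "", reference_sequence))
  if (!nzchar(q) || !nzchar(r)) stop("both sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(r), Biostrings::AAString(q),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  ra <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  qa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- cumsum(ra != "-")
  qry_pos <- cumsum(qa != "-")
  keep <- ra != "-"
  map <- data.frame(
    reference_position = ref_pos[keep],
    query_index = ifelse(qa[keep] == "-", NA_integer_, qry_pos[keep]),
    query_residue = ifelse(qa[keep] == "-", NA_character_, qa[keep]),
    stringsAsFactors = FALSE)
  class(map) <- c("site_map", "data.frame")
  map
}

#' Union of cofactor-contacting positions across structures, in reference
#' numbering
#'
#' For each structure, finds the residues within the cutoff of its cofactor,
#' maps the structure's chain sequence onto the reference numbering frame by
#' pairwise alignment, and returns the sorted union of mapped reference
#' positions. Copies of the same position across homo-oligomer chains
#' collapse to one entry.
#'
#' @param structures List of [parse_structure()] results, each with its
#'   cofactor selector set.
#' @param reference_sequence Protein sequence defining the numbering frame.
#' @param config An [active_site_config()].
#' @return Sorted integer vector of reference positions.
#' @export
active_site_union <- function(structures, reference_sequence,
                              config = active_site_config()) {
  positions <- integer()
  for (s in structures) {
    near <- residues_near_cofactor(s, config)
    for (ch in unique(near$chain)) {
      at <- s$atoms
      sel <- at$record == "ATOM" & at$chain == ch & at$name == "CA" &
        !(at$residue_name %in% water_names())
      if (!any(sel)) next
      resno <- at$residue_seq[sel]
      codes <- bio3d::aa321(at$residue_name[sel])
      keep <- !is.na(codes)
      resno <- resno[keep]; codes <- codes[keep]
      chain_seq <- paste(codes, collapse = "")
      map <- map_positions(chain_seq, reference_sequence)
      hit_res <- near$residue_seq[near$chain == ch]
      hit_idx <- match(hit_res, resno)       # index within the chain sequence
      hit_idx <- hit_idx[!is.na(hit_idx)]
      positions <- c(positions,
                     map$reference_position[match(hit_idx, map$query_index)])
    }
  }
  sort(unique(positions[!is.na(positions)]))
}

#' Alignment columns realizing reference positions
#'
#' @param alignment A [labeled_alignment()] whose reference row, with gaps
#'   removed, is the reference sequence.
#' @param positions Integer vector of reference positions.
#' @return Integer vector of column indices, one per position.
#' @export
alignment_columns <- function(alignment, positions) {
  stopifnot(inherits(alignment, "labeled_alignment"))
  if (is.null(alignment$reference)) {
    stop("alignment has no reference row; set one to use reference numbering")
  }
  ref <- strsplit(alignment$seqs[[alignment$reference]], "")[[1]]
  res_cols <- which(ref != "-")
  if (any(positions < 1 | positions > length(res_cols))) {
    stop("reference positions outside the reference row: ",
         paste(positions[positions < 1 | positions > length(res_cols)],
               collapse = ", "))
  }
  res_cols[positions]
}

#' Extract the active-site sub-alignment
#'
#' Slices the alignment down to the columns realizing the given reference
#' positions (in increasing reference order), preserving labels.
#'
#' @param alignment A [labeled_alignment()] with a reference row.
#' @param positions Integer vector of reference positions (e.g. the 30
#'   cofactor-contacting positions).
#' @return A [labeled_alignment()] of `length(positions)` columns, with the
#'   positions stored in attribute `"positions"`.
#' @export
extract_active_site <- function(alignment, positions) {
  positions <- sort(unique(as.integer(positions)))
  cols <- alignment_columns(alignment, positions)
  m <- alignment_matrix(alignment)[, cols, drop = FALSE]
  seqs <- apply(m, 1, paste, collapse = "")
  out <- labeled_alignment(seqs, alignment$labels, alignment$reference)
  attr(out, "positions") <- positions
  out
}
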