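#' Percent identity between two aligned sequences
#'
#' Identity is computed over the scope columns where at least one of the
#' pair carries a residue: gap-gap columns are excluded, gap-residue columns
#' count as mismatches, so a sequence is always 100% identical to itself.
#'
#' @param seq_a,seq_b Aligned sequences of equal length.
#' @param scope_columns Optional integer vector restricting the comparison
#'   to particular columns; default all columns.
#' @return Percent identity in `[0, 100]` (`NaN` if no scorable columns).
#' @export
percent_identity <- function(seq_a, seq_b, scope_columns = NULL) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) {
    stop("aligned lengths differ: ", length(a), " vs ", length(b))
  }
  if (!is.null(scope_columns)) {
    a <- a[scope_columns]
    b <- b[scope_columns]
  }
  gap <- c("-", ".")
  scorable <- !(a %in% gap & b %in% gap)
  100 * sum(a == b & scorable & !(a %in% gap)) / sum(scorable)
}

#' Pairwise and group-mean identity over an alignment
#'
#' Computes the full pairwise percent-identity matrix over the requested
#' scope and averages it within each ordered pair of groups; within-group
#' means exclude self-comparisons.
#'
#' @param alignment A [labeled_alignment()].
#' @param groups Grouping vector, one entry per sequence; defaults to the
#'   alignment labels.
#' @param scope `"full"` (all columns) or `"active-site"`, which requires
#'   `positions` (or a `"positions"` attribute on the alignment sliced by
#'   [extract_active_site()]).
#' @param positions Reference positions defining the active-site scope.
#' @return Object of class `identity_report`: list with `pairwise` (n x n,
#'   percent), `group_mean` (g x g), and `scope`.
#' @export
group_mean_identity <- function(alignment, groups = NULL,
                                scope = c("full", "active-site"),
                                positions = NULL) {
  stopifnot(inherits(alignment, "labeled_alignment"))
  scope <- match.arg(scope)
  if (is.null(groups)) groups <- alignment$labels
  if (length(groups) != length(alignment$seqs)) {
    stop("one group per sequence required")
  }
  m <- alignment_matrix(alignment)
  if (scope == "active-site") {
    if (is.null(positions)) positions <- attr(alignment, "positions")
    if (is.null(positions)) {
      stop("active-site scope requires 'positions' or an alignment sliced ",
           "by extract_active_site()")
    }
    if (max(positions) <= ncol(m) && !is.null(alignment$reference)) {
      cols <- tryCatch(alignment_columns(alignment, positions),
                       error = function(e) positions)
    } else {
      cols <- positions
    }
    m <- m[, cols, drop = FALSE]
  }
  n <- nrow(m)
  gap <- m %in% c("-", ".")
  dim(gap) <- dim(m)
  pid <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      scorable <- !(gap[i, ] & gap[j, ])
      match_ij <- m[i, ] == m[j, ] & !gap[i, ] & scorable
      pid[i, j] <- pid[j, i] <- 100 * sum(match_ij) / sum(scorable)
    }
  }
  glev <- unique(groups)
  gm <- matrix(NA_real_, length(glev), length(glev),
               dimnames = list(glev, glev))
  for (ga in glev) {
    for (gb in glev) {
      ia <- which(groups == ga)
      ib <- which(groups == gb)
      vals <- pid[ia, ib, drop = FALSE]
      if (ga == gb) {
        if (length(ia) < 2) { gm[ga, gb] <- 100; next }
        vals <- vals[upper.tri(vals)]
      }
      gm[ga, gb] <- mean(vals)
    }
  }
  structure(list(pairwise = pid, group_mean = gm, scope = scope),
            class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  cat("identity_report (", x$scope, " scope), group means (%):\n", sep = "")
  print(round(x$group_mean, 1))
  invisible(x)
}

#' Residues uniquely conserved within one metal-dependence group
#'
#' A (position, residue) pair is reported for a group when the residue
#' occurs in every member of that group and in no member of any other
#' labeled group. The V/Fe union (`VnfAnf`) is additionally tested as a
#' composite group against Nif; sequences labeled `unknown` never
#' participate.
#'
#' @param active_site_alignment A [labeled_alignment()] of active-site
#'   columns (e.g. from [extract_active_site()]).
#' @param groups Which single groups to test (default Nif, Vnf, Anf).
#' @param composite Test the Vnf+Anf union (default `TRUE` when both are
#'   present).
#' @return Data frame with columns `position`, `residue`, `group`, sorted by
#'   position; positions follow the alignment's `"positions"` attribute
#'   when present, otherwise column indices.
#' @export
unique_residues <- function(active_site_alignment,
                            groups = c("Nif", "Vnf", "Anf"),
                            composite = TRUE) {
  stopifnot(inherits(active_site_alignment, "labeled_alignment"))
  m <- alignment_matrix(active_site_alignment)
  labels <- active_site_alignment$labels
  pos <- attr(active_site_alignment, "positions")
  if (is.null(pos)) pos <- seq_len(ncol(m))
  groups <- intersect(groups, unique(labels))
  if (length(groups) == 0) stop("no requested group present in the labels")

  member_sets <- lapply(groups, function(g) which(labels == g))
  names(member_sets) <- groups
  test_sets <- member_sets
  if (composite && all(c("Vnf", "Anf") %in% groups)) {
    test_sets$VnfAnf <- c(member_sets$Vnf, member_sets$Anf)
  }
  out <- list()
  for (g in names(test_sets)) {
    inside <- test_sets[[g]]
    outside <- setdiff(unlist(member_sets), inside)
    for (col in seq_len(ncol(m))) {
      res <- unique(m[inside, col])
      if (length(res) != 1 || res %in% c("-", ".")) next
      if (res %in% m[outside, col]) next
      out[[length(out) + 1]] <- data.frame(
        position = pos[col], residue = res, group = g,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(position = integer(), residue = character(),
                      group = character(), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, out)
  # a residue conserved in both single groups is reported only for the union
  if ("VnfAnf" %in% tab$group) {
    comp_keys <- with(tab[tab$group == "VnfAnf", ], paste(position, residue))
    single <- tab$group %in% c("Vnf", "Anf") &
      paste(tab$position, tab$residue) %in% comp_keys
    tab <- tab[!single, ]
  }
  tab <- tab[order(tab$position, tab$group), ]
  rownames(tab) <- NULL
  tab
}
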