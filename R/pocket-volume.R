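#' Inclusion region for pocket-volume calculation
#'
#' A union of spheres specifying where pocket grid points may be generated,
#' mirroring the manually specified inclusion regions of grid-based pocket
#' volume tools.
#'
#' @param centers Numeric matrix (k x 3) of sphere centers in Angstroms, or
#'   a length-3 vector for a single sphere.
#' @param radii Sphere radii in Angstroms, recycled to the number of centers.
#' @return Object of class `inclusion_region`.
#' @export
inclusion_region <- function(centers, radii) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3, byrow = TRUE)
  centers <- as.matrix(centers)
  if (ncol(centers) != 3) stop("'centers' must have 3 columns (x, y, z)")
  radii <- rep_len(as.numeric(radii), nrow(centers))
  if (any(radii <= 0)) stop("inclusion sphere radii must be positive")
  if (any(!is.finite(centers))) stop("inclusion sphere centers must be finite")
  structure(list(centers = centers, radii = radii), class = "inclusion_region")
}

#' Default van der Waals radius table (Angstroms)
#'
#' Bondi-style radii for the elements common in protein structures plus the
#' transition metals found in nitrogenase cofactors.
#'
#' @return Named numeric vector, element symbol to radius.
#' @export
default_vdw_table <- function() {
  c("H" = 1.20, "C" = 1.70, "N" = 1.55, "O" = 1.52, "S" = 1.80, "P" = 1.80,
    "F" = 1.47, "CL" = 1.75, "BR" = 1.85, "I" = 1.98, "SE" = 1.90,
    "FE" = 2.00, "MO" = 2.10, "V" = 2.05, "MG" = 1.73, "MN" = 2.05,
    "ZN" = 1.39, "CA" = 2.31, "NA" = 2.27, "K" = 2.75, "CU" = 1.40,
    "NI" = 1.63, "CO" = 2.00)
}

#' Pocket-volume configuration
#'
#' @param grid_spacing Lattice spacing in Angstroms (default 0.5).
#' @param vdw_pad Distance pad added to each receptor atom's van der Waals
#'   radius when carving (default 1.09).
#' @param vdw_table Element-to-radius table; see [default_vdw_table()].
#' @param hull_filter Remove grid points outside the convex hull of the
#'   pocket-lining atoms (default `TRUE`).
#' @param contiguity_filter Keep only one lattice-connected component
#'   (default `TRUE`).
#' @param contiguity_seed Either `"largest"` or an xyz coordinate whose
#'   containing component is kept.
#' @param hull_shell Atoms within this distance of the inclusion region
#'   define the convex hull (default 8).
#' @param fallback_radius Radius used for elements missing from
#'   `vdw_table`; `NULL` (default) makes unknown elements an error.
#' @return Object of class `pocket_config`.
#' @export
pocket_config <- function(grid_spacing = 0.5, vdw_pad = 1.09,
                          vdw_table = default_vdw_table(),
                          hull_filter = TRUE, contiguity_filter = TRUE,
                          contiguity_seed = "largest", hull_shell = 8,
                          fallback_radius = NULL) {
  if (grid_spacing <= 0) stop("'grid_spacing' must be positive")
  if (vdw_pad < 0) stop("'vdw_pad' must be non-negative")
  structure(list(grid_spacing = grid_spacing, vdw_pad = vdw_pad,
                 vdw_table = vdw_table, hull_filter = hull_filter,
                 contiguity_filter = contiguity_filter,
                 contiguity_seed = contiguity_seed, hull_shell = hull_shell,
                 fallback_radius = fallback_radius),
            class = "pocket_config")
}

grid_attrs <- function(points, template) {
  attr(points, "anchor") <- attr(template, "anchor")
  attr(points, "spacing") <- attr(template, "spacing")
  points
}

#' Generate the inclusion-region lattice
#'
#' Builds an axis-aligned lattice at the configured spacing, anchored at the
#' minimum corner of the region's bounding box, and keeps the points lying
#' inside at least one inclusion sphere.
#'
#' @param region An [inclusion_region()].
#' @param config A [pocket_config()].
#' @return Numeric matrix (n x 3) of grid points with attributes `"anchor"`
#'   and `"spacing"`.
#' @export
generate_grid <- function(region, config = pocket_config()) {
  stopifnot(inherits(region, "inclusion_region"),
            inherits(config, "pocket_config"))
  h <- config$grid_spacing
  lo <- apply(region$centers - region$radii, 2, min)
  hi <- apply(region$centers + region$radii, 2, max)
  ax <- lapply(1:3, function(d) seq(lo[d], hi[d] + h / 2, by = h))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  colnames(pts) <- c("x", "y", "z")
  inside <- rep(FALSE, nrow(pts))
  for (k in seq_len(nrow(region$centers))) {
    d2 <- (pts[, 1] - region$centers[k, 1])^2 +
      (pts[, 2] - region$centers[k, 2])^2 +
      (pts[, 3] - region$centers[k, 3])^2
    inside <- inside | d2 <= region$radii[k]^2
  }
  pts <- pts[inside, , drop = FALSE]
  attr(pts, "anchor") <- lo
  attr(pts, "spacing") <- h
  pts
}

receptor_atoms <- function(structure, config, exclude_cofactor = TRUE) {
  at <- structure$atoms
  keep <- !(at$residue_name %in% water_names()) & at$element != "H"
  if (exclude_cofactor && !is.null(structure$cofactor)) {
    cof <- cofactor_atoms(structure)
    keep <- keep & !(at$serial %in% cof$serial)
  }
  at <- at[keep, , drop = FALSE]
  radii <- config$vdw_table[at$element]
  if (anyNA(radii)) {
    unknown <- unique(at$element[is.na(radii)])
    if (is.null(config$fallback_radius)) {
      stop("no van der Waals radius for element(s): ",
           paste(unknown, collapse = ", "),
           "; set 'fallback_radius' in pocket_config()")
    }
    radii[is.na(radii)] <- config$fallback_radius
  }
  at$vdw <- as.numeric(radii)
  at
}

#' Carve receptor-occupied volume out of a grid
#'
#' Removes every grid point whose distance to any receptor atom is smaller
#' than that atom's van der Waals radius plus the configured pad. Waters and
#' hydrogens are never part of the receptor set, and the structure's own
#' cofactor is excluded so a pocket can be measured around it.
#'
#' @param points Grid points from [generate_grid()].
#' @param structure A [parse_structure()] result.
#' @param config A [pocket_config()].
#' @param exclude_cofactor Drop the cofactor atoms from the receptor set
#'   (default `TRUE` when a selector is present).
#' @return The retained grid points (attributes preserved).
#' @export
carve <- function(points, structure, config = pocket_config(),
                  exclude_cofactor = TRUE) {
  stopifnot(inherits(structure, "structure3d"))
  if (nrow(points) == 0) return(points)
  at <- receptor_atoms(structure, config, exclude_cofactor)
  if (nrow(at) == 0) return(points)
  keep <- carve_keep_cpp(points[, 1:3, drop = FALSE],
                         as.matrix(at[, c("x", "y", "z")]),
                         at$vdw + config$vdw_pad)
  grid_attrs(points[keep, , drop = FALSE], points)
}

#' Restrict a grid to the convex hull of the pocket-lining atoms
#'
#' Removes points outside the convex hull of the receptor atoms lying
#' within `hull_shell` of the inclusion region; with no region supplied all
#' receptor atoms define the hull.
#'
#' @inheritParams carve
#' @param region Optional [inclusion_region()] used to select pocket-lining
#'   atoms.
#' @return The retained grid points (attributes preserved).
#' @export
hull_filter_points <- function(points, structure, region = NULL,
                               config = pocket_config()) {
  if (nrow(points) == 0) return(points)
  at <- receptor_atoms(structure, config, exclude_cofactor = TRUE)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (!is.null(region)) {
    near <- rep(FALSE, nrow(xyz))
    for (k in seq_len(nrow(region$centers))) {
      d <- sqrt((xyz[, 1] - region$centers[k, 1])^2 +
                  (xyz[, 2] - region$centers[k, 2])^2 +
                  (xyz[, 3] - region$centers[k, 3])^2)
      near <- near | d <= region$radii[k] + config$hull_shell
    }
    xyz <- xyz[near, , drop = FALSE]
  }
  if (nrow(xyz) < 4) stop("need at least 4 pocket-lining atoms for a hull")
  planes <- hull_halfspaces_cpp(xyz)
  s <- points[, 1:3, drop = FALSE] %*% t(planes[, 1:3, drop = FALSE])
  s <- sweep(s, 2, planes[, 4], "+")
  keep <- apply(s, 1, max) <= 1e-7
  grid_attrs(points[keep, , drop = FALSE], points)
}

#' Keep one lattice-connected component of a grid
#'
#' Connectivity is the 26-neighbourhood on the lattice. The component
#' containing the configured seed coordinate is kept; with the default
#' `"largest"` seed the largest component wins, ties resolving to the
#' component containing the lexicographically smallest lattice coordinate.
#'
#' @inheritParams carve
#' @return The retained grid points (attributes preserved).
#' @export
contiguity_filter_points <- function(points, config = pocket_config()) {
  if (nrow(points) <= 1) return(points)
  anchor <- attr(points, "anchor")
  h <- attr(points, "spacing")
  if (is.null(anchor) || is.null(h)) {
    stop("points lack lattice attributes; pass output of generate_grid()")
  }
  idx <- round(sweep(points[, 1:3, drop = FALSE], 2, anchor, "-") / h)
  storage.mode(idx) <- "integer"
  comp <- lattice_components_cpp(idx)
  if (is.numeric(config$contiguity_seed) &&
      length(config$contiguity_seed) == 3) {
    d2 <- colSums((t(points[, 1:3, drop = FALSE]) - config$contiguity_seed)^2)
    chosen <- comp[which.min(d2)]
  } else {
    sizes <- tabulate(comp)
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      ord <- order(idx[, 1], idx[, 2], idx[, 3])
      first_in <- comp[ord][comp[ord] %in% best][1]
      chosen <- first_in
    } else {
      chosen <- best
    }
  }
  grid_attrs(points[comp == chosen, , drop = FALSE], points)
}

#' Grid-based pocket volume of a structure
#'
#' Runs the full pocket pipeline: lattice generation inside the inclusion
#' region, van der Waals carving against the receptor, convex-hull
#' restriction to the pocket-lining shell, and contiguity filtering; the
#' volume is the retained point count times the grid cell volume.
#'
#' @param structure A [parse_structure()] result.
#' @param region An [inclusion_region()].
#' @param config A [pocket_config()].
#' @return Object of class `pocket_result`: list with `volume` (cubic
#'   Angstroms), `points`, and `counts` per pipeline stage.
#' @export
pocket_volume <- function(structure, region, config = pocket_config()) {
  pts <- generate_grid(region, config)
  counts <- c(grid = nrow(pts))
  pts <- carve(pts, structure, config)
  counts <- c(counts, carve = nrow(pts))
  if (config$hull_filter && nrow(pts) > 0) {
    pts <- hull_filter_points(pts, structure, region, config)
  }
  counts <- c(counts, hull = nrow(pts))
  if (config$contiguity_filter && nrow(pts) > 0) {
    pts <- contiguity_filter_points(pts, config)
  }
  counts <- c(counts, contiguous = nrow(pts))
  structure(list(volume = nrow(pts) * config$grid_spacing^3,
                 points = pts, counts = counts, config = config),
            class = "pocket_result")
}

#' @export
print.pocket_result <- function(x, ...) {
  cat("pocket_result: volume", format(x$volume), "A^3\n")
  cat("  stage point counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Compare pocket-volume distributions between groups
#'
#' Summarizes each group (mean, standard deviation, range) and tests every
#' pair of groups for a median difference with the two-sided Wilcoxon
#' rank-sum test.
#'
#' @param volume_sets Named list mapping group labels to numeric vectors of
#'   volumes in cubic Angstroms.
#' @return List with `summary` (one row per group) and `tests` (one row per
#'   group pair with the rank-sum statistic and p-value).
#' @export
compare_volume_groups <- function(volume_sets) {
  if (!is.list(volume_sets) || length(volume_sets) < 2 ||
      is.null(names(volume_sets)) || any(!nzchar(names(volume_sets)))) {
    stop("'volume_sets' must be a named list of at least 2 groups")
  }
  if (any(vapply(volume_sets, length, integer(1)) == 0)) {
    stop("every group must contain at least one volume")
  }
  smry <- do.call(rbind, lapply(names(volume_sets), function(g) {
    v <- volume_sets[[g]]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = stats::sd(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(names(volume_sets), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    wt <- suppressWarnings(stats::wilcox.test(volume_sets[[a]],
                                              volume_sets[[b]],
                                              alternative = "two.sided"))
    data.frame(group_a = a, group_b = b,
               statistic = unname(wt$statistic), p_value = wt$p.value,
               median_diff = stats::median(volume_sets[[a]]) -
                 stats::median(volume_sets[[b]]),
               stringsAsFactors = FALSE)
  }))
  list(summary = smry, tests = tests)
}
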