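#' Active-site position plan of the synthetic nitrogenase family
#'
#' The 30 reference positions (in the alignment's own coordinate frame,
#' matching the classic NifD numbering of the corresponding residues)
#' carried by every simulated family: 11 universally conserved positions,
#' 14 clade-signature positions, and 5 slowly evolving scaffold positions.
#'
#' @return List with `positions`, `conserved` (named residue vector),
#'   `root_signature`, and the per-branch override tables: `anca_override`
#'   (V-like states planted on the branch entering the V/Fe common ancestor
#'   and inherited by both daughters unless overridden again),
#'   `vnf_override` (V-only states arising on the Vnf stem), `anf_override`
#'   (Fe-specific states arising on the Anf stem), and `nif2_override`
#'   (within-Mo variation arising on the Nif-II stem). The
#'   `anca_identifiable` positions are the planted ancestral states that
#'   marginal reconstruction can resolve decisively: states shared by both
#'   daughter lineages, plus Thr-355 and Pro-358 whose daughter states are
#'   exchangeability-distant from the upstream state. Position 427 is
#'   planted at the ancestor but left out, as its Val is only moderately
#'   favored over the upstream Met, mirroring the ambiguous alternative
#'   reconstructions reported for a handful of real active-site positions.
#' @export
active_site_plan <- function() {
  list(
    positions = c(59L, 65L, 66L, 69L, 70L, 96L, 191L, 192L, 195L, 275L,
                  277L, 278L, 279L, 300L, 355L, 356L, 357L, 358L, 359L,
                  360L, 380L, 381L, 424L, 425L, 426L, 427L, 440L, 441L,
                  442L, 443L),
    conserved = c("70" = "V", "191" = "Q", "195" = "H", "275" = "C",
                  "277" = "R", "278" = "S", "356" = "G", "357" = "G",
                  "381" = "F", "424" = "G", "442" = "H"),
    filler = c(59L, 66L, 192L, 279L, 443L),
    root_signature = c("65" = "A", "69" = "G", "96" = "R", "300" = "F",
                       "355" = "I", "358" = "L", "359" = "R", "360" = "P",
                       "380" = "Q", "425" = "A", "426" = "S", "427" = "M",
                       "440" = "Q", "441" = "S"),
    anca_override = c("65" = "C", "96" = "K", "355" = "T", "358" = "P",
                      "360" = "L", "380" = "K", "426" = "R", "427" = "V",
                      "440" = "N"),
    anca_identifiable = c(65L, 96L, 355L, 358L, 360L, 380L, 426L, 440L),
    vnf_override = c("69" = "L", "300" = "W", "425" = "P"),
    anf_override = c("69" = "H", "355" = "P", "358" = "A", "359" = "K",
                     "427" = "P", "441" = "A"),
    nif2_override = c("69" = "A", "355" = "V", "358" = "A", "360" = "S",
                      "380" = "E", "426" = "T", "427" = "I"))
}

#' Planted clade-unique residue table
#'
#' The ground-truth table the generator plants: 3 residues unique to
#' Mo-nitrogenases, 6 to V-nitrogenases, 5 to Fe-nitrogenases, and 6 to the
#' V/Fe union. [unique_residues()] on a generated family recovers exactly
#' this table.
#'
#' @return Data frame with columns `position`, `residue`, `group`.
#' @export
planted_signature_table <- function() {
  tab <- rbind(
    data.frame(position = c(65L, 96L, 440L), residue = c("A", "R", "Q"),
               group = "Nif"),
    data.frame(position = c(69L, 300L, 355L, 358L, 425L, 427L),
               residue = c("L", "W", "T", "P", "P", "V"), group = "Vnf"),
    data.frame(position = c(69L, 355L, 359L, 427L, 441L),
               residue = c("H", "P", "K", "P", "A"), group = "Anf"),
    data.frame(position = c(65L, 96L, 360L, 380L, 426L, 440L),
               residue = c("C", "K", "L", "K", "R", "N"), group = "VnfAnf"))
  tab <- tab[order(tab$position, tab$group), ]
  rownames(tab) <- NULL
  tab
}

#' Specification of a synthetic nitrogenase family
#'
#' Defines the study conditions the generator emulates: the seven-clade
#' family layout (two Mo-nitrogenase clades Nif-I/Nif-II, the V and Fe
#' clades Vnf/Anf, and three uncharacterized clades Mb-Mc, F-Mc, Clfx),
#' JTT sequence evolution on a fixed rooted topology, strongly conserved
#' active-site scaffold positions, and clade-signature residues switched on
#' the stem branches and held fixed within clades.
#'
#' @param clade_sizes Named integer vector of leaves per clade.
#' @param seq_length Total alignment length (default 500).
#' @param within_depth Root-to-tip depth of each clade subtree in
#'   substitutions/site (default 0.12).
#' @param stem_lengths Stem branch lengths per clade; the Anf stem is long
#'   and the Vnf stem short, so reconstruction at the V/Fe common ancestor
#'   is dominated by the V-like states planted there.
#' @param backbone_lengths Backbone branch lengths (root to AncE, root to
#'   AncD, AncD to AncC, AncC to AncB, AncB to AncA).
#' @param active_site_rate Rate multiplier for non-signature active-site
#'   scaffold positions within clades (default 0.2; these positions are
#'   frozen on backbone and stem branches, emulating strong purifying
#'   selection on the pocket scaffold).
#' @param seed Integer seed; the whole family is deterministic given the
#'   spec.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(clade_sizes = c(NifI = 30L, NifII = 20L, MbMc = 8L,
                                        Vnf = 14L, Anf = 14L, FMc = 8L,
                                        Clfx = 3L),
                        seq_length = 500L,
                        within_depth = 0.12,
                        stem_lengths = c(NifI = 0.10, NifII = 0.10,
                                         MbMc = 0.12, Vnf = 0.04, Anf = 0.35,
                                         FMc = 0.12, Clfx = 0.12),
                        backbone_lengths = c(root_AncE = 0.06,
                                             root_AncD = 0.06,
                                             AncD_AncC = 0.06,
                                             AncC_AncB = 0.06,
                                             AncB_AncA = 0.15),
                        active_site_rate = 0.2,
                        seed = 1L) {
  required <- c("NifI", "NifII", "MbMc", "Vnf", "Anf", "FMc", "Clfx")
  if (!all(required %in% names(clade_sizes))) {
    stop("clade_sizes must name all of: ", paste(required, collapse = ", "))
  }
  if (any(clade_sizes < 2)) stop("every clade needs at least 2 members")
  plan <- active_site_plan()
  if (seq_length < max(plan$positions)) {
    stop("seq_length must be at least ", max(plan$positions),
         " to hold the active-site positions")
  }
  if (any(stem_lengths < 0) || any(backbone_lengths < 0) || within_depth < 0) {
    stop("branch lengths must be non-negative")
  }
  structure(list(clade_sizes = clade_sizes[required],
                 seq_length = as.integer(seq_length),
                 within_depth = within_depth,
                 stem_lengths = stem_lengths[required],
                 backbone_lengths = backbone_lengths,
                 active_site_rate = active_site_rate,
                 plan = plan, seed = as.integer(seed)),
            class = "family_spec")
}

clade_label <- function(clade) {
  switch(clade, NifI = "Nif", NifII = "Nif", Vnf = "Vnf", Anf = "Anf",
         "unknown")
}

clade_newick <- function(clade, n, depth, stem) {
  tr <- ape::rcoal(n, tip.label = sprintf("%s_%02d", clade, seq_len(n)))
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- if (d > 0) tr$edge.length * depth / d else tr$edge.length
  s <- ape::write.tree(tr)
  s <- sub(";$", "", s)
  paste0(s, clade, "Anc:", format(stem, scientific = FALSE))
}

family_tree <- function(spec) {
  cs <- spec$clade_sizes
  sub <- stats::setNames(
    lapply(names(cs), function(cl) clade_newick(cl, cs[[cl]],
                                                spec$within_depth,
                                                spec$stem_lengths[[cl]])),
    names(cs))
  bb <- spec$backbone_lengths
  newick <- paste0(
    "((", sub[["NifI"]], ",", sub[["NifII"]], ")AncE:", bb[["root_AncE"]],
    ",(", sub[["Clfx"]], ",(", sub[["FMc"]], ",(", sub[["MbMc"]],
    ",(", sub[["Vnf"]], ",", sub[["Anf"]], ")AncA:", bb[["AncB_AncA"]],
    ")AncB:", bb[["AncC_AncB"]], ")AncC:", bb[["AncD_AncC"]],
    ")AncD:", bb[["root_AncD"]], ")root;")
  ape::read.tree(text = newick)
}

# per-edge evolution of one sequence of state indices (1..20)
evolve_states <- function(states, sites, P) {
  if (length(sites) == 0) return(states)
  for (s in sites) {
    states[s] <- sample.int(20, 1, prob = P[states[s], ])
  }
  states
}

#' Generate a synthetic nitrogenase family with planted ground truth
#'
#' Simulates the family on the fixed labeled topology
#' `((NifI,NifII)AncE,(Clfx,(FMc,(MbMc,(Vnf,Anf)AncA)AncB)AncC)AncD)`:
#' the root sequence is drawn from JTT equilibrium and overwritten at the
#' conserved and signature active-site positions with Mo-nitrogenase-like
#' states; background positions evolve under JTT along every branch;
#' active-site scaffold positions evolve slowly within clades only; and the
#' clade-signature residues are switched on designated stem branches (V-like
#' states on the branch entering AncA, Fe-specific states on the Anf stem,
#' within-Mo variation on the Nif-II stem) and held fixed below.
#'
#' @param spec A [family_spec()].
#' @param model A [substitution_model()]; default JTT.
#' @return List with `alignment` (a [labeled_alignment()], reference row =
#'   first Nif-I leaf), `tree` (rooted `phylo` with named internal nodes),
#'   and `truth` (true tree, every node's true sequence, leaf labels and
#'   clades, the planted signature table, and the active-site plan).
#' @export
generate_family <- function(spec = family_spec(), model = substitution_model()) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  plan <- spec$plan
  L <- spec$seq_length
  aa <- amino_acids()
  tree <- family_tree(spec)
  n_tip <- length(tree$tip.label)
  nnames <- node_names(tree)

  # site classes
  all_pos <- plan$positions
  conserved_pos <- as.integer(names(plan$conserved))
  signature_pos <- as.integer(names(plan$root_signature))
  filler_pos <- plan$filler
  background_pos <- setdiff(seq_len(L), all_pos)

  # root sequence: equilibrium draw, then planted active-site states
  root_states <- sample.int(20, L, replace = TRUE,
                            prob = model$equilibrium_freqs)
  root_states[conserved_pos] <- match(plan$conserved, aa)
  root_states[signature_pos] <- match(plan$root_signature, aa)
  root_states[filler_pos] <- sample.int(20, length(filler_pos), replace = TRUE,
                                        prob = model$equilibrium_freqs)

  # within-clade edges: all strict descendants of a clade MRCA node
  clade_nodes <- match(paste0(names(spec$clade_sizes), "Anc"), nnames) + n_tip
  names(clade_nodes) <- names(spec$clade_sizes)
  in_clade <- rep(FALSE, n_tip + tree$Nnode)
  for (cn in clade_nodes) {
    desc <- c(cn, phangorn_free_descendants(tree, cn))
    in_clade[desc] <- TRUE
  }
  overrides <- list(
    AncA = match(plan$anca_override, aa),
    VnfAnc = match(plan$vnf_override, aa),
    AnfAnc = match(plan$anf_override, aa),
    NifIIAnc = match(plan$nif2_override, aa))
  override_pos <- list(
    AncA = as.integer(names(plan$anca_override)),
    VnfAnc = as.integer(names(plan$vnf_override)),
    AnfAnc = as.integer(names(plan$anf_override)),
    NifIIAnc = as.integer(names(plan$nif2_override)))

  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  elen <- tre$edge.length
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1]] <- root_states
  for (e in rev(seq_len(nrow(edge)))) {   # preorder
    parent <- edge[e, 1]; child <- edge[e, 2]
    st <- seqs[[parent]]
    bl <- elen[e]
    if (bl > 0) {
      st <- evolve_states(st, background_pos, transition_matrix(model, bl))
      if (in_clade[child] && in_clade[parent] && spec$active_site_rate > 0) {
        P_slow <- transition_matrix(model, bl * spec$active_site_rate)
        st <- evolve_states(st, filler_pos, P_slow)
      }
    }
    child_name <- if (child <= n_tip) tre$tip.label[child] else
      nnames[child - n_tip]
    if (child_name %in% names(overrides)) {
      st[override_pos[[child_name]]] <- overrides[[child_name]]
    }
    seqs[[child]] <- st
  }

  node_seq_names <- c(tree$tip.label, nnames)
  all_seqs <- vapply(seqs, function(st) paste(aa[st], collapse = ""),
                     character(1))
  names(all_seqs) <- node_seq_names

  clades <- sub("_[0-9]+$", "", tree$tip.label)
  labels <- vapply(clades, clade_label, character(1))
  reference <- tree$tip.label[clades == "NifI"][1]
  alignment <- labeled_alignment(all_seqs[tree$tip.label], labels, reference)
  truth <- list(tree = tree,
                ancestral_seqs = all_seqs[nnames],
                leaf_seqs = all_seqs[tree$tip.label],
                labels = labels, clades = clades,
                signature_table = planted_signature_table(),
                plan = plan)
  list(alignment = alignment, tree = tree, truth = truth, spec = spec)
}

# descendants of a node (tips and internal), without extra dependencies
phangorn_free_descendants <- function(tree, node) {
  out <- integer()
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack)) {
    out <- c(out, stack)
    stack <- tree$edge[tree$edge[, 1] %in% stack, 2]
  }
  out
}

pdb_atom_line <- function(record, serial, name, resname, chain, resno,
                          x, y, z, occ = 1, b = 0, element = "C") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, chain, resno, x, y, z, occ, b,
          element)
}

fibonacci_sphere <- function(n, radius, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2.399963229728653 * (seq_len(n) - 1)   # golden angle
  cbind(center[1] + radius * r * cos(phi),
        center[2] + radius * r * sin(phi),
        center[3] + radius * z)
}

shell_pdb_lines <- function(xyz, serial0 = 0, chain = "A", resno0 = 0,
                            element = "C") {
  vapply(seq_len(nrow(xyz)), function(i) {
    pdb_atom_line("ATOM", serial0 + i, "CA", "GLY", chain, resno0 + i,
                  xyz[i, 1], xyz[i, 2], xyz[i, 3], element = element)
  }, character(1))
}

#' Toy receptor fixtures with analytically known cavity volumes
#'
#' Builds synthetic PDB text for cavity geometries whose pocket volume under
#' the default carve radii has a closed form, for validating the grid
#' pipeline end to end.
#'
#' `"sphere-shell"`: carbon atoms on a sphere of radius `radius`; the carved
#' cavity is a sphere of radius `radius - vdw(C) - vdw_pad`, so the expected
#' volume is that of the cavity intersected with the inclusion sphere.
#' `"two-chamber"`: two disjoint shells of different radii; the contiguity
#' filter must retain exactly the chamber holding the seed (by default the
#' larger one).
#'
#' @param kind `"sphere-shell"` or `"two-chamber"`.
#' @param params Named list of geometric parameters; all must be positive.
#'   For `"sphere-shell"`: `radius` (default 8), `n_atoms` (180),
#'   `center`, `inclusion_radius` (defaults to the cavity radius). For
#'   `"two-chamber"`: `radius_a` (8), `radius_b` (5.5), `separation` (30),
#'   `n_atoms` per shell (180).
#' @param config A [pocket_config()]; its pad and carbon radius set the
#'   cavity radii.
#' @return List with `pdb` (text lines), `structure`, `region`, and
#'   `expected_volume` in cubic Angstroms (for `"two-chamber"`, the larger
#'   chamber).
#' @export
generate_pocket_fixture <- function(kind = c("sphere-shell", "two-chamber"),
                                    params,
                                    config = pocket_config()) {
  kind <- match.arg(kind)
  if (missing(params) || !is.list(params) || length(params) == 0) {
    stop("'params' must be a non-empty list of geometric parameters")
  }
  if (any(vapply(params, function(p)
    is.numeric(p) && any(p <= 0), logical(1)) &
    !(names(params) %in% "center"))) {
    stop("geometric parameters must be positive")
  }
  carve_r <- unname(config$vdw_table[["C"]] + config$vdw_pad)
  if (kind == "sphere-shell") {
    radius <- params$radius %||% 8
    n_atoms <- params$n_atoms %||% 180
    center <- params$center %||% c(0, 0, 0)
    cavity <- radius - carve_r
    if (cavity <= 0) stop("shell radius smaller than the carve radius")
    incl <- params$inclusion_radius %||% cavity
    xyz <- fibonacci_sphere(n_atoms, radius, center)
    pdb <- shell_pdb_lines(xyz)
    expected <- 4 / 3 * pi * min(cavity, incl)^3
    region <- inclusion_region(center, incl)
  } else {
    ra <- params$radius_a %||% 8
    rb <- params$radius_b %||% 5.5
    sep <- params$separation %||% 30
    n_atoms <- params$n_atoms %||% 180
    cav_a <- ra - carve_r
    cav_b <- rb - carve_r
    if (min(cav_a, cav_b) <= 0) stop("shell radius smaller than the carve radius")
    xyz_a <- fibonacci_sphere(n_atoms, ra, c(0, 0, 0))
    xyz_b <- fibonacci_sphere(n_atoms, rb, c(0, 0, sep))
    pdb <- c(shell_pdb_lines(xyz_a),
             shell_pdb_lines(xyz_b, serial0 = n_atoms, resno0 = n_atoms))
    expected <- 4 / 3 * pi * max(cav_a, cav_b)^3
    region <- inclusion_region(rbind(c(0, 0, 0), c(0, 0, sep)),
                               c(cav_a, cav_b))
  }
  list(pdb = pdb, structure = parse_structure(pdb), region = region,
       expected_volume = expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Toy ligand-receptor complex with known contact distances
#'
#' Places single-atom residues at specified distances from a central ligand
#' group, giving an exact expected answer for distance-cutoff contact
#' detection.
#'
#' @param placement_radii Sorted distances (Angstroms) at which residues are
#'   placed, one residue per radius.
#' @param ligand_atoms Number of ligand atoms at the center (default 1).
#' @return List with `pdb` (text lines), `structure` (cofactor selector set
#'   to the ligand), `radii`, and `expected_contacts(cutoff)`, a function
#'   returning the residue numbers within the cutoff.
#' @export
generate_toy_complex <- function(placement_radii, ligand_atoms = 1) {
  if (ligand_atoms < 1) stop("at least one ligand atom is required")
  radii <- as.numeric(placement_radii)
  if (length(radii) == 0 || any(radii <= 0)) {
    stop("'placement_radii' must be positive distances")
  }
  if (is.unsorted(radii)) stop("'placement_radii' must be sorted increasing")
  lig <- vapply(seq_len(ligand_atoms), function(i) {
    pdb_atom_line("HETATM", i, "FE", "LIG", "L", 900,
                  0.05 * (i - 1), 0, 0, element = "FE")
  }, character(1))
  dirs <- fibonacci_sphere(length(radii), 1)
  res <- vapply(seq_along(radii), function(i) {
    pdb_atom_line("ATOM", ligand_atoms + i, "CA", "GLY", "A", i,
                  radii[i] * dirs[i, 1], radii[i] * dirs[i, 2],
                  radii[i] * dirs[i, 3], element = "C")
  }, character(1))
  pdb <- c(lig, res)
  list(pdb = pdb, structure = parse_structure(pdb, cofactor = "LIG"),
       radii = radii,
       expected_contacts = function(cutoff) which(radii <= cutoff))
}
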