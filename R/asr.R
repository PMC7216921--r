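#' Internal-node display names for a rooted tree
#'
#' Uses existing node labels where present; unlabeled internal nodes get
#' `node<N>` names based on their ape node number.
#'
#' @param tree An `ape::phylo` tree.
#' @return Character vector of length `tree$Nnode`, in ape node order.
#' @export
node_names <- function(tree) {
  n_tip <- length(tree$tip.label)
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", tree$Nnode)
  fallback <- paste0("node", n_tip + seq_len(tree$Nnode))
  ifelse(is.na(labs) | labs == "", fallback, labs)
}

validate_tree_alignment <- function(tree, alignment) {
  stopifnot(inherits(tree, "phylo"), inherits(alignment, "labeled_alignment"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  missing <- setdiff(tree$tip.label, names(alignment$seqs))
  extra <- setdiff(names(alignment$seqs), tree$tip.label)
  if (length(missing) || length(extra)) {
    stop("tree/alignment taxon mismatch; missing from alignment: ",
         paste(missing, collapse = ", "), "; absent from tree: ",
         paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

# Leaf conditional-likelihood matrices: L x 20 indicators; gap or ambiguity
# symbols contribute no information (all-ones row).
leaf_likelihoods <- function(alignment) {
  aa <- amino_acids()
  m <- alignment_matrix(alignment)
  lapply(stats::setNames(seq_len(nrow(m)), rownames(m)), function(i) {
    res <- m[i, ]
    idx <- match(res, aa)
    bad <- is.na(idx) & !(res %in% gap_chars())
    if (any(bad)) {
      stop("unknown residue character '", res[which(bad)[1]], "' in sequence '",
           rownames(m)[i], "' at column ", which(bad)[1])
    }
    lik <- matrix(0, length(res), 20)
    lik[cbind(which(!is.na(idx)), idx[!is.na(idx)])] <- 1
    lik[is.na(idx), ] <- 1
    lik
  })
}

#' Marginal ancestral-state posteriors on a fixed rooted tree
#'
#' Computes, for every internal node and alignment site, the exact marginal
#' posterior distribution over the 20 amino acids given all leaf states,
#' under the supplied reversible substitution model with the equilibrium
#' frequencies as root prior and sites treated independently. Implemented as
#' two-pass belief propagation: a postorder (pruning) pass collects
#' subtree-conditional likelihoods and a preorder pass distributes the
#' complementary evidence. Per-node per-site gap status is inferred
#' separately by Fitch parsimony on residue presence/absence
#' ([infer_gaps()]).
#'
#' @param tree Rooted `ape::phylo` tree with branch lengths in
#'   substitutions/site; tips must match the alignment rows.
#' @param alignment A [labeled_alignment()].
#' @param model A [substitution_model()].
#' @return Object of class `asr_posteriors`: list with `posteriors` (named
#'   list of L x 20 matrices, one per internal node), `gap_flags` (named
#'   list of length-L logicals), `log_likelihood`, `tree`, and `node_names`.
#' @export
site_posteriors <- function(tree, alignment, model) {
  validate_tree_alignment(tree, alignment)
  stopifnot(inherits(model, "substitution_model"))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  L <- nchar(alignment$seqs[[1]])
  pi <- model$equilibrium_freqs

  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  elen <- tre$edge.length
  P_for <- lapply(elen, function(b) transition_matrix(model, b))

  leaves <- leaf_likelihoods(alignment)
  down <- vector("list", n_node)       # subtree-conditional likelihoods
  logscale <- matrix(0, L, n_node)     # per-site log scaling factors
  for (tip in seq_len(n_tip)) down[[tip]] <- leaves[[tre$tip.label[tip]]]

  # postorder accumulation: every edge below a node is processed before the
  # node's own parent edge, so child tables are final when their message
  # (child-conditional likelihood propagated through the branch) is formed
  msg <- vector("list", nrow(edge))
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    msg[[e]] <- down[[ch]] %*% t(P_for[[e]])
    if (is.null(down[[p]])) {
      down[[p]] <- msg[[e]]
      logscale[, p] <- logscale[, ch]
    } else {
      down[[p]] <- down[[p]] * msg[[e]]
      logscale[, p] <- logscale[, p] + logscale[, ch]
    }
    mx <- pmax(apply(down[[p]], 1, max), .Machine$double.xmin)
    down[[p]] <- down[[p]] / mx
    logscale[, p] <- logscale[, p] + log(mx)
  }

  root <- n_tip + 1
  root_lik <- down[[root]] %*% pi
  loglik <- sum(log(root_lik) + logscale[, root])

  # preorder pass: "up" tables carry root prior and off-subtree evidence
  up <- vector("list", n_node)
  up[[root]] <- matrix(pi, L, 20, byrow = TRUE)
  preorder <- rev(seq_len(nrow(edge)))
  for (e in preorder) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    if (ch <= n_tip) next
    sibs <- setdiff(which(edge[, 1] == p), e)
    M <- up[[p]]
    for (s in sibs) M <- M * msg[[s]]
    out <- M %*% P_for[[e]]
    mx <- pmax(apply(out, 1, max), .Machine$double.xmin)
    up[[ch]] <- out / mx
  }

  nnames <- node_names(tre)
  gaps <- infer_gaps(tree, alignment)
  posts <- vector("list", tree$Nnode)
  names(posts) <- nnames
  aa <- amino_acids()
  for (k in seq_len(tree$Nnode)) {
    v <- n_tip + k
    post <- up[[v]] * down[[v]]
    post <- post / rowSums(post)
    colnames(post) <- aa
    posts[[nnames[k]]] <- post
  }
  structure(list(posteriors = posts, gap_flags = gaps,
                 log_likelihood = loglik, tree = tree, node_names = nnames),
            class = "asr_posteriors")
}

#' @export
print.asr_posteriors <- function(x, ...) {
  cat("asr_posteriors:", length(x$posteriors), "internal nodes x",
      nrow(x$posteriors[[1]]), "sites; log-likelihood",
      format(x$log_likelihood), "\n")
  invisible(x)
}

#' Total log-likelihood of an alignment on a tree
#'
#' @inheritParams site_posteriors
#' @return The log-likelihood under the model (equilibrium root prior).
#' @export
tree_log_likelihood <- function(tree, alignment, model) {
  site_posteriors(tree, alignment, model)$log_likelihood
}

resolve_node <- function(posteriors, node) {
  if (is.numeric(node)) {
    n_tip <- length(posteriors$tree$tip.label)
    k <- as.integer(node) - n_tip
    if (k < 1 || k > length(posteriors$posteriors)) {
      stop("node number ", node, " is not an internal node")
    }
    return(names(posteriors$posteriors)[k])
  }
  if (!(node %in% names(posteriors$posteriors))) {
    stop("unknown internal node '", node, "'; available: ",
         paste(names(posteriors$posteriors), collapse = ", "))
  }
  node
}

#' Maximum-a-posteriori ancestral sequence at an internal node
#'
#' Per-site argmax of the marginal posterior; sites flagged as gaps by
#' parsimony are written as `-`. Exact probability ties resolve to the
#' alphabetically first residue and the tied sites are recorded in the
#' `"ties"` attribute.
#'
#' @param posteriors An `asr_posteriors` object from [site_posteriors()].
#' @param node Internal node name or ape node number.
#' @return Protein sequence string with attribute `"ties"`.
#' @export
ml_ancestor <- function(posteriors, node) {
  stopifnot(inherits(posteriors, "asr_posteriors"))
  node <- resolve_node(posteriors, node)
  post <- posteriors$posteriors[[node]]
  aa <- amino_acids()
  ord <- order(aa)  # alphabetical tie-break, independent of storage order
  best <- apply(post[, order(aa), drop = FALSE], 1, which.max)
  res <- sort(aa)[best]
  maxp <- post[cbind(seq_len(nrow(post)), match(res, aa))]
  ties <- which(rowSums(abs(post - maxp) < .Machine$double.eps * 4) > 1)
  res[posteriors$gap_flags[[node]]] <- "-"
  out <- paste(res, collapse = "")
  attr(out, "ties") <- ties
  out
}

#' Bayesian-sampled ancestral sequence variants
#'
#' Draws each site independently from its marginal posterior distribution,
#' producing plausible ancestral variants that carry reconstruction
#' uncertainty. Gap-flagged sites are emitted as `-` in every sample.
#'
#' @inheritParams ml_ancestor
#' @param n_samples Number of sampled sequences (default 100).
#' @param seed Optional integer seed for reproducible draws.
#' @return Character vector of `n_samples` sequences.
#' @export
sample_ancestors <- function(posteriors, node, n_samples = 100, seed = NULL) {
  stopifnot(inherits(posteriors, "asr_posteriors"))
  if (!is.numeric(n_samples) || n_samples < 1) stop("'n_samples' must be >= 1")
  node <- resolve_node(posteriors, node)
  if (!is.null(seed)) set.seed(seed)
  post <- posteriors$posteriors[[node]]
  gap <- posteriors$gap_flags[[node]]
  aa <- amino_acids()
  vapply(seq_len(n_samples), function(i) {
    res <- apply(post, 1, function(p) sample(aa, 1, prob = p))
    res[gap] <- "-"
    paste(res, collapse = "")
  }, character(1))
}

#' Parsimony inference of ancestral gap states
#'
#' Runs Fitch parsimony on the binary presence/absence character of each
#' alignment column, resolving ambiguous nodes toward residue presence, so
#' downstream feature extraction sees a residue rather than a hole wherever
#' parsimony permits one.
#'
#' @inheritParams site_posteriors
#' @return Named list (one entry per internal node, in ape node order) of
#'   length-L logical vectors; `TRUE` marks an inferred gap.
#' @export
infer_gaps <- function(tree, alignment) {
  validate_tree_alignment(tree, alignment)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  m <- alignment_matrix(alignment)
  L <- ncol(m)
  present <- !(m %in% c("-", "."))
  dim(present) <- dim(m)
  rownames(present) <- rownames(m)

  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  # state sets as two logical matrices: can_present / can_absent
  can_p <- matrix(NA, n_node, L)
  can_a <- matrix(NA, n_node, L)
  for (tip in seq_len(n_tip)) {
    pr <- present[tre$tip.label[tip], ]
    can_p[tip, ] <- pr
    can_a[tip, ] <- !pr
  }
  for (p in unique(edge[, 1])) {
    kids <- edge[edge[, 1] == p, 2]
    inter_p <- rep(TRUE, L); inter_a <- rep(TRUE, L)
    union_p <- rep(FALSE, L); union_a <- rep(FALSE, L)
    for (k in kids) {
      inter_p <- inter_p & can_p[k, ]; inter_a <- inter_a & can_a[k, ]
      union_p <- union_p | can_p[k, ]; union_a <- union_a | can_a[k, ]
    }
    empty <- !(inter_p | inter_a)
    can_p[p, ] <- ifelse(empty, union_p, inter_p)
    can_a[p, ] <- ifelse(empty, union_a, inter_a)
  }
  # top-down refinement; ties resolve toward presence
  final <- matrix(NA, n_node, L)
  root <- n_tip + 1
  final[root, ] <- ifelse(can_p[root, ], TRUE, FALSE)
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    if (ch <= n_tip) next
    keep_parent <- ifelse(final[p, ], can_p[ch, ], can_a[ch, ])
    final[ch, ] <- ifelse(keep_parent, final[p, ], can_p[ch, ])
  }
  nnames <- node_names(tre)
  out <- lapply(seq_len(tree$Nnode), function(k) !final[n_tip + k, ])
  names(out) <- nnames
  out
}

#' Mean and spread of per-site maximum posterior probabilities
#'
#' Summarizes reconstruction confidence at a node as the arithmetic mean and
#' population standard deviation of the per-site maximum posterior, the
#' standard support statistic for reconstructed ancestral sequences.
#'
#' @inheritParams ml_ancestor
#' @param site_subset Optional integer vector of sites (columns) to
#'   summarize; default all non-gap sites at the node.
#' @return List with `mean`, `sd`, `n_sites`.
#' @export
posterior_support_summary <- function(posteriors, node, site_subset = NULL) {
  stopifnot(inherits(posteriors, "asr_posteriors"))
  node <- resolve_node(posteriors, node)
  post <- posteriors$posteriors[[node]]
  gap <- posteriors$gap_flags[[node]]
  sites <- if (is.null(site_subset)) which(!gap) else as.integer(site_subset)
  if (any(gap[sites])) stop("site subset includes gap-flagged sites")
  mx <- apply(post[sites, , drop = FALSE], 1, max)
  list(mean = mean(mx),
       sd = sqrt(mean((mx - mean(mx))^2)),
       n_sites = length(sites))
}
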