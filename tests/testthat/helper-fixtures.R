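# Shared fixtures and independent oracles for the test suite.

jtt <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- substitution_model()
    cache
  }
})

# a reduced family: same seven-clade layout and planted truth, fewer leaves
small_spec <- function(seed = 11) {
  family_spec(clade_sizes = c(NifI = 6L, NifII = 5L, MbMc = 3L, Vnf = 4L,
                              Anf = 4L, FMc = 3L, Clfx = 2L),
              seq_length = 450L, seed = seed)
}

small_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_family(small_spec(), jtt())
    cache
  }
})

# Exhaustive marginal-posterior oracle: enumerate every assignment of states
# to the internal nodes and sum path probabilities directly. Independent of
# the pruning implementation (no conditional-likelihood recursion).
enum_posteriors <- function(tree, alignment, model) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  m <- alignment_matrix(alignment)
  L <- ncol(m)
  aa <- amino_acids()
  pi <- model$equilibrium_freqs
  P_edge <- lapply(tree$edge.length, function(b) transition_matrix(model, b))
  assign_grid <- as.matrix(expand.grid(rep(list(1:20), n_int),
                                       KEEP.OUT.ATTRS = FALSE))
  root_col <- 1  # internal node n_tip+1 is column 1 of the grid
  out <- lapply(seq_len(n_int), function(k) matrix(NA_real_, L, 20))
  for (site in seq_len(L)) {
    leaf_state <- match(m[tree$tip.label, site], aa)
    prob <- pi[assign_grid[, root_col]]
    ok <- rep(TRUE, nrow(assign_grid))
    for (e in seq_len(nrow(tree$edge))) {
      par_state <- assign_grid[, tree$edge[e, 1] - n_tip]
      child <- tree$edge[e, 2]
      if (child <= n_tip) {
        ls <- leaf_state[child]
        if (is.na(ls)) next  # gap leaf: no information
        prob <- prob * P_edge[[e]][cbind(par_state, ls)]
      } else {
        prob <- prob * P_edge[[e]][cbind(par_state,
                                         assign_grid[, child - n_tip])]
      }
    }
    for (k in seq_len(n_int)) {
      tot <- rowsum(prob, assign_grid[, k])
      post <- numeric(20)
      post[as.integer(rownames(tot))] <- tot
      out[[k]][site, ] <- post / sum(post)
    }
  }
  names(out) <- node_names(tree)
  out
}

# random rooted binary tree with <= 5 leaves and random branch lengths
random_small_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   tip.label = paste0("t", seq_len(n_leaves)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
  tr
}

random_alignment <- function(tree, n_sites, gap_prob = 0) {
  aa <- amino_acids()
  seqs <- vapply(tree$tip.label, function(x) {
    res <- sample(aa, n_sites, replace = TRUE)
    if (gap_prob > 0) {
      res[stats::runif(n_sites) < gap_prob] <- "-"
    }
    paste(res, collapse = "")
  }, character(1))
  labeled_alignment(seqs)
}

# quadratic-programming membership oracle: p is in conv(X) iff the nearest
# point of the convex hull is p itself
qp_in_hull <- function(p, X, tol = 1e-6) {
  n <- nrow(X)
  D <- X %*% t(X) + diag(1e-10, n)
  d <- as.numeric(X %*% p)
  A <- cbind(rep(1, n), diag(n))
  sol <- quadprog::solve.QP(D, d, A, c(1, rep(0, n)), meq = 1)
  sum((as.numeric(t(X) %*% sol$solution) - p)^2) < tol
}

# breadth-first-search connected components over 26-neighbourhood lattices,
# using a dense pairwise adjacency test rather than hashing
bfs_components <- function(idx) {
  n <- nrow(idx)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    di <- abs(sweep(idx, 2, idx[i, ], "-"))
    adj[i, ] <- apply(di, 1, max) == 1
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# exact two-sided rank-sum reference by full enumeration of group labelings
perm_rank_sum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ranks <- rank(pooled)
  W_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  W_all <- apply(combos, 2, function(ix) {
    sum(rank(pooled)[ix]) - n * (n + 1) / 2
  })
  mu <- n * length(y) / 2
  p <- mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
  list(W = W_obs, p = p)
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_structure <- function(structure, R, shift = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(R)
  structure$atoms$x <- xyz[, 1] + shift[1]
  structure$atoms$y <- xyz[, 2] + shift[2]
  structure$atoms$z <- xyz[, 3] + shift[3]
  structure
}

toy_pdb_lines <- function() {
  c("ATOM      1  CA  GLY A   1       0.000   0.000   4.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       0.000   0.000   6.000  1.00  0.00           C",
    "HETATM    3 FE   LIG L 900       0.000   0.000   0.000  1.00  0.00          FE")
}
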