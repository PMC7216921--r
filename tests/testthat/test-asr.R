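test_that("zero-length star tree gives point-mass posteriors", {
  tr <- ape::read.tree(text = "(a:0,b:0,c:0,d:0)r;")
  aln <- labeled_alignment(c(a = "K", b = "K", c = "K", d = "K"))
  post <- site_posteriors(tr, aln, jtt())
  p <- post$posteriors[[1]][1, ]
  expect_equal(unname(p[match("K", amino_acids())]), 1)
})

test_that("pruning posteriors match exhaustive enumeration", {
  set.seed(101)
  m <- jtt()
  for (i in 1:12) {
    tr <- random_small_tree(sample(3:5, 1))
    aln <- random_alignment(tr, n_sites = 2, gap_prob = 0.1)
    post <- site_posteriors(tr, aln, m)
    ref <- enum_posteriors(tr, aln, m)
    for (nd in names(ref)) {
      expect_lt(max(abs(post$posteriors[[nd]] - ref[[nd]])), 1e-10)
    }
  }
})

test_that("very long branches push posteriors to equilibrium", {
  tr <- ape::read.tree(text = "((a:60,b:60):60,(c:60,d:60):60)r;")
  aln <- labeled_alignment(c(a = "W", b = "C", c = "H", d = "M"))
  post <- site_posteriors(tr, aln, jtt())
  expect_lt(max(abs(post$posteriors[["r"]][1, ] - jtt()$equilibrium_freqs)),
            1e-4)
})

test_that("total likelihood is invariant to root placement", {
  m <- jtt()
  aln <- labeled_alignment(c(a = "ACDKW", b = "ACEKW", c = "GCDKY",
                             d = "GVDKY"))
  # the same unrooted tree rooted on the internal branch and on a's branch
  t1 <- ape::read.tree(text = "((a:1,b:2):0.5,(c:1.5,d:0.7):0.5)r;")
  t2 <- ape::read.tree(text = "(a:0.4,(b:2,(c:1.5,d:0.7):1.0):0.6)r;")
  expect_equal(tree_log_likelihood(t1, aln, m),
               tree_log_likelihood(t2, aln, m), tolerance = 1e-9)
})

test_that("the ML ancestor takes per-site argmax with alphabetical ties", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.1)r;")
  aln <- labeled_alignment(c(a = "K", b = "K"))
  post <- site_posteriors(tr, aln, jtt())
  expect_equal(as.character(ml_ancestor(post, "r")), "K")
  # symmetric two-leaf disagreement: posterior ties between the two leaves
  aln2 <- labeled_alignment(c(a = "D", b = "E"))
  post2 <- site_posteriors(tr, aln2, jtt())
  p <- post2$posteriors[["r"]][1, ]
  if (abs(p[["D"]] - p[["E"]]) < 1e-12) {
    expect_equal(as.character(ml_ancestor(post2, "r")), "D")
  }
  expect_error(ml_ancestor(post, "nope"), "unknown internal node")
})

test_that("Bayesian ancestor sampling is seeded and matches its posterior", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.1)r;")
  post <- site_posteriors(tr, labeled_alignment(c(a = "K", b = "K")), jtt())
  # point-mass posteriors give identical samples
  s <- sample_ancestors(post, "r", n_samples = 20, seed = 1)
  expect_true(all(s == as.character(ml_ancestor(post, "r"))))
  # fixed seed reproduces draws exactly
  fam <- small_family()
  post_f <- site_posteriors(fam$tree, fam$alignment, jtt())
  s1 <- sample_ancestors(post_f, "AncA", n_samples = 5, seed = 99)
  s2 <- sample_ancestors(post_f, "AncA", n_samples = 5, seed = 99)
  expect_identical(s1, s2)

  # empirical frequencies track a (0.7, 0.3) posterior within binomial error
  two <- post
  pvec <- numeric(20)
  pvec[match(c("A", "G"), amino_acids())] <- c(0.7, 0.3)
  two$posteriors[["r"]] <- matrix(pvec, 1, 20,
                                  dimnames = list(NULL, amino_acids()))
  two$gap_flags[["r"]] <- FALSE
  draws <- sample_ancestors(two, "r", n_samples = 10000, seed = 7)
  expect_equal(mean(draws == "A"), 0.7, tolerance = 0.015)
})

test_that("gap parsimony follows Fitch with presence-preferring ties", {
  tr <- ape::read.tree(text = "((a:1,b:1)ab:1,(c:1,d:1)cd:1)r;")
  # no gaps: everything present
  g0 <- infer_gaps(tr, labeled_alignment(c(a = "A", b = "A", c = "A", d = "A")))
  expect_false(any(unlist(g0)))
  # gap in a single leaf: all internal nodes present
  g1 <- infer_gaps(tr, labeled_alignment(c(a = "-", b = "A", c = "A", d = "A")))
  expect_false(any(unlist(g1)))
  # a fully gapped clade: its ancestor is a gap, the root stays present
  g2 <- infer_gaps(tr, labeled_alignment(c(a = "-", b = "-", c = "A", d = "A")))
  expect_true(g2[["ab"]])
  expect_false(g2[["r"]])
  expect_false(g2[["cd"]])
  # root ambiguity (one gapped leaf on each side) resolves toward presence
  g3 <- infer_gaps(tr, labeled_alignment(c(a = "-", b = "A", c = "-", d = "A")))
  expect_false(g3[["r"]])
  expect_false(g3[["ab"]])
  expect_false(g3[["cd"]])
})

test_that("support summaries compute mean and population SD of max posterior", {
  tr <- ape::read.tree(text = "(a:0,b:0)r;")
  post <- site_posteriors(tr, labeled_alignment(c(a = "KW", b = "KW")), jtt())
  s <- posterior_support_summary(post, "r")
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
  # hand-crafted maxima 0.8 and 1.0: mean 0.9, population SD 0.1
  fake <- post
  pm <- matrix(0, 2, 20, dimnames = list(NULL, amino_acids()))
  pm[1, 1] <- 0.8; pm[1, 2] <- 0.2; pm[2, 3] <- 1
  fake$posteriors[["r"]] <- pm
  s2 <- posterior_support_summary(fake, "r")
  expect_equal(s2$mean, 0.9)
  expect_equal(s2$sd, 0.1)
})

test_that("reconstruction recovers planted ancestors at conserved sites", {
  fam <- small_family()
  plan <- fam$spec$plan
  post <- site_posteriors(fam$tree, fam$alignment, jtt())
  strong <- sort(c(as.integer(names(plan$conserved)),
                   as.integer(names(plan$root_signature))))
  for (nd in c("AncB", "AncE")) {
    truth <- strsplit(fam$truth$ancestral_seqs[[nd]], "")[[1]]
    rec <- strsplit(as.character(ml_ancestor(post, nd)), "")[[1]]
    expect_gte(mean(rec[strong] == truth[strong]), 0.95)
  }
  # active-site support exceeds whole-sequence support (slow scaffold sites)
  cols <- alignment_columns(fam$alignment, plan$positions)
  full <- posterior_support_summary(post, "AncB")
  act <- posterior_support_summary(post, "AncB", cols)
  expect_gte(act$mean, full$mean)
})

test_that("taxon mismatches are reported by name", {
  tr <- ape::read.tree(text = "(a:1,b:1)r;")
  expect_error(site_posteriors(tr, labeled_alignment(c(a = "A", x = "A")),
                               jtt()), "x")
})
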