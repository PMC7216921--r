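test_that("extant encoding produces normalized 20-blocks in site order", {
  m <- jtt()
  fam <- small_family()
  active <- extract_active_site(fam$alignment, active_site_plan()$positions)
  X <- encode_extant(active, m)
  expect_equal(ncol(X), 30 * 20)
  expect_equal(nrow(X), length(fam$alignment$seqs))
  blocks <- matrix(X[3, ], ncol = 20, byrow = TRUE)
  expect_lt(max(abs(rowSums(blocks) - 1)), 1e-9)
  expect_true(all(X >= 0 & X <= 1))

  # one site, degenerate weights: a one-hot row
  one <- labeled_alignment(c(s = "A"))
  X1 <- encode_extant(one, m, distribution_config(component_weights = c(1, 0, 0)))
  expect_equal(as.numeric(X1), as.numeric(amino_acids() == "A"))
})

test_that("ancestor encoding uses posterior rows directly", {
  m <- jtt()
  tr <- ape::read.tree(text = "(a:0,b:0)r;")
  post <- site_posteriors(tr, labeled_alignment(c(a = "KW", b = "KW")), m)
  Xa <- encode_ancestor(post, "r", columns = 1:2)
  # point-mass posteriors equal the one-hot extant encoding of the ancestor
  Xs <- encode_extant(labeled_alignment(c(r = "KW")), m,
                      distribution_config(component_weights = c(1, 0, 0)))
  expect_equal(as.numeric(Xa), as.numeric(Xs))
  blocks <- matrix(Xa[1, ], ncol = 20, byrow = TRUE)
  expect_equal(rowSums(blocks), c(1, 1))

  # gap-flagged positions error unless the regularizer fallback is chosen
  gapped <- post
  gapped$gap_flags[["r"]][2] <- TRUE
  expect_error(encode_ancestor(gapped, "r", 1:2), "regularizer")
  Xg <- encode_ancestor(gapped, "r", 1:2, on_gap = "regularizer", model = m)
  expect_equal(unname(Xg[1, 21:40]), unname(m$equilibrium_freqs))
})

test_that("class weights and kernel coefficient follow the stated formulas", {
  labels <- rep(c("Nif", "Vnf", "Anf"), c(240, 14, 14))
  w <- class_weights(labels)
  expect_equal(unname(w["Vnf"]), 268 / (3 * 14))   # = 6.380952...
  expect_equal(unname(w["Nif"]), 268 / (3 * 240))
  X <- matrix(c(0, 1, 1, 0, 1, 1, 0, 0), 2)
  expect_equal(rbf_gamma(X), 1 / (ncol(X) * mean((X - mean(X))^2)))
})

test_that("training on separable classes reaches perfect replicate accuracy", {
  set.seed(5)
  n <- 30
  X <- rbind(matrix(rnorm(n * 4, 0), n, 4), matrix(rnorm(n * 4, 6), n, 4))
  y <- rep(c("Nif", "Vnf"), each = n)
  clf <- train_metal_classifier(X, y, train_config(seed = 2, n_replicates = 5))
  expect_equal(clf$replicate_report$accuracy, rep(1, 5))
  # a training point deep inside its class has positive own-class distance
  res <- classify_metal(clf, X[1, , drop = FALSE])
  expect_equal(res$predicted, "Nif")
  expect_gt(res$Nif, 0)
  # determinism: identical distances on repeated calls
  res2 <- classify_metal(clf, X[1, , drop = FALSE])
  expect_identical(res[, -1], res2[, -1])
})

test_that("degenerate label sets are rejected with informative errors", {
  X <- matrix(rnorm(40), 10)
  expect_error(train_metal_classifier(X, rep("Nif", 10), train_config()),
               "2 classes")
  expect_error(train_metal_classifier(X, c(rep("Nif", 9), "Vnf"),
                                      train_config()), "Vnf")
  expect_error(train_config(train_fraction = 1), "between 0 and 1")
  expect_error(train_config(cv_folds = 1), "at least 2")
})

test_that("training is reproducible and invariant to feature-block permutation", {
  fam <- small_family()
  active <- extract_active_site(fam$alignment, active_site_plan()$positions)
  X <- encode_extant(active, jtt())
  lab <- fam$alignment$labels != "unknown"
  cfg <- train_config(seed = 31, n_replicates = 3)
  a1 <- train_metal_classifier(X[lab, ], fam$alignment$labels[lab], cfg)
  a2 <- train_metal_classifier(X[lab, ], fam$alignment$labels[lab], cfg)
  expect_identical(a1$replicate_report, a2$replicate_report)

  # permute whole 20-blocks consistently: accuracies unchanged
  perm <- as.vector(outer(1:20, (sample(30) - 1) * 20, "+"))
  a3 <- train_metal_classifier(X[lab, perm], fam$alignment$labels[lab], cfg)
  expect_equal(a1$replicate_report$accuracy, a3$replicate_report$accuracy)
})

test_that("doubling class weights leaves separable predictions unchanged", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, 0), 15), matrix(rnorm(60, 5), 15))
  y <- rep(c("Nif", "Vnf"), each = 15)
  gam <- rbf_gamma(X)
  w1 <- class_weights(y)
  f1 <- paleonif:::fit_ovr(X, y, C = 10, gamma = gam, weights = w1)
  f2 <- paleonif:::fit_ovr(X, y, C = 10, gamma = gam, weights = 2 * w1)
  d1 <- paleonif:::ovr_decision(f1, X)
  d2 <- paleonif:::ovr_decision(f2, X)
  expect_equal(colnames(d1)[max.col(d1)], colnames(d2)[max.col(d2)])
})

test_that("one-hot encoding with a unique signature residue separates at any C", {
  # three classes, one diagnostic site each, identical elsewhere
  seqs <- c(n1 = "AAK", n2 = "AAK", v1 = "CAK", v2 = "CAK",
            f1 = "HAK", f2 = "HAK")
  aln <- labeled_alignment(seqs, c("Nif", "Nif", "Vnf", "Vnf", "Anf", "Anf"))
  X <- encode_extant(aln, jtt(), distribution_config(component_weights = c(1, 0, 0)))
  w <- class_weights(aln$labels)
  gam <- rbf_gamma(X)
  for (C in c(0.1, 1, 10, 100)) {
    fits <- paleonif:::fit_ovr(X, aln$labels, C, gam, w)
    d <- paleonif:::ovr_decision(fits, X)
    expect_equal(colnames(d)[max.col(d)], unname(aln$labels))
  }
})

test_that("dimension mismatches are refused at classification time", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 5), 10))
  clf <- train_metal_classifier(X, rep(c("Nif", "Vnf"), each = 10),
                                train_config(n_replicates = 2, seed = 3))
  expect_error(classify_metal(clf, matrix(0, 1, 3)), "dimensionality")
})

test_that("PCA separability reports minimal components per contrast", {
  # disjoint 1-D clouds embedded in 3-D: separable on the first component
  set.seed(2)
  X <- cbind(c(rnorm(20, -8), rnorm(20, 8)), rnorm(40, sd = 0.1),
             rnorm(40, sd = 0.1))
  y <- rep(c("Nif", "Vnf"), each = 20)
  res <- pca_separability(X, y, contrasts = list(list(a = "Nif", b = "Vnf")))
  expect_equal(res$min_components, 1L)

  # identical class distributions: not separable within two components
  X2 <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40), 10))
  res2 <- pca_separability(X2, rep(c("Nif", "Vnf"), each = 10),
                           contrasts = list(list(a = "Nif", b = "Vnf")),
                           max_k = 2)
  expect_true(is.na(res2$min_components))
})
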