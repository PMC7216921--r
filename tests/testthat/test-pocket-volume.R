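test_that("the lattice reproduces analytic sphere volumes and unions", {
  cfg <- pocket_config()
  g <- generate_grid(inclusion_region(c(0, 0, 0), 5), cfg)
  vol <- nrow(g) * cfg$grid_spacing^3
  expect_lt(abs(vol - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.02)

  # refining the spacing converges toward the analytic value
  g2 <- generate_grid(inclusion_region(c(0, 0, 0), 5),
                      pocket_config(grid_spacing = 0.25))
  vol2 <- nrow(g2) * 0.25^3
  expect_lt(abs(vol2 - 4 / 3 * pi * 125), abs(vol - 4 / 3 * pi * 125))

  # a sphere smaller than half the spacing, centered off-lattice, may be empty
  tiny <- generate_grid(inclusion_region(c(0.26, 0.13, 0.07), 0.1),
                        pocket_config(grid_spacing = 0.6))
  expect_equal(nrow(tiny), 0)

  # disjoint spheres: counts add
  ga <- generate_grid(inclusion_region(c(0, 0, 0), 3), cfg)
  gb <- generate_grid(inclusion_region(c(50, 0, 0), 3), cfg)
  gu <- generate_grid(inclusion_region(rbind(c(0, 0, 0), c(50, 0, 0)), 3), cfg)
  expect_equal(nrow(gu), nrow(ga) + nrow(gb))
})

test_that("carving removes points inside vdw radius plus pad", {
  cfg <- pocket_config()
  g <- generate_grid(inclusion_region(c(0, 0, 0), 5), cfg)
  # no receptor atoms: unchanged
  empty <- parse_structure(
    "ATOM      1  CA  GLY A   1      99.000  99.000  99.000  1.00  0.00           C")
  expect_equal(nrow(carve(g, empty, cfg)), nrow(g))

  # single carbon at a grid point removes everything within 1.70 + 1.09
  carbon <- parse_structure(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C")
  kept <- carve(g, carbon, cfg)
  d <- sqrt(rowSums(kept[, 1:3]^2))
  expect_true(all(d >= 2.79))
  removed <- nrow(g) - nrow(kept)
  inside <- sum(sqrt(rowSums(g[, 1:3]^2)) < 2.79)
  expect_equal(removed, inside)

  # adding an atom never increases the retained count
  two <- parse_structure(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       2.000   2.000   0.000  1.00  0.00           C"))
  expect_lte(nrow(carve(g, two, cfg)), nrow(kept))

  # unknown element without fallback errors; fallback accepted
  exotic <- parse_structure(
    "HETATM    1 XX   UNL A   1       0.000   0.000   0.000  1.00  0.00           XX")
  expect_error(carve(g, exotic, cfg), "fallback_radius")
  expect_silent(carve(g, exotic, pocket_config(fallback_radius = 1.7)))
})

test_that("hull membership matches the quadratic-programming oracle", {
  skip_if_not_installed("quadprog")
  set.seed(14)
  for (rep in 1:4) {
    atoms <- matrix(rnorm(3 * 9, sd = 4), ncol = 3)
    pts <- matrix(rnorm(3 * 120, sd = 4), ncol = 3)
    lines <- vapply(seq_len(nrow(atoms)), function(i) {
      sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              i, i, atoms[i, 1], atoms[i, 2], atoms[i, 3])
    }, character(1))
    s <- parse_structure(lines)
    colnames(pts) <- c("x", "y", "z")
    attr(pts, "anchor") <- c(0, 0, 0); attr(pts, "spacing") <- 0.5
    kept <- hull_filter_points(pts, s, config = pocket_config())
    inside_oracle <- apply(pts, 1, function(p) qp_in_hull(p, atoms))
    in_kept <- paste(pts[, 1], pts[, 2], pts[, 3]) %in%
      paste(kept[, 1], kept[, 2], kept[, 3])
    # allow boundary-grazing disagreement only
    disagree <- which(in_kept != inside_oracle)
    if (length(disagree)) {
      for (i in disagree) {
        d <- min(abs(apply(atoms, 1, function(a) sqrt(sum((a - pts[i, ])^2)))))
        expect_lt(d, 0.51)
      }
    } else {
      expect_equal(in_kept, inside_oracle)
    }
  }
})

test_that("hull keeps interior points and rejects far exterior points", {
  tet <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  lines <- vapply(1:4, function(i) {
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, tet[i, 1], tet[i, 2], tet[i, 3])
  }, character(1))
  s <- parse_structure(lines)
  pts <- rbind(c(1, 1, 1), c(2, 2, 2), c(20, 20, 20))
  colnames(pts) <- c("x", "y", "z")
  attr(pts, "anchor") <- c(0, 0, 0); attr(pts, "spacing") <- 1
  kept <- hull_filter_points(pts, s, config = pocket_config())
  expect_equal(nrow(kept), 2)
  expect_true(all(kept[, 1] < 3))
})

test_that("contiguity filtering matches a breadth-first-search oracle", {
  set.seed(33)
  cfg <- pocket_config()
  for (rep in 1:3) {
    idx <- unique(matrix(sample(0:6, 3 * 70, replace = TRUE), ncol = 3))
    pts <- idx * 0.5
    colnames(pts) <- c("x", "y", "z")
    attr(pts, "anchor") <- c(0, 0, 0); attr(pts, "spacing") <- 0.5
    kept <- contiguity_filter_points(pts, cfg)
    comp <- bfs_components(idx)
    largest <- max(tabulate(comp))
    expect_equal(nrow(kept), largest)
  }
  # explicit seed coordinate selects its own component, even a small one
  idx2 <- rbind(unname(as.matrix(expand.grid(0:4, 0:4, 0))), c(20, 20, 0))
  pts2 <- idx2 * 0.5
  colnames(pts2) <- c("x", "y", "z")
  attr(pts2, "anchor") <- c(0, 0, 0); attr(pts2, "spacing") <- 0.5
  kept2 <- contiguity_filter_points(
    pts2, pocket_config(contiguity_seed = c(10, 10, 0)))
  expect_equal(nrow(kept2), 1)
})

test_that("the full pipeline reproduces analytic cavities and stage order", {
  fx <- generate_pocket_fixture("sphere-shell", list(radius = 8))
  pr <- pocket_volume(fx$structure, fx$region)
  expect_lt(abs(pr$volume - fx$expected_volume) / fx$expected_volume, 0.05)
  expect_true(all(diff(pr$counts) <= 0))   # monotone filter stages

  # carving active when the inclusion region overshoots the cavity; a fine
  # shell is used because the closed form assumes a continuous wall (the
  # carved surface bulges slightly between discrete atoms), and the hull
  # step is skipped so the brute-force facet search stays cheap
  fx_wide <- generate_pocket_fixture(
    "sphere-shell", list(radius = 8, inclusion_radius = 8, n_atoms = 700))
  cfg_nohull <- pocket_config(hull_filter = FALSE)
  pr_wide <- pocket_volume(fx_wide$structure, fx_wide$region, cfg_nohull)
  expect_lt(abs(pr_wide$volume - fx_wide$expected_volume) /
              fx_wide$expected_volume, 0.05)
  expect_lt(pr_wide$counts["carve"], pr_wide$counts["grid"])

  # empty inclusion region (off-lattice dust grain) gives volume zero
  empty <- pocket_volume(fx$structure,
                         inclusion_region(c(0.31, 0.17, 0.05), 0.05),
                         pocket_config(grid_spacing = 0.6))
  expect_equal(empty$volume, 0)

  # the two-chamber fixture keeps exactly the larger chamber
  fx2 <- generate_pocket_fixture("two-chamber",
                                 list(radius_a = 8, radius_b = 5.5))
  pr2 <- pocket_volume(fx2$structure, fx2$region)
  expect_lt(abs(pr2$volume - fx2$expected_volume) / fx2$expected_volume, 0.05)
})

test_that("volume is invariant under rigid motion of structure and region", {
  set.seed(91)
  fx <- generate_pocket_fixture("sphere-shell", list(radius = 7, n_atoms = 140))
  base <- pocket_volume(fx$structure, fx$region)
  R <- random_rotation()
  shift <- c(3.1, -7.4, 12.9)
  sr <- rotate_structure(fx$structure, R, shift)
  center <- as.numeric(fx$region$centers %*% t(R)) + shift
  pr <- pocket_volume(sr, inclusion_region(center, fx$region$radii))
  expect_lt(abs(pr$volume - base$volume) / base$volume, 0.05)
})

test_that("group volume comparison matches the exact rank-sum reference", {
  # identical groups: null-centered statistic, zero median difference
  same <- compare_volume_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$tests$median_diff, 0)
  expect_equal(same$tests$statistic, 3 * 3 / 2, tolerance = 1e-9)

  # fully separated groups attain the maximal rank statistic
  apart <- compare_volume_groups(list(lo = c(1, 2, 3), hi = c(101, 102, 103)))
  expect_equal(apart$tests$statistic, 0)

  set.seed(4)
  x <- round(runif(5, 900, 1100), 1)
  y <- round(runif(6, 950, 1250), 1)
  got <- compare_volume_groups(list(x = x, y = y))
  ref <- perm_rank_sum(x, y)
  expect_equal(got$tests$statistic, ref$W)
  expect_equal(got$tests$p_value, ref$p, tolerance = 1e-9)

  expect_error(compare_volume_groups(list(a = 1)), "at least 2")
  expect_error(compare_volume_groups(list(a = 1, b = numeric())), "at least one")
})
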