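test_that("PDB parsing echoes atoms and resolves altlocs by occupancy", {
  s <- parse_structure(toy_pdb_lines(), cofactor = "LIG")
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$z, c(4, 6, 0))
  expect_equal(s$atoms$element, c("C", "C", "FE"))

  alt <- c("ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
           "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 10.00           C")
  sa <- parse_structure(alt)
  expect_equal(nrow(sa$atoms), 1)
  expect_equal(sa$atoms$occupancy, 0.6)
  expect_equal(sa$atoms$x, 1)

  expect_error(parse_structure("REMARK nothing here"), "no ATOM/HETATM")
  bad <- "ATOM      1  CA  GLY A   1       x.000   0.000   0.000  1.00  0.00           C"
  expect_error(parse_structure(bad), "line 1")
})

test_that("contact residues respect the distance cutoff exactly", {
  s <- parse_structure(toy_pdb_lines(), cofactor = "LIG")
  near5 <- residues_near_cofactor(s, active_site_config(cutoff = 5))
  expect_equal(near5$residue_seq, 1)        # 4 A in, 6 A out
  near6 <- residues_near_cofactor(s, active_site_config(cutoff = 6))
  expect_equal(near6$residue_seq, c(1, 2))  # boundary atom included at 6
  # coincident atom at cutoff zero
  s0 <- parse_structure(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2 FE   LIG L 900       0.000   0.000   0.000  1.00  0.00          FE"),
    cofactor = "LIG")
  expect_equal(residues_near_cofactor(s0, active_site_config(cutoff = 0))$residue_seq, 1)
  expect_error(residues_near_cofactor(s, cofactor = "XYZ"), "LIG")
})

test_that("contact sets are monotone in the cutoff and rigid-motion invariant", {
  set.seed(42)
  tc <- generate_toy_complex(sort(runif(12, 2, 9)))
  s <- tc$structure
  r4 <- residues_near_cofactor(s, active_site_config(cutoff = 4))$residue_seq
  r5 <- residues_near_cofactor(s, active_site_config(cutoff = 5))$residue_seq
  expect_true(all(r4 %in% r5))
  expect_equal(r5, tc$expected_contacts(5))
  for (i in 1:3) {
    R <- random_rotation()
    sr <- rotate_structure(s, R, shift = rnorm(3, sd = 20))
    expect_equal(residues_near_cofactor(sr, active_site_config(cutoff = 5))$residue_seq, r5)
  }
})

test_that("position mapping reproduces identity, shifts, and internal gaps", {
  ref <- "MSREEVESLIQEVLEVYPEKARKDRNKHLAV"
  m_id <- map_positions(ref, ref)
  expect_equal(m_id$query_index, seq_len(nchar(ref)))

  # one N-terminal residue deleted: every later position shifts down by one
  query <- substr(ref, 2, nchar(ref))
  m_sh <- map_positions(query, ref)
  expect_true(is.na(m_sh$query_index[1]))
  expect_equal(m_sh$query_index[-1], seq_len(nchar(ref) - 1))

  # 3-residue internal deletion: the hand alignment is the construction
  query2 <- paste0(substr(ref, 1, 10), substr(ref, 14, nchar(ref)))
  m_in <- map_positions(query2, ref)
  expect_equal(m_in$query_index[1:10], 1:10)
  expect_true(all(is.na(m_in$query_index[11:13])))
  expect_equal(m_in$query_index[14:nchar(ref)], 11:(nchar(ref) - 3))

  expect_error(map_positions("", ref), "non-empty")
})

test_that("active-site extraction slices reference-numbered columns", {
  fam <- small_family()
  plan <- active_site_plan()
  active <- extract_active_site(fam$alignment, plan$positions)
  expect_equal(nchar(active$seqs[[1]]), 30L)
  expect_equal(attr(active, "positions"), plan$positions)
  # the universally conserved residues are present in every sequence
  m <- alignment_matrix(active)
  for (p in names(plan$conserved)) {
    col <- match(as.integer(p), plan$positions)
    expect_true(all(m[, col] == plan$conserved[[p]]),
                label = paste("conserved residue at", p))
  }
  # labels survive the slice
  expect_equal(active$labels, fam$alignment$labels)
  expect_error(extract_active_site(fam$alignment, c(1, 10000)), "outside")
  no_ref <- labeled_alignment(c(s1 = "AC", s2 = "AC"))
  expect_error(extract_active_site(no_ref, 1), "reference")
})

test_that("mapped union of contact positions collapses oligomer copies", {
  # two chains carrying the same sequence, ligand near residues 2 and 3
  lines <- c(
    "ATOM      1  CA  ALA A   1      20.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  CYS A   2       3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ASP A   3       0.000   3.500   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLU A   4      25.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  ALA B   1      20.000  40.000   0.000  1.00  0.00           C",
    "ATOM      6  CA  CYS B   2       3.000  40.000   0.000  1.00  0.00           C",
    "ATOM      7  CA  ASP B   3       0.000  43.500   0.000  1.00  0.00           C",
    "ATOM      8  CA  GLU B   4      25.000  40.000   0.000  1.00  0.00           C",
    "HETATM    9 FE   LIG A 900       0.000   0.000   0.000  1.00  0.00          FE",
    "HETATM   10 FE   LIG B 901       0.000  40.000   0.000  1.00  0.00          FE")
  s <- parse_structure(lines, cofactor = "LIG")
  pos <- active_site_union(list(s), reference_sequence = "ACDE")
  expect_equal(pos, c(2L, 3L))
})
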