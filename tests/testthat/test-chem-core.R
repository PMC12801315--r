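test_that("SMILES parsing assigns formulas, hydrogens and aromaticity", {
  m <- parse_smiles("CCO")
  expect_equal(heavy_atom_count(m), 3L)
  expect_equal(molecular_formula(m), "C2H6O")

  b <- parse_smiles("c1ccccc1")
  expect_equal(element_count(b, "C"), 6L)
  expect_equal(cycle_rank(b), 1L)
  expect_true(all(b$atoms$aromatic))
  expect_equal(molecular_formula(b), "C6H6")

  # Kekule input is perceived as aromatic
  expect_identical(canonical_smiles("C1=CC=CC=C1"), canonical_smiles("c1ccccc1"))
  expect_identical(canonical_smiles("C1=CC=CN1"), canonical_smiles("c1cc[nH]c1"))

  expect_equal(molecular_formula(parse_smiles("[NH4+]")), "H4N+")
  expect_equal(element_count(parse_smiles("CC(=O)Oc1ccccc1C(=O)O"), "C"), 9L)
})

test_that("invalid SMILES raise an explicit parse signal, never a crash", {
  expect_error(parse_smiles("C1CC1C("), class = "chemquiz_parse_error")
  expect_error(parse_smiles("C1CC"), class = "chemquiz_parse_error")   # open ring
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), class = "chemquiz_parse_error")
  expect_error(parse_smiles(""), class = "chemquiz_parse_error")
  expect_error(parse_smiles("C=#C"), class = "chemquiz_parse_error")
})

test_that("canonicalization is order-invariant and idempotent", {
  expect_identical(canonical_smiles("OCC"), canonical_smiles("CCO"))
  rotations <- c("c1ccccc1", "C1=CC=CC=C1", "C1C=CC=CC=1")
  expect_length(unique(vapply(rotations, canonical_smiles, character(1))), 1L)

  drug <- druglike_library()
  idx <- with_seed(7L, sample(nrow(drug), 100L))
  for (s in drug$smiles[idx]) {
    cs <- canonical_smiles(s)
    expect_identical(canonical_smiles(cs), cs)
  }
})

test_that("randomize-then-canonicalize equals direct canonicalization on 100 fixtures", {
  drug <- druglike_library()
  idx <- with_seed(11L, sample(nrow(drug), 100L))
  for (k in seq_along(idx)) {
    mol <- parse_smiles(drug$smiles[idx[k]])
    cs <- canonical_smiles(mol)
    v <- randomized_smiles(mol, seed = 1000L + k)
    expect_identical(canonical_smiles(v$text), cs)
  }
})

test_that("variant order maps are element-preserving bijections", {
  drug <- druglike_library()
  idx <- with_seed(13L, sample(nrow(drug), 25L))
  for (k in seq_along(idx)) {
    mol <- parse_smiles(drug$smiles[idx[k]])
    for (v in list(randomized_smiles(mol, k), semicanonical_smiles(mol, k),
                   canonical_variant(mol))) {
      expect_setequal(v$order_map, seq_len(nrow(mol$atoms)))
      reparsed <- parse_smiles(v$text)
      expect_identical(reparsed$atoms$element[seq_along(v$order_map)] |> sort(),
                       mol$atoms$element |> sort())
      # atom at string position i really is the mapped atom: same element
      expect_identical(reparsed$atoms$element, mol$atoms$element[v$order_map])
    }
  }
})

test_that("randomized and semicanonical variants are seed-deterministic", {
  mol <- parse_smiles("CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  expect_identical(randomized_smiles(mol, 42L)$text, randomized_smiles(mol, 42L)$text)
  expect_identical(semicanonical_smiles(mol, 42L)$text, semicanonical_smiles(mol, 42L)$text)
  expect_false(randomized_smiles(mol, 1L)$text == randomized_smiles(mol, 2L)$text)
})

test_that("semicanonical traversal follows canonical rules after the root", {
  mol <- parse_smiles("CCO")
  # find a seed rooting the traversal at the oxygen: remaining traversal is
  # canonical, so the string must be OCC
  o_id <- which(mol$atoms$element == "O")
  for (s in 1:30) {
    v <- semicanonical_smiles(mol, s)
    if (v$order_map[1] == o_id) break
  }
  expect_equal(v$order_map[1], o_id)
  expect_identical(v$text, "OCC")
})

test_that("graph distances match BFS semantics and brute-force enumeration", {
  b <- parse_smiles("c1ccccc1")
  expect_equal(graph_distance(b, 1L, 2L), 1L)
  expect_equal(graph_distance(b, 1L, 4L), 3L)   # para
  expect_error(graph_distance(parse_smiles("C.C"), 1L, 2L), class = "chemquiz_no_path")

  small <- small_molecule_library()
  idx <- with_seed(17L, sample(nrow(small), 30L))
  for (s in small$smiles[idx]) {
    mol <- parse_smiles(s)
    n <- nrow(mol$atoms)
    if (n < 2L) next
    pairs <- with_seed(19L, replicate(3, sample(n, 2L), simplify = FALSE))
    for (p in pairs) {
      d <- graph_distance(mol, p[1], p[2])
      expect_equal(d, oracle_bfs_distance(mol, p[1], p[2]))
      expect_equal(d, oracle_all_simple_paths_min(mol, p[1], p[2]))
      expect_equal(d, graph_distance(mol, p[2], p[1]))  # symmetry
    }
  }
  # triangle inequality on a fused bicycle
  nap <- parse_smiles("c1ccc2ccccc2c1")
  for (trip in list(c(1, 5, 8), c(2, 6, 10), c(3, 7, 9))) {
    expect_lte(graph_distance(nap, trip[1], trip[3]),
               graph_distance(nap, trip[1], trip[2]) + graph_distance(nap, trip[2], trip[3]))
  }
})

test_that("cycle rank matches known ring counts and the external engine", {
  expect_equal(cycle_rank(parse_smiles("CCCCCC")), 0L)
  expect_equal(cycle_rank(parse_smiles("c1ccccc1")), 1L)
  expect_equal(cycle_rank(parse_smiles("c1ccccc1-c1ccccc1")), 2L)
  expect_equal(cycle_rank(parse_smiles("c1ccc2ccccc2c1")), 2L)  # 11 bonds - 10 atoms + 1

  # SSSR referee: RDKit's smallest set of smallest rings on sampled fixtures
  skip_if_not(nzchar(Sys.which("python")))
  drug <- druglike_library()
  idx <- with_seed(23L, sample(nrow(drug), 40L))
  inf <- tempfile(fileext = ".smi")
  writeLines(drug$smiles[idx], inf)
  out <- tryCatch(system2("python", c("-c", shQuote(paste0(
    "from rdkit import Chem\n",
    "import sys\n",
    "for line in open('", inf, "'):\n",
    "    m = Chem.MolFromSmiles(line.strip())\n",
    "    print(len(Chem.GetSSSR(m)))"))), stdout = TRUE, stderr = FALSE),
    error = function(e) NULL)
  skip_if(is.null(out) || length(out) != length(idx))
  expect_equal(vapply(drug$smiles[idx], function(s) cycle_rank(parse_smiles(s)),
                      integer(1), USE.NAMES = FALSE),
               as.integer(out))
})

test_that("canonical equivalence agrees with the OpenBabel referee", {
  skip_if_not(obabel_available())
  drug <- druglike_library()
  idx <- with_seed(29L, sample(nrow(drug), 40L))
  smiles <- drug$smiles[idx]
  variants <- vapply(seq_along(smiles), function(k)
    randomized_smiles(parse_smiles(smiles[k]), 500L + k)$text, character(1))
  ob_a <- obabel_canonical(smiles)
  ob_b <- obabel_canonical(variants)
  expect_identical(ob_a, ob_b)
  # InChI cross-check on the same pairs
  expect_identical(obabel_inchi(smiles), obabel_inchi(variants))
})

test_that("molecule libraries satisfy their contracts", {
  drug <- druglike_library()
  small <- small_molecule_library()
  expect_gte(nrow(drug), 500L)
  expect_gte(nrow(small), 100L)
  expect_true(all(drug$heavy_atoms >= 10L & drug$heavy_atoms <= 30L))
  expect_true(all(small$heavy_atoms <= 10L))
  expect_length(intersect(drug$smiles, small$smiles), 0L)
  # stability of canonicalization over every member (small library fully)
  for (s in small$smiles) expect_identical(canonical_smiles(s), s)
  idx <- with_seed(31L, sample(nrow(drug), 50L))
  for (s in drug$smiles[idx]) expect_identical(canonical_smiles(s), s)
  # per-element formula totals match an independent per-atom tally
  for (s in small$smiles[with_seed(37L, sample(nrow(small), 20L))]) {
    mol <- parse_smiles(s)
    f <- molecular_formula(mol)
    c_in_f <- as.integer(sub(".*?C([0-9]*).*", "\\1", paste0(f, " ")) |>
                           (\(x) ifelse(x == "", "1", x))())
    if (!grepl("C", f)) c_in_f <- 0L
    expect_equal(c_in_f, sum(mol$atoms$element == "C"))
  }
})

test_that("automorphism machinery matches closed-form symmetry counts", {
  expect_length(mol_automorphisms(parse_smiles("c1ccccc1")), 12L)  # dihedral D6
  expect_length(mol_automorphisms(parse_smiles("CCO")), 1L)
  orb <- atom_orbits(parse_smiles("Cc1ccc(C)cc1"))   # para-xylene
  expect_equal(length(unique(orb)), 3L)
})
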