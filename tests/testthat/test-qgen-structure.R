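test_that("counting questions embed the canonical SMILES and exact truths", {
  q <- gen_count_question("c1ccccc1", "carbon")
  expect_equal(q$truth[[1]]$value, 6L)
  expect_match(q$prompt, "c1ccccc1", fixed = TRUE)
  expect_equal(gen_count_question("c1ccccc1-c1ccccc1", "ring")$truth[[1]]$value, 2L)

  # character-level tally oracle on drug-like fixtures
  drug <- druglike_library()
  for (s in drug$smiles[with_seed(3L, sample(nrow(drug), 30L))]) {
    q <- gen_count_question(s, "carbon")
    embedded <- sub(".*SMILES string ([^\n]+)\n.*", "\\1", q$prompt)
    expect_equal(q$truth[[1]]$value, oracle_carbon_tally(embedded))
  }
})

test_that("shortest-path questions include both attachment bonds", {
  # force the end-to-end mark on n-butane by scanning seeds
  mol <- parse_smiles("CCCC")
  found <- FALSE
  for (s in 1:200) {
    q <- gen_shortest_path_question(mol, "canonical", seed = s)
    marked <- parse_smiles(q$meta[[1]]$marked)
    dummies <- which(marked$atoms$dummy)
    anchors <- vapply(dummies, function(d) atom_neighbors(marked, d)[1], integer(1))
    deg <- vapply(anchors, function(a)
      sum(!marked$atoms$dummy[atom_neighbors(marked, a)]), integer(1))
    if (all(deg == 1L)) { found <- TRUE; break }   # both dummies on chain ends
  }
  expect_true(found)
  expect_equal(q$truth[[1]]$value, 5L)   # dummy-C1-C2-C3-C4-dummy

  # para-marked benzene: 3 ring bonds + 2 attachment bonds
  bz <- parse_smiles("c1ccccc1")
  m1 <- attach_dummy(bz, 1L)
  m2 <- attach_dummy(m1$mol, 4L)
  expect_equal(graph_distance(m2$mol, m1$dummy_id, m2$dummy_id), 5L)
})

test_that("shortest-path truths equal brute-force enumeration and ignore the SMILES mode", {
  small <- small_molecule_library()
  pool <- small[small$heavy_atoms >= 4L, ]
  # respect the generator precondition: two substitutable positions
  ok <- vapply(pool$smiles, function(s) {
    m <- parse_smiles(s); sum(m$atoms$hcount >= 1L) >= 2L
  }, logical(1))
  pool <- pool[ok, ]
  idx <- with_seed(9L, sample(nrow(pool), 25L))
  for (k in seq_along(idx)) {
    s <- pool$smiles[idx[k]]
    qc <- gen_shortest_path_question(s, "canonical", seed = 100L + k)
    qr <- gen_shortest_path_question(s, "randomized", seed = 100L + k)
    expect_equal(qc$truth[[1]]$value, qr$truth[[1]]$value)  # graph, not string
    marked <- parse_smiles(qc$meta[[1]]$marked)
    dummies <- which(marked$atoms$dummy)
    expect_equal(qc$truth[[1]]$value,
                 oracle_all_simple_paths_min(marked, dummies[1], dummies[2]))
  }
  # fused bicycle specifically
  q <- gen_shortest_path_question("c1ccc2ccccc2c1", "canonical", seed = 5L)
  marked <- parse_smiles(q$meta[[1]]$marked)
  dummies <- which(marked$atoms$dummy)
  expect_equal(q$truth[[1]]$value,
               oracle_all_simple_paths_min(marked, dummies[1], dummies[2]))
})

test_that("atom-mapping truths are verified isomorphisms with symmetry tolerance", {
  drug <- druglike_library()
  pool <- drug[drug$heavy_atoms <= 24L, ]
  idx <- with_seed(21L, sample(nrow(pool), 15L))
  for (k in seq_along(idx)) {
    mode <- if (k %% 2L) "randomized" else "semicanonical"
    q <- gen_atom_mapping_question(pool$smiles[idx[k]], mode, seed = 300L + k)
    truth <- q$truth[[1]]
    expect_false(identical(truth$a_text, truth$b_text))
    expect_true(check_mapping(truth$map, truth))
    # a transposition of two inequivalent positions must fail
    mol <- parse_smiles(truth$source)
    orb <- atom_orbits(mol)
    wrong <- truth$map
    pos_pair <- NULL
    for (i in seq_along(wrong)) for (j in seq_along(wrong)) {
      if (i < j && orb[truth$a_order[i]] != orb[truth$a_order[j]]) {
        pos_pair <- c(i, j); break
      }
      if (!is.null(pos_pair)) break
    }
    wrong[pos_pair] <- wrong[rev(pos_pair)]
    expect_false(check_mapping(wrong, truth))
  }
})

test_that("mapping acceptance is exactly the automorphism coset on small fixtures", {
  # exhaustive enumeration over all colour-preserving bijections
  for (s in c("c1ccoc1", "Clc1ccc(Cl)cc1", "CC(C)O")) {
    mol <- parse_smiles(s)
    va <- randomized_smiles(mol, 1L)
    vb <- randomized_smiles(mol, 2L)
    truth <- list(source = canonical_smiles(mol),
                  a_order = as.integer(va$order_map),
                  b_order = as.integer(vb$order_map))
    truth$source <- s  # atom ids refer to this parse
    n <- nrow(mol$atoms)
    # candidate maps: all permutations preserving atom colours
    perms <- all_colored_permutations(mol)
    accepted <- 0L
    for (p in perms) {
      # answer map in position space: position i of A -> position of atom
      # p[atom at position i] in B
      amap <- match(p[va$order_map], vb$order_map)
      if (check_mapping(amap, truth)) accepted <- accepted + 1L
    }
    expect_equal(accepted, length(mol_automorphisms(mol)))
  }
})

test_that("identity mapping is accepted when both variants coincide", {
  mol <- parse_smiles("CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  v <- randomized_smiles(mol, 5L)
  truth <- list(source = canonical_smiles(mol),
                a_order = as.integer(v$order_map),
                b_order = as.integer(v$order_map))
  expect_true(check_mapping(seq_along(v$order_map), truth))
})

test_that("self-scoring consistency holds for structure-question generators", {
  drug <- druglike_library()
  for (k in 1:5) {
    s <- drug$smiles[k * 7L]
    qs <- list(gen_count_question(s, "carbon", k),
               gen_shortest_path_question(s, "canonical", k),
               gen_atom_mapping_question(drug$smiles[drug$heavy_atoms <= 24L][k],
                                         "randomized", k))
    for (q in qs) {
      q$id <- "x-1"
      j <- judge_response(q, paste0("Answer: ", q$ref_answer), "strict")
      expect_identical(j$verdict, "correct")
    }
  }
})
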