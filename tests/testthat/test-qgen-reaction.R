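test_that("the template set contains nine complete reaction classes", {
  ts <- reaction_template_set()
  expect_length(ts, 9L)
  expect_setequal(names(ts), c("sn2", "click", "simmons_smith", "suzuki", "amide",
                               "reductive_amination", "fischer", "grignard", "wittig"))
  for (t in ts) {
    expect_true(nzchar(t$conditions))
    expect_gte(length(t$pools), 1L)
    # template self-test on its first-choice demo reactants
    demo <- lapply(t$pools, `[[`, 1L)
    q <- gen_reaction_question(t, "canonical", seed = 1L, reactants = demo)
    expect_s3_class(parse_smiles(q$truth[[1]]$smiles), "molecule")
  }
})

test_that("named rewrites give the textbook products", {
  ts <- reaction_template_set()
  # SN2 on 1-bromopropane: Br replaced by O
  q <- gen_reaction_question(ts$sn2, "canonical", reactants = list("CCCBr"))
  expect_true(smiles_equivalent(q$truth[[1]]$smiles, "CCCO"))
  # click: benzyl azide + phenylacetylene -> 1,4-disubstituted triazole
  q <- gen_reaction_question(ts$click, "canonical",
                             reactants = list("C(c1ccccc1)N=[N+]=[N-]", "C#Cc1ccccc1"))
  expect_true(smiles_equivalent(q$truth[[1]]$smiles,
                                "c1ccc(cc1)Cn1cc(-c2ccccc2)nn1"))
  # ... and not the 1,5 isomer
  expect_false(smiles_equivalent(q$truth[[1]]$smiles,
                                 "C(c1ccccc1)n1nncc1-c1ccccc1"))
  # Simmons-Smith on styrene -> phenylcyclopropane
  q <- gen_reaction_question(ts$simmons_smith, "canonical",
                             reactants = list("C=Cc1ccccc1"))
  expect_true(smiles_equivalent(q$truth[[1]]$smiles, "C1CC1c1ccccc1"))
  # Suzuki: bromobenzene + phenylboronic acid -> biphenyl
  q <- gen_reaction_question(ts$suzuki, "canonical",
                             reactants = list("Brc1ccccc1", "OB(O)c1ccccc1"))
  expect_true(smiles_equivalent(q$truth[[1]]$smiles, "c1ccccc1-c1ccccc1"))
})

test_that("click products always carry the 1,4 substitution pattern", {
  ts <- reaction_template_set()
  for (az in ts$click$pools[[1]]) for (al in ts$click$pools[[2]]) {
    q <- gen_reaction_question(ts$click, "canonical", reactants = list(az, al))
    prod <- parse_smiles(q$truth[[1]]$smiles)
    # locate the triazole: three nitrogens in one aromatic 5-ring
    ns <- which(prod$atoms$element == "N" & prod$atoms$aromatic)
    expect_length(ns, 3L)
    # substituted ring nitrogen (N1) has an exocyclic single-bonded carbon
    n1 <- ns[vapply(ns, function(a) any(vapply(atom_neighbors(prod, a), function(v)
      bond_between(prod, a, v) == "1", logical(1))), logical(1))]
    expect_length(n1, 1L)
    # 1,4 pattern: the substituted ring carbon is NOT adjacent to N1
    ring_c <- which(prod$atoms$element == "C" & prod$atoms$aromatic &
                      vapply(seq_len(nrow(prod$atoms)), function(a)
                        any(atom_neighbors(prod, a) %in% ns), logical(1)) &
                      prod$atoms$hcount == 0L)
    ring_c <- ring_c[vapply(ring_c, function(a)
      sum(vapply(atom_neighbors(prod, a), function(v)
        bond_between(prod, a, v) == "ar", logical(1))) == 2L, logical(1))]
    expect_length(ring_c, 1L)
    expect_false(n1 %in% atom_neighbors(prod, ring_c))
  }
})

test_that("atom balance holds up to each template's declared leaving groups", {
  ts <- reaction_template_set()
  for (t in ts) {
    combos <- expand.grid(lapply(t$pools, seq_along))
    for (r in seq_len(nrow(combos))) {
      rs <- lapply(seq_along(t$pools), function(k) t$pools[[k]][combos[r, k]])
      mols <- lapply(rs, parse_smiles)
      comb <- chemquiz:::combine_all(mols)
      prod <- t$rewrite(comb)
      diff <- chemquiz:::tally_minus(chemquiz:::element_tally(comb),
                                     chemquiz:::element_tally(prod))
      expected <- chemquiz:::tally_minus(t$lost, t$gained)
      expect_identical(diff[order(names(diff))], expected[order(names(expected))],
                       info = paste(t$class, paste(unlist(rs), collapse = " + ")))
    }
  }
})

test_that("reaction questions self-score and respect the SMILES mode", {
  ts <- reaction_template_set()
  for (k in seq_along(ts)) {
    qc <- gen_reaction_question(ts[[k]], "canonical", seed = 50L + k)
    qr <- gen_reaction_question(ts[[k]], "randomized", seed = 50L + k)
    expect_identical(qc$truth[[1]]$smiles, qr$truth[[1]]$smiles)
    for (q in list(qc, qr)) {
      q$id <- "x-1"
      expect_identical(judge_response(q, paste0("Answer: ", q$ref_answer))$verdict,
                       "correct")
    }
    # reactants render differently but parse to the same fragments
    rc <- sub("Reactant\\(s\\): ([^\n]+)\n.*", "\\1", qc$prompt)
    rr <- sub("Reactant\\(s\\): ([^\n]+)\n.*", "\\1", qr$prompt)
    expect_true(smiles_equivalent(rc, rr))
  }
})
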