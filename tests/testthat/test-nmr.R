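test_that("nucleus classes follow symmetry orbits", {
  b <- nucleus_classes(parse_smiles("c1ccccc1"))
  expect_equal(sum(b$kind == "H"), 1L)
  expect_equal(sum(b$kind == "C"), 1L)
  expect_equal(b$n_h[b$kind == "H"], 6L)

  e <- nucleus_classes(parse_smiles("CCO"))
  expect_equal(sum(e$kind == "H"), 3L)   # CH3, CH2, OH
  expect_equal(sum(e$kind == "C"), 2L)
  expect_equal(sum(e$exchangeable), 1L)

  px <- nucleus_classes(parse_smiles("Cc1ccc(C)cc1"))
  expect_equal(sum(px$kind == "H"), 2L)
  expect_equal(sum(px$kind == "C"), 3L)
})

test_that("shift estimates fall in chemically sensible windows", {
  bz <- parse_smiles("c1ccccc1")
  h <- estimate_shift_h(bz, 1L)
  expect_gte(h, 7.0); expect_lte(h, 7.5)
  acetone <- parse_smiles("CC(C)=O")
  cshift <- estimate_shift_c(acetone, 2L)
  expect_gte(cshift, 190); expect_lte(cshift, 210)
  # electronegative neighbour moves protons downfield: ethanol CH2 > CH3
  e <- parse_smiles("CCO")
  expect_gt(estimate_shift_h(e, 2L), estimate_shift_h(e, 1L))
})

test_that("multiplicities follow the n+1 rule with exchangeables excluded", {
  e <- parse_smiles("CCO")
  cls <- nucleus_classes(e)
  hcls <- cls[cls$kind == "H", ]
  lab <- vapply(seq_len(nrow(hcls)), function(i) {
    multiplicity(e, hcls[i, ])
  }, character(1))
  parent1 <- vapply(seq_len(nrow(hcls)), function(i) hcls$atoms[[i]][1], integer(1))
  expect_identical(lab[parent1 == 1L], "t")  # CH3 couples to CH2
  expect_identical(lab[parent1 == 2L], "q")  # CH2: OH excluded
  expect_identical(lab[parent1 == 3L], "br s")

  ip <- parse_smiles("CC(C)C=O")   # isobutyraldehyde: CH couples to 6+1 H
  cls <- nucleus_classes(ip)
  ch <- cls[cls$kind == "H" &
              vapply(cls$atoms, function(a) 2L %in% a, logical(1)), ]
  expect_identical(multiplicity(ip, ch[1, ]), "m")
})

test_that("1D spectra satisfy the integration bookkeeping", {
  for (s in c("CCO", "CC(=O)NC", "Oc1ccccc1", "CC(C)O", "NCCO")) {
    mol <- parse_smiles(s)
    s1 <- simulate_1d(mol)
    h_total <- sum(mol$atoms$hcount)
    expect_equal(sum(s1$h_peaks$integration) + s1$exchangeable_h, h_total)
    expect_true(all(s1$h_peaks$integration >= 1L))
    expect_equal(length(s1$c_peaks),
                 sum(nucleus_classes(mol)$kind == "C"))
    expect_false(is.unsorted(rev(s1$c_peaks)))
  }
})

test_that("2D peak lists satisfy the connectivity contracts", {
  # independent BFS oracle for the HMBC bond-count definition
  for (s in c("CCO", "CC(=O)OCC", "Cc1ccc(O)cc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O")) {
    mol <- parse_smiles(s)
    s2 <- simulate_2d(mol)
    s1 <- simulate_1d(mol)
    # ethanol checks from first principles
    if (s == "CCO") {
      expect_equal(nrow(s2$hsqc), 2L)
      expect_equal(nrow(s2$cosy), 1L)
    }
    # HSQC size = number of protonated carbon classes
    cls <- nucleus_classes(mol)
    prot_c <- sum(vapply(seq_len(nrow(cls)), function(i)
      cls$kind[i] == "C" && mol$atoms$hcount[cls$atoms[[i]][1]] > 0L, logical(1)))
    expect_equal(nrow(s2$hsqc), prot_c)
    # HMBC excludes one-bond pairs
    expect_equal(nrow(dplyr::inner_join(s2$hsqc, s2$hmbc, by = c("c", "h"))), 0L)
    # every HMBC pair corresponds to an H whose parent is 1-2 bonds from the C
    orb <- atom_orbits(mol)
    for (r in seq_len(nrow(s2$hmbc))) {
      found <- FALSE
      for (i in seq_len(nrow(cls))) for (j in seq_len(nrow(cls))) {
        if (cls$kind[i] != "C" || cls$kind[j] != "H" || cls$exchangeable[j]) next
        dmin <- min(vapply(cls$atoms[[i]], function(ca)
          min(vapply(cls$atoms[[j]], function(ha)
            oracle_bfs_distance(mol, ca, ha), integer(1))), integer(1)))
        if (dmin %in% c(1L, 2L) && orb[cls$atoms[[i]][1]] != orb[cls$atoms[[j]][1]]) found <- TRUE
      }
      expect_true(found)
    }
  }
})

test_that("spectrum rendering is deterministic with a frozen golden example", {
  e <- parse_smiles("CCO")
  txt1 <- render_spectra(simulate_1d(e), simulate_2d(e))
  txt2 <- render_spectra(simulate_1d(e), simulate_2d(e))
  expect_identical(txt1, txt2)
  expect_identical(txt1, paste(
    "1H NMR: delta 3.85 (q, 2H), 0.90 (t, 3H); plus 1 exchangeable proton not shown",
    "13C NMR: delta 59.1, 15.1",
    "COSY (1H/1H): (3.85, 0.90)",
    "HSQC (13C/1H): (59.1, 3.85), (15.1, 0.90)",
    "HMBC (13C/1H): (59.1, 0.90), (15.1, 3.85)",
    sep = "\n"))
})

test_that("NMR questions embed formula and spectra and self-score", {
  q <- gen_nmr_question("CCO", "1d")
  expect_match(q$prompt, "C2H6O", fixed = TRUE)
  expect_match(q$prompt, "exchangeable", fixed = TRUE)
  q$id <- "x-1"
  expect_identical(judge_response(q, paste0("Answer: ", q$ref_answer))$verdict, "correct")
  expect_identical(judge_response(q, "Answer: OCC")$verdict, "correct")  # any spelling
  expect_identical(judge_response(q, "Answer: CCN")$verdict, "incorrect")

  b <- gen_nmr_question("c1ccccc1", "1d")
  expect_match(b$prompt, "7.26 (s, 6H)", fixed = TRUE)
  expect_error(gen_nmr_question("CC(C)Cc1ccc(cc1)C(C)C(=O)O", "1d"))  # >10 heavy atoms
})
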