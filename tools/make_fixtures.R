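#!/usr/bin/env Rscript
# Regenerates the packaged fixture libraries under inst/extdata/.
# Run from the package root: Rscript tools/make_fixtures.R
# Both libraries are synthetic: the drug-like set is built from aromatic
# scaffold + substituent recipes (which also yields a reference systematic
# name per molecule); the small set is a curated C/H/N/O enumeration.

suppressMessages({
  library(tibble); library(rlang); library(stringr); library(dplyr)
})
for (f in list.files("R", full.names = TRUE)) source(f)

set.seed(20260929)

# ---- drug-like library -----------------------------------------------------
scaffolds <- scaffold_table()
fg <- functional_group_library()
target <- 520L

seen <- character(0)
rows <- list()
tries <- 0L
while (length(rows) < target && tries < 50000L) {
  tries <- tries + 1L
  sc_name <- sample(names(scaffolds), 1L,
                    prob = c(benzene = .35, pyridine = .25,
                             naphthalene = .2, quinoline = .2)[names(scaffolds)])
  sc <- scaffolds[[sc_name]]
  k <- sample(2:4, 1L)
  if (length(sc$positions) < k) next
  locs <- sort(sample(as.integer(names(sc$positions)), k))
  groups <- sample(fg$name, k)
  built <- tryCatch(
    build_substituted_scaffold(sc_name, tibble(locant = locs, group = groups)),
    error = function(e) NULL)
  if (is.null(built)) next
  n_heavy <- heavy_atom_count(built$mol)
  if (n_heavy < 10L || n_heavy > 30L) next
  can <- canonical_smiles(built$mol)
  if (can %in% seen) next
  seen <- c(seen, can)
  rows[[length(rows) + 1L]] <- tibble(smiles = can, name = built$name)
}
druglike <- bind_rows(rows)
stopifnot(nrow(druglike) >= 500L)

# verify every reference name round-trips to its structure
for (i in seq_len(nrow(druglike))) {
  m <- parse_iupac_name(druglike$name[i])
  stopifnot(!is.null(m), canonical_smiles(m) == druglike$smiles[i])
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
con <- file("inst/extdata/druglike_synthetic.smi", "w")
writeLines(c(
  "# Synthetic drug-like molecule library (stand-in for a ZINC-style sample).",
  "# Polysubstituted aromatic scaffolds, 10-30 heavy atoms, organic subset.",
  "# Columns (tab-separated): canonical SMILES, reference systematic name.",
  paste(druglike$smiles, druglike$name, sep = "\t")), con)
close(con)

# ---- small C/H/N/O library -------------------------------------------------
small <- c(
  # alkanes and cycloalkanes
  "C","CC","CCC","CCCC","CC(C)C","CCCCC","CC(C)CC","CC(C)(C)C","CCCCCC",
  "CCCCCCC","C1CC1","C1CCC1","C1CCCC1","C1CCCCC1","CC1CCCCC1","C1CCCCCC1",
  # alcohols and diols
  "CO","CCO","CCCO","CC(C)O","CCCCO","CC(O)CC","CC(C)(C)O","CCCCCO","OCCO",
  "OCCCO","CC(O)CO","OCC(O)CO","C1CCCCC1O","OCC1CCCCC1","CC(C)CO","OCCCCO",
  # ethers
  "COC","CCOC","CCOCC","COCCOC","C1CCOC1","C1CCOCC1","C1COCCO1","CC1CCCO1",
  # aldehydes
  "C=O","CC=O","CCC=O","CCCC=O","CC(C)C=O","CCCCC=O","OCC=O",
  # ketones
  "CC(C)=O","CCC(C)=O","CCC(CC)=O","CCCC(C)=O","CC(=O)C(C)C","O=C1CCCCC1",
  "O=C1CCCC1","CC(=O)CC(C)C","CC(=O)CO",
  # carboxylic acids
  "OC=O","CC(O)=O","CCC(O)=O","CCCC(O)=O","CC(C)C(O)=O","CCCCC(O)=O",
  "OC(=O)CO","OC(=O)CCC(O)=O","CC(C)(C)CO",
  # esters and lactones
  "COC=O","CC(=O)OC","CC(=O)OCC","CCC(=O)OC","CCOC=O","CC(=O)OC(C)C",
  "O=C1CCCO1","O=C1CCCCO1","CCCC(=O)OC",
  # amines
  "CN","CCN","CCCN","CC(C)N","CNC","CN(C)C","CCNCC","CC(C)CN","C1CCNC1",
  "C1CCNCC1","CN1CCCCC1","C1CNCCN1","C1COCCN1","NCCN","NCCO","NCCCO",
  # amides, ureas, nitriles
  "NC=O","CC(N)=O","CC(=O)NC","CC(=O)N(C)C","CCC(N)=O","NC(N)=O","CCNC(C)=O",
  "CC#N","CCC#N","CC(C)C#N","N#CCC#N",
  # alkenes and alkynes
  "C=C","CC=C","CC=CC","CC(C)=C","C=CC=C","C=CCO","C1=CCCCC1","C1=CCCC1",
  "C#C","CC#C","CC#CC","C=CC#N","C=CC=O","CC=CC=O",
  # benzenoid aromatics
  "c1ccccc1","Cc1ccccc1","CCc1ccccc1","Cc1ccccc1C","Cc1cccc(C)c1",
  "Cc1ccc(C)cc1","Oc1ccccc1","COc1ccccc1","Nc1ccccc1","CNc1ccccc1",
  "O=Cc1ccccc1","CC(=O)c1ccccc1","OC(=O)c1ccccc1","N#Cc1ccccc1",
  "Cc1ccc(O)cc1","Cc1ccc(N)cc1","Oc1ccc(O)cc1","OCc1ccccc1","NCc1ccccc1",
  "Oc1cccc(O)c1","COc1ccc(C)cc1",
  # heteroaromatics
  "c1ccncc1","Cc1ccccn1","Cc1cccnc1","Cc1ccncc1","CCc1ccccn1","c1ccoc1",
  "Cc1ccco1","c1cc[nH]c1","Cc1ccc[nH]1","c1cnccn1","c1ccnnc1","Cc1ccnc(C)c1",
  "c1ccc2[nH]ccc2c1","c1ccc2occc2c1","O=Cc1ccco1","Cc1occc1C","Nc1ccccn1",
  "Oc1ccccn1","Cc1cnccn1"
)
mols <- lapply(small, parse_smiles)
stopifnot(all(vapply(mols, function(m) heavy_atom_count(m) <= 10L, logical(1))))
elems <- unique(unlist(lapply(mols, function(m) m$atoms$element)))
stopifnot(all(elems %in% c("C", "N", "O")))
canon <- vapply(mols, canonical_smiles, character(1))
stopifnot(!anyDuplicated(canon))
stopifnot(length(intersect(canon, druglike$smiles)) == 0L)
stopifnot(length(canon) >= 100L)

con <- file("inst/extdata/small_cnho_synthetic.smi", "w")
writeLines(c(
  "# Synthetic small-molecule library: C/H/N/O only, <= 10 heavy atoms.",
  "# Curated enumeration of common functional-group chemotypes.",
  "# One canonical SMILES per line.",
  canon), con)
close(con)

cat("druglike:", nrow(druglike), "molecules;  small:", length(canon), "molecules\n")
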