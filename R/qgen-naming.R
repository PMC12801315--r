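# SMILES-to-IUPAC question generators: drug-like sampling plus the two
# diagnostic sub-benchmarks (hexasubstituted benzenes probing functional
# group recognition, and 3-halogen scaffolds probing locant numbering).

iupac_prompt <- function(text) {
  paste0("Consider the molecule with SMILES string ", text,
         "\nWrite an IUPAC name for this molecule. Any systematic name that ",
         "denotes this exact structure is acceptable.\n", .answer_footer)
}

#' Generate a drug-like naming question
#'
#' The truth payload is the structure (canonical SMILES), never a name
#' string: an answer is correct if it parses to the intended structure.
#'
#' @param smiles Canonical SMILES of a drug-like library member.
#' @param ref_name The library's reference systematic name (used for
#'   self-scoring).
#' @param smiles_mode `"canonical"` or `"randomized"`.
#' @param seed Integer seed.
#' @return One-row question tibble.
#' @export
gen_iupac_sample_question <- function(smiles, ref_name,
                                      smiles_mode = c("canonical", "randomized"),
                                      seed = 0L) {
  smiles_mode <- match.arg(smiles_mode)
  mol <- parse_smiles(smiles)
  can <- canonical_smiles(mol)
  text <- if (smiles_mode == "canonical") can else randomized_smiles(mol, seed)$text
  question_record("iupac_zinc", iupac_prompt(text), list(smiles = can), ref_name,
                  list(seed = seed, source = can, smiles_mode = smiles_mode))
}

#' Build a hexasubstituted benzene
#'
#' Six distinct groups drawn without replacement from the 40-entry
#' functional-group library, one per ring position.
#'
#' @param seed Integer seed.
#' @param max_tries Bounded retries for (rare) incompatible draws.
#' @return List with `mol`, `name` (reference systematic name) and
#'   `groups`.
#' @export
build_hexasubstituted_benzene <- function(seed, max_tries = 20L) {
  lib <- functional_group_library()
  for (k in seq_len(max_tries)) {
    groups <- with_seed(seed + (k - 1L) * 65537L, sample(lib$name, 6L))
    built <- tryCatch(
      build_substituted_scaffold("benzene", tibble(locant = 1:6, group = groups)),
      error = function(e) NULL)
    if (!is.null(built)) return(c(built, list(groups = groups)))
  }
  abort("could not build a hexasubstituted benzene")
}

#' Build a 3-halogen locant-numbering molecule
#'
#' Three halogens (drawn with replacement from F/Cl/Br/I) on three distinct
#' substitutable positions of the scaffold. Ring nitrogens are never
#' substituted.
#'
#' @param scaffold One of `"benzene"`, `"pyridine"`, `"naphthalene"`,
#'   `"quinoline"`.
#' @param seed Integer seed.
#' @return List with `mol`, `name` and `placements`.
#' @export
build_halogen_locant_molecule <- function(scaffold, seed) {
  sc <- scaffold_table()[[scaffold]]
  if (is.null(sc)) abort(paste0("unknown scaffold '", scaffold, "'"))
  halogens <- c("fluoro", "chloro", "bromo", "iodo")
  pl <- with_seed(seed, tibble(
    locant = sort(sample(as.integer(names(sc$positions)), 3L)),
    group = sample(halogens, 3L, replace = TRUE)))
  built <- build_substituted_scaffold(scaffold, pl)
  c(built, list(placements = pl))
}

#' Generate a functional-group naming question
#'
#' @param seed Integer seed.
#' @return One-row question tibble (category `iupac_fg`).
#' @export
gen_iupac_fg_question <- function(seed = 0L) {
  b <- build_hexasubstituted_benzene(seed)
  can <- canonical_smiles(b$mol)
  question_record("iupac_fg", iupac_prompt(can), list(smiles = can), b$name,
                  list(seed = seed, source = can, smiles_mode = "canonical",
                       groups = b$groups))
}

#' Generate a locant-numbering naming question
#'
#' @param scaffold Scaffold name (see [build_halogen_locant_molecule()]).
#' @param seed Integer seed.
#' @return One-row question tibble (category `iupac_locant`).
#' @export
gen_iupac_locant_question <- function(scaffold, seed = 0L) {
  b <- build_halogen_locant_molecule(scaffold, seed)
  can <- canonical_smiles(b$mol)
  question_record("iupac_locant", iupac_prompt(can), list(smiles = can), b$name,
                  list(seed = seed, source = can, smiles_mode = "canonical",
                       scaffold = scaffold))
}
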