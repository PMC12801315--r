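# Molecular-interpretation question generators: carbon counting, ring
# counting, shortest bond path between two marked positions, and atom
# mapping between two SMILES representations.

#' Generate a counting question (carbons or rings)
#'
#' @param mol A `molecule` or SMILES string (drug-like pool).
#' @param kind `"carbon"` or `"ring"`.
#' @param seed Integer seed recorded in the metadata.
#' @return One-row question tibble.
#' @export
gen_count_question <- function(mol, kind = c("carbon", "ring"), seed = 0L) {
  kind <- match.arg(kind)
  if (is.character(mol)) mol <- parse_smiles(mol)
  smi <- canonical_smiles(mol)
  if (kind == "carbon") {
    truth <- element_count(mol, "C")
    prompt <- paste0("Consider the molecule with SMILES string ", smi,
                     "\nHow many carbon atoms does this molecule contain?\n",
                     .answer_footer)
    cat_name <- "carbon_count"
  } else {
    truth <- cycle_rank(mol)
    if (truth > 6L) abort("ring-count pool is limited to molecules with at most six rings")
    prompt <- paste0("Consider the molecule with SMILES string ", smi,
                     "\nHow many rings does this molecule contain?\n",
                     .answer_footer)
    cat_name <- "ring_count"
  }
  question_record(cat_name, prompt, list(value = truth), truth,
                  list(seed = seed, source = smi, smiles_mode = "canonical"))
}

#' Generate a shortest-path question
#'
#' Two distinct hydrogen-bearing positions are chosen at random and marked
#' with wildcard dummy atoms; the task is the number of bonds on the
#' shortest path between the two dummy atoms (which includes both
#' attachment bonds).
#'
#' @param mol A `molecule` or SMILES string.
#' @param smiles_mode `"canonical"` or `"randomized"` rendering of the
#'   marked molecule.
#' @param seed Integer seed controlling position choice and randomization.
#' @return One-row question tibble.
#' @export
gen_shortest_path_question <- function(mol, smiles_mode = c("canonical", "randomized"),
                                       seed = 0L) {
  smiles_mode <- match.arg(smiles_mode)
  if (is.character(mol)) mol <- parse_smiles(mol)
  eligible <- which(mol$atoms$hcount >= 1L & !mol$atoms$dummy)
  if (length(eligible) < 2L) abort("molecule has fewer than two substitutable positions")
  marked <- with_seed(seed, {
    for (try in 1:50) {
      pick <- sample(eligible, 2L)
      m1 <- tryCatch(attach_dummy(mol, pick[1]), error = function(e) NULL)
      if (is.null(m1)) next
      m2 <- tryCatch(attach_dummy(m1$mol, pick[2]), error = function(e) NULL)
      if (is.null(m2)) next
      break
    }
    if (is.null(m2)) abort("could not mark two positions")
    list(mol = m2$mol, d1 = m1$dummy_id, d2 = m2$dummy_id)
  })
  truth <- graph_distance(marked$mol, marked$d1, marked$d2)
  text <- if (smiles_mode == "canonical") canonical_smiles(marked$mol)
          else randomized_smiles(marked$mol, seed + 1L)$text
  prompt <- paste0(
    "Consider the molecule with SMILES string ", text,
    "\nThe two atoms written as * are dummy atoms marking two positions.",
    "\nHow many bonds are on the shortest path between the two dummy atoms?",
    "\n", .answer_footer)
  question_record("shortest_path", prompt, list(value = truth), truth,
                  list(seed = seed, source = canonical_smiles(mol),
                       marked = canonical_smiles(marked$mol), smiles_mode = smiles_mode))
}

#' Generate an atom-mapping question
#'
#' The molecule is written as two different SMILES strings; the task is to
#' map heavy-atom positions (1-based order of appearance in the string,
#' hydrogens excluded) from the first string to the second. Any mapping
#' equal to the reference composed with a graph automorphism is correct.
#'
#' @param mol A `molecule` or SMILES string, 8-24 heavy atoms.
#' @param variant_mode `"randomized"` (both strings fully randomized) or
#'   `"semicanonical"` (random root, canonical traversal).
#' @param seed Integer seed.
#' @return One-row question tibble.
#' @export
gen_atom_mapping_question <- function(mol, variant_mode = c("randomized", "semicanonical"),
                                      seed = 0L) {
  variant_mode <- match.arg(variant_mode)
  if (is.character(mol)) mol <- parse_smiles(mol)
  n <- heavy_atom_count(mol)
  if (n < 8L || n > 24L) abort("atom-mapping pool uses molecules with 8-24 heavy atoms")
  gen <- function(s) switch(variant_mode,
                            randomized = randomized_smiles(mol, s),
                            semicanonical = semicanonical_smiles(mol, s))
  va <- gen(seed)
  vb <- gen(seed + 7919L)
  bump <- 0L
  while (identical(va$text, vb$text) && bump < 50L) {
    bump <- bump + 1L
    vb <- gen(seed + 7919L + bump)
  }
  map <- match(va$order_map, vb$order_map)
  ref <- paste(sprintf("%d->%d", seq_along(map), map), collapse = ", ")
  prompt <- paste0(
    "The following two SMILES strings represent the same molecule:\n",
    "String A: ", va$text, "\nString B: ", vb$text, "\n",
    "Number the heavy atoms of each string 1, 2, 3, ... in their order of ",
    "appearance (hydrogens are not counted). ",
    "Map every atom position of string A to the corresponding atom position ",
    "of string B.\nWrite the mapping as comma-separated pairs, e.g. ",
    "\"1->2, 2->1, ...\".\n", .answer_footer)
  question_record("atom_map", prompt,
                  list(map = as.integer(map),
                       source = canonical_smiles(mol),
                       a_text = va$text, b_text = vb$text,
                       a_order = as.integer(va$order_map),
                       b_order = as.integer(vb$order_map)),
                  ref,
                  list(seed = seed, source = canonical_smiles(mol),
                       smiles_mode = variant_mode, n_atoms = n))
}
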