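# Reaction-prediction questions. Nine undergraduate reaction classes, each
# defined by a template: a pool of admissible reactants (decorated cores)
# and a graph rewrite producing exactly one sanitizable product. Reagents
# and conditions appear as plain text in the prompt; only the reactant
# SMILES are to be transformed.

element_tally <- function(mol) {
  at <- mol$atoms[!mol$atoms$dummy, ]
  tab <- table(at$element)
  setNames(as.integer(tab), names(tab))
}

tally_minus <- function(a, b) {
  keys <- as.character(unique(c(names(a), names(b))))
  out <- setNames(integer(length(keys)), keys)
  if (length(a)) out[names(a)] <- a
  if (length(b)) out[names(b)] <- out[names(b)] - b
  out[out != 0L]
}

find_atoms <- function(mol, element, charge = NULL, hcount = NULL) {
  idx <- which(mol$atoms$element == element & !mol$atoms$dummy)
  if (!is.null(charge)) idx <- idx[mol$atoms$charge[idx] == charge]
  if (!is.null(hcount)) idx <- idx[mol$atoms$hcount[idx] %in% hcount]
  idx
}

# Exactly-one guard: reactant pools are built so each rewrite site is
# unique; a violation is a template bug, not a chemistry outcome.
the_one <- function(x, what) {
  if (length(x) != 1L) abort(paste0("expected exactly one ", what, ", found ", length(x)),
                             class = "chemquiz_template_error")
  x
}

append_bond <- function(mol, u, v, order = "1") {
  mol$bonds <- dplyr::bind_rows(mol$bonds, tibble(a = u, b = v, order = order))
  mol
}

combine_all <- function(mols) {
  out <- mols[[1]]
  for (m in mols[-1]) out <- mol_combine(out, m)$mol
  out
}

carbonyl_carbons <- function(mol) {
  Filter(function(a) is_carbonyl_c(mol, a), find_atoms(mol, "C"))
}

# ---- rewrites --------------------------------------------------------------

rw_sn2 <- function(mol) {
  br <- the_one(find_atoms(mol, "Br"), "bromide")
  c1 <- atom_neighbors(mol, br)[1]
  rm <- remove_atoms(mol, br, restore_h = FALSE)
  c1 <- rm$idmap[c1]
  cmb <- mol_combine(rm$mol, parse_smiles("O"))
  mol2 <- cmb$mol
  o <- cmb$offset + 1L
  mol2$atoms$hcount[o] <- mol2$atoms$hcount[o] - 1L
  sanitize_molecule(append_bond(mol2, c1, o))
}

rw_click <- function(mol) {
  n3 <- the_one(find_atoms(mol, "N", charge = -1L), "terminal azide nitrogen")
  n2 <- the_one(atom_neighbors(mol, n3), "central azide nitrogen")
  n1 <- the_one(setdiff(atom_neighbors(mol, n2), n3), "substituted azide nitrogen")
  triples <- which(mol$bonds$order == "3")
  tr <- the_one(triples[mol$atoms$element[mol$bonds$a[triples]] == "C" &
                          mol$atoms$element[mol$bonds$b[triples]] == "C"], "alkyne")
  ends <- c(mol$bonds$a[tr], mol$bonds$b[tr])
  ct <- the_one(ends[mol$atoms$hcount[ends] == 1L], "terminal alkyne carbon")
  ci <- setdiff(ends, ct)
  mol$atoms$charge[c(n2, n3)] <- 0L
  ring <- c(n1, n2, n3, ci, ct)
  mol$atoms$aromatic[ring] <- TRUE
  set_ord <- function(m, u, v, o) {
    hit <- which((m$bonds$a == u & m$bonds$b == v) | (m$bonds$a == v & m$bonds$b == u))
    m$bonds$order[hit] <- o
    m
  }
  mol <- set_ord(mol, n1, n2, "ar")
  mol <- set_ord(mol, n2, n3, "ar")
  mol <- set_ord(mol, ci, ct, "ar")
  mol <- append_bond(mol, n3, ci, "ar")   # N3-C4 bond: 1,4-regiochemistry
  mol <- append_bond(mol, ct, n1, "ar")
  sanitize_molecule(mol)
}

rw_simmons_smith <- function(mol) {
  dbl <- which(mol$bonds$order == "2" &
                 mol$atoms$element[mol$bonds$a] == "C" &
                 mol$atoms$element[mol$bonds$b] == "C" &
                 !mol$atoms$aromatic[mol$bonds$a])
  dbl <- the_one(dbl, "alkene")
  u <- mol$bonds$a[dbl]; v <- mol$bonds$b[dbl]
  mol$bonds$order[dbl] <- "1"
  cmb <- mol_combine(mol, parse_smiles("C"))
  mol2 <- cmb$mol
  ch2 <- cmb$offset + 1L
  mol2$atoms$hcount[ch2] <- 2L
  mol2 <- append_bond(mol2, u, ch2)
  mol2 <- append_bond(mol2, v, ch2)
  sanitize_molecule(mol2)
}

rw_suzuki <- function(mol) {
  br <- the_one(find_atoms(mol, "Br"), "aryl bromide")
  c1 <- atom_neighbors(mol, br)[1]
  b <- the_one(find_atoms(mol, "B"), "boronic acid boron")
  b_nb <- atom_neighbors(mol, b)
  oxy <- b_nb[mol$atoms$element[b_nb] == "O"]
  c2 <- the_one(setdiff(b_nb, oxy), "boron-bearing carbon")
  rm <- remove_atoms(mol, c(br, b, oxy), restore_h = FALSE)
  sanitize_molecule(append_bond(rm$mol, rm$idmap[c1], rm$idmap[c2]))
}

rw_amide <- function(mol) {
  cl <- the_one(find_atoms(mol, "Cl"), "acid chloride")
  cc <- atom_neighbors(mol, cl)[1]
  n <- the_one(find_atoms(mol, "N", hcount = 2L), "primary amine nitrogen")
  rm <- remove_atoms(mol, cl, restore_h = FALSE)
  mol2 <- rm$mol
  n <- rm$idmap[n]
  mol2$atoms$hcount[n] <- mol2$atoms$hcount[n] - 1L
  sanitize_molecule(append_bond(mol2, rm$idmap[cc], n))
}

rw_reductive_amination <- function(mol) {
  o_dbl <- which(mol$bonds$order == "2" &
                   ((mol$atoms$element[mol$bonds$a] == "O") |
                      (mol$atoms$element[mol$bonds$b] == "O")))
  o_dbl <- the_one(o_dbl, "carbonyl")
  o <- if (mol$atoms$element[mol$bonds$a[o_dbl]] == "O") mol$bonds$a[o_dbl] else mol$bonds$b[o_dbl]
  cc <- setdiff(c(mol$bonds$a[o_dbl], mol$bonds$b[o_dbl]), o)
  n <- the_one(find_atoms(mol, "N", hcount = 2L), "primary amine nitrogen")
  rm <- remove_atoms(mol, o, restore_h = FALSE)
  mol2 <- rm$mol
  cc <- rm$idmap[cc]; n <- rm$idmap[n]
  mol2$atoms$hcount[cc] <- mol2$atoms$hcount[cc] + 1L
  mol2$atoms$hcount[n] <- mol2$atoms$hcount[n] - 1L
  sanitize_molecule(append_bond(mol2, cc, n))
}

rw_fischer <- function(mol) {
  acid_c <- Filter(function(a) {
    nb <- neighbor_profile(mol, a)
    any(nb$elements == "O" & nb$orders == "2") &&
      any(nb$elements == "O" & nb$orders == "1" & mol$atoms$hcount[nb$ids] == 1L)
  }, find_atoms(mol, "C"))
  acid_c <- the_one(acid_c, "carboxylic acid carbon")
  nb <- neighbor_profile(mol, acid_c)
  oh <- nb$ids[nb$elements == "O" & nb$orders == "1"][1]
  alc_o <- Filter(function(o) {
    cn <- atom_neighbors(mol, o)
    length(cn) == 1L && mol$atoms$element[cn] == "C" && cn != acid_c &&
      !is_carbonyl_c(mol, cn)
  }, find_atoms(mol, "O", hcount = 1L))
  alc_o <- the_one(setdiff(alc_o, oh), "alcohol oxygen")
  rm <- remove_atoms(mol, oh, restore_h = FALSE)
  mol2 <- rm$mol
  alc_o <- rm$idmap[alc_o]
  mol2$atoms$hcount[alc_o] <- mol2$atoms$hcount[alc_o] - 1L
  sanitize_molecule(append_bond(mol2, rm$idmap[acid_c], alc_o))
}

rw_grignard <- function(mol) {
  mg <- the_one(find_atoms(mol, "Mg"), "magnesium")
  mg_nb <- atom_neighbors(mol, mg)
  rC <- the_one(mg_nb[mol$atoms$element[mg_nb] == "C"], "Grignard carbon")
  brs <- mg_nb[mol$atoms$element[mg_nb] == "Br"]
  o_dbl <- which(mol$bonds$order == "2" &
                   ((mol$atoms$element[mol$bonds$a] == "O") |
                      (mol$atoms$element[mol$bonds$b] == "O")))
  o_dbl <- the_one(o_dbl, "carbonyl")
  o <- if (mol$atoms$element[mol$bonds$a[o_dbl]] == "O") mol$bonds$a[o_dbl] else mol$bonds$b[o_dbl]
  cc <- setdiff(c(mol$bonds$a[o_dbl], mol$bonds$b[o_dbl]), o)
  mol$bonds$order[o_dbl] <- "1"
  mol$atoms$hcount[o] <- mol$atoms$hcount[o] + 1L
  rm <- remove_atoms(mol, c(mg, brs), restore_h = FALSE)
  sanitize_molecule(append_bond(rm$mol, rm$idmap[cc], rm$idmap[rC]))
}

rw_wittig <- function(mol) {
  p <- the_one(find_atoms(mol, "P"), "phosphorus")
  yl_bond <- which((mol$bonds$a == p | mol$bonds$b == p) & mol$bonds$order == "2")
  yl_bond <- the_one(yl_bond, "ylide double bond")
  yC <- setdiff(c(mol$bonds$a[yl_bond], mol$bonds$b[yl_bond]), p)
  o_dbl <- which(mol$bonds$order == "2" &
                   ((mol$atoms$element[mol$bonds$a] == "O") |
                      (mol$atoms$element[mol$bonds$b] == "O")))
  o_dbl <- the_one(o_dbl, "carbonyl")
  o <- if (mol$atoms$element[mol$bonds$a[o_dbl]] == "O") mol$bonds$a[o_dbl] else mol$bonds$b[o_dbl]
  cc <- setdiff(c(mol$bonds$a[o_dbl], mol$bonds$b[o_dbl]), o)
  # phosphine side = everything reachable from P without crossing the ylide bond
  g <- mol_graph(mol)
  g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(p, yC)))
  memb <- igraph::components(g)$membership
  p_side <- which(memb == memb[p])
  rm <- remove_atoms(mol, c(p_side, o), restore_h = FALSE)
  sanitize_molecule(append_bond(rm$mol, rm$idmap[cc], rm$idmap[yC], "2"))
}

# ---- template set ----------------------------------------------------------

template_def <- function(class, name, conditions, pools, rewrite, lost, gained) {
  structure(list(class = class, name = name, conditions = conditions,
                 pools = pools, rewrite = rewrite, lost = lost, gained = gained),
            class = "chemquiz_reaction_template")
}

#' @export
print.chemquiz_reaction_template <- function(x, ...) {
  cat("<reaction template> ", x$class, ": ", x$name, "\n", sep = "")
  invisible(x)
}

.ph <- "c1ccccc1"

#' The nine reaction-class templates
#'
#' SN2 hydroxide substitution, copper-catalyzed azide-alkyne cycloaddition,
#' Simmons-Smith cyclopropanation, Suzuki-Miyaura coupling, amide bond
#' formation from an acid chloride, reductive amination, Fischer
#' esterification, Grignard addition to a ketone, and Wittig olefination.
#' Each template carries reactant pools, plain-text conditions, a graph
#' rewrite producing a single product, and its heavy-atom balance sheet
#' (atoms lost to leaving groups, atoms gained from reagents).
#'
#' @return Named list of nine `chemquiz_reaction_template` objects.
#' @export
reaction_template_set <- function() {
  list(
    sn2 = template_def(
      "sn2", "SN2 substitution of bromide by hydroxide",
      "NaOH, water/DMSO, heat",
      list(c("CCBr", "CCCBr", "CCCCBr", "CCCCCBr", "CC(C)CBr", "CC(C)CCBr",
             "C1CCCCC1CBr", "Cc1ccccc1CBr", "c1ccccc1CCBr")),
      rw_sn2, lost = c(Br = 1L), gained = c(O = 1L)),
    click = template_def(
      "click", "copper-catalyzed azide-alkyne cycloaddition",
      "CuSO4, sodium ascorbate, tBuOH/H2O",
      list(c("C(c1ccccc1)N=[N+]=[N-]", "CCCN=[N+]=[N-]", "CCN=[N+]=[N-]",
             "CC(C)CN=[N+]=[N-]", "CCCCN=[N+]=[N-]"),
           c("C#Cc1ccccc1", "C#CCCC", "C#CCO", "C#Cc1ccc(C)cc1", "C#CCOC")),
      rw_click, lost = integer(0), gained = integer(0)),
    simmons_smith = template_def(
      "simmons_smith", "Simmons-Smith cyclopropanation",
      "CH2I2, Zn(Cu) couple, Et2O",
      list(c("C=Cc1ccccc1", "CC=CC", "C=CCCCC", "C1=CCCCC1", "CC(C)=C",
             "CC=Cc1ccccc1", "CCC=CC")),
      rw_simmons_smith, lost = integer(0), gained = c(C = 1L)),
    suzuki = template_def(
      "suzuki", "Suzuki-Miyaura cross-coupling",
      "Pd(PPh3)4, K2CO3, dioxane/H2O",
      list(c("Brc1ccccc1", "Brc1ccc(C)cc1", "Brc1ccc(OC)cc1", "Brc1ccc(F)cc1",
             "Brc1ccccn1"),
           c("OB(O)c1ccccc1", "OB(O)c1ccc(C)cc1", "OB(O)c1ccc(OC)cc1",
             "OB(O)c1ccc(F)cc1")),
      rw_suzuki, lost = c(Br = 1L, B = 1L, O = 2L), gained = integer(0)),
    amide = template_def(
      "amide", "amide bond formation from an acid chloride",
      "Et3N, CH2Cl2, 0 C to rt",
      list(c("CC(=O)Cl", "CCC(=O)Cl", "CC(C)C(=O)Cl", "c1ccccc1C(=O)Cl",
             "CCCC(=O)Cl"),
           c("CN", "CCN", "CC(C)N", "NCc1ccccc1", "NC1CCCCC1")),
      rw_amide, lost = c(Cl = 1L), gained = integer(0)),
    reductive_amination = template_def(
      "reductive_amination", "reductive amination of a ketone or aldehyde",
      "NaBH3CN, MeOH, AcOH (cat.)",
      list(c("CC(C)=O", "CCC(C)=O", "CC(=O)c1ccccc1", "CCC=O", "CCCC=O",
             "O=C1CCCCC1"),
           c("CN", "CCN", "CC(C)N", "NCc1ccccc1", "NC1CCCCC1")),
      rw_reductive_amination, lost = c(O = 1L), gained = integer(0)),
    fischer = template_def(
      "fischer", "Fischer esterification",
      "H2SO4 (cat.), reflux",
      list(c("CC(=O)O", "CCC(=O)O", "CC(C)C(=O)O", "c1ccccc1C(=O)O", "CCCC(=O)O"),
           c("CO", "CCO", "CC(C)O", "OCc1ccccc1", "CCCO")),
      rw_fischer, lost = c(O = 1L), gained = integer(0)),
    grignard = template_def(
      "grignard", "Grignard addition to a ketone",
      "1) Et2O, 0 C; 2) aqueous NH4Cl workup",
      list(c("CC(C)=O", "CCC(C)=O", "CC(=O)c1ccccc1", "O=C1CCCCC1", "CCC(CC)=O"),
           c("C[Mg]Br", "CC[Mg]Br", "CCC[Mg]Br", "c1ccccc1[Mg]Br")),
      rw_grignard, lost = c(Mg = 1L, Br = 1L), gained = integer(0)),
    wittig = template_def(
      "wittig", "Wittig olefination",
      "THF, -78 C to rt",
      list(c("CCC=O", "CCCC=O", "CC(C)=O", "CCC(C)=O", "c1ccccc1C=O"),
           c(paste0("C=P(", .ph, ")(", .ph, ")", .ph),
             paste0("CC=P(", .ph, ")(", .ph, ")", .ph),
             paste0("CCC=P(", .ph, ")(", .ph, ")", .ph))),
      rw_wittig, lost = c(P = 1L, C = 18L, O = 1L), gained = integer(0))
  )
}

sample_reactants <- function(template, seed) {
  with_seed(seed, lapply(template$pools, function(p) sample(p, 1L)))
}

#' Generate a reaction-prediction question
#'
#' @param template A `chemquiz_reaction_template` (one of
#'   [reaction_template_set()]).
#' @param smiles_mode `"canonical"` or `"randomized"` rendering of the
#'   reactants.
#' @param seed Integer seed.
#' @param reactants Optional list of reactant SMILES overriding the seeded
#'   draw (used to keep canonical/randomized pairs on identical reactions).
#' @return One-row question tibble (category `reaction`).
#' @export
gen_reaction_question <- function(template, smiles_mode = c("canonical", "randomized"),
                                  seed = 0L, reactants = NULL) {
  smiles_mode <- match.arg(smiles_mode)
  if (is.null(reactants)) reactants <- sample_reactants(template, seed)
  mols <- lapply(reactants, function(s) if (is_molecule(s)) s else parse_smiles(s))
  combined <- combine_all(mols)
  product <- template$rewrite(combined)
  truth <- canonical_smiles(product)
  text <- if (smiles_mode == "canonical") canonical_smiles(combined)
          else randomized_smiles(combined, seed + 13L)$text
  prompt <- paste0(
    "Reactant(s): ", text, "\n",
    "Reagents and conditions: ", template$conditions, "\n",
    "Write the SMILES string of the major organic product.\n", .answer_footer)
  question_record("reaction", prompt,
                  list(smiles = truth, class = template$class),
                  truth,
                  list(seed = seed, source = canonical_smiles(combined),
                       smiles_mode = smiles_mode, reaction_class = template$class,
                       reactants = vapply(mols, canonical_smiles, character(1))))
}
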