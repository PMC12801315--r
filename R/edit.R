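# Graph-editing primitives used by the question generators: fragment
# attachment (substituent placement, dummy-atom marking) and the atom/bond
# rewrites behind the reaction templates.

#' Combine two molecules into one multi-fragment molecule
#'
#' @param mol1,mol2 `molecule` objects.
#' @return List with `mol` (combined, unsanitized connectivity is untouched
#'   so it remains valid) and `offset` (id shift applied to `mol2` atoms).
#' @export
mol_combine <- function(mol1, mol2) {
  off <- nrow(mol1$atoms)
  atoms <- dplyr::bind_rows(mol1$atoms, mol2$atoms)
  atoms$id <- seq_len(nrow(atoms))
  b2 <- mol2$bonds
  b2$a <- b2$a + off
  b2$b <- b2$b + off
  mol <- structure(list(atoms = atoms, bonds = dplyr::bind_rows(mol1$bonds, b2)),
                   class = "molecule")
  list(mol = mol, offset = off)
}

# Add a bond consuming one implicit hydrogen on each end (the usual
# substitution semantics). Errors if either atom has no hydrogen to give.
add_bond_h <- function(mol, u, v, order = "1") {
  for (w in c(u, v)) {
    if (!mol$atoms$dummy[w]) {
      need <- c(`1` = 1L, `2` = 2L, `3` = 3L)[[order]]
      if (mol$atoms$hcount[w] < need)
        abort(sprintf("atom %d has no free valence for attachment", w),
              class = "chemquiz_edit_error")
      mol$atoms$hcount[w] <- mol$atoms$hcount[w] - need
    }
  }
  mol$bonds <- dplyr::bind_rows(mol$bonds, tibble(a = u, b = v, order = order))
  sanitize_molecule(mol)
}

#' Attach a substituent fragment to an atom
#'
#' The fragment's first atom is its attachment point; a single bond is made
#' to `atom_id`, consuming one implicit hydrogen on each side.
#'
#' @param mol Parent `molecule`.
#' @param atom_id Atom of `mol` to substitute (must carry at least one H).
#' @param fragment A `molecule` or SMILES string whose atom 1 is the
#'   attachment point.
#' @return The substituted `molecule`.
#' @export
attach_fragment <- function(mol, atom_id, fragment) {
  if (is.character(fragment)) fragment <- parse_smiles(fragment)
  cmb <- mol_combine(mol, fragment)
  add_bond_h(cmb$mol, atom_id, cmb$offset + 1L)
}

#' Attach a wildcard dummy atom to mark a position
#'
#' @param mol A `molecule`.
#' @param atom_id Atom to mark; one implicit hydrogen is consumed.
#' @return List with `mol` and `dummy_id` (the id of the new `*` atom).
#' @export
attach_dummy <- function(mol, atom_id) {
  if (mol$atoms$hcount[atom_id] < 1L)
    abort("no free valence for a dummy atom", class = "chemquiz_edit_error")
  dummy <- structure(list(
    atoms = tibble(element = "*", charge = 0L, aromatic = FALSE, hcount = 0L,
                   dummy = TRUE, id = 1L),
    bonds = tibble(a = integer(0), b = integer(0), order = character(0))),
    class = "molecule")
  cmb <- mol_combine(mol, dummy)
  mol2 <- cmb$mol
  mol2$atoms$hcount[atom_id] <- mol2$atoms$hcount[atom_id] - 1L
  mol2$bonds <- dplyr::bind_rows(mol2$bonds, tibble(a = atom_id, b = cmb$offset + 1L, order = "1"))
  list(mol = sanitize_molecule(mol2), dummy_id = cmb$offset + 1L)
}

# Remove atoms (and incident bonds), restoring one implicit hydrogen per
# removed single bond on the surviving partner. Ids are renumbered; the
# returned map gives new id for each old id (NA for removed atoms).
remove_atoms <- function(mol, ids, restore_h = TRUE) {
  keep <- setdiff(seq_len(nrow(mol$atoms)), ids)
  if (restore_h) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[i]; b <- mol$bonds$b[i]
      gone_a <- a %in% ids; gone_b <- b %in% ids
      if (xor(gone_a, gone_b)) {
        surv <- if (gone_a) b else a
        if (!mol$atoms$dummy[surv]) {
          w <- c(`1` = 1L, `2` = 2L, `3` = 3L, ar = 1L)[[mol$bonds$order[i]]]
          mol$atoms$hcount[surv] <- mol$atoms$hcount[surv] + w
        }
      }
    }
  }
  idmap <- rep(NA_integer_, nrow(mol$atoms))
  idmap[keep] <- seq_along(keep)
  bonds <- mol$bonds[!(mol$bonds$a %in% ids) & !(mol$bonds$b %in% ids), ]
  bonds$a <- idmap[bonds$a]
  bonds$b <- idmap[bonds$b]
  atoms <- mol$atoms[keep, ]
  atoms$id <- seq_len(nrow(atoms))
  list(mol = structure(list(atoms = atoms, bonds = bonds), class = "molecule"),
       idmap = idmap)
}

set_bond_order <- function(mol, u, v, order) {
  hit <- which((mol$bonds$a == u & mol$bonds$b == v) | (mol$bonds$a == v & mol$bonds$b == u))
  if (length(hit) != 1L) abort("no such bond", class = "chemquiz_edit_error")
  old <- mol$bonds$order[hit]
  mol$bonds$order[hit] <- order
  ord_num <- c(`1` = 1L, `2` = 2L, `3` = 3L)
  delta <- ord_num[[order]] - ord_num[[old]]
  # compensate with hydrogens so valences stay legal
  for (w in c(u, v)) if (!mol$atoms$dummy[w])
    mol$atoms$hcount[w] <- mol$atoms$hcount[w] - delta
  if (any(mol$atoms$hcount < 0L)) abort("bond-order change exceeds valence",
                                        class = "chemquiz_edit_error")
  sanitize_molecule(mol)
}

# Connected fragments of a multi-fragment molecule, as separate molecules
# in membership order. Returns a list of molecule objects.
split_fragments <- function(mol) {
  comp <- igraph::components(mol_graph(mol))$membership
  lapply(seq_len(max(comp)), function(ci) {
    remove_atoms(mol, which(comp != ci), restore_h = FALSE)$mol
  })
}
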