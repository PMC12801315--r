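#' @importFrom stringr str_detect str_match str_replace_all str_trim
NULL

.aromatic_ok <- c("b", "c", "n", "o", "p", "s")

parse_error <- function(msg, text = NULL) {
  abort(paste0("SMILES parse error: ", msg, if (!is.null(text)) paste0(" in '", text, "'")),
        class = "chemquiz_parse_error")
}

# Parse one bracket atom body (without the enclosing []). Stereo marks and
# isotopes are accepted and discarded; the benchmark carries no stereo truth.
parse_bracket_atom <- function(body, text) {
  m <- regmatches(body, regexec(
    "^([0-9]+)?([A-Z][a-z]?|[a-z]|\\*)(@@|@)?(H[0-9]*)?(\\+[0-9]+|-[0-9]+|\\++|-+)?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0L) parse_error(paste0("bad bracket atom [", body, "]"), text)
  sym <- m[3]
  aromatic <- sym %in% .aromatic_ok
  element <- if (sym == "*") "*" else paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  hpart <- m[5]
  hcount <- if (hpart == "") 0L else if (hpart == "H") 1L else as.integer(substring(hpart, 2))
  cpart <- m[6]
  charge <- 0L
  if (cpart != "") {
    if (grepl("^[+-][0-9]+$", cpart)) {
      charge <- as.integer(cpart)
    } else {
      charge <- nchar(cpart) * if (substr(cpart, 1, 1) == "+") 1L else -1L
    }
  }
  list(element = element, charge = charge, aromatic = aromatic,
       hcount = hcount, dummy = sym == "*", explicit_h = TRUE)
}

#' Parse a SMILES string into a molecule
#'
#' Supports the organic subset, bracket atoms with charges and explicit
#' hydrogen counts, aromatic (lowercase) notation, ring-bond closures
#' (including `%nn`), branches, multi-fragment input via `.`, and wildcard
#' dummy atoms `*`. Stereochemistry annotations (`/`, `\`, `@`) are accepted
#' and stripped. Aromaticity written in Kekule form is perceived for 5- and
#' 6-membered rings by an electron-counting rule; implicit hydrogens are
#' assigned from default valences and the result is sanitized.
#'
#' @param text A SMILES string.
#' @return A `molecule` object.
#' @export
#' @examples
#' parse_smiles("CCO")
#' molecular_formula(parse_smiles("c1ccccc1"))
parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(str_trim(text)))
    parse_error("empty input")
  s <- str_trim(text)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  atoms <- list()
  bonds <- list()
  prev <- NA_integer_          # last atom written in current chain
  pending <- NA_character_     # bond symbol awaiting its atom
  stack <- integer(0)          # branch stack of atom indices
  ring_open <- list()          # closure number -> list(atom, order)

  add_atom <- function(at) {
    atoms[[length(atoms) + 1L]] <<- at
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- if (is.na(pending)) "default" else pending
      bonds[[length(bonds) + 1L]] <<- list(a = prev, b = idx, order = ord)
    } else if (!is.na(pending)) {
      parse_error("bond symbol without preceding atom", s)
    }
    pending <<- NA_character_
    prev <<- idx
  }

  close_ring <- function(num) {
    key <- as.character(num)
    if (is.na(prev)) parse_error("ring closure before any atom", s)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = prev, order = pending)
    } else {
      op <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      if (op$atom == prev) parse_error("ring closure to the same atom", s)
      ord <- if (!is.na(pending)) pending else if (!is.na(op$order)) op$order else "default"
      if (!is.na(pending) && !is.na(op$order) && pending != op$order)
        parse_error("conflicting ring-closure bond orders", s)
      bonds[[length(bonds) + 1L]] <<- list(a = op$atom, b = prev, order = ord)
    }
    pending <<- NA_character_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      add_atom(list(element = two, charge = 0L, aromatic = FALSE, hcount = NA_integer_,
                    dummy = FALSE, explicit_h = FALSE))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(list(element = ch, charge = 0L, aromatic = FALSE, hcount = NA_integer_,
                    dummy = FALSE, explicit_h = FALSE))
      i <- i + 1L
    } else if (ch %in% .aromatic_ok) {
      add_atom(list(element = toupper(ch), charge = 0L, aromatic = TRUE,
                    hcount = NA_integer_, dummy = FALSE, explicit_h = FALSE))
      i <- i + 1L
    } else if (ch == "*") {
      add_atom(list(element = "*", charge = 0L, aromatic = FALSE, hcount = 0L,
                    dummy = TRUE, explicit_h = TRUE))
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) parse_error("unclosed bracket atom", s)
      add_atom(parse_bracket_atom(paste0(chars[(i + 1L):(j - 1L)], collapse = ""), s))
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.na(pending)) parse_error("two consecutive bond symbols", s)
      pending <- switch(ch, "-" = "1", "=" = "2", "#" = "3", ":" = "ar", "/" = "1", "\\" = "1")
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) parse_error("branch before any atom", s)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) parse_error("unmatched ')'", s)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        parse_error("'%' must be followed by two digits", s)
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      if (!is.na(pending)) parse_error("bond symbol before '.'", s)
      i <- i + 1L
    } else {
      parse_error(paste0("unexpected character '", ch, "'"), s)
    }
  }
  if (length(stack) > 0L) parse_error("unclosed branch", s)
  if (length(ring_open) > 0L) parse_error("unclosed ring bond", s)
  if (!is.na(pending)) parse_error("dangling bond symbol", s)
  if (length(atoms) == 0L) parse_error("no atoms", s)

  atoms_df <- tibble(
    element  = vapply(atoms, `[[`, character(1), "element"),
    charge   = vapply(atoms, `[[`, integer(1), "charge"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    hcount   = vapply(atoms, `[[`, integer(1), "hcount"),
    dummy    = vapply(atoms, `[[`, logical(1), "dummy"),
    explicit_h = vapply(atoms, `[[`, logical(1), "explicit_h")
  )
  bonds_df <- if (length(bonds)) tibble(
    a = vapply(bonds, `[[`, integer(1), "a"),
    b = vapply(bonds, `[[`, integer(1), "b"),
    order = vapply(bonds, `[[`, character(1), "order")
  ) else tibble(a = integer(0), b = integer(0), order = character(0))

  finalize_molecule(atoms_df, bonds_df, s)
}

# Shared post-processing: default-bond resolution, implicit hydrogens,
# Kekule aromatization, sanitization.
finalize_molecule <- function(atoms_df, bonds_df, text) {
  in_cycle <- cycle_edge_flags(nrow(atoms_df), bonds_df)

  if (nrow(bonds_df)) {
    is_default <- bonds_df$order == "default"
    both_arom <- atoms_df$aromatic[bonds_df$a] & atoms_df$aromatic[bonds_df$b]
    bonds_df$order[is_default & both_arom & in_cycle] <- "ar"
    bonds_df$order[bonds_df$order == "default"] <- "1"
  }

  # aromatic atoms must sit in an aromatic ring
  if (any(atoms_df$aromatic)) {
    has_ar <- rep(FALSE, nrow(atoms_df))
    ar_bonds <- bonds_df[bonds_df$order == "ar", ]
    has_ar[c(ar_bonds$a, ar_bonds$b)] <- TRUE
    if (any(atoms_df$aromatic & !has_ar))
      parse_error("aromatic atom outside an aromatic ring", text)
  }

  # implicit hydrogens from default valences (before Kekule promotion, so the
  # hydrogen count reflects the written valence)
  mol0 <- structure(list(atoms = atoms_df, bonds = bonds_df), class = "molecule")
  sums <- bond_order_sums(mol0)
  for (i in seq_len(nrow(atoms_df))) {
    if (atoms_df$explicit_h[i]) next
    dv <- .default_valences[[atoms_df$element[i]]]
    if (is.null(dv)) parse_error(paste0("element ", atoms_df$element[i],
                                        " needs a bracket atom"), text)
    dv <- dv[dv >= sums[i]]
    atoms_df$hcount[i] <- if (length(dv)) dv[1] - sums[i] else 0L
  }
  atoms_df$explicit_h <- NULL
  atoms_df$id <- seq_len(nrow(atoms_df))

  mol <- structure(list(atoms = atoms_df, bonds = bonds_df), class = "molecule")
  mol <- perceive_aromaticity(mol)
  tryCatch(sanitize_molecule(mol), error = function(e) {
    abort(paste0(conditionMessage(e), " in '", text, "'"), class = "chemquiz_parse_error")
  })
}

# TRUE for every bond that lies on a cycle (i.e. is not a bridge).
cycle_edge_flags <- function(n_atoms, bonds_df) {
  if (nrow(bonds_df) == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(bonds_df$a, bonds_df$b), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nrow(bonds_df))
  flags[as.integer(br)] <- FALSE
  flags
}

# Smallest rings: for every cycle edge, the shortest cycle through it.
smallest_rings <- function(mol, max_size = 7L) {
  bonds_df <- mol$bonds
  in_cycle <- cycle_edge_flags(nrow(mol$atoms), bonds_df)
  if (!any(in_cycle)) return(list())
  g <- mol_graph(mol)
  rings <- list()
  seen <- character(0)
  for (i in which(in_cycle)) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(bonds_df$a[i], bonds_df$b[i])))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = bonds_df$a[i],
                                                  to = bonds_df$b[i])$vpath[[1]])
    if (length(sp) == 0L || length(sp) > max_size) next
    ring <- as.integer(sp)
    key <- paste(sort(ring), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

# Promote Kekule-form 5/6-membered rings to aromatic when a simple
# pi-electron count reaches an aromatic sextet. An atom contributes 1 pi
# electron through an endocyclic double bond, 2 through a heteroatom lone
# pair, and blocks aromatization when it has an exocyclic double bond.
perceive_aromaticity <- function(mol) {
  rings <- smallest_rings(mol, max_size = 6L)
  if (length(rings) == 0L) return(mol)
  in_cycle <- cycle_edge_flags(nrow(mol$atoms), mol$bonds)
  ring_atoms <- unique(unlist(rings))

  contribution <- function(a) {
    if (mol$atoms$aromatic[a]) return(1L)
    inc <- which(mol$bonds$a == a | mol$bonds$b == a)
    dbl <- inc[mol$bonds$order[inc] == "2"]
    if (length(dbl)) {
      endo <- any(in_cycle[dbl] &
                    (mol$bonds$a[dbl] %in% ring_atoms) & (mol$bonds$b[dbl] %in% ring_atoms))
      return(if (endo) 1L else -1L)  # exocyclic double bond blocks
    }
    if (mol$atoms$element[a] %in% c("N", "O", "S") && mol$atoms$charge[a] <= 0L) return(2L)
    -1L
  }

  changed <- FALSE
  for (ring in rings) {
    if (!length(ring) %in% c(5L, 6L)) next
    if (all(mol$atoms$aromatic[ring])) next
    contribs <- vapply(ring, contribution, integer(1))
    if (any(contribs < 0L)) next
    if (sum(contribs) != 6L) next
    mol$atoms$aromatic[ring] <- TRUE
    for (k in seq_along(ring)) {
      u <- ring[k]; v <- ring[if (k == length(ring)) 1L else k + 1L]
      hit <- which((mol$bonds$a == u & mol$bonds$b == v) | (mol$bonds$a == v & mol$bonds$b == u))
      mol$bonds$order[hit] <- "ar"
    }
    changed <- TRUE
  }
  if (changed) mol else mol
}
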