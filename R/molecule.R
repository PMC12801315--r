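#' @import tibble
#' @importFrom rlang abort warn .data
#' @importFrom stats setNames
NULL

# Default valences used both for implicit-H assignment and sanitization.
# Multi-valent elements (S, P) list every allowed valence; the smallest one
# that accommodates the explicit bonds is used for implicit hydrogens.
.default_valences <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

# Charge-adjusted allowed valences for the organic subset.
.charged_valences <- list(
  `N+` = 4L, `N-` = 2L, `O+` = 3L, `O-` = 1L, `C+` = 3L, `C-` = 3L,
  `S+` = c(3L, 5L), `S-` = 1L, `P+` = 4L, `B-` = 4L
)

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Construct a molecule object
#'
#' A molecule is an attributed graph: a tibble of atoms (element, formal
#' charge, aromatic flag, implicit hydrogen count, dummy-atom marker) and a
#' tibble of bonds (two atom ids and a bond order, one of `"1"`, `"2"`,
#' `"3"`, `"ar"`). Atom ids are row indices, stable for the lifetime of the
#' object. Users normally obtain molecules from [parse_smiles()] rather than
#' calling this directly.
#'
#' @param atoms Tibble with columns `element`, `charge`, `aromatic`,
#'   `hcount`, `dummy`.
#' @param bonds Tibble with columns `a`, `b`, `order`.
#' @param sanitize Run the valence check (default `TRUE`).
#' @return An object of class `molecule`.
#' @export
new_molecule <- function(atoms, bonds, sanitize = TRUE) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (nrow(atoms) == 0L) abort("molecule must contain at least one atom", class = "chemquiz_parse_error")
  atoms$id <- seq_len(nrow(atoms))
  mol <- structure(list(atoms = atoms, bonds = bonds), class = "molecule")
  if (sanitize) sanitize_molecule(mol) else mol
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", molecular_formula(x), ": ",
      nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' @export
format.molecule <- function(x, ...) canonical_smiles(x)

is_molecule <- function(x) inherits(x, "molecule")

# Sum of bond orders at each atom; aromatic bonds count 1.5 and the total is
# rounded up, which reproduces the usual aromatic valence bookkeeping
# (aromatic C with two ring bonds -> 3, fusion carbon with three -> 5 -> capped).
bond_order_sums <- function(mol) {
  n <- nrow(mol$atoms)
  s <- numeric(n)
  if (nrow(mol$bonds)) {
    w <- c(`1` = 1, `2` = 2, `3` = 3, ar = 1.5)[mol$bonds$order]
    for (i in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$a[i]] <- s[mol$bonds$a[i]] + w[i]
      s[mol$bonds$b[i]] <- s[mol$bonds$b[i]] + w[i]
    }
  }
  as.integer(ceiling(s - 1e-9))
}

allowed_valences <- function(element, charge) {
  if (charge != 0L) {
    key <- paste0(element, if (charge > 0) strrep("+", charge) else strrep("-", -charge))
    v <- .charged_valences[[key]]
    if (!is.null(v)) return(v)
  }
  v <- .default_valences[[element]]
  if (is.null(v)) return(NA_integer_)  # unconstrained (metals etc. in brackets)
  v
}

#' Validate the chemistry of a molecule
#'
#' Checks that every atom's total valence (explicit bonds plus implicit
#' hydrogens) is allowed for its element and formal charge. Dummy atoms and
#' bracket elements outside the organic subset are unconstrained.
#'
#' @param mol A `molecule`.
#' @return The molecule, invisibly validated; aborts with class
#'   `chemquiz_parse_error` on a valence violation.
#' @export
sanitize_molecule <- function(mol) {
  # Per-atom candidate valence sums. Aromatic bonds are ambiguous between a
  # single and a "1.5" contribution (lone-pair donors vs. fusion atoms), so
  # any consistent reading is accepted.
  ord_num <- c(`1` = 1, `2` = 2, `3` = 3)
  n <- nrow(mol$atoms)
  fixed <- numeric(n); n_ar <- integer(n)
  for (i in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[i]
    for (v in c(mol$bonds$a[i], mol$bonds$b[i])) {
      if (o == "ar") n_ar[v] <- n_ar[v] + 1L else fixed[v] <- fixed[v] + ord_num[[o]]
    }
  }
  for (i in seq_len(n)) {
    at <- mol$atoms[i, ]
    if (at$dummy) next
    allowed <- allowed_valences(at$element, at$charge)
    if (length(allowed) == 1L && is.na(allowed)) next
    cand <- unique(c(fixed[i] + n_ar[i],                       # aromatic as single
                     floor(fixed[i] + 1.5 * n_ar[i]),          # sextet reading
                     ceiling(fixed[i] + 1.5 * n_ar[i])))
    tot <- as.integer(cand) + at$hcount
    if (!any(tot %in% allowed)) {
      tot <- tot[1]
      abort(sprintf("valence error: atom %d (%s%s) has total valence %d, allowed %s",
                    i, at$element,
                    if (at$charge != 0) sprintf("%+d", at$charge) else "",
                    tot, paste(allowed, collapse = "/")),
            class = "chemquiz_parse_error")
    }
  }
  mol
}

#' Count atoms of one element
#'
#' @param mol A `molecule`.
#' @param element Element symbol, e.g. `"C"`. `"H"` counts implicit
#'   hydrogens.
#' @return Integer count.
#' @export
element_count <- function(mol, element) {
  if (element == "H") return(sum(mol$atoms$hcount))
  sum(mol$atoms$element == element & !mol$atoms$dummy)
}

#' Number of heavy (non-hydrogen) atoms
#' @param mol A `molecule`.
#' @param include_dummy Count wildcard dummy atoms too (default `FALSE`).
#' @return Integer count.
#' @export
heavy_atom_count <- function(mol, include_dummy = FALSE) {
  if (include_dummy) nrow(mol$atoms) else sum(!mol$atoms$dummy)
}

#' Molecular formula in Hill notation
#'
#' Carbon first, hydrogen second, remaining elements alphabetical. Implicit
#' hydrogens are included; dummy atoms are ignored. A net formal charge is
#' appended as a sign suffix.
#'
#' @param mol A `molecule`.
#' @return A string such as `"C2H6O"`.
#' @export
molecular_formula <- function(mol) {
  at <- mol$atoms[!mol$atoms$dummy, ]
  counts <- as.list(table(at$element))
  counts$H <- sum(at$hcount) + (counts$H %||% 0L)
  counts <- counts[vapply(counts, function(x) x > 0L, logical(1))]
  fmt <- function(el) paste0(el, if (counts[[el]] > 1L) counts[[el]] else "")
  order_els <- if (!is.null(counts$C)) {
    c("C", if (!is.null(counts$H)) "H", sort(setdiff(names(counts), c("C", "H"))))
  } else {
    sort(names(counts))   # no carbon: strictly alphabetical, H in place
  }
  body <- paste0(vapply(order_els, fmt, character(1)), collapse = "")
  q <- sum(at$charge)
  suffix <- if (q == 0L) "" else if (q == 1L) "+" else if (q == -1L) "-"
            else sprintf("%+d", q)
  paste0(body, suffix)
}

#' Number of independent rings (cycle rank)
#'
#' Bonds minus atoms plus connected components; for ordinary organic
#' chemistry this equals the size of the smallest set of smallest rings.
#'
#' @param mol A `molecule`.
#' @return Integer ring count.
#' @export
cycle_rank <- function(mol) {
  g <- mol_graph(mol)
  as.integer(nrow(mol$bonds) - nrow(mol$atoms) + igraph::components(g)$no)
}

#' Neighbour atom ids of an atom
#' @param mol A `molecule`.
#' @param id Atom id.
#' @return Integer vector of neighbouring atom ids.
#' @export
atom_neighbors <- function(mol, id) {
  c(mol$bonds$b[mol$bonds$a == id], mol$bonds$a[mol$bonds$b == id])
}

bond_between <- function(mol, u, v) {
  hit <- (mol$bonds$a == u & mol$bonds$b == v) | (mol$bonds$a == v & mol$bonds$b == u)
  if (!any(hit)) NA_character_ else mol$bonds$order[which(hit)[1L]]
}
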