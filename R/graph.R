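# Graph-theoretic utilities built on igraph. Bond orders are carried either
# as edge attributes (plain molecular graph) or encoded as coloured
# bond-vertices (for canonical labelling and automorphisms, since the BLISS
# backend takes vertex colours only).

#' Molecular graph as an igraph object
#'
#' Vertices are atoms (with `element`, `charge`, `aromatic`, `hcount`,
#' `dummy` attributes); edges carry the bond `order`.
#'
#' @param mol A `molecule`.
#' @return An undirected `igraph` graph.
#' @export
mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "element", value = mol$atoms$element)
  g <- igraph::set_vertex_attr(g, "charge", value = mol$atoms$charge)
  g <- igraph::set_vertex_attr(g, "aromatic", value = mol$atoms$aromatic)
  g <- igraph::set_vertex_attr(g, "hcount", value = mol$atoms$hcount)
  g <- igraph::set_vertex_attr(g, "dummy", value = mol$atoms$dummy)
  if (nrow(mol$bonds)) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a, mol$bonds$b))
    g <- igraph::set_edge_attr(g, "order", value = mol$bonds$order)
  }
  g
}

# Colour key distinguishing chemically distinct atoms.
atom_colors <- function(mol) {
  key <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$aromatic,
               mol$atoms$hcount, mol$atoms$dummy)
  match(key, sort(unique(key)))
}

# Auxiliary graph with one extra coloured vertex per bond, so that vertex
# colours alone encode bond orders for BLISS.
bond_vertex_graph <- function(mol) {
  n <- nrow(mol$atoms)
  m <- nrow(mol$bonds)
  ac <- atom_colors(mol)
  bc <- n + match(mol$bonds$order, c("1", "2", "3", "ar"))  # offset past atom colours
  g <- igraph::make_empty_graph(n = n + m, directed = FALSE)
  if (m) {
    g <- igraph::add_edges(g, c(rbind(mol$bonds$a, n + seq_len(m),
                                      mol$bonds$b, n + seq_len(m))))
  }
  list(graph = g, colors = c(ac, if (m) bc), n_atoms = n)
}

#' Canonical atom ranks
#'
#' Deterministic total order on atoms, invariant to the input atom
#' numbering, computed by the BLISS canonical-labelling algorithm on a
#' coloured auxiliary graph that encodes elements, charges, aromaticity,
#' hydrogen counts and bond orders.
#'
#' @param mol A `molecule`.
#' @return Integer vector: `rank[i]` is the canonical rank of atom `i`
#'   (1 = first).
#' @export
canonical_ranks <- function(mol) {
  bg <- bond_vertex_graph(mol)
  lab <- igraph::canonical_permutation(bg$graph, colors = bg$colors)$labeling
  rank(lab[seq_len(bg$n_atoms)])
}

#' Shortest path length between two atoms, in bonds
#'
#' Breadth-first-search distance on the molecular graph.
#'
#' @param mol A `molecule`.
#' @param a,b Distinct atom ids.
#' @return Integer bond count; aborts with class `chemquiz_no_path` if the
#'   atoms lie in different fragments.
#' @export
graph_distance <- function(mol, a, b) {
  stopifnot(a != b, a >= 1, b >= 1, a <= nrow(mol$atoms), b <= nrow(mol$atoms))
  d <- igraph::distances(mol_graph(mol), v = a, to = b)[1, 1]
  if (!is.finite(d)) abort("no path between atoms (disconnected fragments)",
                           class = "chemquiz_no_path")
  as.integer(d)
}

#' Automorphism group of the molecular graph
#'
#' All atom permutations preserving elements, charges, aromaticity,
#' hydrogen counts and bond orders. Generators come from BLISS; the full
#' group is produced by closure (bounded, as benchmark molecules have small
#' symmetry groups).
#'
#' @param mol A `molecule`.
#' @param max_size Abort if the group grows beyond this many elements.
#' @return List of integer permutation vectors (each maps atom id to its
#'   image), always including the identity.
#' @export
mol_automorphisms <- function(mol, max_size = 100000L) {
  bg <- bond_vertex_graph(mol)
  gens <- igraph::automorphism_group(bg$graph, colors = bg$colors)
  n <- bg$n_atoms
  gens <- lapply(gens, function(p) as.integer(p)[seq_len(n)])
  identity_p <- seq_len(n)
  elems <- list(identity_p)
  keys <- paste(identity_p, collapse = ",")
  frontier <- list(identity_p)
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) {
      for (g in gens) {
        q <- g[p]
        k <- paste(q, collapse = ",")
        if (!k %in% keys) {
          keys <- c(keys, k)
          elems[[length(elems) + 1L]] <- q
          nxt[[length(nxt) + 1L]] <- q
          if (length(elems) > max_size) abort("automorphism group too large")
        }
      }
    }
    frontier <- nxt
  }
  elems
}

#' Atom symmetry classes (automorphism orbits)
#'
#' @param mol A `molecule`.
#' @return Integer vector assigning each atom an orbit index (1-based,
#'   ordered by smallest member atom id).
#' @export
atom_orbits <- function(mol) {
  bg <- bond_vertex_graph(mol)
  gens <- igraph::automorphism_group(bg$graph, colors = bg$colors)
  n <- bg$n_atoms
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry) }
  for (g in gens) {
    p <- as.integer(g)[seq_len(n)]
    for (i in seq_len(n)) if (p[i] != i) union_(i, p[i])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

# All simple paths between two atoms; brute-force oracle used by tests and
# the acceptance script, independent of the BFS route.
all_simple_path_lengths <- function(mol, a, b) {
  g <- mol_graph(mol)
  paths <- igraph::all_simple_paths(g, from = a, to = b)
  vapply(paths, function(p) length(p) - 1L, integer(1))
}
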