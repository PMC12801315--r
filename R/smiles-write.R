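# SMILES writers. All writers share one depth-first renderer that records
# the atom order of appearance, so every emitted string comes with an
# order_map (position in string -> atom id) when requested.

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the random number generator, evaluates `expr`, and restores the
#' caller's RNG state. All question generation draws its randomness this
#' way, so a recorded seed reproduces any question in isolation.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Implicit hydrogen count an organic-subset atom would receive on re-parse;
# NA when the atom cannot be written bare.
expected_implicit_h <- function(mol, i, fixed, n_ar) {
  at <- mol$atoms[i, ]
  if (at$dummy || at$charge != 0L || !at$element %in% .organic_subset) return(NA_integer_)
  if (at$aromatic && !tolower(at$element) %in% .aromatic_ok) return(NA_integer_)
  dv <- .default_valences[[at$element]]
  s <- as.integer(ceiling(fixed[i] + 1.5 * n_ar[i] - 1e-9))
  dv <- dv[dv >= s]
  if (length(dv)) dv[1] - s else 0L
}

atom_token <- function(mol, i, fixed, n_ar) {
  at <- mol$atoms[i, ]
  if (at$dummy) return("*")
  sym <- if (at$aromatic) tolower(at$element) else at$element
  exp_h <- expected_implicit_h(mol, i, fixed, n_ar)
  if (!is.na(exp_h) && exp_h == at$hcount) return(sym)
  h <- if (at$hcount == 0L) "" else if (at$hcount == 1L) "H" else paste0("H", at$hcount)
  ch <- if (at$charge == 0L) "" else if (at$charge == 1L) "+" else if (at$charge == -1L) "-"
        else sprintf("%+d", at$charge)
  paste0("[", sym, h, ch, "]")
}

bond_token <- function(mol, order, u, v) {
  switch(order,
    "1" = if (mol$atoms$aromatic[u] && mol$atoms$aromatic[v]) "-" else "",
    "2" = "=",
    "3" = "#",
    "ar" = "")
}

# Write one connected fragment rooted at `root`; `order_fn(u, nbrs)` returns
# the neighbour visitation order. Returns the text and atom appearance order.
write_fragment <- function(mol, root, order_fn, fixed, n_ar) {
  nbr <- vector("list", nrow(mol$atoms))
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[i]; b <- mol$bonds$b[i]
    nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
  }
  visited <- rep(FALSE, nrow(mol$atoms))
  children <- vector("list", nrow(mol$atoms))
  ring_pairs <- list()
  appearance <- integer(0)

  dfs <- function(u, parent) {
    visited[u] <<- TRUE
    appearance[length(appearance) + 1L] <<- u
    for (v in order_fn(u, setdiff(nbr[[u]], parent))) {
      if (visited[v]) {
        key1 <- paste(u, v); key2 <- paste(v, u)
        if (!key1 %in% names(ring_pairs) && !key2 %in% names(ring_pairs))
          ring_pairs[[key1]] <<- c(u, v)
      } else {
        children[[u]] <<- c(children[[u]], v)
        dfs(v, u)
      }
    }
  }
  dfs(root, NA_integer_)

  # ring-closure digits, allocated in appearance order with reuse
  pos <- match(seq_len(nrow(mol$atoms)), appearance)
  ring_info <- list()  # atom -> list of (digit, order, emit_symbol)
  if (length(ring_pairs)) {
    closures <- do.call(rbind, unname(ring_pairs))
    first <- pmin(pos[closures[, 1]], pos[closures[, 2]])
    second <- pmax(pos[closures[, 1]], pos[closures[, 2]])
    ord_idx <- order(first, second)
    in_use <- logical(99)
    free_list <- rep(list(integer(0)), length(appearance) + 1L)
    for (k in ord_idx) {
      u <- closures[k, 1]; v <- closures[k, 2]
      p1 <- min(pos[u], pos[v]); p2 <- max(pos[u], pos[v])
      # free everything scheduled strictly before p1
      for (p in seq_len(p1)) {
        for (d in free_list[[p]]) in_use[d] <- FALSE
        free_list[[p]] <- integer(0)
      }
      digit <- which(!in_use)[1]
      in_use[digit] <- TRUE
      free_list[[p2 + 1L]] <- c(free_list[[p2 + 1L]], digit)
      border <- bond_between(mol, u, v)
      for (w in c(u, v)) {
        ring_info[[as.character(w)]] <- c(ring_info[[as.character(w)]],
          list(list(digit = digit, order = border, emit = pos[w] == p1,
                    other = if (w == u) v else u)))
      }
    }
  }

  render <- function(u) {
    out <- atom_token(mol, u, fixed, n_ar)
    for (rc in ring_info[[as.character(u)]]) {
      sym <- if (rc$emit) bond_token(mol, rc$order, u, rc$other) else ""
      dig <- if (rc$digit > 9L) paste0("%", sprintf("%02d", rc$digit)) else as.character(rc$digit)
      out <- paste0(out, sym, dig)
    }
    kids <- children[[u]]
    if (length(kids)) {
      for (i in seq_along(kids)) {
        v <- kids[i]
        sub <- paste0(bond_token(mol, bond_between(mol, u, v), u, v), render(v))
        out <- paste0(out, if (i < length(kids)) paste0("(", sub, ")") else sub)
      }
    }
    out
  }
  list(text = render(root), order = appearance)
}

bond_sum_parts <- function(mol) {
  n <- nrow(mol$atoms)
  fixed <- numeric(n); n_ar <- integer(n)
  ord_num <- c(`1` = 1, `2` = 2, `3` = 3)
  for (i in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[i]
    for (v in c(mol$bonds$a[i], mol$bonds$b[i])) {
      if (o == "ar") n_ar[v] <- n_ar[v] + 1L else fixed[v] <- fixed[v] + ord_num[[o]]
    }
  }
  list(fixed = fixed, n_ar = n_ar)
}

write_smiles_ordered <- function(mol, roots, order_fn, fragment_order = NULL) {
  parts <- bond_sum_parts(mol)
  comp <- igraph::components(mol_graph(mol))$membership
  n_comp <- max(comp)
  frag <- vector("list", n_comp)
  for (ci in seq_len(n_comp)) {
    members <- which(comp == ci)
    root <- roots[roots %in% members][1]
    if (is.na(root)) root <- members[1]
    frag[[ci]] <- write_fragment(mol, root, order_fn, parts$fixed, parts$n_ar)
  }
  ord <- fragment_order %||% order(vapply(frag, `[[`, character(1), "text"))
  text <- paste(vapply(frag[ord], `[[`, character(1), "text"), collapse = ".")
  order_map <- unlist(lapply(frag[ord], `[[`, "order"), use.names = FALSE)
  list(text = text, order_map = order_map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical SMILES string
#'
#' Deterministic and invariant to the input atom order: the depth-first
#' traversal is rooted at the atom of smallest canonical rank (dummy atoms
#' take precedence, so marked positions always start the string) and visits
#' neighbours in canonical-rank order. Idempotent under re-parsing.
#'
#' @param mol A `molecule`, or a SMILES string which is parsed first.
#' @return A SMILES string.
#' @export
#' @examples
#' canonical_smiles("OCC") == canonical_smiles("CCO")
canonical_smiles <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  ranks <- canonical_ranks(mol)
  cand <- if (any(mol$atoms$dummy)) which(mol$atoms$dummy) else seq_len(nrow(mol$atoms))
  roots <- cand[order(ranks[cand])]
  # one preferred root per fragment, beginning with the global best
  order_fn <- function(u, nbrs) nbrs[order(ranks[nbrs])]
  write_smiles_ordered(mol, roots, order_fn)$text
}

new_smiles_variant <- function(text, order_map, mode) {
  structure(list(text = text, order_map = order_map, mode = mode),
            class = "smiles_variant")
}

#' @export
print.smiles_variant <- function(x, ...) {
  cat("<smiles_variant ", x$mode, "> ", x$text, "\n", sep = "")
  invisible(x)
}

#' Randomized SMILES variant
#'
#' Writes the molecule by a depth-first traversal with a seeded random root
#' and random neighbour order. The same molecule and seed always give the
#' same string, and the result re-canonicalizes to the molecule's canonical
#' SMILES.
#'
#' @param mol A `molecule` or SMILES string.
#' @param seed Integer seed for the traversal.
#' @return A `smiles_variant`: `text`, `order_map` (position of appearance
#'   in the string to atom id), and `mode`.
#' @export
randomized_smiles <- function(mol, seed) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  with_seed(seed, {
    roots <- sample(seq_len(nrow(mol$atoms)))
    order_fn <- function(u, nbrs) if (length(nbrs) > 1L) sample(nbrs) else nbrs
    n_comp <- igraph::components(mol_graph(mol))$no
    frag_ord <- if (n_comp > 1L) sample(n_comp) else NULL
    w <- write_smiles_ordered(mol, roots, order_fn, fragment_order = frag_ord)
    new_smiles_variant(w$text, w$order_map, "randomized")
  })
}

#' Semicanonical SMILES variant
#'
#' Traversal rooted at a seeded random atom but following canonical
#' neighbour ranking thereafter, so large substructures keep their
#' canonical spelling while the string as a whole differs.
#'
#' @inheritParams randomized_smiles
#' @return A `smiles_variant`.
#' @export
semicanonical_smiles <- function(mol, seed) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  ranks <- canonical_ranks(mol)
  with_seed(seed, {
    roots <- sample(seq_len(nrow(mol$atoms)))
    order_fn <- function(u, nbrs) nbrs[order(ranks[nbrs])]
    w <- write_smiles_ordered(mol, roots, order_fn)
    new_smiles_variant(w$text, w$order_map, "semicanonical")
  })
}

#' Canonical SMILES variant with order map
#'
#' Like [canonical_smiles()] but returns the `smiles_variant` carrying the
#' atom appearance order.
#'
#' @param mol A `molecule` or SMILES string.
#' @return A `smiles_variant`.
#' @export
canonical_variant <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  ranks <- canonical_ranks(mol)
  cand <- if (any(mol$atoms$dummy)) which(mol$atoms$dummy) else seq_len(nrow(mol$atoms))
  roots <- cand[order(ranks[cand])]
  order_fn <- function(u, nbrs) nbrs[order(ranks[nbrs])]
  w <- write_smiles_ordered(mol, roots, order_fn)
  new_smiles_variant(w$text, w$order_map, "canonical")
}
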