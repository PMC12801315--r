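# Shared test fixtures and independent oracles. The oracles deliberately
# avoid the code paths they check: breadth-first search is re-implemented
# on the bond table, carbon counting is done at the character level, and
# OpenBabel serves as an external canonicalization/InChI referee.

bench_cache <- new.env(parent = emptyenv())

# The default benchmark is expensive; build it once per test run.
get_default_bench <- function() {
  if (is.null(bench_cache$bench)) bench_cache$bench <- generate_benchmark(default_config())
  bench_cache$bench
}

# Independent BFS on the raw bond table (no igraph).
oracle_bfs_distance <- function(mol, from, to) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[i]; b <- mol$bonds$b[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) if (is.na(dist[v])) { dist[v] <- dist[u] + 1L; queue <- c(queue, v) }
  }
  dist[to]
}

# Exhaustive simple-path enumeration (depth-first, no igraph).
oracle_all_simple_paths_min <- function(mol, from, to) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[i]; b <- mol$bonds$b[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  best <- Inf
  visit <- function(u, depth, seen) {
    if (u == to) { best <<- min(best, depth); return(invisible()) }
    for (v in adj[[u]]) if (!seen[v]) {
      seen2 <- seen; seen2[v] <- TRUE
      visit(v, depth + 1L, seen2)
    }
  }
  seen <- rep(FALSE, n); seen[from] <- TRUE
  visit(from, 0L, seen)
  as.integer(best)
}

# Character-level carbon tally: counts C/c atoms in a SMILES string,
# skipping Cl and handling bracket atoms explicitly.
oracle_carbon_tally <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars); i <- 1L; count <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (chars[j] != "]") j <- j + 1L
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      sym <- regmatches(body, regexec("^[0-9]*([A-Za-z][a-z]?)", body))[[1]][2]
      if (sym %in% c("C", "c")) count <- count + 1L
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      i <- i + 2L
    } else {
      if (ch %in% c("C", "c")) count <- count + 1L
      i <- i + 1L
    }
  }
  count
}

obabel_available <- function() nzchar(Sys.which("obabel"))

# Batch-canonicalize SMILES with OpenBabel; returns a character vector.
obabel_canonical <- function(smiles) {
  inf <- tempfile(fileext = ".smi"); outf <- tempfile(fileext = ".smi")
  writeLines(smiles, inf)
  system2("obabel", c(inf, "-ocan", "-O", outf), stdout = FALSE, stderr = FALSE)
  trimws(readLines(outf))
}

obabel_inchi <- function(smiles) {
  inf <- tempfile(fileext = ".smi"); outf <- tempfile(fileext = ".txt")
  writeLines(smiles, inf)
  system2("obabel", c(inf, "-oinchi", "-O", outf), stdout = FALSE, stderr = FALSE)
  trimws(readLines(outf))
}

# Enumerate all element/charge/hcount-preserving atom bijections of a
# small molecule by brute force over permutations within element groups.
all_colored_permutations <- function(mol) {
  key <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$hcount, mol$atoms$aromatic)
  groups <- split(seq_along(key), key)
  perm_lists <- lapply(groups, function(g) {
    if (length(g) == 1L) return(list(g))
    pm <- combinat_permn(g)
    pm
  })
  out <- list(integer(nrow(mol$atoms)))
  for (gi in seq_along(groups)) {
    new_out <- list()
    for (base in out) for (p in perm_lists[[gi]]) {
      b2 <- base
      b2[groups[[gi]]] <- p
      new_out[[length(new_out) + 1L]] <- b2
    }
    out <- new_out
  }
  out
}

# Minimal permutation enumerator (avoids external packages).
combinat_permn <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_permn(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}
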