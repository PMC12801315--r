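# Rule-based NMR simulation. Chemically equivalent nuclei are identified as
# automorphism orbits of the molecular graph; chemical shifts come from
# deterministic additive increment tables keyed on the local environment;
# multiplicities follow the n+1 rule over vicinal protons. The goal is
# chemically sensible, fully reproducible peak lists that discriminate
# between library molecules - scoring is structure-based, so absolute
# shift accuracy is not the contract.

#' Symmetry-equivalent nucleus classes
#'
#' Partitions carbons and hydrogen-bearing heavy atoms into equivalence
#' classes derived from graph automorphism orbits. Hydrogens are implicit:
#' an H class is represented by the orbit of its parent heavy atoms.
#'
#' @param mol A `molecule`.
#' @return Tibble with columns `kind` (`"H"` or `"C"`), `atoms` (list of
#'   member atom ids; for H the parent heavy atoms), `n_h` (total hydrogens
#'   in the class, 0 for C classes), `exchangeable` (H on N/O/S).
#' @export
nucleus_classes <- function(mol) {
  orb <- atom_orbits(mol)
  rows <- list()
  for (o in sort(unique(orb))) {
    members <- which(orb == o)
    el <- mol$atoms$element[members[1]]
    hc <- mol$atoms$hcount[members[1]]
    if (mol$atoms$dummy[members[1]]) next
    if (el == "C") {
      rows[[length(rows) + 1L]] <- tibble(kind = "C", atoms = list(members),
                                          n_h = 0L, exchangeable = FALSE)
    }
    if (hc > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        kind = "H", atoms = list(members), n_h = hc * length(members),
        exchangeable = el %in% c("N", "O", "S"))
    }
  }
  dplyr::bind_rows(rows)
}

# ---- shift estimation ------------------------------------------------------

neighbor_profile <- function(mol, a) {
  nb <- atom_neighbors(mol, a)
  nb <- nb[!mol$atoms$dummy[nb]]
  list(
    ids = nb,
    elements = mol$atoms$element[nb],
    orders = vapply(nb, function(v) bond_between(mol, a, v), character(1)),
    aromatic = mol$atoms$aromatic[nb]
  )
}

is_carbonyl_c <- function(mol, a) {
  if (mol$atoms$element[a] != "C" || mol$atoms$aromatic[a]) return(FALSE)
  np <- neighbor_profile(mol, a)
  any(np$elements == "O" & np$orders == "2")
}

#' Estimated carbon-13 chemical shift for an atom
#'
#' Additive-increment estimate: a base value for the carbon environment
#' (sp3, alkene, alkyne, aromatic, carbonyl, nitrile) plus neighbour
#' increments for heteroatoms and conjugation. Rounded to 0.1 ppm.
#'
#' @param mol A `molecule`.
#' @param a A carbon atom id.
#' @return Shift in ppm.
#' @export
estimate_shift_c <- function(mol, a) {
  stopifnot(mol$atoms$element[a] == "C")
  np <- neighbor_profile(mol, a)
  shift <- if (mol$atoms$aromatic[a]) {
    s <- 128.5
    for (k in seq_along(np$ids)) {
      v <- np$ids[k]
      if (np$orders[k] == "ar" && mol$atoms$element[v] == "N") s <- s + 21
      if (np$orders[k] != "ar") {
        # exocyclic substituent: ipso increments by first atom
        el <- mol$atoms$element[v]
        s <- s + switch(el, O = 27, N = if (mol$atoms$charge[v] > 0) 20 else 19,
                        C = 9, F = 35, Cl = 6, Br = -5, I = -32, S = 10, 0)
      }
    }
    s
  } else if (any(np$orders == "3" & np$elements == "N")) {
    118
  } else if (any(np$orders == "3" & np$elements == "C")) {
    72 + 8 * sum(np$elements == "C" & np$orders != "3")
  } else if (any(np$orders == "2" & np$elements == "O")) {
    has_n <- any(np$elements == "N" & np$orders == "1")
    single_o <- np$ids[np$elements == "O" & np$orders == "1"]
    if (has_n) 170
    else if (length(single_o)) {
      if (mol$atoms$hcount[single_o[1]] > 0L) 177 else 170.5
    }
    else if (mol$atoms$hcount[a] > 0L) 201
    else 206
  } else if (any(np$orders == "2" & np$elements == "C")) {
    123 + 8 * sum(np$elements == "C" & np$orders == "1") +
      25 * sum(np$elements == "O")
  } else {
    s <- 6 + 9.1 * sum(np$elements == "C" & !np$aromatic &
                         !vapply(np$ids, function(v) is_carbonyl_c(mol, v), logical(1)))
    for (k in seq_along(np$ids)) {
      v <- np$ids[k]
      el <- mol$atoms$element[v]
      if (el == "O") s <- s + 44
      else if (el == "N") s <- s + 22
      else if (el == "F") s <- s + 63
      else if (el == "Cl") s <- s + 31
      else if (el == "Br") s <- s + 20
      else if (el == "I") s <- s + 7
      else if (el == "S") s <- s + 13
      else if (el == "C" && np$aromatic[k]) s <- s + 15.1  # 9.1 + ring anisotropy
      else if (el == "C" && is_carbonyl_c(mol, v)) s <- s + 23.1
    }
    s
  }
  round(shift, 1)
}

#' Estimated proton chemical shift for hydrogens on an atom
#'
#' @param mol A `molecule`.
#' @param a The parent heavy atom id (must carry at least one hydrogen).
#' @return Shift in ppm, rounded to 0.01.
#' @export
estimate_shift_h <- function(mol, a) {
  stopifnot(mol$atoms$hcount[a] > 0L)
  el <- mol$atoms$element[a]
  np <- neighbor_profile(mol, a)
  carbonyl_nb <- vapply(np$ids, function(v) is_carbonyl_c(mol, v), logical(1))
  shift <-
    if (el == "O") {
      if (any(carbonyl_nb)) 11.5
      else if (any(np$aromatic)) 5.6
      else 2.2
    } else if (el == "N") {
      if (any(carbonyl_nb)) 7.6
      else if (any(np$aromatic)) 3.7
      else 1.8
    } else if (el == "S") {
      1.5
    } else if (mol$atoms$aromatic[a]) {
      s <- 7.26
      ring_nb <- np$ids[np$orders == "ar"]
      if (any(mol$atoms$element[ring_nb] == "N")) s <- s + 1.3
      for (v in ring_nb) {
        for (w in atom_neighbors(mol, v)) {
          if (w == a || mol$atoms$dummy[w]) next
          if (bond_between(mol, v, w) == "ar") next
          wel <- mol$atoms$element[w]
          if (wel == "O") s <- s - 0.4
          else if (wel == "N" && mol$atoms$charge[w] > 0) s <- s + 0.8   # nitro
          else if (wel == "N") s <- s - 0.6
          else if (wel == "C" && is_carbonyl_c(mol, w)) s <- s + 0.55
        }
      }
      s
    } else if (any(np$orders == "2" & np$elements == "O")) {
      9.8
    } else if (any(np$orders == "2" & np$elements == "C")) {
      5.4 + 0.6 * sum(np$aromatic | carbonyl_nb)
    } else if (any(np$orders == "3")) {
      2.5
    } else {
      s <- switch(as.character(min(mol$atoms$hcount[a], 3L)),
                  "3" = 0.90, "2" = 1.25, "1" = 1.50, 0.20)
      for (k in seq_along(np$ids)) {
        v <- np$ids[k]
        vel <- mol$atoms$element[v]
        inc <- if (vel == "O") 2.6
          else if (vel == "N") 1.5
          else if (vel == "F") 3.2
          else if (vel == "Cl") 2.1
          else if (vel == "Br") 1.75
          else if (vel == "I") 1.2
          else if (vel == "S") 1.3
          else if (vel == "C" && np$aromatic[k]) 1.4
          else if (vel == "C" && carbonyl_nb[k]) 1.2
          else if (vel == "C" && np$orders[k] == "1" &&
                     any(vapply(atom_neighbors(mol, v), function(w)
                       w != a && bond_between(mol, v, w) %in% c("2", "3"), logical(1)))) 0.45
          else 0
        s <- s + inc
      }
      s
    }
  round(shift, 2)
}

#' Multiplicity label for a proton class
#'
#' n+1 rule over vicinal (three-bond) protons: hydrogens on carbons
#' adjacent to the class's parent atoms, excluding exchangeable protons,
#' protons of the same equivalence class, and geminal partners. A single
#' coupling partner class with n protons gives s/d/t/q/quint (n = 0..4);
#' more protons or several inequivalent partner classes give a multiplet;
#' exchangeable classes are broad singlets.
#'
#' @param mol A `molecule`.
#' @param class_row One row of [nucleus_classes()] with `kind == "H"`.
#' @param classes The full class table (computed if missing).
#' @return One of `"s"`, `"d"`, `"t"`, `"q"`, `"quint"`, `"m"`, `"br s"`.
#' @export
multiplicity <- function(mol, class_row, classes = NULL) {
  if (class_row$exchangeable) return("br s")
  orb <- atom_orbits(mol)
  parents <- class_row$atoms[[1]]
  own_orbit <- orb[parents[1]]
  partner_orbits <- integer(0)
  n <- 0L
  for (p in parents) {
    for (v in atom_neighbors(mol, p)) {
      if (mol$atoms$dummy[v] || mol$atoms$element[v] != "C") next
      if (orb[v] == own_orbit) next
      if (mol$atoms$hcount[v] == 0L) next
      if (!orb[v] %in% partner_orbits) {
        partner_orbits <- c(partner_orbits, orb[v])
        n <- n + mol$atoms$hcount[v] * sum(orb == orb[v])
      }
    }
  }
  if (length(partner_orbits) == 0L) return("s")
  if (length(partner_orbits) > 1L) return("m")
  switch(as.character(n), "1" = "d", "2" = "t", "3" = "q", "4" = "quint", "m")
}

# Deterministic collision nudge: classes closer than the minimum separation
# are pushed apart in descending-shift order.
separate_shifts <- function(shifts, min_sep, digits) {
  ord <- order(-shifts, seq_along(shifts))
  out <- shifts
  for (k in seq_along(ord)[-1]) {
    prev <- out[ord[k - 1]]
    if (prev - out[ord[k]] < min_sep) out[ord[k]] <- round(prev - min_sep, digits)
  }
  out
}

#' Simulate a 1D NMR spectrum pair
#'
#' @param mol A `molecule`.
#' @return List of class `spectrum_1d`: `formula`, `h_peaks` (tibble
#'   `shift`, `mult`, `integration`, descending shift), `c_peaks` (numeric,
#'   descending), `exchangeable_h` (count of protons omitted from the
#'   proton peak list).
#' @export
simulate_1d <- function(mol) {
  cls <- nucleus_classes(mol)
  hc <- cls[cls$kind == "H" & !cls$exchangeable, ]
  h_peaks <- tibble(shift = numeric(0), mult = character(0), integration = integer(0))
  if (nrow(hc)) {
    shifts <- vapply(seq_len(nrow(hc)), function(i)
      estimate_shift_h(mol, hc$atoms[[i]][1]), numeric(1))
    shifts <- separate_shifts(shifts, 0.05, 2)
    mults <- vapply(seq_len(nrow(hc)), function(i)
      multiplicity(mol, hc[i, ]), character(1))
    h_peaks <- tibble(shift = shifts, mult = mults, integration = hc$n_h) |>
      dplyr::arrange(dplyr::desc(.data$shift), .data$mult)
  }
  cc <- cls[cls$kind == "C", ]
  c_peaks <- numeric(0)
  if (nrow(cc)) {
    c_peaks <- vapply(seq_len(nrow(cc)), function(i)
      estimate_shift_c(mol, cc$atoms[[i]][1]), numeric(1))
    c_peaks <- sort(separate_shifts(c_peaks, 0.5, 1), decreasing = TRUE)
  }
  structure(list(
    formula = molecular_formula(mol),
    h_peaks = h_peaks,
    c_peaks = c_peaks,
    exchangeable_h = sum(cls$n_h[cls$kind == "H" & cls$exchangeable])
  ), class = "spectrum_1d")
}

#' Simulate 2D COSY/HSQC/HMBC peak lists
#'
#' COSY correlates vicinal proton classes; HSQC pairs each proton class
#' with its directly bonded carbon class; HMBC pairs proton classes with
#' carbons two or three bonds from the proton (one-bond pairs excluded).
#' Peaks are reported as shift pairs using the 1D shift assignments.
#'
#' @param mol A `molecule`.
#' @return List of class `spectrum_2d` with tibbles `cosy` (`h1`, `h2`),
#'   `hsqc` (`c`, `h`), `hmbc` (`c`, `h`).
#' @export
simulate_2d <- function(mol) {
  cls <- nucleus_classes(mol)
  orb <- atom_orbits(mol)
  d <- igraph::distances(mol_graph(mol))

  hc <- cls[cls$kind == "H" & !cls$exchangeable, ]
  cc <- cls[cls$kind == "C", ]
  h_shift <- vapply(seq_len(nrow(hc)), function(i)
    estimate_shift_h(mol, hc$atoms[[i]][1]), numeric(1))
  h_shift <- separate_shifts(h_shift, 0.05, 2)
  c_shift <- vapply(seq_len(nrow(cc)), function(i)
    estimate_shift_c(mol, cc$atoms[[i]][1]), numeric(1))
  c_shift <- separate_shifts(c_shift, 0.5, 1)
  h_orbit <- vapply(seq_len(nrow(hc)), function(i) orb[hc$atoms[[i]][1]], integer(1))
  c_orbit <- vapply(seq_len(nrow(cc)), function(i) orb[cc$atoms[[i]][1]], integer(1))

  cosy <- list(); hsqc <- list(); hmbc <- list()
  if (nrow(hc) >= 2L) {
    for (i in seq_len(nrow(hc) - 1L)) for (j in (i + 1L):nrow(hc)) {
      pi_ <- hc$atoms[[i]]; pj <- hc$atoms[[j]]
      if (any(d[pi_, pj, drop = FALSE] == 1))
        cosy[[length(cosy) + 1L]] <- tibble(h1 = max(h_shift[i], h_shift[j]),
                                            h2 = min(h_shift[i], h_shift[j]))
    }
  }
  for (i in seq_len(nrow(cc))) for (j in seq_len(nrow(hc))) {
    dd <- d[cc$atoms[[i]], hc$atoms[[j]], drop = FALSE]
    if (c_orbit[i] == h_orbit[j]) {
      hsqc[[length(hsqc) + 1L]] <- tibble(c = c_shift[i], h = h_shift[j])
    } else if (any(dd == 1 | dd == 2)) {
      hmbc[[length(hmbc) + 1L]] <- tibble(c = c_shift[i], h = h_shift[j])
    }
  }
  empty_hh <- tibble(h1 = numeric(0), h2 = numeric(0))
  empty_ch <- tibble(c = numeric(0), h = numeric(0))
  arrange_ch <- function(x) dplyr::arrange(x, dplyr::desc(.data$c), dplyr::desc(.data$h))
  structure(list(
    cosy = if (length(cosy)) dplyr::arrange(dplyr::bind_rows(cosy),
                                            dplyr::desc(.data$h1), dplyr::desc(.data$h2))
           else empty_hh,
    hsqc = if (length(hsqc)) arrange_ch(dplyr::bind_rows(hsqc)) else empty_ch,
    hmbc = if (length(hmbc)) arrange_ch(dplyr::bind_rows(hmbc)) else empty_ch
  ), class = "spectrum_2d")
}

#' Render simulated spectra as prompt text
#'
#' @param s1 A `spectrum_1d`.
#' @param s2 Optionally a `spectrum_2d`.
#' @return A single character string, deterministic for a given molecule.
#' @export
render_spectra <- function(s1, s2 = NULL) {
  fmt_h <- function(p) sprintf("%.2f (%s, %dH)", p$shift, p$mult, p$integration)
  h_line <- if (nrow(s1$h_peaks)) {
    paste0("1H NMR: delta ",
           paste(vapply(seq_len(nrow(s1$h_peaks)), function(i)
             fmt_h(s1$h_peaks[i, ]), character(1)), collapse = ", "))
  } else "1H NMR: no nonexchangeable protons"
  if (s1$exchangeable_h > 0L)
    h_line <- paste0(h_line, sprintf("; plus %d exchangeable proton%s not shown",
                                     s1$exchangeable_h,
                                     if (s1$exchangeable_h > 1L) "s" else ""))
  c_line <- if (length(s1$c_peaks)) {
    paste0("13C NMR: delta ", paste(sprintf("%.1f", s1$c_peaks), collapse = ", "))
  } else "13C NMR: no carbon signals"
  out <- paste(h_line, c_line, sep = "\n")
  if (!is.null(s2)) {
    pair_h <- function(df) if (nrow(df)) paste(sprintf("(%.2f, %.2f)", df$h1, df$h2),
                                               collapse = ", ") else "none"
    pair_c <- function(df) if (nrow(df)) paste(sprintf("(%.1f, %.2f)", df$c, df$h),
                                               collapse = ", ") else "none"
    out <- paste(out,
                 paste0("COSY (1H/1H): ", pair_h(s2$cosy)),
                 paste0("HSQC (13C/1H): ", pair_c(s2$hsqc)),
                 paste0("HMBC (13C/1H): ", pair_c(s2$hmbc)),
                 sep = "\n")
  }
  out
}
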