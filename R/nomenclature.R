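# Systematic nomenclature support: aromatic scaffolds with standard locant
# numbering, a library of common substituents with their prefix names, a
# namer for molecules built by substituent placement, and a restricted
# name parser used as the arbiter of naming-question answers. The parser
# covers detachable-prefix nomenclature on benzene, pyridine, naphthalene
# and quinoline, simple substituted chain parents with one principal
# characteristic group, and a handful of retained names.

#' Aromatic scaffolds with locant numbering
#'
#' Each scaffold records its SMILES and the mapping from IUPAC locants to
#' atom ids of the parsed structure. Only substitutable CH positions are
#' listed (ring nitrogens and fusion atoms are excluded).
#'
#' @return Named list of scaffold descriptors (`smiles`, `positions`).
#' @export
scaffold_table <- function() {
  list(
    benzene = list(
      smiles = "c1ccccc1",
      positions = c(`1` = 1L, `2` = 2L, `3` = 3L, `4` = 4L, `5` = 5L, `6` = 6L)),
    pyridine = list(
      smiles = "n1ccccc1",
      positions = c(`2` = 2L, `3` = 3L, `4` = 4L, `5` = 5L, `6` = 6L)),
    naphthalene = list(
      smiles = "c1ccc2ccccc2c1",
      positions = c(`1` = 10L, `2` = 1L, `3` = 2L, `4` = 3L,
                    `5` = 5L, `6` = 6L, `7` = 7L, `8` = 8L)),
    quinoline = list(
      smiles = "c1ccc2ccccc2n1",
      positions = c(`2` = 1L, `3` = 2L, `4` = 3L,
                    `5` = 5L, `6` = 6L, `7` = 7L, `8` = 8L))
  )
}

#' Library of 40 common functional groups
#'
#' Substituent prefixes with singly attaching SMILES fragments (atom 1 is
#' the attachment point, carrying a free valence as an implicit hydrogen).
#' Every entry attaches cleanly to an aromatic carbon.
#'
#' @return Tibble with columns `name` and `smiles`.
#' @export
functional_group_library <- function() {
  tibble::tribble(
    ~name,               ~smiles,
    "fluoro",            "F",
    "chloro",            "Cl",
    "bromo",             "Br",
    "iodo",              "I",
    "nitro",             "[NH+](=O)[O-]",
    "cyano",             "C#N",
    "hydroxy",           "O",
    "amino",             "N",
    "methyl",            "C",
    "ethyl",             "CC",
    "propyl",            "CCC",
    "propan-2-yl",       "C(C)C",
    "butyl",             "CCCC",
    "tert-butyl",        "C(C)(C)C",
    "methoxy",           "OC",
    "ethoxy",            "OCC",
    "propoxy",           "OCCC",
    "trifluoromethyl",   "C(F)(F)F",
    "trifluoromethoxy",  "OC(F)(F)F",
    "formyl",            "C=O",
    "acetyl",            "C(C)=O",
    "propanoyl",         "C(CC)=O",
    "carboxy",           "C(O)=O",
    "methoxycarbonyl",   "C(=O)OC",
    "ethoxycarbonyl",    "C(=O)OCC",
    "carbamoyl",         "C(N)=O",
    "acetamido",         "NC(C)=O",
    "methylamino",       "NC",
    "dimethylamino",     "N(C)C",
    "ethylamino",        "NCC",
    "sulfanyl",          "S",
    "methylsulfanyl",    "SC",
    "methanesulfonyl",   "S(C)(=O)=O",
    "sulfamoyl",         "S(N)(=O)=O",
    "phenyl",            "c1ccccc1",
    "benzyl",            "Cc1ccccc1",
    "phenoxy",           "Oc1ccccc1",
    "ethenyl",           "C=C",
    "prop-2-enyl",       "CC=C",
    "cyclopropyl",       "C1CC1"
  )
}

fg_smiles <- function(name) {
  lib <- functional_group_library()
  s <- lib$smiles[lib$name == name]
  if (length(s) != 1L) abort(paste0("unknown functional group '", name, "'"))
  s
}

#' Build a substituted aromatic scaffold and its systematic name
#'
#' @param scaffold One of `"benzene"`, `"pyridine"`, `"naphthalene"`,
#'   `"quinoline"`.
#' @param placements Tibble (or data frame) with columns `locant` (integer)
#'   and `group` (functional-group name from [functional_group_library()]).
#' @return List with `mol` (the substituted `molecule`) and `name`
#'   (a parsable systematic name using the given locants).
#' @export
build_substituted_scaffold <- function(scaffold, placements) {
  sc <- scaffold_table()[[scaffold]]
  if (is.null(sc)) abort(paste0("unknown scaffold '", scaffold, "'"))
  placements <- tibble::as_tibble(placements)
  if (anyDuplicated(placements$locant)) abort("duplicate locants")
  mol <- parse_smiles(sc$smiles)
  for (i in seq_len(nrow(placements))) {
    pos <- sc$positions[[as.character(placements$locant[i])]]
    if (is.null(pos) || is.na(pos)) abort(paste0("locant ", placements$locant[i],
                                                 " not substitutable on ", scaffold))
    mol <- attach_fragment(mol, pos, fg_smiles(placements$group[i]))
  }
  list(mol = mol, name = substituent_prefix_name(placements, scaffold))
}

# Assemble "1-bromo-2-chloro-4-nitro<parent>" style names. Groups are
# alphabetized (ignoring the 'tert-' multiplier-like particle); duplicated
# groups collapse into di/tri/... with a combined locant set.
substituent_prefix_name <- function(placements, parent) {
  if (nrow(placements) == 0L) return(parent)
  mult <- c("", "di", "tri", "tetra", "penta", "hexa")
  groups <- split(placements$locant, placements$group)
  alpha_key <- function(g) sub("^tert-", "", g)
  groups <- groups[order(vapply(names(groups), alpha_key, character(1)))]
  segs <- vapply(seq_along(groups), function(i) {
    g <- names(groups)[i]
    locs <- sort(as.integer(groups[[i]]))
    paste0(paste(locs, collapse = ","), "-", mult[length(locs)], g)
  }, character(1))
  paste0(paste(segs, collapse = "-"), parent)
}

# ---- name parsing ----------------------------------------------------------

.chain_roots <- c(meth = 1L, eth = 2L, prop = 3L, but = 4L, pent = 5L,
                  hex = 6L, hept = 7L, oct = 8L, non = 9L, dec = 10L)

.retained_parents <- list(
  phenol        = list(scaffold = "benzene", implied = "hydroxy"),
  toluene       = list(scaffold = "benzene", implied = "methyl"),
  aniline       = list(scaffold = "benzene", implied = "amino"),
  anisole       = list(scaffold = "benzene", implied = "methoxy"),
  benzaldehyde  = list(scaffold = "benzene", implied = "formyl"),
  benzonitrile  = list(scaffold = "benzene", implied = "cyano"),
  `benzoic acid` = list(scaffold = "benzene", implied = "carboxy"),
  acetophenone  = list(scaffold = "benzene", implied = "acetyl")
)

# Split the detachable-prefix part of a name into (locants, group) pairs.
# Returns NULL if any part fails to parse.
parse_prefix_segments <- function(prefix) {
  lib <- functional_group_library()
  gnames <- lib$name[order(-nchar(lib$name))]
  mult <- c(di = 2L, tri = 3L, tetra = 4L, penta = 5L, hexa = 6L)
  out <- list()
  s <- prefix
  while (nzchar(s)) {
    s <- sub("^-", "", s)
    locs <- integer(0)
    m <- regmatches(s, regexec("^([0-9]+(,[0-9]+)*)-", s))[[1]]
    if (length(m)) {
      locs <- as.integer(strsplit(m[2], ",")[[1]])
      s <- substring(s, nchar(m[1]) + 1L)
    }
    hit <- NULL
    for (g in gnames) {
      if (startsWith(s, g)) { hit <- g; count <- 1L; break }
    }
    if (is.null(hit)) {
      for (mu in names(mult)) {
        if (startsWith(s, mu)) {
          rest <- substring(s, nchar(mu) + 1L)
          for (g in gnames) {
            if (startsWith(rest, g)) { hit <- g; count <- mult[[mu]]; s <- rest; break }
          }
          if (!is.null(hit)) break
        }
      }
    }
    if (is.null(hit)) return(NULL)
    s <- substring(s, nchar(hit) + 1L)
    if (length(locs) == 0L) locs <- rep(NA_integer_, count)
    if (length(locs) != count) return(NULL)
    for (l in locs) out[[length(out) + 1L]] <- list(locant = l, group = hit)
  }
  out
}

# Chain parents: the acid/aldehyde suffix carbon is carbon 1 of the chain
# itself, so those are built from the full chain rather than by attachment.
parse_chain_parent <- function(s) {
  m <- regmatches(s, regexec(
    "^(meth|eth|prop|but|pent|hex|hept|oct|non|dec)an(e|ol|al|one|amine|oic acid|-([0-9]+)-ol|-([0-9]+)-one|-([0-9]+)-amine)$", s))[[1]]
  if (length(m) == 0L) return(NULL)
  n <- .chain_roots[[m[2]]]
  suf <- m[3]
  loc <- 1L
  if (grepl("^-", suf)) {
    loc <- as.integer(regmatches(suf, regexec("[0-9]+", suf))[[1]])
    suf <- sub("^-[0-9]+-", "", suf)
  }
  if (suf == "e") suf <- "ane"
  if (loc > n) return(NULL)
  mol <- parse_smiles(paste(rep("C", n), collapse = ""))
  mol <- switch(suf,
    ane = mol,
    ol = attach_fragment(mol, loc, "O"),
    amine = attach_fragment(mol, loc, "N"),
    one = { cmb <- mol_combine(mol, parse_smiles("O"))
            add_bond_h(cmb$mol, loc, cmb$offset + 1L, order = "2") },
    al = { cmb <- mol_combine(mol, parse_smiles("O"))
           add_bond_h(cmb$mol, 1L, cmb$offset + 1L, order = "2") },
    `oic acid` = { cmb <- mol_combine(mol, parse_smiles("O"))
                   m2 <- add_bond_h(cmb$mol, 1L, cmb$offset + 1L, order = "2")
                   attach_fragment(m2, 1L, "O") },
    return(NULL))
  list(mol = mol, n_positions = n, kind = "chain")
}

#' Parse a systematic chemical name into a molecule
#'
#' Restricted nomenclature parser: detachable substituent prefixes (the
#' [functional_group_library()] roster, with di/tri/... multipliers and
#' locants) on the four aromatic scaffolds, simple chain parents
#' (methane..decane with one -ol/-al/-one/-amine/-oic acid suffix), and a
#' few retained names (phenol, toluene, aniline, ...). Returns `NULL` when
#' the name is outside the grammar, mirroring a parse failure.
#'
#' @param name A chemical name.
#' @return A `molecule`, or `NULL` if the name cannot be parsed.
#' @export
parse_iupac_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) return(NULL)
  s <- tolower(str_trim(name))
  s <- gsub("[‐-―−]", "-", s)   # unicode dashes
  s <- gsub("\\s+", " ", s)
  if (!nzchar(s)) return(NULL)

  try_build <- function(expr) tryCatch(expr, error = function(e) NULL)

  # scaffold parents
  for (sc in names(scaffold_table())) {
    if (endsWith(s, sc)) {
      prefix <- substr(s, 1L, nchar(s) - nchar(sc))
      prefix <- sub("-$", "", prefix)
      segs <- if (nzchar(prefix)) parse_prefix_segments(prefix) else list()
      if (is.null(segs)) next
      pl <- tibble(locant = vapply(segs, function(x) x$locant, integer(1)),
                   group = vapply(segs, function(x) x$group, character(1)))
      if (nrow(pl) == 1L && is.na(pl$locant[1]))
        pl$locant[1] <- as.integer(names(scaffold_table()[[sc]]$positions)[1])
      if (anyNA(pl$locant) || anyDuplicated(pl$locant)) next
      res <- try_build(build_substituted_scaffold(sc, pl)$mol)
      if (!is.null(res)) return(res)
    }
  }

  # retained parents with an implied group at position 1
  for (rp in names(.retained_parents)) {
    if (endsWith(s, rp)) {
      info <- .retained_parents[[rp]]
      prefix <- sub("-$", "", substr(s, 1L, nchar(s) - nchar(rp)))
      segs <- if (nzchar(prefix)) parse_prefix_segments(prefix) else list()
      if (is.null(segs)) next
      pl <- tibble(locant = c(1L, vapply(segs, function(x) x$locant, integer(1))),
                   group = c(info$implied, vapply(segs, function(x) x$group, character(1))))
      if (anyNA(pl$locant) || anyDuplicated(pl$locant)) next
      res <- try_build(build_substituted_scaffold(info$scaffold, pl)$mol)
      if (!is.null(res)) return(res)
    }
  }

  # chain parents, longest matching suffix first
  for (cut in seq_len(nchar(s))) {
    tail_s <- substring(s, cut)
    cp <- parse_chain_parent(tail_s)
    if (!is.null(cp)) {
      prefix <- sub("-$", "", substr(s, 1L, cut - 1L))
      segs <- if (nzchar(prefix)) parse_prefix_segments(prefix) else list()
      if (is.null(segs)) next
      mol <- cp$mol
      ok <- TRUE
      for (seg in segs) {
        lo <- seg$locant
        if (is.na(lo)) lo <- if (length(segs) == 1L) 1L else NA_integer_
        if (is.na(lo) || lo > cp$n_positions) { ok <- FALSE; break }
        mol <- tryCatch(attach_fragment(mol, lo, fg_smiles(seg$group)),
                        error = function(e) NULL)
        if (is.null(mol)) { ok <- FALSE; break }
      }
      if (ok) return(mol)
    }
  }
  NULL
}

#' Check an IUPAC-style name against a reference structure
#'
#' The name is parsed to a structure by [parse_iupac_name()] and compared
#' to the truth by canonical-graph equivalence; any name that denotes the
#' intended structure is accepted, regardless of locant or ordering
#' conventions. Unparsable names are simply wrong answers.
#'
#' @param name Candidate name.
#' @param truth A `molecule` or canonical SMILES of the intended structure.
#' @return Logical flag.
#' @export
check_iupac <- function(name, truth) {
  mol <- parse_iupac_name(name)
  if (is.null(mol)) return(FALSE)
  smiles_equivalent(canonical_smiles(mol),
                    if (is_molecule(truth)) canonical_smiles(truth) else truth)
}
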