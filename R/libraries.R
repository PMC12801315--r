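# Bundled molecule libraries. Both are synthetic stand-ins generated by
# tools/make_fixtures.R: a drug-like set of polysubstituted aromatic
# scaffolds (each with a reference systematic name), and a curated set of
# C/H/N/O molecules of at most ten heavy atoms for 1D NMR questions.

.chemquiz_cache <- new.env(parent = emptyenv())

read_smi_file <- function(path) {
  if (!file.exists(path)) abort(paste0("fixture file missing: ", path),
                                class = "chemquiz_fixture_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(smiles = vapply(parts, `[[`, character(1), 1),
         name = vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_,
                       character(1)))
}

#' Drug-like molecule library
#'
#' At least 500 synthetic drug-like molecules (10-30 heavy atoms, organic
#' subset elements), each bundled with a reference systematic name derived
#' from its construction recipe. Deterministic: the same packaged fixture
#' file is returned on every call.
#'
#' @return Tibble with columns `smiles` (canonical), `name` (reference
#'   systematic name) and `heavy_atoms`.
#' @export
druglike_library <- function() {
  if (!is.null(.chemquiz_cache$druglike)) return(.chemquiz_cache$druglike)
  path <- system.file("extdata", "druglike_synthetic.smi", package = "chemquiz")
  df <- read_smi_file(path)
  df$heavy_atoms <- vapply(df$smiles, function(s) heavy_atom_count(parse_smiles(s)),
                           integer(1), USE.NAMES = FALSE)
  .chemquiz_cache$druglike <- df
  df
}

#' Small-molecule library (C/H/N/O, at most 10 heavy atoms)
#'
#' Curated molecules used for 1D NMR elucidation questions.
#'
#' @return Tibble with columns `smiles` (canonical), `name` (common name
#'   where recorded) and `heavy_atoms`.
#' @export
small_molecule_library <- function() {
  if (!is.null(.chemquiz_cache$small)) return(.chemquiz_cache$small)
  path <- system.file("extdata", "small_cnho_synthetic.smi", package = "chemquiz")
  df <- read_smi_file(path)
  df$heavy_atoms <- vapply(df$smiles, function(s) heavy_atom_count(parse_smiles(s)),
                           integer(1), USE.NAMES = FALSE)
  .chemquiz_cache$small <- df
  df
}
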