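# NMR structure-elucidation question assembly.

#' Generate an NMR elucidation question
#'
#' The prompt contains the molecular formula and the rendered simulated
#' spectra (1D proton/carbon; optionally COSY, HSQC and HMBC for 2D mode);
#' the task is to write the SMILES of the molecule.
#'
#' @param mol A `molecule` or SMILES string. 1D questions draw from the
#'   small C/H/N/O library (up to 10 heavy atoms); 2D questions from the
#'   drug-like library (up to 30 heavy atoms).
#' @param mode `"1d"` or `"2d"`.
#' @param seed Integer seed recorded in metadata.
#' @return One-row question tibble (category `nmr_1d` or `nmr_2d`).
#' @export
gen_nmr_question <- function(mol, mode = c("1d", "2d"), seed = 0L) {
  mode <- match.arg(mode)
  if (is.character(mol)) mol <- parse_smiles(mol)
  n <- heavy_atom_count(mol)
  if (mode == "1d" && n > 10L) abort("1D NMR questions use molecules of at most 10 heavy atoms")
  if (mode == "2d" && n > 30L) abort("2D NMR questions use molecules of at most 30 heavy atoms")
  s1 <- simulate_1d(mol)
  s2 <- if (mode == "2d") simulate_2d(mol) else NULL
  spec_text <- render_spectra(s1, s2)
  can <- canonical_smiles(mol)
  prompt <- paste0(
    "A molecule has the molecular formula ", s1$formula, ". ",
    "Its simulated NMR data (shifts in ppm) are:\n", spec_text, "\n",
    "Determine the structure and write its SMILES string.\n", .answer_footer)
  question_record(paste0("nmr_", mode), prompt, list(smiles = can), can,
                  list(seed = seed, source = can, smiles_mode = "canonical",
                       formula = s1$formula, spectrum = spec_text))
}
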