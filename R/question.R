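# Shared question-record plumbing. A question is one row of a tibble with a
# machine-checkable truth payload; the whole benchmark is a tibble of such
# rows that serializes to JSONL.

.answer_footer <- paste0(
  "Give your final answer on the last line of your response, ",
  "in the form \"Answer: <your answer>\".")

question_record <- function(category, prompt, truth, ref_answer, meta) {
  tibble(
    id = NA_character_,
    category = category,
    prompt = prompt,
    truth = list(truth),
    ref_answer = as.character(ref_answer),
    meta = list(meta)
  )
}

#' Derive reproducible sub-seeds from a master seed
#'
#' One master seed fans out to `n` per-question seeds, each within the
#' 32-bit integer range.
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
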