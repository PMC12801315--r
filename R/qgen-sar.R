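# Free-Wilson analysis questions: additive substituent-contribution
# instances on a benzofuran scaffold with three halogen-bearing positions,
# plus the analytic solver used as the internal oracle.

.fw_scaffold_smiles <- "c1ccc2occc2c1"
.fw_positions <- c(2L, 9L, 6L)      # two benzo CH sites and the furan C2 site
.fw_substituents <- c("F", "Cl", "Br")

fw_molecule <- function(combo) {
  mol <- parse_smiles(.fw_scaffold_smiles)
  for (p in seq_along(.fw_positions))
    mol <- attach_fragment(mol, .fw_positions[p], combo[p])
  mol
}

fw_design_row <- function(combo) {
  row <- c(1)
  for (p in 1:3) row <- c(row, combo[p] == "Cl", combo[p] == "Br")
  as.numeric(row)
}

#' Solve a Free-Wilson instance analytically
#'
#' Fits the additive model (intercept plus per-position substituent
#' contributions) to the training combinations and predicts the query.
#' With seven independent training rows the system is square and the
#' prediction exact; when the design is rank-deficient the query is only
#' predicted if its indicator vector lies in the row space, otherwise the
#' instance is underdetermined and an error of class
#' `chemquiz_underdetermined` is raised.
#'
#' @param training Tibble/data frame with columns `r1`, `r2`, `r3`
#'   (substituents among F/Cl/Br) and `score`.
#' @param query Character vector of three substituents.
#' @return Predicted score (numeric; integer-valued for noise-free
#'   instances).
#' @export
solve_free_wilson <- function(training, query) {
  training <- tibble::as_tibble(training)
  X <- t(vapply(seq_len(nrow(training)), function(i)
    fw_design_row(c(training$r1[i], training$r2[i], training$r3[i])),
    numeric(7)))
  y <- training$score
  xq <- fw_design_row(query)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    if (qr(rbind(X, xq))$rank > qrX$rank)
      abort("query is not determined by the training set",
            class = "chemquiz_underdetermined")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  } else {
    beta <- solve(X, y)
  }
  as.numeric(xq %*% beta)
}

# Draw one full instance: random integer substituent values, eight distinct
# combinations (7 training + 1 query) with a full-rank training design.
fw_instance <- function(seed, noise = FALSE) {
  all_combos <- as.matrix(expand.grid(.fw_substituents, .fw_substituents,
                                      .fw_substituents, stringsAsFactors = FALSE))
  with_seed(seed, {
    v <- matrix(sample(1:20, 9L, replace = TRUE), nrow = 3,
                dimnames = list(NULL, .fw_substituents))
    repeat {
      pick <- sample(nrow(all_combos), 8L)
      train <- all_combos[pick[1:7], , drop = FALSE]
      X <- t(apply(train, 1, fw_design_row))
      if (qr(X)$rank == 7L) break
    }
    query <- all_combos[pick[8], ]
    score <- function(combo) sum(vapply(1:3, function(p) v[p, combo[p]], numeric(1)))
    train_scores <- apply(train, 1, score)
    # noise scale calibrated so the additive model still pins the query to
    # within the scorer's +/-2 tolerance for >= 95% of instances (the exact
    # 7x7 solve amplifies training noise at the query point)
    shown_scores <- if (noise) train_scores + round(stats::rnorm(7, 0, 0.45)) else train_scores
    list(values = v, train = train, train_scores = train_scores,
         shown_scores = as.integer(shown_scores), query = query,
         truth = score(query), noise = noise)
  })
}

#' Generate a Free-Wilson question
#'
#' Seven scaffold molecules with different halogen combinations at three
#' positions are listed with their scores (the sum of per-position
#' substituent values); the task is to predict the score of an eighth,
#' unseen combination. The query is always uniquely determined by the
#' training rows (full-rank check at generation). The noisy variant
#' perturbs only the displayed training scores with rounded unit Gaussian
#' noise; the truth stays the noise-free sum and scoring allows a +/-2
#' tolerance.
#'
#' @param seed Integer seed.
#' @param noise Add noise to the displayed training scores.
#' @return One-row question tibble (category `free_wilson`).
#' @export
gen_free_wilson_question <- function(seed = 0L, noise = FALSE) {
  inst <- fw_instance(seed, noise)
  train_smiles <- apply(inst$train, 1, function(cb) canonical_smiles(fw_molecule(cb)))
  query_smiles <- canonical_smiles(fw_molecule(inst$query))
  # generator guard: the analytic solver must reproduce the generating sum
  solved <- solve_free_wilson(
    tibble(r1 = inst$train[, 1], r2 = inst$train[, 2], r3 = inst$train[, 3],
           score = inst$train_scores), inst$query)
  if (abs(solved - inst$truth) > 1e-8)
    abort("internal inconsistency in Free-Wilson instance")
  lines <- paste(sprintf("%s  score = %d", train_smiles, inst$shown_scores),
                 collapse = "\n")
  prompt <- paste0(
    "The scores of seven molecules are determined by the sum of independent ",
    "contributions of their substituents at three positions of a shared ",
    "scaffold.", if (inst$noise) " The measured scores contain a small amount of noise." else "",
    "\n", lines, "\n",
    "Predict the score of the following molecule:\n", query_smiles, "\n",
    .answer_footer)
  question_record("free_wilson", prompt,
                  list(value = inst$truth, noise = inst$noise,
                       train = unname(apply(inst$train, 1, paste, collapse = "")),
                       shown_scores = inst$shown_scores,
                       query = paste(inst$query, collapse = "")),
                  inst$truth,
                  list(seed = seed, source = query_smiles, noise = inst$noise,
                       smiles_mode = "canonical"))
}
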