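# Answer extraction and category-specific equivalence checking. The
# scorer never re-generates questions: every judgment is made from the
# question row's truth payload alone.

.numeric_categories <- c("carbon_count", "ring_count", "shortest_path", "free_wilson")
.smiles_categories <- c("reaction", "nmr_1d", "nmr_2d")
.name_categories <- c("iupac_zinc", "iupac_fg", "iupac_locant")

#' Extract the answer span from a free-text response
#'
#' Strict mode takes the content of the last line matching the mandated
#' `Answer: <...>` pattern. Lenient mode falls back to a category-aware
#' pattern search: the last number for numeric categories, the last
#' parsable SMILES-like token for structure categories, the last
#' position-pair list for mapping questions, and the last non-empty line
#' for naming questions.
#'
#' @param response Response text (may span multiple lines).
#' @param mode `"strict"` or `"lenient"`.
#' @param category Question category (needed for lenient fallbacks).
#' @return The extracted answer string, or `NA_character_` if nothing is
#'   found.
#' @export
extract_answer <- function(response, mode = c("strict", "lenient"), category = NULL) {
  mode <- match.arg(mode)
  if (is.null(response) || length(response) != 1L || is.na(response))
    return(NA_character_)
  lines <- strsplit(response, "\n", fixed = TRUE)[[1]]
  hits <- regmatches(lines, regexec("^\\s*answer\\s*:\\s*(.+?)\\s*$", lines,
                                    ignore.case = TRUE))
  vals <- vapply(hits, function(h) if (length(h)) h[2] else NA_character_, character(1))
  vals <- vals[!is.na(vals)]
  if (length(vals)) return(vals[length(vals)])
  if (mode == "strict" || is.null(category)) return(NA_character_)

  if (category %in% c(.numeric_categories)) {
    m <- gregexpr("-?[0-9]+(\\.[0-9]+)?", response)[[1]]
    if (m[1] == -1L) return(NA_character_)
    return(substring(response, m[length(m)],
                     m[length(m)] + attr(m, "match.length")[length(m)] - 1L))
  }
  if (category == "atom_map") {
    m <- gregexpr("[0-9]+\\s*(->|=>|:|=)\\s*[0-9]+", response)[[1]]
    if (m[1] == -1L) return(NA_character_)
    pairs <- substring(response, m, m + attr(m, "match.length") - 1L)
    return(paste(pairs, collapse = ", "))
  }
  if (category %in% .smiles_categories) {
    toks <- regmatches(response,
                       gregexpr("[][A-Za-z0-9@+()=#$:%*./\\\\-]{2,}", response))[[1]]
    for (tok in rev(toks)) {
      if (!grepl("[A-Za-z]", tok)) next
      ok <- tryCatch({ parse_smiles(tok); TRUE }, error = function(e) FALSE)
      if (ok) return(tok)
    }
    return(NA_character_)
  }
  if (category %in% .name_categories) {
    nz <- lines[nzchar(trimws(lines))]
    if (!length(nz)) return(NA_character_)
    return(sub("\\.$", "", trimws(nz[length(nz)])))
  }
  NA_character_
}

#' Structure-level SMILES equivalence
#'
#' Both strings are parsed (stereochemistry is stripped on parsing) and
#' compared by canonical-form equality of the molecular graphs.
#'
#' @param a,b SMILES strings.
#' @return `TRUE`/`FALSE`; an unparseable input gives `FALSE` with an
#'   attribute `note = "unparseable"`.
#' @export
smiles_equivalent <- function(a, b) {
  ma <- tryCatch(if (is_molecule(a)) a else parse_smiles(a), error = function(e) NULL)
  mb <- tryCatch(if (is_molecule(b)) b else parse_smiles(b), error = function(e) NULL)
  if (is.null(ma) || is.null(mb))
    return(structure(FALSE, note = "unparseable"))
  canonical_smiles(ma) == canonical_smiles(mb)
}

# Parse an atom-mapping answer into an integer vector (position i of A ->
# value at i in B). NULL if malformed or not a bijection over 1..n.
parse_mapping_answer <- function(text, n) {
  if (is.na(text)) return(NULL)
  m <- gregexpr("([0-9]+)\\s*(?:->|=>|:|=)\\s*([0-9]+)", text)[[1]]
  if (m[1] == -1L) return(NULL)
  pairs <- substring(text, m, m + attr(m, "match.length") - 1L)
  from <- as.integer(sub("^([0-9]+).*", "\\1", pairs))
  to <- as.integer(sub(".*?([0-9]+)$", "\\1", pairs))
  if (anyDuplicated(from)) return(NULL)
  map <- rep(NA_integer_, n)
  ok <- from >= 1L & from <= n & to >= 1L & to <= n
  if (!all(ok)) return(NULL)
  map[from] <- to
  if (anyNA(map) || anyDuplicated(map)) return(NULL)
  map
}

#' Check an atom-mapping answer against the reference molecule
#'
#' A mapping is accepted iff the induced atom correspondence is a
#' bijection that preserves elements and bonds (with orders) - i.e. the
#' answer equals the stored reference composed with some graph
#' automorphism. Symmetry is therefore never penalized.
#'
#' @param answer_map Integer vector (A position i maps to B position
#'   `answer_map[i]`), or text parsed with the `i->j` grammar.
#' @param truth The `truth` payload of an atom-mapping question (fields
#'   `source`, `a_order`, `b_order`).
#' @return Logical flag.
#' @export
check_mapping <- function(answer_map, truth) {
  mol <- parse_smiles(truth$source)
  n <- nrow(mol$atoms)
  if (is.character(answer_map)) answer_map <- parse_mapping_answer(answer_map, n)
  if (is.null(answer_map) || length(answer_map) != n) return(FALSE)
  if (anyNA(answer_map) || anyDuplicated(answer_map)) return(FALSE)
  a_order <- truth$a_order
  b_order <- truth$b_order
  # induced atom correspondence: atom a_order[i] -> atom b_order[answer_map[i]]
  corr <- integer(n)
  corr[a_order] <- b_order[answer_map]
  if (anyDuplicated(corr)) return(FALSE)
  if (!all(mol$atoms$element[corr] == mol$atoms$element) ||
      !all(mol$atoms$charge[corr] == mol$atoms$charge) ||
      !all(mol$atoms$hcount[corr] == mol$atoms$hcount))
    return(FALSE)
  key <- function(u, v, o) paste(pmin(u, v), pmax(u, v), o)
  orig <- sort(key(mol$bonds$a, mol$bonds$b, mol$bonds$order))
  mapped <- sort(key(corr[mol$bonds$a], corr[mol$bonds$b], mol$bonds$order))
  identical(orig, mapped)
}

numeric_answers_equal <- function(answer, value, tol = 0) {
  x <- suppressWarnings(as.numeric(trimws(answer)))
  if (is.na(x)) return(NA)
  abs(x - value) <= tol + 1e-9
}

#' Judge one response against one question
#'
#' @param question One-row question tibble (as produced by the
#'   generators).
#' @param response Free-text response (or `NA` for a missing response).
#' @param mode Answer-extraction mode, `"strict"` or `"lenient"`.
#' @return Tibble row: `id`, `category`, `answer`, `verdict`
#'   (`"correct"`, `"incorrect"`, `"unparseable"`), `note`.
#' @export
judge_response <- function(question, response, mode = "strict") {
  category <- question$category
  truth <- question$truth[[1]]
  ans <- extract_answer(response, mode, category)
  verdict <- "incorrect"; note <- ""
  if (is.na(ans)) {
    verdict <- "unparseable"
    note <- if (is.na(response)) "missing response" else "no answer found"
  } else if (category %in% .numeric_categories) {
    tol <- if (isTRUE(truth$noise)) 2 else 0
    eq <- numeric_answers_equal(ans, truth$value, tol)
    if (is.na(eq)) { verdict <- "unparseable"; note <- "not a number" }
    else if (eq) verdict <- "correct"
  } else if (category %in% .smiles_categories) {
    eq <- smiles_equivalent(ans, truth$smiles)
    if (identical(attr(eq, "note"), "unparseable")) {
      verdict <- "unparseable"; note <- "SMILES did not parse"
    } else if (eq) verdict <- "correct"
  } else if (category %in% .name_categories) {
    mol <- parse_iupac_name(ans)
    if (is.null(mol)) { verdict <- "unparseable"; note <- "name did not parse" }
    else if (smiles_equivalent(canonical_smiles(mol), truth$smiles)) verdict <- "correct"
  } else if (category == "atom_map") {
    n <- length(truth$a_order)
    map <- parse_mapping_answer(ans, n)
    if (is.null(map)) { verdict <- "unparseable"; note <- "mapping did not parse" }
    else if (check_mapping(map, truth)) verdict <- "correct"
  } else {
    abort(paste0("unknown category '", category, "'"))
  }
  tibble(id = question$id, category = category, answer = ans,
         verdict = verdict, note = note)
}

#' Score a benchmark against a set of responses
#'
#' @param questions Question tibble (a benchmark).
#' @param responses Tibble with columns `id` and `response`; questions
#'   without a response are judged incorrect.
#' @param mode `"strict"` or `"lenient"` extraction.
#' @return A `chemquiz_score` object: `judgments` (per-question tibble),
#'   `by_category` (n, k, accuracy with 95% CI), `overall`, `mode`.
#' @export
score_benchmark <- function(questions, responses, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  responses <- tibble::as_tibble(responses)
  if (anyDuplicated(questions$id)) abort("duplicate question ids in benchmark")
  if (anyDuplicated(responses$id)) abort("duplicate ids in responses")
  unknown <- setdiff(responses$id, questions$id)
  if (length(unknown)) abort(paste0("responses reference unknown question ids: ",
                                    paste(utils::head(unknown, 3), collapse = ", ")))
  resp <- setNames(responses$response, responses$id)
  judgments <- dplyr::bind_rows(lapply(seq_len(nrow(questions)), function(i) {
    qid <- questions$id[i]
    r <- if (qid %in% names(resp)) resp[[qid]] else NA_character_
    judge_response(questions[i, ], r, mode)
  }))
  by_cat <- judgments |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$verdict == "correct"),
                     .groups = "drop") |>
    dplyr::mutate(accuracy = .data$k / .data$n)
  cis <- lapply(seq_len(nrow(by_cat)), function(i) binomial_ci(by_cat$k[i], by_cat$n[i]))
  by_cat$ci_low <- vapply(cis, `[[`, numeric(1), 1)
  by_cat$ci_high <- vapply(cis, `[[`, numeric(1), 2)
  n <- nrow(judgments); k <- sum(judgments$verdict == "correct")
  ci <- binomial_ci(k, n)
  structure(list(judgments = judgments, by_category = by_cat,
                 overall = tibble(n = n, k = k, accuracy = k / n,
                                  ci_low = ci[1], ci_high = ci[2]),
                 mode = mode),
            class = "chemquiz_score")
}

#' @export
print.chemquiz_score <- function(x, ...) {
  cat("<chemquiz_score> ", x$overall$k, "/", x$overall$n, " correct (",
      sprintf("%.1f%%", 100 * x$overall$accuracy), "), mode = ", x$mode, "\n", sep = "")
  print(x$by_category)
  invisible(x)
}

# ---- evaluation statistics -------------------------------------------------

#' Wald 95% confidence interval for a binomial proportion
#'
#' The estimate plus/minus 1.96 standard errors, clipped to the unit
#' interval.
#'
#' @param k Number of successes.
#' @param n Number of trials (must be at least 1).
#' @return Numeric vector `c(low, high)`.
#' @export
binomial_ci <- function(k, n) {
  if (n < 1L) abort("binomial_ci requires n >= 1")
  stopifnot(k >= 0L, k <= n)
  p <- k / n
  se <- sqrt(p * (1 - p) / n)
  c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
}

#' One-tailed McNemar test on discordant counts
#'
#' Exact binomial tail: with `b` and `c` the discordant counts between two
#' paired classifiers, the p value is `P(X >= max(b, c))` for
#' `X ~ Binomial(b + c, 1/2)`. Returns 1 when there are no discordant
#' pairs.
#'
#' @param b Count of items the first condition got right and the second
#'   wrong.
#' @param c Count of items the second condition got right and the first
#'   wrong.
#' @return The one-sided p value.
#' @export
mcnemar_one_tailed <- function(b, c) {
  stopifnot(b >= 0L, c >= 0L)
  n <- b + c
  if (n == 0L) return(1)
  stats::pbinom(max(b, c) - 1L, n, 0.5, lower.tail = FALSE)
}

#' Compare two score reports with one-tailed McNemar tests
#'
#' @param a,b `chemquiz_score` objects computed on the same benchmark.
#' @return Tibble with per-category and overall rows: discordant counts
#'   `b` (correct in `a` only), `c` (correct in `b` only) and the
#'   one-tailed p value.
#' @export
compare_scores <- function(a, b) {
  ja <- a$judgments; jb <- b$judgments
  if (!identical(ja$id, jb$id))
    abort("score reports do not cover the same benchmark")
  ca <- ja$verdict == "correct"; cb <- jb$verdict == "correct"
  rows <- function(idx, label) {
    bb <- sum(ca[idx] & !cb[idx]); cc <- sum(!ca[idx] & cb[idx])
    tibble(category = label, b = bb, c = cc, p = mcnemar_one_tailed(bb, cc))
  }
  cats <- unique(ja$category)
  dplyr::bind_rows(
    dplyr::bind_rows(lapply(cats, function(cat) rows(ja$category == cat, cat))),
    rows(rep(TRUE, nrow(ja)), "overall"))
}
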