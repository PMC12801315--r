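# Benchmark assembly: reproducible generation of the full question set
# from a single configuration, plus JSONL serialization.

#' Default benchmark configuration
#'
#' Per-category question counts summing to 816. Starred categories in the
#' count table are split 50/50 between canonical and randomized SMILES
#' (shortest path, drug-like naming, reactions) or between the two variant
#' modes (atom mapping: randomized/semicanonical; Free-Wilson:
#' noise-free/noisy).
#'
#' @param seed Master seed; every per-question seed derives from it.
#' @param counts Named list of per-category counts (defaults shown in the
#'   function definition).
#' @return A `chemquiz_config` list.
#' @export
default_config <- function(seed = 20260423L, counts = NULL) {
  base <- list(
    carbon_count = 60L, ring_count = 60L, shortest_path = 120L,
    atom_map = 72L, iupac_zinc = 200L, iupac_fg = 40L, iupac_locant = 40L,
    free_wilson = 40L, reaction = 90L, nmr_1d = 44L, nmr_2d = 50L)
  if (!is.null(counts)) base[names(counts)] <- lapply(counts, as.integer)
  if (any(unlist(base) < 0L)) abort("question counts must be non-negative")
  structure(list(seed = as.integer(seed), counts = base), class = "chemquiz_config")
}

sample_pool <- function(df, n, seed, category) {
  if (n > nrow(df))
    abort(paste0("category '", category, "' requests ", n,
                 " questions but the pool has only ", nrow(df), " molecules"),
          class = "chemquiz_capacity_error")
  df[with_seed(seed, sample(nrow(df), n)), , drop = FALSE]
}

#' Generate the full benchmark
#'
#' Deterministic: identical configurations give identical question
#' tibbles. Every question records its own seed, so any single question
#' can be regenerated in isolation.
#'
#' @param config A `chemquiz_config` from [default_config()].
#' @return Tibble of question records (`id`, `category`, `prompt`,
#'   `truth`, `ref_answer`, `meta`).
#' @export
generate_benchmark <- function(config = default_config()) {
  counts <- config$counts
  cat_seeds <- derive_seeds(config$seed, length(counts) + 1L)
  names(cat_seeds) <- c(names(counts), "extra")
  drug <- druglike_library()
  small <- small_molecule_library()
  out <- list()
  add <- function(q) out[[length(out) + 1L]] <<- q

  simple_gen <- function(category, pool, gen) {
    n <- counts[[category]]
    if (n == 0L) return(invisible())
    rows <- sample_pool(pool, n, cat_seeds[[category]], category)
    qseeds <- derive_seeds(cat_seeds[[category]] + 1L, n)
    for (i in seq_len(n)) add(gen(rows[i, ], qseeds[i], i))
  }

  simple_gen("carbon_count", drug, function(row, s, i)
    gen_count_question(row$smiles, "carbon", seed = s))
  ring_pool <- drug  # pool construction keeps cycle rank within six rings
  simple_gen("ring_count", ring_pool, function(row, s, i)
    gen_count_question(row$smiles, "ring", seed = s))
  n_sp <- counts$shortest_path
  simple_gen("shortest_path", drug, function(row, s, i)
    gen_shortest_path_question(row$smiles,
                               if (i <= ceiling(n_sp / 2)) "canonical" else "randomized",
                               seed = s))
  n_am <- counts$atom_map
  simple_gen("atom_map", drug[drug$heavy_atoms >= 8L & drug$heavy_atoms <= 24L, ],
             function(row, s, i)
               gen_atom_mapping_question(row$smiles,
                                         if (i <= ceiling(n_am / 2)) "randomized"
                                         else "semicanonical",
                                         seed = s))

  # drug-like naming: the same molecules asked in both SMILES modes
  n_iz <- counts$iupac_zinc
  if (n_iz > 0L) {
    n_mols <- ceiling(n_iz / 2)
    rows <- sample_pool(drug, n_mols, cat_seeds[["iupac_zinc"]], "iupac_zinc")
    qseeds <- derive_seeds(cat_seeds[["iupac_zinc"]] + 1L, n_iz)
    for (i in seq_len(n_iz)) {
      mi <- if (i <= n_mols) i else i - n_mols
      mode <- if (i <= n_mols) "canonical" else "randomized"
      add(gen_iupac_sample_question(rows$smiles[mi], rows$name[mi], mode, qseeds[i]))
    }
  }
  if (counts$iupac_fg > 0L) {
    qseeds <- derive_seeds(cat_seeds[["iupac_fg"]], counts$iupac_fg)
    for (i in seq_len(counts$iupac_fg)) add(gen_iupac_fg_question(qseeds[i]))
  }
  if (counts$iupac_locant > 0L) {
    qseeds <- derive_seeds(cat_seeds[["iupac_locant"]], counts$iupac_locant)
    scaffolds <- names(scaffold_table())
    for (i in seq_len(counts$iupac_locant))
      add(gen_iupac_locant_question(scaffolds[(i - 1L) %% 4L + 1L], qseeds[i]))
  }
  if (counts$free_wilson > 0L) {
    n_fw <- counts$free_wilson
    qseeds <- derive_seeds(cat_seeds[["free_wilson"]], n_fw)
    for (i in seq_len(n_fw))
      add(gen_free_wilson_question(qseeds[i], noise = i > ceiling(n_fw / 2)))
  }
  if (counts$reaction > 0L) {
    templates <- reaction_template_set()
    n_rx <- counts$reaction
    n_pairs <- ceiling(n_rx / 2)
    qseeds <- derive_seeds(cat_seeds[["reaction"]], n_pairs)
    drawn <- list()
    pair_info <- lapply(seq_len(n_pairs), function(i) {
      tpl <- templates[[(i - 1L) %% length(templates) + 1L]]
      s <- qseeds[i]
      for (k in 0:25) {
        rs <- sample_reactants(tpl, s + k * 104729L)
        key <- paste(tpl$class, paste(unlist(rs), collapse = "|"))
        if (is.null(drawn[[key]])) { drawn[[key]] <<- TRUE; break }
      }
      list(tpl = tpl, reactants = rs, seed = s + k * 104729L)
    })
    for (i in seq_len(n_rx)) {
      pi_ <- if (i <= n_pairs) i else i - n_pairs
      mode <- if (i <= n_pairs) "canonical" else "randomized"
      info <- pair_info[[pi_]]
      add(gen_reaction_question(info$tpl, mode, info$seed, reactants = info$reactants))
    }
  }

  nmr_gen <- function(category, pool, mode) {
    n <- counts[[category]]
    if (n == 0L) return(invisible())
    ord <- with_seed(cat_seeds[[category]], sample(nrow(pool)))
    qseeds <- derive_seeds(cat_seeds[[category]] + 1L, nrow(pool))
    seen <- character(0)
    taken <- 0L
    for (j in ord) {
      if (taken >= n) break
      q <- gen_nmr_question(pool$smiles[j], mode, seed = qseeds[j])
      spec <- q$meta[[1]]$spectrum
      key <- paste(q$meta[[1]]$formula, spec)
      if (key %in% seen) next   # non-discriminating within the library draw
      seen <- c(seen, key)
      taken <- taken + 1L
      add(q)
    }
    if (taken < n)
      abort(paste0("category '", category, "' could not assemble ", n,
                   " discriminable questions"), class = "chemquiz_capacity_error")
  }
  nmr_gen("nmr_1d", small, "1d")
  nmr_gen("nmr_2d", drug[drug$heavy_atoms <= 30L, ], "2d")

  bench <- dplyr::bind_rows(out)
  bench <- bench |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(id = sprintf("%s-%03d", .data$category, dplyr::row_number())) |>
    dplyr::ungroup()
  # restore generation order grouped by category in config order
  bench <- bench[order(match(bench$category, names(counts))), ]
  bench
}

#' Self-consistency responses: the stored truths as answers
#'
#' @param questions A benchmark tibble.
#' @return Tibble with `id` and `response` (`"Answer: <truth>"`), suitable
#'   for [score_benchmark()]; a correct scorer accepts every one.
#' @export
self_responses <- function(questions) {
  tibble(id = questions$id,
         response = paste0("Answer: ", questions$ref_answer))
}

#' Load a benchmark configuration from a YAML file
#'
#' Recognized fields: `seed` (integer) and `counts` (a mapping of category
#' name to question count); anything omitted falls back to the defaults.
#'
#' @param path YAML file path.
#' @return A `chemquiz_config`.
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  default_config(seed = x$seed %||% 20260423L, counts = x$counts)
}

# ---- JSONL serialization ---------------------------------------------------

#' Write a benchmark (or responses/judgments) to JSONL
#'
#' One JSON object per line, UTF-8.
#'
#' @param questions Question tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_benchmark <- function(questions, path) {
  lines <- vapply(seq_len(nrow(questions)), function(i) {
    jsonlite::toJSON(list(
      id = questions$id[i], category = questions$category[i],
      prompt = questions$prompt[i], truth = questions$truth[[i]],
      ref_answer = questions$ref_answer[i], meta = questions$meta[[i]]),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a benchmark JSONL file
#'
#' @param path Path written by [write_benchmark()].
#' @return Question tibble.
#' @export
read_benchmark <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    tibble(id = x$id, category = x$category, prompt = x$prompt,
           truth = list(x$truth), ref_answer = as.character(x$ref_answer),
           meta = list(x$meta))
  })
  dplyr::bind_rows(rows)
}

#' Read a JSONL response file
#'
#' Each line must be an object with `id` and `response` fields.
#'
#' @param path Path to the response file.
#' @return Tibble with `id` and `response`.
#' @export
read_responses <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                  error = function(e) NULL)
    if (is.null(x) || is.null(x$id))
      abort(paste0("malformed response on line ", i), class = "chemquiz_schema_error")
    tibble(id = as.character(x$id),
           response = if (is.null(x$response)) NA_character_ else as.character(x$response))
  })
  dplyr::bind_rows(rows)
}

# Cheap deterministic content checksum for the manifest (no external
# digest dependency).
content_checksum <- function(text) {
  v <- utf8ToInt(paste(text, collapse = "\n"))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Benchmark manifest
#'
#' Records the configuration, category counts and fixture checksums so a
#' benchmark file can be traced to its inputs.
#'
#' @param config The `chemquiz_config` used.
#' @param questions The generated benchmark tibble.
#' @return A list suitable for JSON serialization.
#' @export
benchmark_manifest <- function(config, questions) {
  list(
    schema_version = "1",
    seed = config$seed,
    counts = config$counts,
    n_questions = nrow(questions),
    category_counts = as.list(table(questions$category)),
    fixtures = list(
      druglike = content_checksum(readLines(
        system.file("extdata", "druglike_synthetic.smi", package = "chemquiz"))),
      small = content_checksum(readLines(
        system.file("extdata", "small_cnho_synthetic.smi", package = "chemquiz")))
    )
  )
}
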