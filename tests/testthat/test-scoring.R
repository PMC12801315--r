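test_that("strict extraction takes only the mandated final answer line", {
  expect_identical(extract_answer("reasoning...\nAnswer: 7", "strict"), "7")
  expect_identical(extract_answer("Answer: 3\nmore\nAnswer: 7", "strict"), "7")
  expect_identical(extract_answer("answer:  CCO ", "strict"), "CCO")
  expect_true(is.na(extract_answer("the distance is 7 bonds", "strict")))
  expect_true(is.na(extract_answer(NA_character_, "strict")))
})

test_that("lenient extraction recovers answers from unformatted text", {
  expect_identical(extract_answer("the distance is 7 bonds", "lenient", "shortest_path"), "7")
  expect_identical(extract_answer("count 5 then 9 total", "lenient", "carbon_count"), "9")
  expect_identical(extract_answer("product is CCO I think", "lenient", "reaction"), "CCO")
  expect_identical(extract_answer("map: 1->2 and 2 -> 1", "lenient", "atom_map"),
                   "1->2, 2 -> 1")
  expect_identical(extract_answer("I believe it is\nethanol", "lenient", "iupac_zinc"),
                   "ethanol")

  # grammar fixture: 50 synthetic noisy numeric responses
  set.seed(404)
  for (k in 1:50) {
    val <- sample(1:50, 1)
    noise <- paste(sample(c("therefore", "we", "conclude", "path", "bond"),
                          5, replace = TRUE), collapse = " ")
    resp <- paste0("First I count 3 rings. ", noise, " so the result is ", val)
    expect_identical(extract_answer(resp, "lenient", "shortest_path"),
                     as.character(val))
  }
})

test_that("SMILES equivalence is representation-invariant", {
  expect_true(smiles_equivalent("OCC", "CCO"))
  expect_false(smiles_equivalent("CCO", "CCN"))
  expect_false(smiles_equivalent("not_a_smiles((", "CCO"))
  expect_identical(attr(smiles_equivalent("((", "CCO"), "note"), "unparseable")

  drug <- druglike_library()
  idx <- with_seed(3L, sample(nrow(drug), 200L, replace = TRUE))
  for (k in seq_along(idx)) {
    s <- drug$smiles[idx[k]]
    expect_true(smiles_equivalent(randomized_smiles(s, k)$text, s))
  }
  idx2 <- with_seed(5L, sample(nrow(drug), 200L, replace = TRUE))
  for (k in seq_along(idx2)) {
    other <- drug$smiles[if (idx2[k] == 1L) 2L else idx2[k] - 1L]
    expect_false(isTRUE(smiles_equivalent(drug$smiles[idx2[k]], other)))
  }
})

test_that("binomial confidence intervals match the closed form", {
  expect_equal(binomial_ci(50, 100), c(0.402, 0.598), tolerance = 1e-3)
  expect_equal(binomial_ci(0, 10), c(0, 0))
  expect_equal(binomial_ci(10, 10), c(1, 1))
  ci <- binomial_ci(75, 100)
  expect_equal(ci[2] - ci[1], 2 * 1.96 * sqrt(0.75 * 0.25 / 100), tolerance = 1e-12)
  expect_error(binomial_ci(0, 0))
})

test_that("one-tailed McNemar matches direct binomial-tail summation", {
  expect_equal(mcnemar_one_tailed(0, 0), 1)
  expect_equal(mcnemar_one_tailed(0, 5), 0.03125)
  expect_equal(mcnemar_one_tailed(5, 0), 0.03125)
  direct_tail <- function(b, c) {
    n <- b + c; k <- max(b, c)
    sum(vapply(k:n, function(x) choose(n, x) * 0.5^n, numeric(1)))
  }
  set.seed(77)
  for (rep in 1:50) {
    b <- sample(0:12, 1); c <- sample(0:12, 1)
    expect_equal(mcnemar_one_tailed(b, c), direct_tail(b, c), tolerance = 1e-12)
  }
})

test_that("score_benchmark aggregates exactly and validates inputs", {
  qs <- dplyr::bind_rows(
    gen_count_question("c1ccccc1", "carbon", 1L),
    gen_count_question("CCO", "carbon", 2L),
    gen_count_question("c1ccccc1-c1ccccc1", "ring", 3L),
    gen_count_question("c1ccc2ccccc2c1", "ring", 4L))
  qs$id <- sprintf("q-%d", 1:4)
  # constructed fixture with known k/n: two right, one wrong, one missing
  resp <- tibble::tibble(id = c("q-1", "q-2", "q-3"),
                         response = c("Answer: 6", "Answer: 3", "Answer: 2"))
  sc <- score_benchmark(qs, resp, "strict")
  expect_equal(sc$overall$k, 2L)
  expect_equal(sc$overall$n, 4L)
  expect_equal(sc$overall$accuracy, 0.5)
  expect_identical(sc$judgments$verdict[sc$judgments$id == "q-4"], "unparseable")
  expect_match(sc$judgments$note[sc$judgments$id == "q-4"], "missing")

  expect_error(score_benchmark(qs, dplyr::bind_rows(resp, resp[1, ]), "strict"),
               "duplicate")
  expect_error(score_benchmark(qs, tibble::tibble(id = "zz-9", response = "Answer: 1")),
               "unknown")
  # empty responses give zero accuracy
  sc0 <- score_benchmark(qs, tibble::tibble(id = character(0), response = character(0)))
  expect_equal(sc0$overall$accuracy, 0)
})

test_that("lenient mode never scores below strict mode", {
  qs <- dplyr::bind_rows(
    gen_count_question("c1ccccc1", "carbon", 1L),
    gen_count_question("CCO", "carbon", 2L),
    gen_count_question("c1ccccc1-c1ccccc1", "ring", 3L))
  qs$id <- sprintf("q-%d", 1:3)
  resp <- tibble::tibble(
    id = qs$id,
    response = c("Answer: 6", "I count carbons... total 7", "there are 2 rings here"))
  strict <- score_benchmark(qs, resp, "strict")
  lenient <- score_benchmark(qs, resp, "lenient")
  expect_gte(lenient$overall$k, strict$overall$k)
  expect_equal(lenient$overall$k, 2L)   # ring recovered, wrong carbon stays wrong
  expect_equal(strict$overall$k, 1L)
})

test_that("numeric comparison tolerates formatting", {
  q <- gen_count_question("c1ccccc1", "carbon", 1L); q$id <- "q-1"
  for (a in c("Answer: 6", "Answer:  6 ", "Answer: 6.0", "Answer: +6"))
    expect_identical(judge_response(q, a)$verdict, "correct")
  expect_identical(judge_response(q, "Answer: six")$verdict, "unparseable")
})

test_that("report tidiers and comparison behave", {
  qs <- dplyr::bind_rows(lapply(1:6, function(k)
    gen_count_question(druglike_library()$smiles[k], "carbon", k)))
  qs$id <- sprintf("q-%d", 1:6)
  good <- self_responses(qs)
  bad <- good; bad$response[1:3] <- "Answer: 0"
  sa <- score_benchmark(qs, bad)
  sb <- score_benchmark(qs, good)
  cmp <- compare_scores(sa, sb)
  ov <- cmp[cmp$category == "overall", ]
  expect_equal(ov$b, 0L); expect_equal(ov$c, 3L)
  expect_equal(ov$p, 0.125)
  same <- compare_scores(sa, sa)
  expect_true(all(same$p == 1))
  expect_s3_class(tidy(sb), "tbl_df")
  expect_equal(glance(sb)$accuracy, 1)
  expect_s3_class(autoplot(sb), "ggplot")
})
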