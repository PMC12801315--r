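# chemquiz

Short-answer organic-chemistry questions with machine-verifiable ground
truths, and a scorer for free-text answers.

Benchmarks for evaluating language models on chemistry are dominated by
multiple-choice general knowledge, which can be solved by elimination and
says little about whether a model can actually *read a molecule*.
`chemquiz` takes the other route: every question is generated
algorithmically from a molecular graph, so the ground truth is exact, the
question pool is unbounded (new sets from a new seed), and answers are
judged by structure — a SMILES answer by graph equivalence, a chemical
name by parsing it back to a structure, an atom mapping by verifying it
is an isomorphism. It is aimed at people building or evaluating
LLM/assistant systems for chemistry, and at anyone who needs paired,
reproducible molecular-comprehension tasks with exact answer keys.

## Question categories

| category | task | truth |
|---|---|---|
| `carbon_count`, `ring_count` | count carbons / rings in a SMILES | integer |
| `shortest_path` | bonds between two `*`-marked positions | integer (BFS distance) |
| `atom_map` | map atom positions between two SMILES spellings of one molecule | any automorphism-equivalent bijection |
| `iupac_zinc`, `iupac_fg`, `iupac_locant` | name the molecule | the structure (name parsed and compared as a graph) |
| `free_wilson` | predict an additive substituent-contribution score for an unseen R-group combination | integer (exactly determined by the 7 training rows) |
| `reaction` | product of one of nine undergraduate reaction classes | canonical product SMILES |
| `nmr_1d`, `nmr_2d` | structure from formula + simulated ¹H/¹³C (and COSY/HSQC/HMBC) peak lists | canonical SMILES |

The default build is 816 questions. Several categories are split 50/50
between canonical and randomized SMILES, which lets the same molecule be
probed with and without its familiar spelling; atom mapping splits between
fully randomized and "semicanonical" (random root, canonical traversal)
variants.

At the core sits a small molecular-graph engine: a SMILES parser/writer
pair in which every emitted string carries an `order_map` from string
position to atom id, exact canonicalization via BLISS canonical labelling
on a coloured auxiliary graph, and automorphism orbits for both
atom-mapping tolerance and NMR equivalence classes. A Free-Wilson score
for substituents s₁…s₃ at three scaffold positions is the additive model
y = μ + Σₚ v[p, sₚ]; the solver recovers the query value from seven
training rows by exact linear solve. Accuracy reports carry Wald 95%
intervals p̂ ± 1.96·√(p̂(1−p̂)/n) and paired reports are compared with an
exact one-tailed McNemar test, P(X ≥ max(b,c)), X ~ Binomial(b+c, ½).

## Worked example

```r
library(chemquiz)

cfg <- default_config(seed = 7L, counts = list(
  carbon_count = 5L, ring_count = 0L, shortest_path = 5L, atom_map = 0L,
  iupac_zinc = 0L, iupac_fg = 0L, iupac_locant = 5L, free_wilson = 5L,
  reaction = 0L, nmr_1d = 5L, nmr_2d = 0L))
bench <- generate_benchmark(cfg)

cat(bench$prompt[bench$category == "nmr_1d"][1])
#> A molecule has the molecular formula CH3NO. Its simulated NMR data (shifts in ppm) are:
#> 1H NMR: delta 9.80 (s, 1H); plus 2 exchangeable protons not shown
#> 13C NMR: delta 170.0
#> Determine the structure and write its SMILES string.
#> Give your final answer on the last line of your response, in the form "Answer: <your answer>".
```

One peak at 170 ppm, an aldehyde-like proton, two exchangeable H and a
CH₃NO formula: formamide. Scoring accepts `NC=O`, `C(N)=O` or any other
spelling of that graph. Feed the stored answer key back in (corrupting
one answer to show a miss):

```r
responses <- self_responses(bench)
responses$response[1] <- "Answer: 999"
report <- score_benchmark(bench, responses, mode = "strict")
report
#> <chemquiz_score> 24/25 correct (96.0%), mode = strict
#> # A tibble: 5 × 6
#>   category          n     k accuracy ci_low ci_high
#>   <chr>         <int> <int>    <dbl>  <dbl>   <dbl>
#> 1 carbon_count      5     4      0.8  0.449       1
#> 2 free_wilson       5     5      1    1           1
#> 3 iupac_locant      5     5      1    1           1
#> 4 nmr_1d            5     5      1    1           1
#> 5 shortest_path     5     5      1    1           1
```

`tidy(report)` returns the per-category table, `glance(report)` the
overall row, `autoplot(report)` a bar chart with the confidence
intervals, and `compare_scores(a, b)` the McNemar comparison of two runs.
`write_benchmark()` / `read_benchmark()` and `read_responses()` move
everything through JSONL; `inst/cli/chemquiz` wraps generate/score/compare
for shell use.

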