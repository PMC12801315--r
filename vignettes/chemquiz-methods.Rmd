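---
title: "Methods: generating and scoring verifiable chemistry questions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generating and scoring verifiable chemistry questions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemquiz)
```

## What the package does

`chemquiz` builds short-answer organic-chemistry question sets whose ground
truths are machine-verifiable, and scores free-text answers against them.
The benchmark probes three competencies: reading molecular structure out of
SMILES strings (counting, shortest paths, atom mapping), translating
structures into chemical language (systematic naming), and chemical
reasoning (additive structure-activity analysis, reaction products, NMR
structure elucidation). Every question is generated algorithmically from a
recorded seed, so the whole benchmark is reproducible from its
configuration alone, and fresh question sets can be produced at will.

The default build contains 816 questions in eleven category/sub-benchmark
groups: carbon counting (60), ring counting (60), shortest path (120, half
canonical and half randomized SMILES), atom mapping (72, half fully
randomized and half semicanonical), drug-like naming (200: 100 molecules
asked in both canonical and randomized form), functional-group naming (40),
locant naming (40), Free-Wilson analysis (40: half noise-free, half noisy),
reaction prediction (90: nine classes, five reactions each, both SMILES
modes), and NMR elucidation (44 questions from 1D spectra, 50 from 1D+2D
spectra). The total and the subset sizes of 100 naming molecules per mode,
50 2D-NMR structures, seven training molecules per Free-Wilson question and
five questions per reaction class are fixed contracts checked by the test
suite; the split of the remaining categories is a package choice,
adjustable in the configuration.

## The molecular graph engine

Molecules are attributed graphs: atoms carry element, formal charge,
aromatic flag and implicit-hydrogen count; bonds carry order (single,
double, triple, aromatic). The SMILES parser covers the organic subset,
bracket atoms, ring closures, branches and multi-fragment input, and
strips stereochemistry on ingestion — no task in the benchmark has a
stereochemical ground truth, so a single achiral graph per molecule keeps
every comparison unambiguous. Aromaticity written in Kekulé form is
perceived for five- and six-membered rings with a simple electron count
(endocyclic double bond = 1 π electron, heteroatom lone pair = 2, an
exocyclic double bond blocks the ring); this is deliberately narrower than
a full aromaticity model but covers the chemotypes the generators emit and
the common ways an answer might be spelled.

Canonical atom ranking is delegated to the BLISS canonical-labelling
algorithm (via igraph) on an auxiliary coloured graph: atoms are coloured
by (element, charge, aromaticity, H count) and each bond contributes one
extra vertex coloured by bond order, so vertex colours alone encode the
full attributed graph. This gives exact, input-order-invariant
canonicalization — the round trip `canonical(randomize(m)) == canonical(m)`
is tested over the fixture libraries, and agreement with OpenBabel's
independent canonicalization and InChI is cross-checked in the test suite.

Three writers share one depth-first renderer that records the atom order
of appearance, so every string comes with an `order_map` (string position
to atom id):

* **canonical** — root at the atom of smallest canonical rank (wildcard
  dummy atoms take precedence, so marked positions always start the
  string), neighbours visited in rank order;
* **randomized** — seeded random root and neighbour order;
* **semicanonical** — seeded random root, canonical order thereafter, so
  large substructures keep their canonical spelling.

## Question categories and their ground truths

**Counting.** Carbon counts and ring counts (cycle rank: bonds − atoms +
components, which equals the smallest-set-of-smallest-rings size for the
fixture chemistry — cross-checked against RDKit's SSSR in the tests; the
fixture recipes cannot produce the cage systems where the two definitions
diverge, and molecules never exceed six rings).

**Shortest path.** Two hydrogen-bearing positions are chosen at random and
marked with wildcard `*` atoms; marking attaches a dummy rather than
substituting an atom, so the parent molecule is intact and the reported
distance includes both attachment bonds. The truth is the BFS distance
between the two dummies, verified against exhaustive simple-path
enumeration on all small instances.

**Atom mapping.** The molecule (8–24 heavy atoms) is written as two
different strings; positions are heavy atoms numbered 1-based in order of
appearance, as stated in the prompt. The stored truth composes the two
order maps, but scoring accepts *any* mapping whose induced atom
correspondence preserves elements and bonds — i.e. the truth composed with
any graph automorphism — so molecular symmetry is never penalized. On
small symmetric fixtures the set of accepted mappings is verified to be
exactly the automorphism coset by exhaustive enumeration.

**Naming.** The truth payload of every naming question is a structure,
never a name string: an answer is correct iff it parses to the intended
graph. Name parsing is done by the package's own restricted
systematic-nomenclature parser, which covers detachable substituent
prefixes from the 40-group library (with multipliers and locants) on
benzene, pyridine, naphthalene and quinoline, simple chain parents with
one principal characteristic group, and a few retained names. The
generators emit only names inside this grammar, and every generated
molecule's reference name is validated by round trip at build time. The
40-entry functional-group roster (halogens, nitro, cyano, hydroxy, amino,
alkyl/alkoxy, acyl, ester, amide, sulfonyl, aryl, and relatives) is a
package choice satisfying the stated cardinality; each entry is singly
attaching and benzene-compatible. Locant questions place three halogens
(drawn with replacement from F/Cl/Br/I) on distinct CH positions using the
standard numbering of each scaffold; ring nitrogens are never substituted.
Accepting any structurally correct name (rather than one preferred
spelling) is the design point; locant conventions such as lowest-locant
numbering are therefore not enforced on answers.

**Free-Wilson.** The scaffold is benzofuran with three substitution sites
(two benzo CH positions and the furan 2-position), each taking one of
{F, Cl, Br}; per-position substituent values are integers drawn uniformly
from 1–20, chosen to keep prompts human-legible, and a molecule's score is
their sum. Eight distinct combinations are drawn; the model is
reparameterized (intercept + two indicator contrasts per position = seven
parameters) and combinations are redrawn until the seven training rows
have full rank, so the query is pinned by construction, not by luck. The
noisy variant adds rounded unit-variance Gaussian noise to the *displayed*
training scores only; the truth stays the noise-free sum and scoring
allows ±2 units (noise-free questions require exact match). The noise
magnitude and tolerance are package choices: under them the analytic
solver stays within tolerance for well over 95% of seeds, which the test
suite checks, and noise-free parameter recovery is exact across 1000
seeds.

**Reactions.** Nine undergraduate classes: SN2 hydroxide substitution,
copper-catalyzed azide–alkyne click (always the 1,4-regioisomer, asserted
structurally on every instance), Simmons–Smith cyclopropanation,
Suzuki–Miyaura coupling, plus five package-chosen classes in the same
spirit of unambiguity — amide formation from an acid chloride, reductive
amination, Fischer esterification, Grignard addition to a ketone, and
Wittig olefination (stereochemistry stripped). Each template pairs small
reactant pools with a graph rewrite that yields exactly one sanitizable
product; reagents and conditions appear as plain text, never as SMILES to
transform. Heavy-atom balance up to each template's declared leaving
groups is asserted over every pool combination.

**NMR.** Equivalent nuclei are automorphism orbits of the molecular graph
(implicit hydrogens inherit their parent atom's orbit; geminal and
homotopic protons never split each other). Chemical shifts come from
deterministic additive increment tables — a base value per environment
(sp³/alkene/alkyne/aromatic/carbonyl/nitrile for ¹³C; CH₃/CH₂/CH, aromatic,
aldehyde, O–H/N–H classes for ¹H) plus neighbour increments for
heteroatoms, conjugation and halogens — rounded to 0.01 ppm (¹H) and
0.1 ppm (¹³C). The published simulators' methods are not reproduced here;
what the task needs is chemical plausibility and discriminability, since
scoring is structure-based. Classes closer than 0.05 ppm (¹H) / 0.5 ppm
(¹³C) are pushed apart deterministically in descending-shift order, so no
two inequivalent classes coincide. Multiplicities follow the n+1 rule over
vicinal protons on carbon: one coupling-partner class with n = 0–4 protons
gives s/d/t/q/quint, anything larger or mixed inequivalent partners is a
multiplet, and exchangeable protons (on N/O/S) are broad singlets that are
*omitted* from the peak list — the solver must notice the gap between the
formula's H count and the total integration, mirroring how such questions
are reasoned about in practice. COSY correlates vicinal proton classes,
HSQC pairs each proton class with its directly bonded carbon, HMBC spans
two to three bonds and excludes every one-bond pair. 1D questions draw
from the small C/H/N/O library (≤10 heavy atoms), 2D questions from the
drug-like library (≤30 heavy atoms); within one build no two NMR questions
share an identical rendered spectrum set (non-discriminating draws are
skipped).

## Scoring

Responses must end with an `Answer: <...>` line; strict extraction reads
only that. Lenient extraction falls back to a category-aware search (last
number, last parsable SMILES token, last `i->j` pair list, last non-empty
line for names) and, by construction, never scores below strict mode. A
missing or unextractable answer is an incorrect answer — benchmarks
containing failed generations still total correctly. Numeric comparison
tolerates whitespace, signs and trailing `.0`; structure comparison is
canonical-graph equality after stereo stripping; name answers go through
the nomenclature parser. Aggregation reports per-category and overall
accuracies with Wald 95% confidence intervals (p̂ ± 1.96·SE, clipped to
[0, 1]), and paired score reports are compared with an exact one-tailed
McNemar test, P(X ≥ max(b, c)) for X ~ Binomial(b + c, ½).

## Fixture libraries

No external molecule collections are downloaded. The drug-like library
(520 molecules, 10–30 heavy atoms) is generated by
`tools/make_fixtures.R` from aromatic scaffold + substituent recipes —
each member therefore ships with a reference systematic name derived from
its construction, which self-scoring of naming questions requires. The
small library (155 molecules, C/H/N/O, ≤10 heavy atoms) is a curated
enumeration of common functional-group chemotypes. Both files are
tab-separated plain text under `inst/extdata/`, flagged as synthetic in
their headers. What passing tests on these libraries shows is that the
machinery is correct on polysubstituted-aromatic and small-molecule
chemistry; it does not certify behaviour on chemotypes outside the
recipes (fused aliphatic systems, charged drugs, organometallics beyond
the reaction reagents).

## Numerical and degenerate-input choices

* Atom ids are 1-based in prompts and ground truths, 0-based nowhere;
  positions count heavy atoms in order of appearance in the string.
* Seeds: one master seed fans out to per-category and per-question seeds
  (recorded in each question's metadata), all below 2³¹.
* Degenerate draws are resampled with bounded retries: identical variant
  pairs in atom mapping, substitution sites without a free valence,
  rank-deficient Free-Wilson designs, duplicate reactant draws,
  non-discriminating NMR spectra. Every such path has a hard error behind
  it rather than silent acceptance.
* Valence sanitization accepts any consistent reading of aromatic bond
  contributions (lone-pair donor vs. fusion atom); parse failures are
  signalled with a dedicated condition class and treated by the scorer as
  wrong answers, never crashes.
* Problem sizes in the routine test run are scaled to the property being
  checked: canonicalization round trips over 100 fixtures, Free-Wilson
  recovery over 1000 seeds, exhaustive automorphism enumeration only on
  molecules small enough for complete permutation search.

## Known limitations

* The name grammar is a subset of IUPAC nomenclature; valid names outside
  it (e.g. fused-ring von-Baeyer names, substituent nesting with bis/tris)
  are scored as unparseable. For the generated benchmark this is
  irrelevant — every reference name lies inside the grammar — but scoring
  arbitrary model output will under-credit exotic spellings.
* NMR shifts are plausible, not literature-accurate; they are stable
  anchors for structure elucidation, not predictions.
* The drug-like library is a synthetic stand-in: it matches the intended
  size and element profile but not the scaffold diversity of a real
  screening collection.
* Aromaticity perception covers 4n+2 counts of 6 on 5/6-membered rings;
  azulenes, tropylium and similar systems are out of scope.
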