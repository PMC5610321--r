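---
title: "Multiple encoding vectors: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple encoding vectors: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mevtree)
```

## The model

`mevtree` compares DNA sequences without aligning them. A sequence
*Q* = (*s₁*, …, *sₙ*) is recoded three times, once per binary property of the
bases:

* **R/Y** — purines {A,G} vs pyrimidines {C,T};
* **M/K** — amino {A,C} vs keto {G,T};
* **S/W** — strong H-bond {G,C} vs weak H-bond {A,T}.

Each recoding turns *Q* into a two-letter string, and each of the six letters
*L* is summarised by three numbers computed over the positions *i* where the
letter occurs:

* the count `n_L`;
* the mean position `μ_L`;
* the scaled second moment `D₂^L = Σ (i − μ_L)² / (n_L · n)` — the variance
  of the letter's positions divided by the sequence length.

The 18 numbers, concatenated in the fixed order R, Y, M, K, S, W as
(count, mean, moment) triplets, form the *multiple encoding vector*. The
three encodings are redundant views of the same four-letter composition
(knowing any two determines per-base counts), but their positional moments
are not: together they capture where each chemical class of base concentrates
along the molecule, which plain k-mer composition ignores.

Two sequences are compared by the Euclidean distance between their vectors;
a set of sequences becomes a symmetric distance matrix; and the matrix is
clustered by UPGMA into a rooted, ultrametric binary tree. UPGMA's implicit
assumption — an approximately constant divergence rate across lineages — is
inherited by the whole pipeline.

### Assumptions and limitations

The vector is **length-sensitive by construction**: counts grow like *n*,
mean positions like *n*/2 and `D₂` like *n*/12. Two sequences that differ
mostly in length are far apart regardless of homology, so inputs should be
approximately complete, comparable units (whole genomes, whole chromosomes,
or the same intact gene in every taxon). Partial or truncated records will
distort the tree. There is no model-based correction for multiple
substitutions either: distances are raw feature-space geometry, not expected
substitution counts, so branch lengths are descriptive rather than
evolutionary time.

The method also assumes a single contiguous coordinate system per taxon.
Multi-chromosome genomes must be reduced to one comparable sequence per taxon
(e.g. the same chromosome for all taxa) before encoding.

## The FFP baseline

For comparison the package ships the classical k-mer approach: the *feature
frequency profile* of a sequence is the relative frequency of its
`n − k + 1` overlapping k-mers, and two profiles are compared by
Jensen–Shannon divergence

JSD(p, q) = H((p+q)/2) − (H(p) + H(q))/2,

with entropies in bits so that the divergence lies in [0, 1]. The word length
follows the rule `k = floor(log₄ n)` applied to the minimum sequence length
in the dataset — the k at which the 4^k possible words roughly match the
number of word occurrences. `ffp_distance()` accepts an explicit `k`
override for experimentation.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `normalize` | `mev_encode()` | `FALSE` | divide all 18 features by `n`. The raw vector is the method's definition and what all tests exercise; the normalized variant is offered because the features have incommensurate magnitudes (counts ~n, means ~n/2, moments ~n/12) and a scale-free view can help when lengths differ by design. It is off by default and excluded from the validated behaviour. |
| `k` | `ffp_distance()` | `choose_k(min length)` | k-mer word length (bases). |
| `n_clades`, `taxa_per_clade` | `simulate_clades()` | — | planted design shape. |
| `sequence_length` | `simulate_clades()` | — | bases; all simulated sequences share it exactly (see below). |
| `within_rate`, `between_rate` | `simulate_clades()` | — | per-site substitution probabilities in [0, 1), clade ancestor → taxon and root → clade ancestor respectively; `between_rate > within_rate` is enforced because it is the separability condition that makes a planted partition meaningful. |
| `seed` | simulator, CLI | — | every random draw derives from it through stable sub-seeding, so a dataset is a pure function of (design, seed). |

## Numerical choices

* **Positions are 1-based** (`i = 1..n`), matching the definition of the
  moments.
* **Empty letters.** When a letter never occurs, `μ_L` and `D₂^L` are 0/0.
  Both are defined as 0 — the natural "no positional mass" limit — so vectors
  stay finite and comparable. Any constant would do; 0 keeps distances small
  between sequences that both lack a letter.
* **Ambiguity codes.** The moments are defined only for classified bases, so
  characters outside {A,C,G,T} are removed before indexing (with a per-record
  count and warning) rather than kept as zero-weight placeholders, which
  would shift every downstream position. RNA `U` is silently mapped to `T`.
* **Stable second moment.** `D₂` is computed in the centered two-pass form
  `Σ(pos − μ)²` rather than the one-pass `Σi² − n_L μ²`, which loses up to
  ~10 significant digits to cancellation at 10 Mb scale. A test pins the two
  forms against each other (1e-9 relative) at sizes where doubles are exact.
  The count–length product in the denominator is accumulated in doubles;
  32-bit integer arithmetic would overflow beyond ~46 kb.
* **`choose_k` epsilon.** `floor(log₄ n)` is evaluated with a +1e-9 nudge so
  that exact powers of 4 (where the logarithm lands on an integer up to
  floating error) are not rounded down.
* **JSD base and clamping.** Entropies use log base 2, giving the
  conventional [0, 1] range (the base rescales all distances uniformly and
  cannot change a UPGMA topology). The result is clamped to [0, 1] to absorb
  last-ulp floating noise at the boundaries.
* **Sparse profiles.** k-mer counting is dense (a 4^k table via
  `Biostrings::oligonucleotideFrequency`) but only observed words are stored,
  so k = 9 profiles (262144 possible words) stay small.
* **UPGMA tie-breaking.** When several pairs attain the minimal distance,
  the lexicographically smallest (row, column) pair in current cluster order
  is merged. The update is the size-weighted arithmetic mean (true UPGMA,
  not WPGMA). Any consistent tie rule yields a valid UPGMA tree; fixing one
  makes every output byte-reproducible. Other implementations may break ties
  differently, so agreement with them is contractual at topology level, not
  at the Newick-string level.
* **Degenerate inputs.** Empty sequences, duplicate ids, non-square or
  asymmetric matrices, negative or non-finite distances, and k larger than a
  sequence are all rejected with errors naming the offender; a 2-taxon matrix
  is the smallest accepted tree problem.

## What the simulator does and does not emulate

`simulate_clades()` plants a star-of-stars: a uniform random root, one
ancestor per clade at `between_rate` substitutions from the root, and taxa at
`within_rate` from their clade ancestor. That reproduces the *shape* of a
clustered dataset — tight groups separated by larger distances — which is
exactly what the clustering claims of the method need for validation.

It deliberately omits much of real molecular evolution: no indels (the
encoding is length-sensitive, so holding length fixed isolates the
substitution signal), no transition/transversion bias or rate heterogeneity
(uniform replacement among the three alternatives), no GC-content skew
(uniform root), and no nested clade structure below the planted level.
Passing the planted-partition tests therefore shows the pipeline separates
substitution-structured groups under equal lengths; it does not certify
performance on real genomes with unequal lengths, indels or compositional
bias — on real data the completeness caveat above is the binding constraint.

## Validation design

The test suite checks, at sizes chosen to run in seconds to a few minutes on
one CPU:

* hand-worked values: the 18-vector of `ATGC`, letter statistics of
  homopolymers, a 3-taxon UPGMA execution, a closed-form JSD value;
* exhaustive agreement of the encoder with a definitional brute-force oracle
  on *all* sequences of length ≤ 6, plus randomized longer cases;
* algebraic invariants: per-scheme count conservation
  `n_L + n_L' = n`, the position-mass identity
  `n_Lμ_L + n_L'μ_L' = n(n+1)/2`, reversal symmetry (`μ → n+1−μ`, counts and
  `D₂` invariant), and the bound `D₂ ≤ (n−1)²/(4n)`;
* metric axioms of the distance matrix, ultrametricity and monotone merge
  heights of UPGMA, exact cophenetic reconstruction of ultrametric inputs,
  and agreement with a recompute-from-scratch UPGMA oracle on ≤ 8 taxa and
  with an independent implementation (phangorn) at topology level;
* planted-partition recovery at the reference design (3 clades × 4 taxa,
  5 kb, 1% within, 15% between) for both pipelines;
* a timing sanity check that 59 synthetic 1 Mb sequences encode within five
  minutes — the package's scaled stand-in for bacterial-genome workloads.

```{r example}
seqs <- simulate_clades(3, 4, 5000, within_rate = 0.01, between_rate = 0.15,
                        seed = 42)
tree <- mev_upgma(mev_distance(mev_encode(seqs)))
partition_rf(clade_partition(tree, 3),
             dplyr::transmute(seqs, id, cluster = clade))
```
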