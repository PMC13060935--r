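---
title: "Resolving assembly-graph tangles from coverage and read alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving assembly-graph tangles from coverage and read alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long, highly similar genomic repeats collapse in assembly graphs into
*tangles*: small subgraphs whose internal traversal is ambiguous, leaving
gaps between contigs in scaffolded telomere-to-telomere assemblies. The
information needed to choose a traversal is usually present but fragmented:
sequencing depth constrains how many times each collapsed edge must be
walked, and long-read-to-graph alignments constrain the local order of
walks. `tanglepatch` combines the two into a single best-supported
traversal and emits it as a standalone *model sequence* — plausible and
data-consistent, but by construction not guaranteed correct, which is why it
is never patched into a scaffold automatically.

## Graph representation

GFA stores sequence on nodes. All algorithms here run on the dual
representation: junctions become vertices and each segment one edge,
available in both orientations. Internally every junction is represented by
two mirror-image *oriented vertices* (`v7a`/`v7b`), one per reading
direction, which makes the directed structure of the bidirected graph
explicit: a walk that is legal forward is legal reverse-complemented with
all orientations flipped. Junction identity is the transitive closure of the
link relation over segment ends; link overlaps (CIGAR `<int>M`) are stored
and consumed only when sequence is emitted, so the multiplicity and path
stages are overlap-agnostic.

Within one tangle the simplifying assumption is made that only one of an
edge and its reverse complement is reachable from the boundary; a consistent
orientation frame is propagated across the tangle and a conflict (an
inverted repeat inside the tangle) marks it unsupported rather than
producing a wrong answer.

## Tangle detection

A tangle is delimited by *unique* boundary edges — edges expected exactly
once in the finished genome. Uniqueness is called from length and coverage:

| parameter | default | meaning |
|---|---|---|
| `min_unique_len` | 100 kbp | length floor for unique edges |
| `unique_cov_window` | 0.7–1.3 × median | coverage window around the median coverage of long edges |
| `max_tangle_fraction` | 0.2 | tangle length ≤ this fraction of its component |

The defaults suit mammalian-scale HiFi graphs; the test fixtures override
`min_unique_len` and `max_tangle_fraction` because their flanks are only
hundreds of bases long. Candidates are grown from non-unique edges, stopping
at unique edges; the frontier unique edges become the boundary, so the
boundary set is minimal by construction. Tangles whose boundary is not two
or four unique edges (one or two traversal paths) are reported but flagged
unresolvable. The expected per-traversal coverage Cov_u is the median
coverage of the boundary edges unless supplied by the user.

Detection is purely structural; it deliberately does not use scaffold paths
(which is how boundary pairs would be matched in a production assembly
workflow), so for four-boundary tangles the x–y pairing is chosen by the
optimiser (both pairings are scored; see below).

## Multiplicity estimation

With unknown integer multiplicities `mult(e)` the model is

- flow conservation at every tangle vertex (boundary edges fixed at 1),
- `mult(e) ≥ 1` for *reasonably covered* edges, `cov(e) ≥ 0.5·Cov_u`
  (`rc_threshold`, inclusive),
- objective `min Σ_e |cov(e)/Cov_u − mult(e)|`.

Flow conservation is what rescues the estimate when naive rounding fails:
at a vertex with two incoming and one outgoing edge all near Cov_u, rounding
gives multiplicities (1, 1, 1), which no traversal realises; the optimum
under flow constraints doubles the outgoing edge at objective cost 1.

The program is solved exactly rather than through an external MILP backend.
The constraint matrix is a directed incidence matrix, so the solution set is
a particular solution plus the cycle space of the tangle: after choosing a
spanning forest, fixing the non-tree ("free") edges forces every tree edge
by peeling leaves. The solver enumerates free-edge values in increasing
per-edge cost with branch-and-bound pruning against a per-edge lower-bound
table. On tangle-scale problems (tens of edges, cycle rank well below that)
this is exact and fast; the test suite verifies objective equality with
brute-force enumeration on hundreds of random tangles. A per-tangle time
limit (`milp_time_limit`, default 300 s) returns the best incumbent with a
warning in the degenerate case.

Numerical choices: multiplicities are bounded above by
`ceiling(4·max(cov)/Cov_u)` (at least 2) — a generous envelope around the
coverage signal; objective comparisons use a 1e-12 strict-improvement
margin; ties between optima are resolved by the deterministic search order
(value candidates sorted by cost, edges by spanning-tree order). Among
score-equivalent optima the choice is immaterial downstream: only read
support distinguishes traversals.

If the strict problem is infeasible — two reasonably covered edges that
cannot both be traversed — the at-least-once constraints are dropped and the
solve repeated (`relaxed = TRUE` in the report). If even the relaxed
problem is infeasible (no x→y path at all) the tangle is reported
unsolvable and skipped; the batch continues.

`tune_cov_u = TRUE` re-solves over {0.9, 1.0, 1.1}×Cov_u and keeps the
lowest objective. It is off by default: the grid is a crude proxy for
coverage mis-estimation and silently changing the normaliser makes reports
harder to compare.

## Finding the best traversal

Each edge of multiplicity *n* expands to *n* identical multiedges; edges of
multiplicity 0 are removed. Flow conservation plus connectivity of the
positive-multiplicity edges guarantees an Eulerian path from the end of the
incoming boundary edge to the start of the outgoing one, found by
Hierholzer's algorithm with seeded random multiedge choice — different seeds
give different valid starting paths.

The *swap* move exchanges two non-overlapping step intervals that start at
the same vertex A and end at the same vertex B. It preserves the multiset
of edges and vertex adjacency — it reorders repeat units. Swaps connect the
whole Eulerian path space with fixed endpoints (any path can be transformed
into any other by iteratively extending the common prefix with swaps;
`check_swap_connectivity()` verifies this constructively on every
enumerable instance in the test corpus). Hill-climbing therefore has no
unreachable optimum, though it can still stall in a local one.

Scoring: a read supports a path if its walk (the alignment's path column,
clipped to the tangle plus boundary) occurs as an exact contiguous substring
of the path in the alphabet of oriented edge labels. Matching is done with
an Aho-Corasick automaton over edge-label tokens; each read also has its
reverse-complement pattern tried (strand is unknown) and counts at most
once. Inexact matching is deliberately out of scope — exact substring
semantics is what makes multi-pattern matching cheap enough to sit inside
the optimisation loop.

The search applies the first strictly score-improving swap of a randomly
shuffled scan and stops when a full scan finds none; first-improvement was
chosen over best-improvement because scans are cheap and gradients short. A
cap of 10,000 accepted swaps per restart is a safety valve only (scores are
integers bounded by the read count, so termination is guaranteed anyway).
Default `restarts = 10`, `seed = 42`, both exposed; the best final score
across restarts wins, ties broken by the lexicographically smallest label
sequence, which makes the whole pipeline deterministic given its inputs.

## Two-path (four-boundary) tangles

Tangles shared by both haplotypes are traversed by two genomic paths. The
joint model keeps one multiplicity budget: all four boundary edges are fixed
at multiplicity 1 and one MILP is solved; flow conservation then forces two
unit paths. For traversal the two paths are represented as a single
combined path joined through a sentinel connector step, so a single swap
mechanism covers both within-path reordering and the exchange of
same-endpoint subpaths between paths, and the sentinel token (never part of
a read pattern) stops matches from spanning the junction between paths. Both
ways of pairing sources with sinks are optimised and the better-scoring one
kept. This is the minimal extension consistent with the joint flow
constraints; richer diploid-aware formulations are future work.

## Reference-free metrics

Two per-tangle metrics are reported, never thresholded:

- **coverage divergence** — `Σ_e |cov(e)/Cov_u − mult(e)| / |E|` over tangle
  edges: how far the accepted copy numbers sit from the raw coverage signal;
  sensitive to coverage non-uniformity.
- **unsupported read fraction** — the fraction of tangle read walks that are
  not exact substrings of any output path (0 by convention, flagged, when
  there are no alignments).

High values indicate either a questionable traversal or an intrinsically
hard tangle; the two cannot be separated without a reference, so no
pass/fail recommendation is made.

## The synthetic fixture generator

`plant_repeat_tangle()` emulates the situation the tool targets: a tandem
array of `n_units` near-identical units (point mutations at rate
`divergence`) flanked by unique sequence, collapsed by exact k-mer collapse
— a forward-strand de Bruijn graph compacted into unitigs (`k = 21` at toy
scale). Coverage is planted as `mult · Cov_u · (1 + ε)`, ε ~ U(−0.1, 0.1),
exercising the solver's rounding robustness; `divergence = 0` collapses the
array into a single repeat edge of multiplicity `n_units`, the hardest,
most homogeneous case. Read walks are exact subpaths of the true traversal
(2 to `max_len` steps): the pipeline consumes aligner output, so base-level
read errors are out of scope. `random_tangle_fixture()` complements this
with arbitrary small topologies (parallel edges, loops) built from a random
planted traversal, used for property tests of the solver and optimiser.

What passing on these fixtures does *not* show about real data: coverage
bias beyond ±10% multiplicative noise, alignment errors and chimeric walks,
haplotype-imbalanced coverage, inverted repeats, and collapse models other
than exact k-mer identity (real multiplex-DBG graphs have variable-order
structure). The end-to-end tests show the machinery is correct under the
model's assumptions, not that the assumptions hold for any particular
genome.

## Problem sizes used in the tests

The test suite and acceptance script run entirely on generated fixtures:
200 random tangles (3–8 edges) checked against brute-force enumeration of
every bounded multiplicity vector; 1,000 seeded Eulerian draws replayed;
a 50-multigraph corpus (≤ 8 multiedges, ≤ 30 Eulerian paths each, so the
all-ordered-pairs check stays enumerable) for swap-connectivity; 500
scoring instances against a sliding-window oracle; 100 tiny instances for
global-optimum reachability with 10 restarts; and 50 planted repeat arrays
(3 units × 120 bp, 3% divergence, 80 reads of 3–10 steps) recovered end to
end byte-identically, plus a short-read arm (2-step walks) checking that
sequence content — total length and every planted variant allele with its
k-flank context — is preserved even when unit order cannot be pinned down.
The content check is the honest form of the order-free guarantee: when one
unit carries two mutations separated by a collapsed stretch longer than k,
a legal traversal can recombine alleles between units, so whole-unit
containment is not implied by the model.

## Known limitations

- Tangles with other than two or four boundary nodes, inverted repeats
  inside a tangle, and inter-chromosomal repeats are detected but refused.
- The exact solver's worst case is exponential in the tangle's cycle rank;
  beyond the scales tested (dozens of edges) the time limit may bind and
  yield an incumbent rather than a proven optimum.
- Boundary-pair matching for four-boundary tangles is score-based, not
  scaffold-based.
- Coverage is taken from a single technology; multi-platform joint
  estimation is not modelled.
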