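---
title: "Enumerating all maximum cliques in correlation graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating all maximum cliques in correlation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcenum)
```

## Why enumerate every maximum clique

Thresholding a gene co-expression matrix produces an unweighted graph whose
densest fully connected subgraphs — cliques — are candidate co-response
modules. Pipelines that extract *a* maximum clique are not reproducible
across implementations, because real correlation graphs typically contain
several maximum cliques, and which one a solver returns is an accident of
traversal order. `mcenum` therefore solves maximum clique *enumeration*:
find ω(G), the clique number, and return every clique of that size.

The worst case is daunting — a graph on n vertices can hold 3^(n/3) maximal
cliques, and the Moon–Moser family (`moon_moser_graph()`) attains that
bound — but real correlation graphs have exploitable structure: their
maximum cliques overlap heavily, usually inside one dense region. Every
algorithmic layer in this package is aimed at that structure.

## The algorithms

### Basic backtracking

`enumerate_maximal_cliques()` is the classic Bron–Kerbosch recursion over
three vertex sets: COMPSUB (the clique being built), CANDIDATES (vertices
adjacent to all of COMPSUB, not yet tried), and NOT (vertices adjacent to
all of COMPSUB that have already headed their own branch). When CANDIDATES
and NOT are both empty, COMPSUB is maximal; NOT exists so no maximal clique
is reported twice. A pivot vertex chosen from CANDIDATES ∪ NOT with the
most neighbors among CANDIDATES restricts branching to its non-neighbors,
which realizes the standard early termination: if some member of NOT is
adjacent to every candidate, the branch dies immediately. Ties everywhere
break toward the lowest canonical vertex index, so search-node counts and
output order are deterministic. Cliques stream to an optional callback as
found; nothing obliges the caller to hold the full (possibly astronomically
large) collection in memory.

### Maximum Clique Finder

`find_maximum_clique()` finds one witness and ω(G):

1. **Greedy lower bound** (`greedy_clique()`): start with the
   highest-degree vertex and its highest-degree neighbor, then repeatedly
   add the highest-degree vertex adjacent to the whole clique, discarding
   incompatible vertices each round. Degrees are recomputed in the
   shrinking residual subgraph; ties break by lowest index.
2. **Preprocessing** with the bound k: vertices of degree < k − 1 are
   peeled (`peel_low_degree()`); universal vertices (degree n − 1) are
   forced into every maximum clique and set aside
   (`extract_universal()`); each vertex whose closed neighborhood
   greedy-colors with fewer than k colors is excluded
   (`color_exclude()`) — a k-clique needs k distinct colors, so such a
   vertex cannot be in one. The coloring is first-fit over the closed
   neighborhood in descending induced degree, ties by lowest index: the
   classical largest-first heuristic, chosen for determinism and speed
   rather than coloring quality, since any proper coloring gives a valid
   upper bound.
3. **Branching**: in-or-out recursion on the candidate vertex with the
   most remaining co-candidates. A node dies when |C| + |P| cannot beat
   the best size found. Within each node, cheap rules re-run: candidates
   that cannot head a good-enough clique are dropped, candidates adjacent
   to all other candidates are forced in, and — because only one witness
   is needed — a candidate missing exactly one other candidate (degree
   n − 2 within P) has its lone non-neighbor discarded.

Coloring exclusion is applied once at the root rather than per node: on the
small residual graphs left after peeling, per-node coloring costs more than
the nodes it saves. The greedy bound is not re-run at internal nodes; the
incumbent is updated only when branching itself finds a larger clique.

### Intelligent backtracking

Knowing k = ω(G) turns Bron–Kerbosch into a maximum-clique enumerator with
one cut: any node where |COMPSUB| + |CANDIDATES| < k cannot produce a
maximum clique. `mcenum` applies the cut child-side — a child that cannot
reach k is never visited and contributes no search node — and first shrinks
the graph with `color_exclude()` at the true k. The NOT-based maximality
pruning is kept; the cut is an addition, not a replacement.

### Parameterized enumeration

`enumerate_maximum_cliques(g, "parameterized")` converts the MCF branching
into an enumerator: a global list holds all cliques of the largest size
found so far; finding a strictly larger clique flushes and refreshes the
list. Two soundness changes distinguish it from the single-witness search:
the pruning bound admits ties (a branch is cut only when |C| + |P| is
*strictly* below the incumbent size, so co-maximum cliques survive), and
the degree n − 2 lone-non-neighbor rule is disabled once branching begins —
it assumes a single witness suffices and would silently discard any clique
through the removed vertex. The 4-cycle is the minimal counterexample
(every vertex has degree n − 2, yet all four edges are maximum cliques) and
is pinned in the tests. Universal vertices extracted before branching are
re-attached to every reported clique. Emitted member sets are
canonicalized and deduplicated; in-or-out branching visits each vertex
subset along at most one decision path, so duplicates should not arise, but
the collection container enforces it regardless.

## Reductions that preserve every maximum clique

A **maximum clique cover** (MCC) is a vertex set intersecting every maximum
clique. `mcc_cover()` builds one greedily — find a maximum clique, delete
it, repeat until ω drops — and `mcc_reduce()` removes every vertex neither
in the cover nor adjacent to it. In practice the cover's neighborhoods
blanket most of the graph, so little is removed; the concept earns its keep
by leading to the vertex-level refinement.

An **essential vertex** lies in every maximum clique, equivalently
ω(G) > ω(G − v). `essential_set()` tests only the members of one maximum
clique found by MCF (essential vertices must lie in it), so k deletion
tests replace n. `es_reduce()` removes all non-neighbors of each essential
vertex; since every maximum clique contains the essential vertex, none is
lost, and the residual is often a small fraction of the input. One pass
already preserves all maximum cliques; `iterate = TRUE` re-runs to a fixed
point as an optional optimization. Essential vertices are mutually
adjacent, so the reduction can never remove one.

## Building graphs from expression data

`correlate()` computes Pearson correlations between probe rows across
conditions, `threshold_graph()` keeps edges with weight **at or above** the
threshold t (inclusive), and `build_correlation_graph()` chains the two.
Choices a user should know about:

- **Missing values** use pairwise-complete observations; pairs with fewer
  than 3 complete condition pairs, or zero variance, have no defined
  correlation and are omitted (and listed in the `omitted` attribute).
  With complete data, pairwise-complete equals full-vector correlation.
- **P-value mode** (`weight_kind = "pvalue"`, the right choice when data
  are missing, since supports differ across pairs) computes the two-sided
  p-value of r from t = r√((s−2)/(1−r²)) on s − 2 degrees of freedom; the
  threshold direction flips to at-or-*below* t.
- **Signed thresholding** is the default (r ≥ t keeps only positive
  co-expression); `absolute = TRUE` switches to |r| ≥ t.
- **Log transform** is base 2 (`log_transform()`), the microarray
  convention; non-positive values are a reported error, never silently
  dropped.
- Fewer than 12 conditions triggers a prominent warning (error with
  `strict = TRUE`): correlations over so few samples produce unacceptable
  false-edge rates, but toy inputs still run.

## The synthetic test kit, and what it does not show

All testing runs on generated graphs:

- `moon_moser_graph(q)` — the complete q-partite graph with parts of 3;
  its 3^q part-transversals are exactly its maximal cliques (worst case).
- `clique_sensitivity_graph()` — an 8-vertex clique-sensitivity example: K5 plus
  three vertices attached to three members each; deleting one K5 edge
  turns 1 maximum clique of size 5 into 4 of size 4.
- `planted_overlap_graph()` — the correlation-graph regime: several
  cliques of a chosen size sharing a fixed core, plus independent
  background edges; post-validated (brute force for n ≤ 25, else
  Bron–Kerbosch) so the planted cliques are *exactly* the maximum cliques,
  re-drawing background edges deterministically from the seed when a draw
  spoils that.
- `degree_weighted_graph()` — the null model: edges placed independently
  with probability d_u·d_v/Σd (capped at 1, the expected-degree
  convention), typically fed a power-law degree sequence
  (`power_law_degrees()`, exponent 2.5, degrees 1–50). Heavy-tailed
  degrees alone do not produce large cliques: at n = 500 these graphs stay
  at ω ≤ ~5 while a planted graph of the same edge density holds its
  size-20 cliques — the qualitative contrast motivating the essential-set
  approach.
- `brute_force_maximal()` — an exhaustive subset oracle (C++, bitmask
  dynamic programming, guarded at n ≤ 25) sharing no code with the R
  search kernels; igraph serves as a second, fully external cross-check in
  one test.

Synthetic graphs do not reproduce the scale (tens of thousands of vertices,
millions of edges), the degree correlations, or the noise structure of real
transcriptomic graphs. Passing tests show the algorithms are *exact* and
that the reductions preserve maximum cliques; observed node-count
orderings (intelligent ≤ basic on every suite graph) are evidence about
graphs of this kind, not a theorem.

## Numerical and design choices

- Problem sizes: the randomized equivalence suite uses 200 seeded graphs
  with n ∈ {12, 16, 20} and edge probability ∈ {0.3, 0.5, 0.7} — large
  enough for rich clique structure, small enough for the exhaustive
  oracle; the random-contrast study uses 20 seeds at n = 500.
- Determinism: every tie anywhere (pivot, branch vertex, greedy choices,
  coloring order) breaks toward the lowest canonical vertex index; vertex
  labels sort numerically when all parse as integers, lexicographically
  otherwise. Identical input and configuration give byte-identical output.
- Budgets: enumeration accepts `budget_nodes`; exhaustion yields
  `status = "halted"` with the partial (always sound) list, replacing
  wall-clock cutoffs with a hardware-independent contract.
- Degenerate inputs: the empty graph has ω = 0 and no cliques; an
  edgeless graph has ω = 1 with every vertex a maximum clique; the greedy
  heuristic on an edgeless graph returns a single vertex.
- `extract_universal()` on a 3-path forces the middle vertex (degree
  n − 1); it genuinely lies in both maximum cliques.

## Known limitations

- The R search kernels favor clarity and auditability; graphs with
  millions of edges would want the same algorithms behind a compiled
  kernel.
- Only Pearson correlation (signed or absolute) and its p-value are
  offered as edge weights; no Spearman or mutual information, and no
  multiple-testing correction of p-values.
- `es_reduce()` helps exactly when maximum cliques overlap; on graphs with
  disjoint maximum cliques the essential set is empty and nothing is
  removed — detectably, via the empty `essential` field.
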