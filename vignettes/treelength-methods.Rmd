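---
title: "Treelength optimization: models, heuristics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treelength optimization: models, heuristics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treelen)
```

## The optimization criterion

Given unaligned nucleotide sequences, treelength optimization seeks a tree
`T`, with leaves bijectively labeled by the inputs and a gap-free sequence
`s_v` at every internal node, minimizing

$$\mathrm{TL}(T) \;=\; \sum_{(u,v)\in E(T)} d(s_u, s_v),$$

where `d` is a pairwise edit distance. The distance is determined by a
`CostScheme`: a substitution cost for matches (0 by default), transitions
(A↔G, C↔T) and transversions, and a gap cost `f(l) = g_open + g_ext · l`
charged once per *maximal* run of `l` gap columns. Three regimes matter:

* `g_open = 0` — "simple" gap costs; the gap cost is additive over run
  splitting, `f(a+b) = f(a) + f(b)`.
* `g_open > 0` — "affine" gap costs; long gaps are cheaper per residue than
  many short ones, which rewards treating an indel event as one unit.
* `g_open = ∞` — indels forbidden. With equal-length inputs the edit
  distance degenerates to the site-wise substitution cost, and the
  treelength of any tree equals its parsimony score. The package asserts
  this equivalence against an independent per-site Sankoff oracle in its
  test suite.

Both the joint problem and the fixed-tree problem (optimal ancestral
sequences on a known topology) are NP-hard, which dictates the architecture
below: heuristics for realistic sizes, exhaustive oracles for tiny ones.

### Preset constants

The three named criteria ship as presets, every field overridable through
`costPreset(name, ...)`:

| preset    | transition | transversion | gap open | gap extend | note |
|-----------|-----------:|-------------:|---------:|-----------:|------|
| `simple1` | 1 | 1 | 0   | 1   | every event costs 1 |
| `simple2` | 1 | 2 | 0   | 2   | indel residues and transversions cost 2 |
| `affine`  | 1 | 2 | 2   | 0.5 | positive opening charge |
| `mp`      | 1 | 1 | ∞  | –   | maximum parsimony limit |

The *structure* of the criteria (simple vs affine vs forbidden) is the
meaningful axis; the specific constants are conventional values in the
prior literature on these criteria, and nothing in the package assumes
them — the test suite exercises all presets plus overridden schemes.

Costs are stored as IEEE doubles. All preset constants are dyadic
(0, 0.5, 1, 2, ∞), so sums and comparisons of preset treelengths are exact
in double arithmetic; user-supplied non-dyadic costs get ordinary double
precision. Terminal gaps are charged exactly like internal gaps: the edit
model has no reason to exempt sequence ends, and exempting them would break
the symmetry `d(a, b) = d(b, a)` on unequal-length inputs.

## Pairwise alignment

`alignPair()` implements the three-state (match / gap-in-b / gap-in-a)
affine-gap recurrence; with `g_open = 0` the three-state recurrence reduces
exactly to the two-state simple-gap solution, so a single code path serves
both regimes. Ties are broken in the fixed order *diagonal, gap-in-b,
gap-in-a* at every cell, which makes the traceback — and everything built
on it, in particular implied alignments — a deterministic function of the
inputs. `enumerateAlignmentsCost()` is the correctness oracle: a recursion
over all monotone alignments with no memoisation, feasible to length 8,
against which the DP is checked on hundreds of random pairs under all four
presets.

## Fixed-tree solvers

`scoreFixedTree()` offers three solvers, all of which recompute their final
score from the node sequences so the reported treelength is always the
verifiable edge sum:

* **lifted** — every internal node receives the sequence of some leaf; the
  optimal such labeling is found by dynamic programming over the tree on
  the all-pairs leaf edit-distance matrix. Under a metric distance the best
  lifted labeling is a 2-approximation of the optimal assignment, a bound
  the test suite verifies against the exact solver on brute-forceable
  instances. It is the default pool-scoring method: deterministic, fast,
  and never worse than twice optimal under unit costs.
* **do** — a direct-optimization-style pass: post-order, each internal node
  is the column-wise consensus of the optimal pairwise alignment of its
  children (gap-vs-base columns keep the base; base/base ties resolve
  alphabetically, a fixed arbitrary rule chosen for determinism), followed
  by hill climbing that re-lifts any node onto a neighbor's sequence while
  that strictly shortens the tree (at most 20 sweeps; in practice the fixed
  point arrives in 2–3).
* **exact** — enumerates all ancestral candidate strings over {A,C,G,T} up
  to length `maxLen` (default 4; 341 candidates) and solves the resulting
  finite label assignment problem exactly by Sankoff-style DP. Restricted
  to `maxTaxa` (default 5) leaves; it exists to referee the heuristics, not
  to be used at scale.

Traversal rooting is deterministic everywhere: the root is the internal
node adjacent to the lexicographically smallest leaf label. Trees are
standardized to their unrooted form before scoring so that a degree-2
"root" node can never add a phantom edge; the degenerate two-leaf tree is
scored directly as the pairwise edit distance, with the connector node
carrying the smaller-labelled leaf's sequence. Polytomies are scored as-is
(edge sum over the multifurcating tree), never resolved silently.

## Implied alignments

Each edge of a scored tree implies an optimal pairwise alignment of its
endpoint sequences; the transitive closure of the site matches across edges
partitions sites into homology classes — the columns of the implied
multiple alignment. The delicate part is column *order*. This package
builds it by threading: a pre-order pass seeds the column order with the
root's sites and, for each child edge, splices the child's unmatched sites
into the global order immediately before the next parent site matched by
the pairwise alignment (or at the end). Because every insertion is local to
an edge whose parent sites are already ordered, the result is consistent
with every sequence's site order *by construction* — no conflict resolution
or class splitting is ever needed, and on a two-leaf tree the implied
alignment is bit-identical to `alignPair()` output. An alternative design
(topological sort of a precedence graph with cycle splitting) solves the
same problem but requires a conflict-repair path that can never be
exercised on tree-structured closures; the threading construction was
chosen because its correctness is structural. Rows are restricted to
leaves and columns no leaf occupies are dropped.

## p-ECR moves and the pool search

A random p-ECR move contracts `p` internal edges chosen uniformly without
replacement — "randomly selected" admits no other natural reading — and
then refines every polytomy back to binary by repeatedly grouping a
uniformly chosen pair of its children under a new node. Contraction removes
at most `p` bipartitions and refinement only adds, so the missing branch
rate between input and output is at most `p/(n-3)`; on a 4-leaf star the
refinement is uniform over the three topologies (verified by chi-square).
On trees too small for the requested `p`, `p` is clamped to the internal
edge count with a warning rather than erroring: the move is still
well-defined, just maximally disruptive.

`beetleSearch()` assembles a pool: the starting trees (user-supplied
Newick and/or internal baselines — neighbor joining on edit distances, or
random topologies), plus 20 independent p-ECR neighbors of each with
`p ~ U{1..5}` (counts configurable). Neighbors are drawn independently and
not deduplicated: duplicates are harmless for the minimum and
deduplication would distort the neighborhood distribution. Every candidate
is scored by the fixed-tree solver (lifted by default; `do` optionally —
which of the two a user prefers is recorded in the returned assignments'
`method` field), and the shortest tree wins, ties broken by insertion
order so that starting trees beat equal-scoring neighbors. Since every
starting tree is in the pool, the winner is never longer than any supplied
tree — this is the whole guarantee of the pool design, and the reason
normalized scores (`treelength / baseline treelength`) are at most 1
whenever the baseline is in the pool. The search is single-round by
design; iterating neighborhoods is out of scope.

## Error metrics

* `missingBranchRate(ref, est)` — the fraction of the reference's internal
  bipartitions absent from the estimate. Only the reference's edge count
  enters the denominator: when estimates may be unresolved, the symmetric
  Robinson–Foulds distance is biased in favor of unresolved trees, while
  the false-negative convention is not. For binary pairs the two halves of
  the symmetric difference coincide and the FN rate equals normalized RF
  (cross-checked against an independent implementation in the tests).
  `rfDistance()` is provided as a secondary output only.
* `spFN(ref, est)` — the fraction of the reference alignment's homologous
  residue pairs (over all taxon pairs and columns, sites indexed within
  each degapped sequence) missing from the estimate. Columns where either
  row of a taxon pair has a gap contribute no pairs. Ambiguity codes are
  rejected here; the metric's semantics for them are not well defined.
* `majorityConsensus(trees)` — exactly the splits in strictly more than
  half of the inputs, realized as one (possibly multifurcating) tree.

## The simulator

`evolveSequences()` emulates standard indel-aware sequence evolution: an
i.i.d. uniform root sequence of `rootLength` sites; along each branch of
length `b`, per-site substitution counts `~ Poisson(r_sub · b)` with a
K2P-style transition/transversion choice (`tsTvRatio` = expected
transitions per transversion, default 2), and indel events
`~ Poisson(r_indel · b · L)` with uniform positions, insertion probability
`insertionFraction`, and lengths from a geometric (mean `1/p`) or
mixture-of-geometrics model. The mixture option exists because real gap
length distributions combine a median of 1 with very long tails — a shape
no single geometric fits. The `short` / `medium` / `long` presets
(p = 0.7, 0.45, 0.25) give stochastically ordered mean gap lengths and
stand in for the qualitative short/medium/long axes of published
simulation conditions; the exact parameter bundles of any particular
published study are not replicated.

Homology is tracked exactly: insertions create new columns spliced into
the global column order directly after their anchor site, deletions mark
sites absent in the descendant lineage, and the true alignment is read off
the leaf rows (columns absent from every leaf are dropped). Per-branch
tallies of realized substitution and indel events feed
`contractZeroEventBranches()`: internal branches with zero realized events
— not zero expectation — are contracted to form the reference tree,
because recovering a branch on which nothing happened is a matter of
chance. `empiricalStats()` reports the condition-table statistics (p-
distances, gap percentage, gap-run lengths, resolution). In p-distances,
columns where both rows carry gaps are excluded and gap-vs-base columns
count as mismatches.

What the simulator does *not* emulate: rate heterogeneity across sites,
codon structure, selection, and empirical gap-length tails beyond what the
mixture model captures. Tests passing on simulated data therefore
demonstrate correctness of the machinery under the stated model, not
accuracy claims about any particular biological dataset.

One boundary choice: branch lengths of exactly 0 are accepted (they are
the zero-event limit and useful for degenerate-input tests); negative or
missing lengths are errors.

## Determinism, seeds and degenerate inputs

Every randomized operation is a pure function of its inputs and an integer
seed (`withr::with_seed` underneath, so the caller's RNG state is never
clobbered); omitting the seed draws from the current stream, which lets
compound operations consume one stream. Degenerate cases have defined
behavior rather than crashes: empty sequences align at gap cost; a
reference tree with no internal edges makes the missing branch rate `NaN`
with a warning, as does a zero treelength baseline in normalization; mp
schemes on unequal-length inputs yield an infinite edit distance
(`editDistance`) or an informative error where an alignment must be
materialized (`alignPair`).

## Problem sizes in the test suite

The suite checks the pairwise DP against exhaustive enumeration on 200
random pairs (lengths ≤ 6) under all four presets; the parsimony
equivalence on 50 instances of up to 8 taxa; heuristic-vs-exact dominance
and the 2-approximation bound on 50 brute-forceable instances (≤ 5 taxa,
lengths ≤ 4); the pool-search guarantee on 100 random instances; the p-ECR
contract on 100 trees of 20–100 leaves plus 5000 uniformity draws; and
simulator moment recovery on alignments with over 1000 observed gap runs.
These sizes were chosen so the whole suite runs in about a minute while
each property still has enough replication to be meaningful.

## Known limitations

* The fixed-tree heuristics carry no optimality guarantee beyond the
  lifted 2-approximation under metric costs; `do` can occasionally score
  worse than `lifted` on adversarial instances (the suite asserts it stays
  within 10%).
* `exact` scales only to toy instances (its purpose is verification).
* The implied alignment depends on the heuristic ancestral sequences;
  equivalence with any external implementation's output cannot be asserted,
  only the criterion's semantics.
* NEXUS/PHYLIP formats, amino-acid alphabets, position-dependent costs and
  multi-round search are out of scope.
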