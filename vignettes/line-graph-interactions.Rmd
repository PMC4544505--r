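---
title: "Enumerating bonded interactions with iterated line graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating bonded interactions with iterated line graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intramol)
```

## The model

A molecule's covalent skeleton is a simple, loopless, connected graph
$G$: $p$ vertices (atoms or coarse-grained beads), $q$ edges (bonds),
every atom in at least one bond. Bonded $n$-body interactions are walks
of adjacent bonds: a *bend* is two bonds at a common hinge atom, a
*4-body term* is two bends sharing a bond. The line graph $L(G)$ —
vertices are the edges of $G$, adjacency means a shared endpoint — turns
each of these statements into plain graph adjacency one level up, so the
iterated transformation

$$L^n(G) = L(L^{n-1}(G)), \qquad L^0(G) = G$$

carries the whole hierarchy: $N_n(G) = |V(L^{n-1}(G))|$ counts the
$n$-body terms. Algebraically $A(L(G)) = Z^\top Z - 2I_q$ with $Z$ the
vertex-edge incidence matrix; the package builds $L(G)$ combinatorially
(pairs of incident edges at each vertex) and checks that identity in its
test suite, so an error in either route would surface as a disagreement.

Three distinct 4-body types exist, and the hierarchy distinguishes them
without any geometric input. Each vertex at level $n$ of the interaction
DAG $H_\nu(G)$ backtracks to a sequence of $2^{n-1}$ atomic indexes (each
level concatenates its two parents' sequences). At $n = 4$ the sorted
multiplicity signature of that sequence is decisive:

* $(3,3,1,1)$ over four distinct atoms — **proper torsion**: two hinge
  atoms forming the shared bond, rotation described by a dihedral angle;
* $(4,2,1,1)$ — **improper dihedral**: a single common hinge carrying
  three peripheral atoms, used to hold planar groups or stereocentres;
* $(3,3,2)$ over three atoms — **degenerate 3-cycle**: the two "flap"
  atoms coincide because the bends close a triangle.

Any other signature is impossible on a simple graph, and the classifier
treats one as an internal error rather than data to tolerate. Impropers
and 3-cycles each appear three times among the level-4 vertices (one per
choice of shared bond), which is why the ledger identity reads
$N_4 = N_\mathrm{prop} + 3N_\mathrm{impr} + 3N_\mathrm{3cyc}$; the
`dedupe` option of `interaction_table()` collapses each such triple to a
single physical record keyed by its canonical participant tuple.

## Closed forms and the checksum discipline

All counts up to order 4 follow from vertex degrees and the adjacency
matrix alone:

$$N_2 = \tfrac12\mathrm{Tr}\,D,\quad
  N_3 = \tfrac12 u^\top D^2 u - N_2,\quad
  N_\mathrm{impr} = \tfrac16 u^\top D^3 u - N_3 - \tfrac13 N_2,$$
$$N_\mathrm{prop} + 3N_\mathrm{3cyc} = \tfrac12 u^\top DAD\,u - 2N_3 - N_2,
  \qquad N_\mathrm{3cyc} = \tfrac16\mathrm{Tr}\,A^3.$$

`closed_form_counts()` evaluates these with exact integer arithmetic:
every division by 2, 3 or 6 is checked for zero remainder, because a
fractional intermediate can only mean the formula was applied to
something that is not a valid simple connected graph. On top of that it
verifies the independent identity
$N_4 = \tfrac12 u^\top D\,Q\,D\,u - 5N_3 - 2N_2$ (with $Q = A + D$ the
signless Laplacian), the handshake $N_2 = q$, and the binomial forms
$N_3 = \sum_v \binom{\deg v}{2}$, $N_\mathrm{impr} = \sum_v
\binom{\deg v}{3}$. A further cross-check lives in
`brute_force_counts()`, which shares no code with the closed forms: it
enumerates bends as edge pairs, impropers as edge triples, torsions as
simple 4-paths keyed by their middle bond, triangles as 3-cliques. One
quantity, three routes (closed form, line-graph vertex count, subgraph
enumeration) — the tests demand exact agreement on every fixture and on
two hundred seeded random connected graphs.

A small wrinkle in the count conventions deserves a note: the atom count
$N_1$ is defined as $p = |V(G)|$ (the 1-body terms coupling to an
external field). An alternative expression sometimes written for it,
$\tfrac12 u^\top A u$, actually evaluates to $q$ — it is the handshake
count of bonds, not atoms — so the package's `n1` is $p$ and the
$\tfrac12 u^\top A u$ quantity only appears as the $N_2$ identity.

```{r counts}
tauro <- read_graph(system.file("extdata", "taurocholate.edges",
                                package = "intramol"))
closed_form_counts(tauro)
```

## Limit classes, planarity, and the line index

Iterating $L$ has exactly four possible fates: cycles are fixed points,
the claw $K_{1,3}$ collapses onto the triangle, paths shed one vertex per
step until nothing is left, and everything else is *prolific* — growth
without bound. `classify_limit()` decides this from the degree sequence,
and `iterate_line_graphs()` therefore takes a vertex budget (default
100,000 per level) that converts runaway growth into a flagged partial
result instead of an out-of-memory failure.

The *line index* $\xi(G)$ is the smallest $m$ with $L^m(G)$ nonplanar.
Non-prolific graphs stay planar forever ($\xi = \infty$, returned without
iterating); prolific graphs satisfy $0 \le \xi \le 4$, so `line_index()`
iterates with a planarity test at each level and treats exhausting its
`max_levels` cap (default 6, deliberately above the theoretical bound) as
an internal error. For a simulation practitioner $\xi$ is a compact
signal of how quickly the interaction hierarchy becomes densely
entangled.

Planarity itself is decided by a left-right (LR) planarity test written
for this package: a DFS orientation with low-point bookkeeping followed
by the conflict-pair partition of back edges into two interleaving-free
sides. It is verdict-only — no embedding or Kuratowski certificate — with
two shortcuts ($p < 5$ or $q < 9$ planar; $q > 3p - 6$ nonplanar). Its
correctness is covered three ways in the tests: named families (grids,
$K_4$, outer cycles planar; $K_5$, $K_{3,3}$, the Petersen graph and
their subdivisions nonplanar), agreement with an exhaustive
rotation-system oracle that declares a tiny graph planar exactly when
some cyclic dart ordering attains Euler characteristic
$V - E + F = 2$, and the two worked molecular examples below.

```{r xi}
toy <- read_graph(system.file("extdata", "methylcyclopropane.edges",
                              package = "intramol"))
line_index(toy)
line_index(tauro)
```

## Numerical and representational choices

* **Canonical order.** Vertex labels are opaque strings kept verbatim;
  ordering is a natural sort (digit runs compare numerically), so the
  integer atom labels common in topology files sort as numbers. Edges
  are ordered lexicographically by their (min, max) endpoints, and a
  line-graph vertex inherits the label `"(a,b)"` of its parent edge, so
  labels nest across levels and the natural order of nested labels
  reproduces the parent edge order — an invariant the constructor
  asserts at every level rather than assumes.
* **Connectivity as a hard gate.** Enumeration and hierarchy operations
  refuse disconnected input: one molecule per graph, splitting
  multi-molecule systems is the caller's job. The validator computes the
  verdict twice (Kirchhoff rank $p-1$ via exact fraction-free Bareiss
  elimination with an overflow guard and an SVD fallback at tolerance
  $10^{-9}\sigma_\max$, and plain traversal) and insists the two agree.
* **Canonical participants.** Output records are diff-stable: bends
  $(i, j, k)$ with hinge $j$ and $i < k$; propers oriented to the
  lexicographically smaller of the two traversal directions; impropers
  hinge-first with sorted periphery; 3-cycles as sorted triples. The
  variant group of an improper or 3-cycle is its participant tuple —
  precisely what its three rotational sequences share.
* **Orders above 4** are supported by the machinery (counts via
  `count_via_line_graphs()`, raw sequences in the table) but emitted as
  `unclassified`: the sub-type taxonomy beyond $n = 4$ multiplies
  quickly and is out of scope here.

## What the fixture generator does and does not emulate

`make_fixture()` produces the analytic families (paths, cycles, claw,
complete graphs) and random connected graphs assembled as a uniform
random spanning tree (uniform Prüfer sequence) plus $k$ distinct extra
edges, giving $q = p - 1 + k$ by construction and exact reproducibility
from one integer seed. These exercise every code path — trees, sparse
cyclic graphs, dense cores — at the scale of coarse-grained molecular
models ($p \le 12$ in the property tests, which keeps the brute-force
oracle exact and the whole suite fast). They are *connectivity* fixtures
only: no element types, bond orders or coordinates, and no attempt to
mimic chemical degree statistics (a random spanning tree happily emits
degree-6 beads). Passing tests therefore certify the combinatorics of
enumeration and classification on arbitrary simple connected graphs, not
the chemical plausibility of any particular topology file.

## Known limitations

* Interactions are purely topological; assigning force constants,
  functional forms or equilibrium geometry is downstream work, as is
  reading chemistry formats (MOL/SDF/PDB) — input is an edge list or
  adjacency CSV.
* The planarity test returns a verdict only; users wanting a drawing or
  a Kuratowski witness need a different tool.
* The brute-force oracle is deliberately capped at $p \le 64$; the
  closed forms and the DAG have no such cap, but prolific growth makes
  levels beyond $n \approx 5$ large quickly, which is what the vertex
  budget is for.
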