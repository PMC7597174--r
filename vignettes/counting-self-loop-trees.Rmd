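---
title: "Counting trees with self-loops: the method behind treeloops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting trees with self-loops: the method behind treeloops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeloops)
```

## The counting problem

`treeloops` counts, exactly and without generating a single tree, all
mutually non-isomorphic trees with `n` vertices and `delta` self-loops and
no multi-edges.  Such trees matter in chemical graph theory: repeatedly
deleting degree-1 and degree-2 vertices of a chemical graph leaves its
*polymer topology*, a connected graph with every vertex of degree at least
three (a self-loop adding 2 to its vertex's degree), and the tree-like
polymer topologies of cycle rank `r` are exactly trees carrying `r`
self-loops that meet the degree condition.  Knowing the size of the search
space before enumerating candidate structures is the point of counting
rather than listing.

Two rooted trees are isomorphic here when some bijection of the vertex
sets maps root to root, preserves each vertex's self-loop count, and
preserves adjacency.  Unrooted isomorphism drops the root condition.

## The dynamic program over (Maxv, Maxs)

For a rooted tree `H`, write `Maxv(H)` for the vertex count of the
largest subtree hanging off a child of the root, and `Maxs(H)` for the
largest self-loop total among child subtrees of exactly that size (both 0
for a single vertex).  The DP state is the count of rooted trees with `i`
vertices and `j` loops whose profile is bounded — three families per
state:

* `h(i, j, m<=, d<=)`: `Maxv <= m` and `Maxs <= d`,
* `h(i, j, m=, d<=)`: `Maxv = m`, `Maxs <= d`,
* `h(i, j, m=, d=)`: `Maxv = m`, `Maxs = d`.

The first two unwind telescopically
(`h(i,j,m<=,d<=) = h(i,j,m-1<=,d<=) + h(i,j,m=,d<=)` and the analogue in
`d`), so the engine's real work is the third family.  A tree with profile
exactly `(m, d)` has some number `q >= 1` of *maximal* child subtrees,
those drawn from the family `H(m, d, m-1<=, d<=)` — subtrees with `m`
vertices, `d` loops, and no child of their own as large as `m`.  Deleting
all `q` of them leaves the *residual tree*, which either still has a
size-`m` child subtree with fewer than `d` loops, or has only strictly
smaller children.  Choosing the `q` maximal subtrees is an unordered
selection with repetition, so each `q` contributes the multiset
coefficient

$$c(m,d;q) = \binom{h(m,d,m{-}1\le,d\le) + q - 1}{q}$$

times the residual-tree count.  The feasible `q` run to
`floor((i-1)/m)`, further capped by `floor(j/d)` when `d >= 1`; an empty
range contributes 0.  Base cases: a single vertex has profile `(0, 0)`
regardless of its loops; `m = 0` with `i >= 2` is impossible; `m = 1`
trees are stars, giving `h(i, j, 1<=, d<=) = d + 1` for `i = 2` and `1`
for `i >= 3, d = 0`.

The table is filled bottom-up in the order vertices `i`, loops `j`,
size bound `m`, loop bound `d`; the coefficient `c(m,d;q)` is maintained
incrementally as `c := c * (h + q - 1) / q` with an exactness assertion
on every division (each step is again a binomial coefficient, so a
nonzero remainder can only mean a corrupted table).
`build_table(..., cross_check = TRUE)` additionally recomputes every
incremental coefficient from the closed form and stops on any
disagreement; the test suite runs that self-check on a full `(12, 6)`
table.

### Index ranges: a deliberate widening

The recurrence's residual-tree references need fourth indices up to the
full loop budget `j` even when the user's query caps `d` below `delta`
(the `d = 0` branch references `h(i - qm, j, ..., j<=)`).  The package
therefore always computes the complete table — `m` up to `i - 1` and `d`
up to `j` for every sub-instance — and answers capped queries by lookup.
This spends more memory than the tightest possible accounting in exchange
for having every referenced cell defined; the top-level query has
`d = delta` anyway, and a full `(30, 10)` table holds about
10<sup>5</sup> cells per family, far from a constraint at desk scale.
Out-of-range indices follow the family semantics: `m >= i` clamps to
`i - 1` for the `<=` family but yields an empty `=` family, and negative
indices count 0.

## From rooted to unrooted: the centroid

Every tree has a centroid (Jordan): either a unique vertex whose removal
leaves components of at most `floor((n-1)/2)` vertices, or — only for
even `n` — a unique edge splitting the tree into two halves of exactly
`n/2`.  Rooting at the centroid makes the unrooted count two reads of the
rooted table:

* unicentroidal trees are rooted trees whose child subtrees are capped at
  `floor((n-1)/2)` vertices: the cell `h(n, delta, floor((n-1)/2)<=, delta<=)`;
* bicentroidal trees are **unordered pairs** of rooted half-trees on
  `n/2` vertices splitting the loops as `i` and `delta - i`.  Distinct
  loop splits pair distinct families and contribute a plain product; the
  balanced split (even `delta` only) pairs a family with itself and
  contributes pairs with repetition, `C(h + 1, 2)`.

The bicentroid's conceptual "virtual root" on the middle edge is never
materialized — the unordered-pair formula replaces it.  The half-size
cells `h(n/2, i, n/2-1<=, i<=)` are already stored in the `(n, delta)`
table, so one build serves both terms.

## Polymer-topology bounds

Writing `t(n, delta)` for the unrooted counts and `p(r)` for the number
of tree-like polymer topologies (self-loops, no multi-edges) of cycle
rank `r`:

* **Lower bound**: placing `k` loops on *every* vertex of a simple tree
  on `n` vertices yields a polymer topology of rank `nk`, so
  `p(r) >= sum over nk = r of t(n, 0)` — a sum over the divisors of `r`.
* **Upper bound**: `ceiling(n/2) + 1` loops are the fewest that can bring
  every vertex of an `n`-vertex tree (`n >= 2`) to degree 3 — a diameter-
  `n/2` caterpillar achieves it, and the test suite constructs that
  witness explicitly — so ranks `r < ceiling(n/2) + 1` admit no
  `n`-vertex polymer and `p(r) <= sum of t(n, r)` over
  `n <= 2(r - 1)`.

At `r = 1` the lower bound's premise fails: one vertex with one loop has
degree 2 and is not a polymer, yet the divisor sum counts it, so the
printed bounds cross (`lower = 1 > upper = 0`).  `polymer_bounds(1)`
computes the formulas as stated and flags the result `valid = FALSE`
with a warning rather than silently excluding the term; from rank 2 on
the bracket is consistent.  The `n = 1` term of the upper sum (feasible
for `r >= 2`, a bouquet of `r` loops on one vertex) is likewise kept as
the formula states.

## Exact arithmetic

The benchmark count for `(30, 10)` is 2,547,562,522,909,694,331 — beyond
both 2^53 (exact doubles) and, soon after, 2^63.  Every count in the
package is therefore an exact arbitrary-precision integer, stored in the
compiled core as base-10^9 limb vectors and surfaced to R as decimal
character strings; `big_add()`, `big_mul()` and `big_cmp()` combine them
without ever passing through a double.  JSON output renders counts as
digit strings for the same reason.  There is no floating point, no
rounding and no randomness anywhere in the counting path, so results are
bit-identical across runs and platforms.

## The brute-force oracle

An independent enumerator certifies the DP on small instances.  It knows
nothing of the recurrences: it exhausts all parent arrays (parent of
vertex `i` chosen among `1..i-1` — every rooted tree admits such a
labelling) crossed with all compositions of the loop budget over the
vertices, and deduplicates by a canonical code — each vertex's loop count
followed by its children's codes in a fixed byte-wise order, so code
equality coincides with rooted isomorphism.  Unrooted classes are coded
after re-rooting at the centroid.  Generation is deliberately naive
(auditability over speed) and guarded to `n <= 8`, `delta <= 5` by
default; the guard can be raised explicitly.

The equivalence tests run the full grid `n <= 7`, `delta <= 4` for
rooted and unrooted counts, and compare every `(Maxv, Maxs)` bucket
against the classifier on `n <= 6`, `delta <= 3` — about 3 × 10^5
generated trees, a couple of minutes of R time.  Those grid sizes are the
package's chosen trade-off between coverage and test-suite latency:
isomorphism-class structure does not change character above them, but the
naive generator's cost grows factorially.  A second check compares the
iterative engine against an independently written top-down memoized
recursion (`h_rooted_memo()`, plain R doubles, valid below 2^53) on
`n <= 8`, `delta <= 4` — two engines, one specification, catching
loop-order and initialization mistakes that an oracle of shared ancestry
would miss.

Because the oracle enumerates *abstract* trees, passing these tests says
nothing about chemical plausibility (valence, atom typing) of any
particular structure — the package counts topologies, not molecules.

## Degenerate inputs and conventions

* `n = 1` is a valid tree for any `delta` (all loops on the lone vertex);
  `t(1, delta) = h(1, delta) = 1`.
* Self-loops contribute 2 to their vertex's degree (the convention the
  polymer degree argument needs); cycle rank of a loop-tree equals its
  loop count.
* Empty summation ranges (e.g. the bicentroid loop-split sum at
  `delta = 0`, or the upper polymer sum at `r = 1`) contribute 0.
* `bicentroid_count()` rejects odd `n` outright rather than returning 0,
  since calling it there indicates a caller error.

## Worked example

```{r example}
t_unrooted(10, 5)          # unrooted trees, 10 vertices, 5 self-loops
h_rooted(10, 5)            # their rooted counterparts
tbl <- build_table(6, 2)
h_eq_eq(normalize_key(6, 2, 3, 1), tbl)  # profile-exact bucket
polymer_bounds(4)          # bracket on rank-4 tree-like polymer topologies
```

## Limitations

* Multi-edges are out of scope throughout; the bounds on `p(r)` are
  bounds, not exact values, precisely because most polymer topologies are
  not trees with loops.
* The enumerator, not the DP, is the scaling bottleneck of the *test
  suite*; the DP itself runs the `(30, 10)` benchmark in well under a
  second, and its cost grows polynomially (roughly `n^2` times a
  `delta`-dependent factor), so far larger instances are reachable if
  needed.
* `h_rooted_memo()` is a validation aid only; it deliberately fails fast
  once a count would leave the exact double range.
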