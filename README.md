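# treeloops

Exact counting of mutually non-isomorphic trees with a given number of
vertices and self-loops (no multi-edges), rooted and unrooted, plus exact
lower/upper bounds on the number of tree-like polymer topologies of a
given cycle rank.

## Why

Counting a space of chemical-graph skeletons before generating it tells
you whether generation is even feasible.  Trees with `n` vertices and
`delta` self-loops have cycle rank `delta` and include all tree-like
polymer topologies — the skeletons left when a chemical graph's degree-1
and degree-2 vertices are repeatedly deleted.  `treeloops` counts these
isomorphism classes by dynamic programming, never materializing a tree.

The DP state is the profile of the root's largest child subtree: `Maxv`,
its vertex count, and `Maxs`, the largest loop total among child subtrees
of that size.  Writing `h(n, Δ, m≤, d≤)` for the number of rooted classes
with `Maxv ≤ m` and `Maxs ≤ d`, the profile-exact family satisfies

    h(n, Δ, m=, d=) = Σ_q  C(h(m, d, m−1≤, d≤) + q − 1, q) · (residual-tree count)

where `q` counts the maximal child subtrees and the binomial is a
multiset coefficient (unordered choice with repetition).  Unrooted counts
follow from Jordan's centroid: root odd-`n` trees at their unicentroid;
for even `n` add the bicentroidal classes, which are unordered pairs of
rooted half-trees splitting the loop budget.  All arithmetic is exact
arbitrary-precision integer arithmetic (counts are returned as decimal
strings — the benchmark value for 30 vertices and 10 loops already
exceeds 2^53).

A deliberately naive brute-force enumerator (`enumerate_rooted()`,
`enumerate_unrooted()`, canonical-code deduplication) provides
independent ground truth on small instances; the test suite checks the
DP against it on every instance with `n ≤ 7`, `Δ ≤ 4` and every
`(Maxv, Maxs)` bucket with `n ≤ 6`, `Δ ≤ 3`.

## Worked example

```r
library(treeloops)

t_unrooted(10, 5)
#> [1] "91037"

h_rooted(10, 5)
#> [1] "814496"

polymer_bounds(4)
#> <polymer_bounds> rank 4: 4 <= p(r) <= 454
```

`t_unrooted(10, 5)` says there are exactly 91,037 non-isomorphic trees
with 10 vertices and 5 self-loops; `h_rooted` counts their rooted
versions (each unrooted class contributes one rooting per symmetry-
distinct vertex, hence the larger number).  `polymer_bounds(4)` brackets
the number of tree-like polymer topologies of cycle rank 4 between 4
(the distinct simple trees that yield rank 4 by uniform loop placement)
and 454 (all trees with 4 loops on up to 6 vertices).

Lower-level access: `build_table(n, delta)` exposes the full DP table,
queried with `h_le_le()` / `h_eq_le()` / `h_eq_eq()` on normalized keys,
e.g.

```r
tbl <- build_table(6, 2)
h_eq_eq(normalize_key(6, 2, 3, 1), tbl)
#> [1] "25"
```

is the number of rooted classes on 6 vertices and 2 loops whose largest
child subtree has exactly 3 vertices carrying exactly 1 loop.

## Command line

```sh
Rscript exec/treeloops unrooted 10 5        # 91037
Rscript exec/treeloops rooted 2 3           # 4
Rscript exec/treeloops bounds 2             # lower 2 / upper 3 / valid true
Rscript exec/treeloops table --format tsv   # the benchmark grid
```

`--format json` renders counts as digit strings so no consumer ever
parses them through a double.

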