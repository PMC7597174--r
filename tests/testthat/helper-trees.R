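# Shared helpers: count comparison, random relabelling, and a
# constructive witness for the loop budget that forces every vertex of a
# tree up to polymer degree.

expect_count_equal <- function(actual, expected) {
  expect_identical(actual, as.character(expected))
}

# Apply a vertex permutation to a loop_tree: perm[v] is the new label of v.
relabel_tree <- function(tree, perm) {
  n <- tree$n
  parent <- integer(n)
  loops <- integer(n)
  for (v in seq_len(n)) {
    p <- tree$parent[v]
    parent[perm[v]] <- if (p == 0L) 0L else perm[p]
    loops[perm[v]] <- tree$loops[v]
  }
  loop_tree(parent, loops)
}

# A random loop_tree on n vertices with delta loops (parent[v] < v).
random_loop_tree <- function(n, delta) {
  parent <- c(0L, if (n > 1L) vapply(2:n, function(v) sample.int(v - 1L, 1L), 1L))
  loops <- integer(n)
  if (delta > 0L) {
    at <- sample.int(n, delta, replace = TRUE)
    for (v in at) loops[v] <- loops[v] + 1L
  }
  loop_tree(parent, loops)
}

# Caterpillar witness that ceiling(n/2) + 1 self-loops suffice to push
# every vertex of some n-vertex tree to degree >= 3 (a self-loop adding 2):
# a path of n/2 edges whose interior vertices each carry one extra leaf,
# and one loop on every remaining degree-deficient vertex.
polymer_witness_tree <- function(n) {
  stopifnot(n %% 2L == 0L, n >= 4L)
  k <- n %/% 2L
  parent <- integer(n)
  for (v in 2:(k + 1L)) parent[v] <- v - 1L          # the spine
  leaves <- seq_len(n - k - 1L)                       # one per interior vertex
  for (i in leaves) parent[k + 1L + i] <- 1L + i
  deg <- tabulate(parent[parent > 0L], nbins = n) +
    as.integer(parent > 0L)
  loops <- as.integer(deg < 3L)
  loop_tree(parent, loops)
}

# Vertex degrees counting each self-loop as 2.
tree_degrees <- function(tree) {
  deg <- tabulate(tree$parent[tree$parent > 0L], nbins = tree$n) +
    as.integer(tree$parent > 0L)
  deg + 2L * tree$loops
}
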