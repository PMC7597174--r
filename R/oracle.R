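# Brute-force ground truth on small instances.
#
# The enumerator exhausts parent arrays (parent of vertex i chosen among
# vertices 1..i-1, vertex 1 the root — every rooted tree admits such a
# labelling) crossed with all compositions of the self-loop budget over
# the vertices, and deduplicates by a canonical code.  It is deliberately
# naive and independent of the dynamic program: its only job is to certify
# the DP's counts on instances small enough to list.

#' Construct a tree with per-vertex self-loop counts
#'
#' @param parent integer vector: `parent[v]` is the parent of vertex `v`,
#'   with `0` (or `NA`) marking the root.  Exactly one root is required
#'   and the structure must be a connected tree.
#' @param loops integer vector of nonnegative per-vertex self-loop counts
#'   (default none).
#' @return An object of class `"loop_tree"` with fields `n`, `parent`
#'   (0 at the root), `loops` and `root`.
#' @examples
#' # 3-path rooted at an end, one loop on the middle vertex
#' loop_tree(c(0, 1, 2), c(0, 1, 0))
#' @export
loop_tree <- function(parent, loops = integer(length(parent))) {
  parent <- as.integer(parent)
  parent[is.na(parent)] <- 0L
  n <- length(parent)
  if (n < 1L) stop("a tree needs at least one vertex", call. = FALSE)
  loops <- as.integer(loops)
  if (length(loops) != n || anyNA(loops) || any(loops < 0L)) {
    stop("'loops' must give a nonnegative count for every vertex", call. = FALSE)
  }
  root <- which(parent == 0L)
  if (length(root) != 1L) {
    stop("exactly one vertex must have no parent (the root)", call. = FALSE)
  }
  if (any(parent < 0L) || any(parent > n) || any(parent == seq_len(n))) {
    stop("parent pointers must name another vertex in 1..n", call. = FALSE)
  }
  # connectivity + acyclicity: walking up from every vertex must reach the
  # root in at most n steps
  for (v in seq_len(n)) {
    u <- v
    for (step in seq_len(n)) {
      if (u == root) break
      u <- parent[u]
    }
    if (u != root) {
      stop("parent pointers contain a cycle; not a tree", call. = FALSE)
    }
  }
  structure(list(n = n, parent = parent, loops = loops, root = root),
            class = "loop_tree")
}

#' @export
print.loop_tree <- function(x, ...) {
  cat(sprintf("<loop_tree> %d vertices, %d self-loops, root %d\n",
              x$n, sum(x$loops), x$root))
  invisible(x)
}

adjacency_list <- function(tree) {
  adj <- vector("list", tree$n)
  for (v in seq_len(tree$n)) {
    p <- tree$parent[v]
    if (p > 0L) {
      adj[[v]] <- c(adj[[v]], p)
      adj[[p]] <- c(adj[[p]], v)
    }
  }
  adj
}

#' Canonical code of a rooted tree with self-loops
#'
#' A nested fingerprint: the code of a vertex is its self-loop count
#' followed by the codes of its children sorted in a fixed (byte-wise)
#' order.  Two rooted trees are isomorphic — by a bijection preserving the
#' root, per-vertex loop counts and adjacency — exactly when their root
#' codes are equal.
#'
#' @param tree a [loop_tree()].
#' @param root vertex at which to root (defaults to the tree's own root).
#' @return The code as a character scalar.
#' @examples
#' a <- loop_tree(c(0, 1, 2), c(0, 1, 0))
#' b <- loop_tree(c(2, 3, 0), c(0, 1, 0)) # same shape, relabelled
#' canonical_code(a) == canonical_code(b)
#' @export
canonical_code <- function(tree, root = tree$root) {
  if (!inherits(tree, "loop_tree")) {
    stop("'tree' must be a loop_tree", call. = FALSE)
  }
  root <- check_scalar_int(root, "root", min = 1)
  if (root > tree$n) stop("'root' is not a vertex of the tree", call. = FALSE)
  adj <- adjacency_list(tree)
  loops <- tree$loops
  rec <- function(v, from) {
    nb <- setdiff(adj[[v]], from)
    if (length(nb) == 0L) return(paste0("(", loops[v], ":)"))
    kids <- vapply(nb, rec, character(1L), from = v)
    paste0("(", loops[v], ":", paste0(sort(kids, method = "radix"),
                                      collapse = ""), ")")
  }
  rec(root, 0L)
}

# All parent arrays on n vertices with parent[v] < v (vertex 1 the root):
# a matrix with one column per rooted labelled tree in topological order.
parent_arrays <- function(n) {
  if (n == 1L) return(matrix(0L, nrow = 1L, ncol = 1L))
  choices <- lapply(seq_len(n - 1L), seq_len)
  g <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  rbind(0L, t(g))
}

# All compositions of `total` into `parts` nonnegative parts, one per column.
compositions <- function(total, parts) {
  if (parts == 1L) return(matrix(as.integer(total), nrow = 1L))
  cols <- lapply(0:total, function(first) {
    rbind(as.integer(first), compositions(total - first, parts - 1L))
  })
  do.call(cbind, cols)
}

children_of <- function(parent, n) {
  ch <- vector("list", n)
  if (n > 1L) {
    s <- split(2:n, parent[2:n])
    ch[as.integer(names(s))] <- s
  }
  ch
}

# Fast canonical code when `parent` is topologically ordered (parent < child)
# so a single reverse sweep resolves all children before their parent.
code_topological <- function(children, loops, order) {
  code <- character(length(loops))
  for (v in rev(order)) {
    kids <- children[[v]]
    if (is.null(kids)) {
      code[v] <- paste0("(", loops[v], ":)")
    } else {
      code[v] <- paste0("(", loops[v], ":",
                        paste0(sort(code[kids], method = "radix"),
                               collapse = ""), ")")
    }
  }
  code[order[1L]]
}

guard_instance <- function(n, delta, max_n, max_delta) {
  if (n > max_n || delta > max_delta) {
    stop(sprintf(paste0("instance (n = %d, delta = %d) exceeds the brute-force ",
                        "guard (n <= %d, delta <= %d); raise max_n/max_delta ",
                        "deliberately if you really want this"),
                 n, delta, max_n, max_delta), call. = FALSE)
  }
  invisible(TRUE)
}

#' Enumerate rooted isomorphism classes by brute force
#'
#' Generates every rooted tree with `n` vertices and `delta` self-loops
#' (all parent arrays crossed with all loop compositions) and returns the
#' set of distinct canonical codes; its length is the ground-truth rooted
#' count.  Exponential — guarded to desk-scale instances.
#'
#' @inheritParams build_table
#' @param max_n,max_delta instance-size guards.
#' @return Sorted character vector of distinct canonical codes.
#' @examples
#' length(enumerate_rooted(3, 0)) # 2: path from an end, star from the centre
#' @export
enumerate_rooted <- function(n, delta, max_n = 8L, max_delta = 5L) {
  n <- check_scalar_int(n, "n", min = 1)
  delta <- check_scalar_int(delta, "delta", min = 0)
  guard_instance(n, delta, max_n, max_delta)
  pm <- parent_arrays(n)
  cm <- compositions(delta, n)
  codes <- character(ncol(pm) * ncol(cm))
  t <- 0L
  for (pi in seq_len(ncol(pm))) {
    children <- children_of(pm[, pi], n)
    for (ci in seq_len(ncol(cm))) {
      t <- t + 1L
      codes[t] <- code_topological(children, cm[, ci], seq_len(n))
    }
  }
  sort(unique(codes), method = "radix")
}

# Subtree sizes under a topologically ordered parent array.
subtree_sizes <- function(parent, n) {
  size <- rep(1L, n)
  for (v in n:2) size[parent[v]] <- size[parent[v]] + size[v]
  size
}

# Centroid vertices of the underlying simple tree (self-loops are
# irrelevant to component sizes).  One vertex -> unicentroid; two
# (necessarily adjacent, n even) -> bicentroid.
centroid_vertices <- function(parent, n) {
  if (n == 1L) return(1L)
  size <- subtree_sizes(parent, n)
  children <- children_of(parent, n)
  maxcomp <- integer(n)
  for (v in seq_len(n)) {
    comp <- n - size[v]
    kids <- children[[v]]
    if (!is.null(kids)) comp <- max(comp, size[kids])
    maxcomp[v] <- comp
  }
  which(maxcomp <= n %/% 2L)
}

# Breadth-first order and parent pointers when re-rooting at `root`,
# optionally cut at the edge towards `block`.
reroot_plan <- function(adj, root, n, block = 0L) {
  order <- integer(n)
  par <- integer(n)
  order[1L] <- root
  par[root] <- 0L
  seen <- logical(n)
  seen[root] <- TRUE
  if (block > 0L) seen[block] <- TRUE
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    v <- order[head]
    for (u in adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        tail <- tail + 1L
        order[tail] <- u
        par[u] <- v
      }
    }
    head <- head + 1L
  }
  list(order = order[seq_len(tail)], parent = par)
}

#' Enumerate unrooted isomorphism classes by brute force
#'
#' As [enumerate_rooted()], but each generated tree is first rooted at its
#' centroid, which makes the code independent of the generated labelling:
#' unicentroidal trees take the code at the centroid, bicentroidal trees
#' the sorted pair of half codes across the centroid edge.
#'
#' @inheritParams enumerate_rooted
#' @return Sorted character vector of distinct centroid-rooted codes.
#' @examples
#' length(enumerate_unrooted(4, 0)) # 2: the path and the star
#' @export
enumerate_unrooted <- function(n, delta, max_n = 8L, max_delta = 5L) {
  n <- check_scalar_int(n, "n", min = 1)
  delta <- check_scalar_int(delta, "delta", min = 0)
  guard_instance(n, delta, max_n, max_delta)
  pm <- parent_arrays(n)
  cm <- compositions(delta, n)
  codes <- character(ncol(pm) * ncol(cm))
  t <- 0L
  for (pi in seq_len(ncol(pm))) {
    parent <- pm[, pi]
    cent <- centroid_vertices(parent, n)
    adj <- adjacency_list(list(n = n, parent = parent))
    if (length(cent) == 1L) {
      plan <- reroot_plan(adj, cent, n)
      children <- children_of2(plan$parent, plan$order)
      for (ci in seq_len(ncol(cm))) {
        t <- t + 1L
        codes[t] <- code_topological(children, cm[, ci], plan$order)
      }
    } else {
      u <- cent[1L]; v <- cent[2L]
      plan_u <- reroot_plan(adj, u, n, block = v)
      plan_v <- reroot_plan(adj, v, n, block = u)
      ch_u <- children_of2(plan_u$parent, plan_u$order)
      ch_v <- children_of2(plan_v$parent, plan_v$order)
      for (ci in seq_len(ncol(cm))) {
        t <- t + 1L
        loops <- cm[, ci]
        half <- sort(c(code_topological(ch_u, loops, plan_u$order),
                       code_topological(ch_v, loops, plan_v$order)),
                     method = "radix")
        codes[t] <- paste0("[", half[1L], "|", half[2L], "]")
      }
    }
  }
  sort(unique(codes), method = "radix")
}

# children lists from explicit parent pointers restricted to `order`
children_of2 <- function(parent, order) {
  ch <- vector("list", length(parent))
  for (v in order) {
    p <- parent[v]
    if (p > 0L) ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

#' Size and loop profile of the largest child subtree
#'
#' Returns `c(Maxv, Maxs)` for a rooted tree: the vertex count of the
#' largest child subtree of the root, and the largest self-loop total
#' among child subtrees attaining that size; both 0 for a single vertex.
#'
#' @param tree a [loop_tree()].
#' @return Integer vector `c(Maxv, Maxs)`.
#' @examples
#' max_v_max_s(loop_tree(c(0, 1, 2), c(0, 1, 0))) # c(2, 1)
#' @export
max_v_max_s <- function(tree) {
  if (!inherits(tree, "loop_tree")) {
    stop("'tree' must be a loop_tree", call. = FALSE)
  }
  adj <- adjacency_list(tree)
  kids <- setdiff(adj[[tree$root]], 0L)
  if (length(kids) == 0L) return(c(0L, 0L))
  sizes <- integer(length(kids))
  loopsums <- integer(length(kids))
  for (i in seq_along(kids)) {
    plan <- reroot_plan(adj, kids[i], tree$n, block = tree$root)
    sizes[i] <- length(plan$order)
    loopsums[i] <- sum(tree$loops[plan$order])
  }
  mv <- max(sizes)
  c(mv, max(loopsums[sizes == mv]))
}

#' Bucket rooted classes by (Maxv, Maxs)
#'
#' Enumerates all rooted isomorphism classes with `n` vertices and `delta`
#' self-loops and tallies them by the size and loop profile of their
#' largest child subtree.  Bucket sizes are the ground truth for the
#' `h(n, delta, m=, d=)` cells of the dynamic program.
#'
#' @inheritParams enumerate_rooted
#' @return A data frame with integer columns `m`, `d`, `count`, sorted by
#'   `(m, d)`.
#' @examples
#' classify_counts(3, 1) # 5 classes over buckets (1,0) (1,1) (2,0) (2,1)
#' @export
classify_counts <- function(n, delta, max_n = 8L, max_delta = 5L) {
  n <- check_scalar_int(n, "n", min = 1)
  delta <- check_scalar_int(delta, "delta", min = 0)
  guard_instance(n, delta, max_n, max_delta)
  pm <- parent_arrays(n)
  cm <- compositions(delta, n)
  total <- ncol(pm) * ncol(cm)
  codes <- character(total)
  ms <- integer(total)
  ds <- integer(total)
  t <- 0L
  for (pi in seq_len(ncol(pm))) {
    parent <- pm[, pi]
    children <- children_of(parent, n)
    size <- subtree_sizes(parent, n)
    rootkids <- children[[1L]]
    for (ci in seq_len(ncol(cm))) {
      t <- t + 1L
      loops <- cm[, ci]
      codes[t] <- code_topological(children, loops, seq_len(n))
      if (is.null(rootkids)) {
        # single vertex: both profile values are zero
      } else {
        loopsum <- loops
        for (v in n:2) loopsum[parent[v]] <- loopsum[parent[v]] + loopsum[v]
        mv <- max(size[rootkids])
        ms[t] <- mv
        ds[t] <- max(loopsum[rootkids][size[rootkids] == mv])
      }
    }
  }
  keep <- !duplicated(codes)
  tab <- table(paste(ms[keep], ds[keep], sep = ","))
  md <- do.call(rbind, strsplit(names(tab), ",", fixed = TRUE))
  out <- data.frame(m = as.integer(md[, 1L]), d = as.integer(md[, 2L]),
                    count = as.integer(tab), row.names = NULL)
  out[order(out$m, out$d), , drop = FALSE]
}

#' Write and read trees in a plain-text edge-list format
#'
#' One block per tree: a header line `n delta`, then `n - 1` lines `u v`
#' (child, parent), then one line `v:count` per vertex carrying at least
#' one self-loop; blocks are separated by blank lines.  Vertex 1 is the
#' root by convention.  Intended for small regression fixtures and
#' documentation, not for scale.
#'
#' @param trees a list of [loop_tree()] objects.
#' @param file path to write to / read from.
#' @return `write_loop_trees()` returns `file` invisibly;
#'   `read_loop_trees()` returns a list of [loop_tree()] objects.
#' @export
write_loop_trees <- function(trees, file) {
  if (inherits(trees, "loop_tree")) trees <- list(trees)
  blocks <- vapply(trees, function(tr) {
    stopifnot(inherits(tr, "loop_tree"))
    lines <- sprintf("%d %d", tr$n, sum(tr$loops))
    for (v in seq_len(tr$n)) {
      if (tr$parent[v] > 0L) {
        lines <- c(lines, sprintf("%d %d", v, tr$parent[v]))
      }
    }
    looped <- which(tr$loops > 0L)
    lines <- c(lines, sprintf("%d:%d", looped, tr$loops[looped]))
    paste(lines, collapse = "\n")
  }, character(1L))
  writeLines(paste(blocks, collapse = "\n\n"), file)
  invisible(file)
}

#' @rdname write_loop_trees
#' @export
read_loop_trees <- function(file) {
  txt <- readLines(file)
  breaks <- cumsum(!nzchar(trimws(txt)))
  blocks <- split(txt[nzchar(trimws(txt))], breaks[nzchar(trimws(txt))])
  lapply(unname(blocks), function(lines) {
    header <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
    n <- header[1L]
    parent <- integer(n)
    loops <- integer(n)
    for (ln in lines[-1L]) {
      ln <- trimws(ln)
      if (grepl(":", ln, fixed = TRUE)) {
        kv <- as.integer(strsplit(ln, ":", fixed = TRUE)[[1L]])
        loops[kv[1L]] <- kv[2L]
      } else {
        uv <- as.integer(strsplit(ln, "\\s+")[[1L]])
        parent[uv[1L]] <- uv[2L]
      }
    }
    loop_tree(parent, loops)
  })
}
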