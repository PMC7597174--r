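# The rooted-count table and its query surface.
#
# A count table holds, for every sub-instance (i, j) with i <= n and
# j <= delta, the three count families
#   h(i, j, m<=, d<=)  rooted trees with Maxv <= m and Maxs <= d,
#   h(i, j, m=,  d<=)  Maxv exactly m,
#   h(i, j, m=,  d=)   Maxv exactly m and Maxs exactly d,
# where Maxv is the vertex count of the largest child subtree of the root
# and Maxs the largest self-loop total among child subtrees of that size.

#' Normalize a count query
#'
#' Caps the subtree-size bound at `n - 1` (no child subtree can be larger)
#' and the subtree-loop bound at `delta`, the clamping under which the
#' count families are invariant.  Normalization is idempotent.
#'
#' @param n vertex count, integer `>= 1`.
#' @param delta total self-loop count, integer `>= 0`.
#' @param m bound on the vertex count of the largest child subtree.
#' @param d bound on the self-loop count among largest child subtrees.
#' @return An object of class `"dp_key"` with fields `n`, `delta`, `m_cap`
#'   and `d_cap`.
#' @examples
#' normalize_key(5, 2, 99, 99) # m_cap 4, d_cap 2
#' @export
normalize_key <- function(n, delta, m, d) {
  n <- check_scalar_int(n, "n", min = 1)
  delta <- check_scalar_int(delta, "delta", min = 0)
  m <- check_scalar_int(m, "m", min = 0)
  d <- check_scalar_int(d, "d", min = 0)
  structure(
    list(n = n, delta = delta,
         m_cap = min(m, n - 1L), d_cap = min(d, delta)),
    class = "dp_key"
  )
}

#' @export
print.dp_key <- function(x, ...) {
  cat(sprintf("<dp_key> n = %d, delta = %d, m_cap = %d, d_cap = %d\n",
              x$n, x$delta, x$m_cap, x$d_cap))
  invisible(x)
}

#' Build the rooted-count table
#'
#' Runs the bottom-up dynamic program that fills all three count families
#' for every `1 <= i <= n`, `0 <= j <= delta`, `0 <= m <= i - 1` and
#' `0 <= d <= j`, in the order vertices, then loops, then subtree-size
#' bound, then subtree-loop bound.  The inner recurrence decomposes a tree
#' by the number `q` of maximal child subtrees at its root, weighting each
#' `q` by the multiset coefficient of the maximal-subtree family;
#' the coefficient is maintained incrementally with an exact-division
#' assertion at every step.
#'
#' All arithmetic is exact arbitrary precision; the table is held outside
#' the R heap and queried through [h_le_le()], [h_eq_le()] and
#' [h_eq_eq()].
#'
#' @param n largest vertex count covered, integer `>= 1`.
#' @param delta largest self-loop count covered, integer `>= 0`.
#' @param cross_check if `TRUE`, additionally recompute every incremental
#'   multiset coefficient from its closed form and stop on any mismatch
#'   (a self-diagnostic; roughly doubles the work).
#' @return An object of class `"count_table"`.
#' @examples
#' tbl <- build_table(4, 1)
#' h_le_le(normalize_key(4, 1, 3, 1), tbl) # rooted count h(4, 1)
#' @export
build_table <- function(n, delta, cross_check = FALSE) {
  n <- check_scalar_int(n, "n", min = 1)
  delta <- check_scalar_int(delta, "delta", min = 0)
  structure(
    list(ptr = cpp_build_table(n, delta, isTRUE(cross_check)),
         n_max = n, delta_max = delta),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> n <= %d, delta <= %d (3 families, exact integers)\n",
              x$n_max, x$delta_max))
  invisible(x)
}

check_table <- function(table, key) {
  if (!inherits(table, "count_table")) {
    stop("'table' must be a count_table built by build_table()", call. = FALSE)
  }
  if (!inherits(key, "dp_key")) {
    stop("'key' must be a dp_key from normalize_key()", call. = FALSE)
  }
  if (key$n > table$n_max || key$delta > table$delta_max) {
    stop(sprintf("table covers (n <= %d, delta <= %d) but the key asks for (%d, %d)",
                 table$n_max, table$delta_max, key$n, key$delta), call. = FALSE)
  }
  invisible(TRUE)
}

#' Query the count families
#'
#' `h_le_le()` returns the number of non-isomorphic rooted trees with
#' `key$n` vertices and `key$delta` self-loops whose largest child subtree
#' has at most `m_cap` vertices and, among child subtrees of that maximal
#' size, at most `d_cap` self-loops.  `h_eq_le()` fixes the subtree size
#' exactly; `h_eq_eq()` fixes both size and loop count exactly.
#'
#' @param key a normalized query from [normalize_key()].
#' @param table a [build_table()] result covering `(key$n, key$delta)`.
#' @return Exact count as a decimal character string.
#' @examples
#' tbl <- build_table(3, 1)
#' h_eq_eq(normalize_key(3, 1, 2, 1), tbl) # "2"
#' @export
h_le_le <- function(key, table) {
  check_table(table, key)
  cpp_lookup(table$ptr, key$n, key$delta, key$m_cap, key$d_cap, "le_le")
}

#' @rdname h_le_le
#' @export
h_eq_le <- function(key, table) {
  check_table(table, key)
  cpp_lookup(table$ptr, key$n, key$delta, key$m_cap, key$d_cap, "eq_le")
}

#' @rdname h_le_le
#' @export
h_eq_eq <- function(key, table) {
  check_table(table, key)
  cpp_lookup(table$ptr, key$n, key$delta, key$m_cap, key$d_cap, "eq_eq")
}

#' Count non-isomorphic rooted trees with self-loops
#'
#' The number `h(n, delta)` of mutually non-isomorphic rooted trees with
#' `n` vertices and `delta` self-loops and no multi-edges, i.e. the
#' unconstrained cell `h(n, delta, n-1<=, delta<=)` of the count table.
#'
#' @inheritParams build_table
#' @param table optionally, an existing [build_table()] result covering
#'   `(n, delta)`; built on the fly when `NULL`.
#' @return Exact count as a decimal character string.
#' @examples
#' h_rooted(2, 3)  # "4": the loop split between root and child, 4 ways
#' h_rooted(10, 0) # "719" rooted trees on 10 vertices
#' @export
h_rooted <- function(n, delta, table = NULL) {
  n <- check_scalar_int(n, "n", min = 1)
  delta <- check_scalar_int(delta, "delta", min = 0)
  if (is.null(table)) table <- build_table(n, delta)
  h_le_le(normalize_key(n, delta, n - 1L, delta), table)
}

#' Serialize a count table to JSON
#'
#' Dumps every stored cell of the three families as decimal strings keyed
#' by `"i,j,m,d"`, for debugging and external inspection.  Values are kept
#' as strings so that no consumer is tempted to read them as doubles.
#'
#' @param table a [build_table()] result.
#' @param file optional path; when given, the JSON is written there and the
#'   path returned invisibly.
#' @return JSON as a length-1 character vector (class `json`), or the file
#'   path invisibly.
#' @export
table_to_json <- function(table, file = NULL) {
  if (!inherits(table, "count_table")) {
    stop("'table' must be a count_table", call. = FALSE)
  }
  one_family <- function(fam) {
    d <- cpp_dump_family(table$ptr, fam)
    stats::setNames(as.list(d$value),
                    paste(d$i, d$j, d$k, d$p, sep = ","))
  }
  obj <- list(
    n_max = table$n_max,
    delta_max = table$delta_max,
    le_le = one_family("le_le"),
    eq_le = one_family("eq_le"),
    eq_eq = one_family("eq_eq")
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(file))
  }
  json
}
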