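# Unrooted counts via Jordan's centroid.
#
# Every tree has either a unicentroid (a unique vertex whose removal
# leaves components of at most floor((n-1)/2) vertices) or, for even n, a
# bicentroid (an edge splitting the tree into two halves of exactly n/2
# vertices).  Rooting at the centroid makes the unrooted count a pair of
# reads from the rooted table: unicentroidal trees are rooted trees whose
# child subtrees all have at most floor((n-1)/2) vertices, and
# bicentroidal trees are unordered pairs of rooted half-trees.

#' Count unicentroidal trees
#'
#' The number of non-isomorphic trees with `n` vertices and `delta`
#' self-loops whose centroid is a single vertex: the table cell
#' `h(n, delta, floor((n-1)/2)<=, delta<=)`.
#'
#' @inheritParams h_rooted
#' @return Exact count as a decimal character string.
#' @examples
#' unicentroid_count(4, 0) # "1": only the 4-star
#' @export
unicentroid_count <- function(n, delta, table = NULL) {
  n <- check_scalar_int(n, "n", min = 1)
  delta <- check_scalar_int(delta, "delta", min = 0)
  if (is.null(table)) table <- build_table(n, delta)
  h_le_le(normalize_key(n, delta, (n - 1L) %/% 2L, delta), table)
}

#' Count bicentroidal trees
#'
#' For even `n`, the number of non-isomorphic trees with `n` vertices and
#' `delta` self-loops whose centroid is an edge.  Removing the bicentroid
#' leaves an unordered pair of rooted trees on `n/2` vertices whose loop
#' counts sum to `delta`, each half with child subtrees of fewer than
#' `n/2` vertices:
#' \deqn{\sum_{i=0}^{\lfloor(\Delta-1)/2\rfloor} h_i h_{\Delta-i}
#'       + \alpha \binom{h_{\Delta/2}+1}{2},}
#' where \eqn{h_i = h(n/2, i, n/2-1\le, i\le)} and \eqn{\alpha = 1} iff
#' `delta` is even (the same-family pair term counts unordered pairs with
#' repetition).  The half-size cells are read from the `(n, delta)` table,
#' which stores them already.
#'
#' @inheritParams h_rooted
#' @return Exact count as a decimal character string.
#' @examples
#' bicentroid_count(2, 3) # "2": loop splits {0,3} and {1,2}
#' @export
bicentroid_count <- function(n, delta, table = NULL) {
  n <- check_scalar_int(n, "n", min = 2)
  delta <- check_scalar_int(delta, "delta", min = 0)
  if (n %% 2L != 0L) {
    stop("bicentroids exist only for an even number of vertices", call. = FALSE)
  }
  if (is.null(table)) table <- build_table(n, delta)
  half <- n %/% 2L
  total <- "0"
  if (delta >= 1L) {
    for (i in 0:((delta - 1L) %/% 2L)) {
      a <- h_le_le(normalize_key(half, i, half - 1L, i), table)
      b <- h_le_le(normalize_key(half, delta - i, half - 1L, delta - i), table)
      total <- big_add(total, big_mul(a, b))
    }
  }
  if (delta %% 2L == 0L) {
    hh <- h_le_le(normalize_key(half, delta %/% 2L, half - 1L, delta %/% 2L),
                  table)
    total <- big_add(total, multiset_coefficient(hh, 2L))
  }
  total
}

#' Count non-isomorphic unrooted trees with self-loops
#'
#' The number `t(n, delta)` of mutually non-isomorphic (unrooted) trees
#' with `n` vertices, `delta` self-loops and no multi-edges:
#' [unicentroid_count()] for odd `n`, plus [bicentroid_count()] when `n`
#' is even.  A single table built for `(n, delta)` serves both terms.
#'
#' @inheritParams h_rooted
#' @return Exact count as a decimal character string.
#' @examples
#' t_unrooted(10, 0) # "106" simple trees on 10 vertices
#' t_unrooted(3, 1)  # "2": loop on the path's centre or on an end
#' @export
t_unrooted <- function(n, delta, table = NULL) {
  n <- check_scalar_int(n, "n", min = 1)
  delta <- check_scalar_int(delta, "delta", min = 0)
  if (is.null(table)) table <- build_table(n, delta)
  uni <- unicentroid_count(n, delta, table)
  if (n %% 2L != 0L) return(uni)
  big_add(uni, bicentroid_count(n, delta, table))
}
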