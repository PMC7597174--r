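# Bounds on the number of tree-like polymer topologies.
#
# A polymer topology is a connected graph in which every vertex has degree
# at least three (a self-loop contributing 2); it is the skeleton left
# after repeatedly deleting degree-1 and degree-2 vertices of a chemical
# graph.  For trees with self-loops and no multi-edges the cycle rank
# equals the number of self-loops, and the unrooted counts t(n, delta)
# sandwich the number p(r) of tree-like polymer topologies of rank r.

#' Lower bound on the number of tree-like polymer topologies
#'
#' Every simple tree on `n` vertices with `k` self-loops placed on each
#' vertex is a polymer topology of cycle rank `n * k`, and distinct trees
#' stay distinct, so
#' \deqn{p(r) \ge \sum_{nk = r} t(n, 0),}
#' the sum running over all factorizations of `r` into positive `n` and
#' `k` — that is, over the divisors `n` of `r`.
#'
#' @param r cycle rank, integer `>= 1`.
#' @return Exact bound as a decimal character string.
#' @examples
#' polymer_lower(4) # t(1,0) + t(2,0) + t(4,0) = "4"
#' @export
polymer_lower <- function(r) {
  r <- check_scalar_int(r, "r", min = 1)
  total <- "0"
  for (n in seq_len(r)) {
    if (r %% n == 0L) total <- big_add(total, t_unrooted(n, 0L))
  }
  total
}

#' Upper bound on the number of tree-like polymer topologies
#'
#' A tree on `n >= 2` vertices needs at least `ceiling(n/2) + 1`
#' self-loops before every vertex can reach degree three, so every rank-r
#' tree-like polymer on `n` vertices exists only when
#' `ceiling(n/2) + 1 <= r`.  Counting all trees with `r` loops on each
#' feasible vertex count gives
#' \deqn{p(r) \le \sum_{\lceil n/2\rceil + 1 \le r} t(n, r),}
#' a finite sum since `n <= 2(r - 1)`.  The empty sum at `r = 1` is 0.
#'
#' @inheritParams polymer_lower
#' @return Exact bound as a decimal character string.
#' @examples
#' polymer_upper(2) # t(1,2) + t(2,2) = "3"
#' @export
polymer_upper <- function(r) {
  r <- check_scalar_int(r, "r", min = 1)
  total <- "0"
  n <- 1L
  while (ceiling(n / 2) + 1L <= r) {
    total <- big_add(total, t_unrooted(n, r))
    n <- n + 1L
  }
  total
}

#' Bracket the number of tree-like polymer topologies of a given rank
#'
#' Bundles [polymer_lower()] and [polymer_upper()] for cycle rank `r`.
#' The bounds are computed exactly as stated; at `r = 1` the lower bound's
#' premise fails (a single vertex with one loop has degree 2, not a
#' polymer) and the lower bound exceeds the upper bound — the result is
#' returned as computed with `valid = FALSE` and a warning, never silently
#' repaired.
#'
#' @inheritParams polymer_lower
#' @return An object of class `"polymer_bounds"`: a list with `rank`,
#'   `lower`, `upper` (decimal strings) and logical `valid`
#'   (`lower <= upper`).
#' @examples
#' polymer_bounds(2) # lower "2", upper "3"
#' @export
polymer_bounds <- function(r) {
  r <- check_scalar_int(r, "r", min = 1)
  lower <- polymer_lower(r)
  upper <- polymer_upper(r)
  valid <- big_cmp(lower, upper) <= 0L
  if (!valid) {
    warning("polymer bounds for rank ", r, " are inconsistent (lower ", lower,
            " > upper ", upper, "); the rank-1 case lies outside the bound's premise",
            call. = FALSE)
  }
  structure(list(rank = r, lower = lower, upper = upper, valid = valid),
            class = "polymer_bounds")
}

#' @export
print.polymer_bounds <- function(x, ...) {
  cat(sprintf("<polymer_bounds> rank %d: %s <= p(r) <= %s%s\n",
              x$rank, x$lower, x$upper,
              if (x$valid) "" else "  [INVALID: lower exceeds upper]"))
  invisible(x)
}
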