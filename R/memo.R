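# Reference implementation: top-down memoized recursion written straight
# from the recurrences, independent of the iterative table's loop order
# and of the compiled code.  Used to cross-check the primary engine on
# instances whose counts fit exactly in a double (< 2^53); kept in plain
# R on purpose.

#' Rooted count by memoized recursion (reference engine)
#'
#' Computes `h(n, delta)` with a direct top-down recursion over the three
#' count families, memoized in an environment.  Exact only while every
#' intermediate count stays below 2^53 (checked; small instances only) —
#' use [h_rooted()] for anything serious.  Exists so the test suite can
#' compare two independently written engines.
#'
#' @inheritParams build_table
#' @return The count as a double.
#' @examples
#' h_rooted_memo(6, 2) == as.numeric(h_rooted(6, 2))
#' @export
h_rooted_memo <- function(n, delta) {
  n <- check_scalar_int(n, "n", min = 1)
  delta <- check_scalar_int(delta, "delta", min = 0)
  memo <- new.env(parent = emptyenv(), hash = TRUE)

  guard <- function(x) {
    if (x >= 2^53) {
      stop("count exceeds the exact double range; use h_rooted()", call. = FALSE)
    }
    x
  }

  hLL <- function(i, j, k, p) {
    if (k < 0L || p < 0L) return(0)
    k <- min(k, i - 1L)
    p <- min(p, j)
    if (i == 1L) return(1)
    if (k == 0L) return(0)
    key <- paste0("L", i, ".", j, ".", k, ".", p)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- guard(hLL(i, j, k - 1L, p) + hEL(i, j, k, p))
    memo[[key]] <- v
    v
  }

  hEL <- function(i, j, k, p) {
    if (k > i - 1L) return(0)
    p <- min(p, j)
    if (i == 1L) return(1)   # k forced to 0 here
    if (k == 0L) return(0)
    if (p == 0L) return(hEE(i, j, k, 0L))
    key <- paste0("E", i, ".", j, ".", k, ".", p)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- guard(hEL(i, j, k, p - 1L) + hEE(i, j, k, p))
    memo[[key]] <- v
    v
  }

  hEE <- function(i, j, k, p) {
    if (k > i - 1L || p > j) return(0)
    if (i == 1L) return(if (k == 0L && p == 0L) 1 else 0)
    if (k == 0L) return(0)
    if (k == 1L && (i == 2L || p == 0L)) return(1)
    key <- paste0("X", i, ".", j, ".", k, ".", p)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    lmax <- (i - 1L) %/% k
    if (p >= 1L) lmax <- min(lmax, j %/% p)
    fam <- hLL(k, p, k - 1L, p)
    v <- 0
    if (lmax >= 1L) {
      for (q in seq_len(lmax)) {
        cq <- guard(choose(fam + q - 1, q))
        v <- v + cq * (
          if (p == 0L) {
            hLL(i - q * k, j, min(i - k * q - 1L, k - 1L), j)
          } else {
            hEL(i - k * q, j - p * q, k, min(j - p * q, p - 1L)) +
              hLL(i - k * q, j - p * q, min(i - k * q - 1L, k - 1L), j - p * q)
          })
        guard(v)
      }
    }
    memo[[key]] <- v
    v
  }

  hLL(n, delta, n - 1L, delta)
}
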