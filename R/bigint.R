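# Exact integer arithmetic on decimal strings.  Counts produced by this
# package routinely exceed 2^53, so they are carried as character vectors
# of decimal digits and combined with these helpers, never as doubles.

#' Coerce a value to an exact count string
#'
#' Accepts a nonnegative integer-valued numeric (exactly representable,
#' i.e. below 2^53) or a string of decimal digits, and returns the
#' canonical decimal string.
#'
#' @param x scalar numeric or character.
#' @return A decimal character scalar.
#' @keywords internal
#' @noRd
as_count <- function(x) {
  if (length(x) != 1L) stop("expected a scalar count", call. = FALSE)
  if (is.character(x)) {
    if (!grepl("^[0-9]+$", x)) {
      stop("count strings must contain only decimal digits: '", x, "'",
           call. = FALSE)
    }
    return(sub("^0+(?=.)", "", x, perl = TRUE))
  }
  if (is.numeric(x)) {
    if (is.na(x) || x < 0 || x != trunc(x)) {
      stop("counts must be nonnegative integers", call. = FALSE)
    }
    if (x >= 2^53) {
      stop("numeric counts above 2^53 are not exact; pass a digit string",
           call. = FALSE)
    }
    return(sprintf("%.0f", x))
  }
  stop("cannot interpret an object of class '", class(x)[1L],
       "' as a count", call. = FALSE)
}

#' Exact arithmetic on decimal count strings
#'
#' Addition, multiplication and three-way comparison of nonnegative exact
#' integers represented as decimal strings.  These are the primitives used
#' to combine table cells (bicentroid products, polymer-bound sums) without
#' ever leaving exact arithmetic.
#'
#' @param a,b nonnegative integers, as digit strings or exact numerics.
#' @return `big_add()` and `big_mul()` return a decimal string; `big_cmp()`
#'   returns -1, 0 or 1 as `a` is less than, equal to or greater than `b`.
#' @examples
#' big_add("999999999999999999", "1")
#' big_mul("123456789", "987654321")
#' big_cmp("10", "9")
#' @export
big_add <- function(a, b) cpp_big_add(as_count(a), as_count(b))

#' @rdname big_add
#' @export
big_mul <- function(a, b) cpp_big_mul(as_count(a), as_count(b))

#' @rdname big_add
#' @export
big_cmp <- function(a, b) cpp_big_cmp(as_count(a), as_count(b))

#' Multiset coefficient (combinations with repetition)
#'
#' The number of multisets of size `t` drawn from a family of
#' `family_size` distinct members, \eqn{\binom{h + t - 1}{t}}.  This is the
#' coefficient weighting each choice of `t` maximal child subtrees in the
#' rooted-count recurrence.
#'
#' @param family_size nonnegative integer (digit string or exact numeric);
#'   may exceed the double range.
#' @param t nonnegative integer number of draws.
#' @return Exact value as a decimal character string; `"1"` when `t = 0`,
#'   `"0"` when `family_size = 0` and `t >= 1`.
#' @examples
#' multiset_coefficient(3, 2) # "6"
#' multiset_coefficient(2, 3) # "4"
#' @export
multiset_coefficient <- function(family_size, t) {
  t <- check_scalar_int(t, "t", min = 0)
  cpp_multiset_coefficient(as_count(family_size), t)
}

# Shared scalar-integer validator used across the user-facing API.
check_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != trunc(x)) {
    stop("'", name, "' must be a single integer", call. = FALSE)
  }
  if (x < min) {
    stop("'", name, "' must be at least ", min, call. = FALSE)
  }
  as.integer(x)
}
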