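# Exact string arithmetic and the multiset coefficient.

test_that("string arithmetic is exact beyond the double range", {
  expect_identical(big_add("9007199254740992", "1"), "9007199254740993")
  expect_identical(big_mul("999999999999999999", "999999999999999999"),
                   "999999999999999998000000000000000001")
  expect_identical(big_add("0", "0"), "0")
  expect_identical(big_mul("0", "123456789123456789"), "0")
  expect_identical(big_cmp("2547562522909694331", "2547562522909694330"), 1L)
  expect_identical(big_cmp("99", "100"), -1L)
  expect_identical(big_cmp("0100", "100"), 0L)
})

test_that("string arithmetic agrees with doubles where doubles are exact", {
  set.seed(11)
  a <- sample.int(1e6, 25)
  b <- sample.int(1e6, 25)
  expect_identical(mapply(big_add, a, b, USE.NAMES = FALSE),
                   as.character(a + b))
  expect_identical(mapply(big_mul, a, b, USE.NAMES = FALSE),
                   sprintf("%.0f", as.numeric(a) * b))
  expect_identical(mapply(big_cmp, a, b, USE.NAMES = FALSE),
                   as.integer(sign(a - b)))
})

test_that("counts reject malformed input", {
  expect_error(big_add("12x", "1"), "decimal digits")
  expect_error(big_add(-1, "1"), "nonnegative")
  expect_error(big_add(1.5, "1"), "nonnegative integers")
  expect_error(big_add(2^53, "1"), "not exact")
})

test_that("multiset coefficient matches combinations with repetition", {
  expect_count_equal(multiset_coefficient(3, 2), 6)
  expect_count_equal(multiset_coefficient(2, 3), 4)
  for (q in c(0L, 1L, 7L, 40L)) {
    expect_count_equal(multiset_coefficient(1, q), 1)
  }
  expect_count_equal(multiset_coefficient(5, 0), 1)
  expect_count_equal(multiset_coefficient(0, 0), 1)
  expect_count_equal(multiset_coefficient(0, 3), 0)
  # dense small grid against R's own binomial
  for (h in 0:8) {
    for (t in 0:8) {
      expect_count_equal(multiset_coefficient(h, t), choose(h + t - 1, t))
    }
  }
})

test_that("multiset coefficient stays exact for huge families", {
  h <- "1000000000000000000" # 1e18: h*(h+1)/2 needs ~36 digits
  expect_identical(multiset_coefficient(h, 2),
                   "500000000000000000500000000000000000")
  expect_error(multiset_coefficient(3, -1), "at least 0")
})
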