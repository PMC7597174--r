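# The rooted-count dynamic program: boundary cells, recurrence cells,
# whole-table structure, and agreement with the independent reference
# recursion.

test_that("boundary cells follow the base cases", {
  tbl <- build_table(3, 2)
  # single vertex: Maxv = Maxs = 0, exactly when it exists
  expect_count_equal(h_eq_eq(normalize_key(1, 0, 0, 0), tbl), 1)
  expect_count_equal(h_eq_eq(normalize_key(1, 2, 0, 1), tbl), 0)
  expect_count_equal(h_eq_le(normalize_key(1, 2, 0, 2), tbl), 1)
  expect_count_equal(h_le_le(normalize_key(1, 2, 0, 2), tbl), 1)
  # n >= 2 with subtree-size cap 0 is impossible
  expect_count_equal(h_le_le(normalize_key(3, 0, 0, 0), tbl), 0)
  # star-shaped boundary: all child subtrees are loopless singletons
  expect_count_equal(h_eq_eq(normalize_key(3, 0, 1, 0), tbl), 1)
})

test_that("two-vertex trees count the loop split", {
  tbl <- build_table(2, 5)
  expect_count_equal(h_eq_le(normalize_key(2, 5, 1, 3), tbl), 4)
  expect_count_equal(h_le_le(normalize_key(2, 3, 1, 3), tbl), 4)
  expect_count_equal(h_rooted(2, 3), 4)
})

test_that("recurrence cells match hand enumeration on 3 vertices", {
  tbl <- build_table(3, 1)
  # root with two children, the loop on one child
  expect_count_equal(h_eq_eq(normalize_key(3, 1, 1, 1), tbl), 1)
  # end-rooted path, loop below the root
  expect_count_equal(h_eq_eq(normalize_key(3, 1, 2, 1), tbl), 2)
  expect_count_equal(h_eq_le(normalize_key(3, 1, 2, 1), tbl), 3)
  expect_count_equal(h_rooted(3, 1, tbl), 5)
})

test_that("rooted simple-tree counts match the brute-force 10-vertex value", {
  tbl <- build_table(10, 0)
  expect_count_equal(h_le_le(normalize_key(10, 0, 9, 0), tbl), 719)
  expect_count_equal(h_rooted(4, 0), 4)
  expect_count_equal(h_rooted(1, 7), 1)
})

test_that("closed forms hold for one and two vertices", {
  for (delta in c(0L, 1L, 17L, 60L)) {
    expect_count_equal(h_rooted(1, delta), 1)
    expect_count_equal(h_rooted(2, delta), delta + 1)
  }
})

test_that("counts are monotone in vertices and loops", {
  for (n in 1:8) {
    for (delta in 0:4) {
      expect_true(big_cmp(h_rooted(n, delta + 1L), h_rooted(n, delta)) >= 0)
      expect_true(big_cmp(h_rooted(n + 1L, delta), h_rooted(n, delta)) >= 0)
    }
  }
})

test_that("iterative table agrees with the top-down reference recursion", {
  for (n in 1:8) {
    for (delta in 0:4) {
      expect_identical(h_rooted_memo(n, delta), as.numeric(h_rooted(n, delta)),
                       label = sprintf("memo(%d, %d)", n, delta))
    }
  }
})

test_that("partition identities hold across a small table", {
  tbl <- build_table(5, 3)
  for (i in 1:5) {
    for (j in 0:3) {
      for (k in 0:(i - 1L)) {
        for (p in 0:j) {
          key <- normalize_key(i, j, k, p)
          ll <- h_le_le(key, tbl)
          el <- h_eq_le(key, tbl)
          ee <- h_eq_eq(key, tbl)
          if (k >= 1L) {
            prev <- h_le_le(normalize_key(i, j, k - 1L, p), tbl)
            expect_identical(big_add(prev, el), ll)
          }
          if (p >= 1L) {
            prev <- h_eq_le(normalize_key(i, j, k, p - 1L), tbl)
            expect_identical(big_add(prev, ee), el)
          }
        }
      }
    }
  }
})

test_that("self-checking build passes its incremental-coefficient assertions", {
  expect_no_error(build_table(8, 4, cross_check = TRUE))
})

test_that("queries outside the table's coverage are refused", {
  tbl <- build_table(4, 2)
  expect_error(h_le_le(normalize_key(5, 2, 4, 2), tbl), "covers")
  expect_error(h_le_le(normalize_key(4, 3, 3, 3), tbl), "covers")
  expect_error(h_le_le(list(n = 4), tbl), "dp_key")
  expect_error(h_le_le(normalize_key(4, 2, 3, 2), "nope"), "count_table")
})

test_that("JSON serialization round-trips exact cell values", {
  tbl <- build_table(3, 1)
  parsed <- jsonlite::fromJSON(table_to_json(tbl))
  expect_identical(parsed$n_max, 3L)
  expect_identical(parsed$le_le[["3,1,2,1"]], h_rooted(3, 1))
  expect_identical(parsed$eq_eq[["3,1,2,1"]], "2")
  expect_identical(parsed$le_le[["1,0,0,0"]], "1")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  table_to_json(tbl, file = tmp)
  expect_identical(jsonlite::fromJSON(tmp)$eq_le[["2,1,1,1"]], "2")
})
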