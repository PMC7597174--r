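# The brute-force enumerator itself: canonical codes, centroids, and the
# (Maxv, Maxs) classifier.

test_that("loop_tree validates its structure", {
  expect_s3_class(loop_tree(c(0, 1, 2), c(0, 1, 0)), "loop_tree")
  expect_error(loop_tree(c(0, 0, 1)), "exactly one vertex")
  expect_error(loop_tree(c(2, 1)), "exactly one vertex")   # a 2-cycle, no root
  expect_error(loop_tree(c(0, 3, 2)), "cycle")             # 2 <-> 3 detached
  expect_error(loop_tree(c(0, 1), c(-1, 0)), "nonnegative")
})

test_that("canonical codes are invariant under relabelling", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    tr <- random_loop_tree(n, sample(0:4, 1))
    perm <- sample.int(n)
    tr2 <- relabel_tree(tr, perm)
    expect_identical(canonical_code(tr2, perm[tr$root]), canonical_code(tr))
  }
})

test_that("canonical codes separate genuinely different placements", {
  loop_on_root <- loop_tree(c(0, 1, 2), c(1, 0, 0))
  loop_on_mid <- loop_tree(c(0, 1, 2), c(0, 1, 0))
  loop_on_end <- loop_tree(c(0, 1, 2), c(0, 0, 1))
  codes <- c(canonical_code(loop_on_root), canonical_code(loop_on_mid),
             canonical_code(loop_on_end))
  expect_identical(anyDuplicated(codes), 0L)
  expect_identical(canonical_code(loop_tree(0L, 5L)), "(5:)")
})

test_that("rooted enumeration finds the right class counts", {
  expect_length(enumerate_rooted(1, 5), 1)
  expect_length(enumerate_rooted(2, 1), 2)
  expect_length(enumerate_rooted(3, 0), 2)
  expect_length(enumerate_rooted(4, 0), 4)
})

test_that("unrooted enumeration collapses rootings", {
  expect_length(enumerate_unrooted(1, 0), 1)
  expect_length(enumerate_unrooted(4, 0), 2)
  expect_length(enumerate_unrooted(3, 1), 2)
})

test_that("instance guards refuse explosive inputs unless overridden", {
  expect_error(enumerate_rooted(9, 0), "guard")
  expect_error(enumerate_unrooted(3, 6), "guard")
  expect_length(enumerate_rooted(9, 0, max_n = 9), 286)
})

test_that("the child-subtree profile matches hand-worked cases", {
  expect_identical(max_v_max_s(loop_tree(0L, 3L)), c(0L, 0L))
  expect_identical(max_v_max_s(loop_tree(c(0, 1, 2), c(0, 1, 0))), c(2L, 1L))
  expect_identical(max_v_max_s(loop_tree(c(0, 1, 1), c(1, 0, 0))), c(1L, 0L))
  # two maximal subtrees: Maxs is the larger loop total among them
  expect_identical(max_v_max_s(loop_tree(c(0, 1, 1, 2, 3), c(0, 0, 0, 0, 2))),
                   c(2L, 2L))
})

test_that("the classifier buckets every class exactly once", {
  cc <- classify_counts(3, 1)
  expect_identical(cc, data.frame(m = c(1L, 1L, 2L, 2L), d = c(0L, 1L, 0L, 1L),
                                  count = c(1L, 1L, 1L, 2L)))
  expect_identical(classify_counts(1, 0),
                   data.frame(m = 0L, d = 0L, count = 1L))
  expect_identical(classify_counts(2, 0),
                   data.frame(m = 1L, d = 0L, count = 1L))
  for (n in 3:6) {
    cc <- classify_counts(n, 2)
    expect_identical(sum(cc$count), length(enumerate_rooted(n, 2)))
  }
})

test_that("centroid components obey Jordan's bound", {
  # independent component-size computation by edge removal
  comp_sizes <- function(parent, n, v) {
    sizes <- integer(0)
    for (start in which(seq_len(n) != v)) {
      reach <- start
      repeat {
        grown <- unique(c(reach,
                          parent[reach][parent[reach] > 0L],
                          which(parent %in% reach)))
        grown <- setdiff(grown, v)
        if (length(grown) == length(reach)) break
        reach <- grown
      }
      sizes <- c(sizes, length(reach))
    }
    unique(sizes)
  }
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    tr <- random_loop_tree(n, 0)
    cent <- treeloops:::centroid_vertices(tr$parent, n)
    expect_true(length(cent) %in% c(1L, 2L))
    if (length(cent) == 1L) {
      expect_true(all(comp_sizes(tr$parent, n, cent) <= (n - 1) %/% 2))
    } else {
      expect_identical(n %% 2L, 0L)
      for (v in cent) {
        expect_true(max(comp_sizes(tr$parent, n, v)) == n %/% 2L)
      }
    }
  }
})

test_that("edge-list fixtures round-trip", {
  trees <- list(
    loop_tree(c(0, 1, 2), c(0, 1, 0)),
    loop_tree(0L, 5L),
    loop_tree(c(0, 1, 1, 2), c(2, 0, 1, 0))
  )
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  write_loop_trees(trees, tmp)
  back <- read_loop_trees(tmp)
  expect_length(back, 3)
  for (i in seq_along(trees)) {
    expect_identical(canonical_code(back[[i]]), canonical_code(trees[[i]]))
    expect_identical(sum(back[[i]]$loops), sum(trees[[i]]$loops))
  }
})
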