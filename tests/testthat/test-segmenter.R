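mk_chain <- function(anchors, n_seq) {
  structure(list(anchors = lapply(anchors, function(a) {
    a$occs$type <- "exact"; a$occs$identity <- 1; a
  }), n_seq = n_seq), class = "chain_set")
}

mk_anchor <- function(len, seq, start)
  list(length = len,
       occs = data.frame(seq = seq, start = start, end = start + len))

test_that("one all-covering anchor gives head/anchor/tail and no fragments", {
  ss <- memalign:::new_sequence_set(c("a", "b", "c"),
                                    c("AAACGTACGTTT", "CCACGTACGTGG",
                                      "TTACGTACGTAA"))
  ch <- mk_chain(list(mk_anchor(8, 1:3, c(3, 3, 3))), 3)
  plan <- build_segmentation(ch, ss)
  kinds <- vapply(plan$columns, function(b) b$kind, character(1))
  expect_equal(kinds, c("segment", "anchor", "segment"))
  expect_equal(nrow(plan$fragments), 0)
  expect_equal(segment_count(plan), 2)
  expect_true(memalign:::plan_tiles_ok(plan, ss))
})

test_that("zero anchors degenerate to one whole-sequence segment", {
  ss <- memalign:::new_sequence_set(c("a", "b"), c("ACGT", "AGGT"))
  plan <- build_segmentation(mk_chain(list(), 2), ss)
  expect_length(plan$columns, 1)
  expect_equal(plan$columns[[1]]$kind, "segment")
  expect_equal(nrow(plan$columns[[1]]$members), 2)
  expect_true(memalign:::plan_tiles_ok(plan, ss))
})

test_that("a sequence skipped by an anchor contributes a fragment", {
  # anchors A (all three) and B (seqs 1, 2 only): seq 3's span between A and
  # the tail is a fragment bounded by A on the left
  ss <- memalign:::new_sequence_set(
    c("a", "b", "c"),
    c("ACGTAAAATTTTCCGG", "ACGTCCCCTTTTGGAA", "ACGTGGGGAACC"))
  ch <- mk_chain(list(mk_anchor(4, 1:3, c(1, 1, 1)),
                      mk_anchor(4, 1:2, c(9, 9))), 3)
  plan <- build_segmentation(ch, ss)
  fr <- plan$fragments
  expect_true(any(fr$seq == 3 & fr$left_anchor == 1 & is.na(fr$right_anchor)))
  expect_true(memalign:::plan_tiles_ok(plan, ss))
  # segment between A and B holds only the sequences covered by both
  seg1 <- Filter(function(b) b$kind == "segment" && b$id == "seg1",
                 plan$columns)[[1]]
  expect_setequal(seg1$members$seq, c(1, 2))
})

test_that("plans tile random pipeline chains exactly", {
  set.seed(17)
  for (i in 1:6) {
    fam <- simulate_family(600, sample(3:6, 1), runif(1, 0.85, 0.98), seed = i)
    mems <- find_mems(fam$seqs, 12, coverage = 0.6)
    sel <- select_colinear(mems, "global", n_seq = length(fam$seqs$seqs))
    ch <- augment_with_local_matches(sel, fam$seqs)
    plan <- build_segmentation(ch, fam$seqs)
    expect_true(memalign:::plan_tiles_ok(plan, fam$seqs))
  }
})

test_that("colinearity violations are a hard error", {
  ss <- memalign:::new_sequence_set(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"))
  ch <- mk_chain(list(mk_anchor(4, 1:2, c(1, 5)),
                      mk_anchor(4, 1:2, c(5, 1))), 2)
  expect_error(build_segmentation(ch, ss), "colinearity")
})
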