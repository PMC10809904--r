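mk_mem <- function(len, seq, start) {
  occs <- data.frame(seq = seq, start = start, end = start + len)
  list(length = len, occs = occs, k = length(unique(seq)),
       size = len * length(unique(seq)))
}

test_that("colinear anchors are kept and crossing anchors resolved by size", {
  a <- mk_mem(5, c(1, 2), c(1, 1))
  b <- mk_mem(4, c(1, 2), c(11, 9))
  sel <- select_colinear(list(a, b), "global")
  expect_length(sel, 2)
  # crossing pair: keep only the larger in global mode
  a2 <- mk_mem(6, c(1, 2), c(1, 11))   # size 12
  b2 <- mk_mem(4, c(1, 2), c(11, 1))   # size 8
  sel2 <- select_colinear(list(a2, b2), "global")
  expect_length(sel2, 1)
  expect_equal(sel2[[1]]$size, 12)
})

test_that("local mode trims an overlapping anchor to fit", {
  a <- mk_mem(9, c(1, 2), c(1, 1))     # occupies 1..9
  b <- mk_mem(7, c(1, 2), c(7, 7))     # overlaps by 3
  glob <- select_colinear(list(a, b), "global", l_min = 2)
  expect_length(glob, 1)
  loc <- select_colinear(list(a, b), "local", l_min = 2)
  expect_length(loc, 2)
  trimmed <- loc[[2]]
  expect_equal(trimmed$length, 4)           # left edge moved to 10
  expect_true(all(trimmed$occs$start == 10))
  # trimming below l_min drops the anchor instead
  loc2 <- select_colinear(list(a, b), "local", l_min = 5)
  expect_length(loc2, 1)
})

test_that("global selection matches the exhaustive colinear optimum", {
  set.seed(77)
  for (i in 1:40) {
    inst <- rand_mem_instance(max_mems = 9)
    sel <- select_colinear(inst$mems, "global", n_seq = inst$n_seq)
    got <- sum(vapply(sel, function(m) m$size, numeric(1)))
    expect_equal(got, oracle_best_colinear(inst$mems))
    # the returned chain really is pairwise colinear in its order
    if (length(sel) > 1)
      for (x in seq_len(length(sel) - 1))
        expect_true(oracle_before(sel[[x]], sel[[x + 1]]))
    # local mode never has smaller total size
    loc <- select_colinear(inst$mems, "local", n_seq = inst$n_seq)
    expect_gte(sum(vapply(loc, function(m) m$size, numeric(1))), got)
  }
})

test_that("multi-occurrence MEMs are reduced to one occurrence per sequence", {
  m <- mk_mem(4, c(1, 1, 2, 3), c(5, 50, 7, 6))
  red <- memalign:::reduce_multiplicity(m)
  expect_equal(nrow(red$occs), 3)
  # the occurrence nearest the median relative start survives
  expect_equal(red$occs$start[red$occs$seq == 1], 5)
})

test_that("local alignment augments a chain with approximate occurrences", {
  core <- "ACGTACGTACGTACGTACGT"          # 20 bp anchor
  s1 <- paste0("TTTT", core, "GGGG")
  s2 <- paste0("CCCC", core, "AAAA")
  core_mut <- core
  substr(core_mut, 10, 10) <- "A"          # one substitution
  s3 <- paste0("GGGG", core_mut, "TTTT")
  ss <- memalign:::new_sequence_set(c("a", "b", "c"), c(s1, s2, s3))
  mems <- find_mems(ss, 10, coverage = 0.5)
  sel <- select_colinear(mems, "global", n_seq = 3)
  chains <- augment_with_local_matches(sel, ss)
  occ <- do.call(rbind, lapply(chains$anchors, function(a) a$occs))
  expect_true(any(occ$type == "approx" & occ$seq == 3))
  # per sequence at most one occurrence per anchor, exact/approx disjoint
  for (a in chains$anchors)
    expect_false(anyDuplicated(a$occs$seq) > 0)
  # windows too small yield no hit instead of an error
  chains2 <- augment_with_local_matches(sel, ss, gap_frac_max = 0)
  expect_s3_class(chains2, "chain_set")
})

test_that("augmented chains remain pairwise colinear", {
  set.seed(99)
  for (i in 1:5) {
    fam <- simulate_family(800, 5, 0.9, seed = i)
    mems <- find_mems(fam$seqs, 12, coverage = 0.6)
    sel <- select_colinear(mems, "global", n_seq = 5)
    if (length(sel) < 2) next
    chains <- augment_with_local_matches(sel, fam$seqs)
    anchors <- lapply(chains$anchors, function(a)
      list(occs = a$occs[, c("seq", "start", "end")]))
    for (x in seq_len(length(anchors) - 1))
      for (y in (x + 1):length(anchors))
        expect_true(memalign:::occs_before(anchors[[x]]$occs,
                                           anchors[[y]]$occs))
  }
})
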