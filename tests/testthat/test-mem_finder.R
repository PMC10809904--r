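test_that("LCP intervals on banana and a nested run", {
  idx <- build_index(as.integer(factor(strsplit("banana$", "")[[1]],
                                       levels = c("$", "a", "b", "n"))))
  iv <- find_lcp_intervals(idx, 2)
  expect_equal(iv$lo, c(3, 6))
  expect_equal(iv$hi, c(4, 7))
  expect_equal(iv$match_len, c(3, 2))
  # nothing longer than the text
  expect_equal(nrow(find_lcp_intervals(idx, 10)), 0)
  expect_error(find_lcp_intervals(idx, 1), "l_min")
  # a run whose interior exceeds the threshold also yields the nested node
  nodes <- memalign:::lcp_interval_nodes_cpp(c(0L, 1L, 3L, 2L, 0L), 2L)
  expect_equal(nrow(nodes), 2)
  expect_true(any(nodes[, "lo"] == 2 & nodes[, "hi"] == 4 &
                  nodes[, "match_len"] == 2))
  expect_true(any(nodes[, "lo"] == 2 & nodes[, "hi"] == 3 &
                  nodes[, "match_len"] == 3))
})

test_that("MEM extraction finds the shared maximal matches", {
  ss <- memalign:::new_sequence_set(c("s1", "s2"), c("ACGTACGT", "TTACGTAA"))
  mems <- find_mems(ss, 4)
  keys <- mem_keys_pkg(mems)
  # the two pairwise-maximal 5-mers
  expect_true(mem_key(5, c(1, 2), c(1, 3)) %in% keys)
  expect_true(mem_key(5, c(1, 2), c(4, 2)) %in% keys)
  # identical sequences give a single whole-length MEM
  ss2 <- memalign:::new_sequence_set(c("a", "b"), c("ACGTACGT", "ACGTACGT"))
  m2 <- find_mems(ss2, 8)
  expect_length(m2, 1)
  expect_equal(m2[[1]]$length, 8)
  expect_equal(m2[[1]]$k, 2)
})

test_that("MEM list equals the brute-force maximal-match oracle", {
  set.seed(31)
  for (i in 1:15) {
    ss <- rand_seq_set(max_len = 60, dash_prob = if (i %% 3 == 0) 0.1 else 0)
    ct <- concat_sequences(ss)
    idx <- build_index(ct)
    orc_all <- oracle_mems(ss$seqs, 2)
    for (l_min in c(2, 3, 5, 8)) {
      mems <- extend_to_mems(idx, find_lcp_intervals(idx, l_min))
      orc <- orc_all[vapply(orc_all, function(m) m$length >= l_min, logical(1))]
      expect_identical(mem_keys_pkg(mems), mem_keys_oracle(orc))
    }
  }
})

test_that("every reported occurrence spells the same string", {
  set.seed(41)
  ss <- rand_seq_set(n = 4, max_len = 100)
  mems <- find_mems(ss, 3)
  for (m in mems) {
    spelled <- substring(ss$seqs[m$occs$seq], m$occs$start, m$occs$end - 1)
    expect_length(unique(spelled), 1)
    expect_equal(unique(nchar(spelled)), m$length)
    expect_false(grepl("-", spelled[1], fixed = TRUE))
  }
})

test_that("raising l_min never adds a MEM", {
  set.seed(43)
  ss <- rand_seq_set(n = 3, max_len = 120)
  ct <- concat_sequences(ss)
  idx <- build_index(ct)
  prev <- NULL
  for (l_min in c(2, 4, 6, 10)) {
    keys <- mem_keys_pkg(extend_to_mems(idx, find_lcp_intervals(idx, l_min)))
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("coverage filter keeps exactly the MEMs with k > floor(c*n)", {
  fake <- function(k) list(length = 10, k = k, size = 10 * k,
                           occs = data.frame(seq = seq_len(k), start = 1,
                                             end = 11))
  # k = 7 passes at n = 10, c = 0.6; k = 6 does not
  out <- filter_by_coverage(list(fake(7), fake(6)), 0.6, 10)
  expect_equal(vapply(out, function(m) m$k, numeric(1)), 7)
  # c = 0 keeps everything with k >= 1
  expect_length(filter_by_coverage(list(fake(1), fake(2)), 0, 10), 2)
  # n = 4, c = 0.8: floor(3.2) = 3, so full coverage is required
  expect_length(filter_by_coverage(list(fake(3)), 0.8, 4), 0)
  expect_length(filter_by_coverage(list(fake(4)), 0.8, 4), 1)
})
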