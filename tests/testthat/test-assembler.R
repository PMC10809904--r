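test_that("simple concatenation and all-gap column removal", {
  b1 <- memalign:::new_aligned_block("seg0", "segment", 1:2, c("AC", "AC"))
  b2 <- memalign:::new_aligned_block("seg1", "segment", 1:2, c("GT", "GT"))
  out <- concatenate_and_refine(list(b1, b2))
  expect_equal(out$rows, c("ACGT", "ACGT"))
  b3 <- memalign:::new_aligned_block("seg2", "segment", 1:2, c("-T", "-T"))
  out2 <- concatenate_and_refine(list(b1, b3))
  expect_equal(out2$rows, c("ACT", "ACT"))
  expect_equal(out2$width, 3)
})

test_that("junction refinement slides a stranded residue across the gap", {
  b1 <- memalign:::new_aligned_block("seg0", "segment", 1:2, c("A-", "AC"))
  b2 <- memalign:::new_aligned_block("seg1", "segment", 1:2, c("C", "-"))
  out <- concatenate_and_refine(list(b1, b2))
  expect_equal(out$rows, c("AC", "AC"))
  expect_equal(sp_score(out)$sp_total, 0)
})

test_that("refinement never raises SP and is idempotent on random junctions", {
  set.seed(37)
  for (i in 1:30) {
    n <- sample(2:5, 1)
    mat <- do.call(rbind, strsplit(rand_gapped_rows(n, sample(8:30, 1), 0.3),
                                   ""))
    junctions <- sort(sample(seq_len(ncol(mat) - 1), sample(1:3, 1)))
    sp_of <- function(m) sp_score(as_msa(apply(m, 1, paste0, collapse = "")))$sp_total
    before_sp <- sp_of(mat)
    r1 <- memalign:::refine_mat(mat, junctions)
    expect_lte(sp_of(r1$mat), before_sp)
    r2 <- memalign:::refine_mat(r1$mat, r1$junctions)
    expect_identical(r2$mat, r1$mat)
    # rows still degap to the originals
    expect_identical(degap(apply(r1$mat, 1, paste0, collapse = "")),
                     degap(apply(mat, 1, paste0, collapse = "")))
  }
})

test_that("fragments are integrated shortest-sequence-first", {
  # the anchor covers seqs 1-2 only; seqs 3 and 4 are whole-sequence
  # fragments with 10 and 16 pending bases, forcing 2 and 6 new columns
  ss <- memalign:::new_sequence_set(
    c("a", "b", "c", "d"),
    c("CCCCGGGG", "CCCCGGGG", "CCCCGGGGTT", "CCCCGGGGTTTTTTTT"))
  ch <- structure(list(anchors = list(
    list(length = 8, occs = data.frame(seq = 1:2, start = 1, end = 9,
                                       type = "exact", identity = 1))),
    n_seq = 4), class = "chain_set")
  plan <- build_segmentation(ch, ss)
  expect_true(memalign:::plan_tiles_ok(plan, ss))
  expect_equal(sort(plan$fragments$seq), c(3, 4))
  blocks <- memalign:::align_plan_blocks(plan, ss)
  full <- integrate_fragments(plan, blocks, ss)
  ids <- vapply(full, function(b) b$id, character(1))
  # the first insertion event ("ins1") comes from seq 3, the sequence with
  # the smaller pending length, and adds exactly its 2 overhang columns
  ins1_w <- sum(vapply(full[ids == "ins1"], function(b) b$width, numeric(1)))
  expect_equal(ins1_w, 2)
  out <- concatenate_and_refine(full, ids = ss$ids)
  expect_identical(degap(out$rows), ss$seqs)
})

test_that("no fragments leaves block content unchanged", {
  ss <- memalign:::new_sequence_set(c("a", "b"), c("AACCGG", "AACCGG"))
  ch <- structure(list(anchors = list(
    list(length = 2, occs = data.frame(seq = 1:2, start = 3, end = 5,
                                       type = "exact", identity = 1))),
    n_seq = 2), class = "chain_set")
  plan <- build_segmentation(ch, ss)
  blocks <- memalign:::align_plan_blocks(plan, ss)
  full <- integrate_fragments(plan, blocks, ss)
  direct <- concatenate_and_refine(full, ids = ss$ids, refine = FALSE)
  expect_identical(direct$rows, c("AACCGG", "AACCGG"))
})

test_that("whole pipelines degap to their inputs", {
  set.seed(53)
  for (i in 1:5) {
    fam <- simulate_family(700, sample(3:8, 1), runif(1, 0.88, 0.99), seed = i)
    msa <- align_sequences(fam$seqs, run_config(l_min = 15, coverage = 0.6))
    expect_identical(degap(msa$rows), fam$seqs$seqs)
    m <- do.call(rbind, strsplit(msa$rows, ""))
    expect_true(all(colSums(m != "-") > 0))
  }
})
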