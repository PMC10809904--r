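test_that("FASTA reading joins wrapped lines and validates records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "AC", "GT"), f)
  ss <- read_fasta(f)
  expect_identical(ss$ids, c("s1", "s2"))
  expect_identical(ss$seqs, c("ACGT", "ACGT"))

  writeLines(c(">s1", "ACGT", ">s1", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">s1", "ACGT", ">s2"), f)
  expect_error(read_fasta(f), "s2")
})

test_that("preprocessing masks every non-ACGT character and keeps length", {
  expect_identical(preprocess_seqs("acgtN"), "ACGT-")
  expect_identical(preprocess_seqs("ACGT"), "ACGT")
  expect_identical(preprocess_seqs("RYWS"), "----")
  set.seed(1)
  s <- paste(sample(c(LETTERS, "-", "n"), 300, TRUE), collapse = "")
  p <- preprocess_seqs(s)
  expect_equal(nchar(p), nchar(s))
  expect_false(grepl("[^ACGT-]", p))
})

test_that("concatenation records boundaries and a bijective coordinate map", {
  ss <- memalign:::new_sequence_set(c("a", "b"), c("AC", "GT"))
  ct <- concat_sequences(ss)
  expect_equal(ct$N, 6)
  expect_equal(ct$boundaries$start, c(1, 4))
  expect_equal(ct$boundaries$end, c(3, 6))
  # separator position maps to no sequence; others map back exactly
  expect_true(is.na(global_to_local(ct, 3)$seq))
  m <- global_to_local(ct, 5)
  expect_equal(m$seq, 2); expect_equal(m$local, 2)
  # separators occur exactly n times and sort below all sequence symbols
  expect_equal(sum(is.na(ct$seq_of)), 2)
  expect_true(all(ct$codes[is.na(ct$seq_of)] < min(ct$codes[!is.na(ct$seq_of)])))
})

test_that("concatenation is invertible on random sequence sets", {
  set.seed(11)
  for (i in 1:20) {
    ss <- rand_seq_set(max_len = 80, dash_prob = if (i %% 3 == 0) 0.1 else 0)
    ct <- concat_sequences(ss)
    expect_identical(memalign:::extract_sequences(ct), ss$seqs)
    # every masked position has a unique symbol below A and above separators
    dash <- ct$codes[!is.na(ct$seq_of)][
      strsplit(paste(ss$seqs, collapse = ""), "")[[1]] == "-"]
    expect_false(anyDuplicated(dash) > 0)
  }
})

test_that("alignment FASTA writing round-trips and rejects ragged rows", {
  m <- as_msa(c("AC-T", "ACGT"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(m, f)
  back <- read_fasta(f)
  expect_identical(back$seqs, m$rows)
  expect_identical(degap(back$seqs), degap(m$rows))
  expect_error(write_fasta(as_msa(c("AC", "ACG")), f), "ragged")
})
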