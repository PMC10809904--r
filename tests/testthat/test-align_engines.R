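test_that("local alignment scores match hand-checked cases", {
  la <- local_align("ACGT", "ACGT")
  expect_equal(la$score, 8)
  expect_equal(la$gap_fraction, 0)
  expect_equal(la$identity, 1)
  # all-mismatch pair: best hit is a single matching character
  expect_equal(local_align("ACGT", "TTTT")$score, 2)
  # one substitution in eight
  la3 <- local_align("ACGTACGT", "ACGTTCGT")
  expect_equal(la3$score, 2 * 7 - 3)
  expect_equal(la3$gap_fraction, 0)
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("local alignment equals an independent implementation and its score
           re-derives from the op list", {
  skip_if_not_installed("Biostrings")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = TRUE)
  set.seed(19)
  for (i in 1:30) {
    q <- rand_dna(sample(5:50, 1))
    t <- rand_dna(sample(5:80, 1))
    la <- local_align(q, t)
    ref <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 5, gapExtension = 2)
    expect_equal(la$score, Biostrings::score(ref))
    if (!is.na(la$q_start)) expect_equal(rescore_local(la, q, t), la$score)
  }
})

test_that("internal progressive MSA aligns and degaps exactly", {
  rows <- msa_internal(c("ACGT", "ACGT", "ACGT"))
  expect_equal(rows, c("ACGT", "ACGT", "ACGT"))
  seqs <- c("ACGTACGT", "ACGTCGT", "ACGGTACGT")
  rows2 <- msa_internal(seqs)
  expect_identical(degap(rows2), seqs)
  expect_length(unique(nchar(rows2)), 1)
  # empty members become all-gap rows
  rows3 <- msa_internal(c("ACGT", "", "ACGT"))
  expect_identical(degap(rows3), c("ACGT", "", "ACGT"))
})

test_that("segment alignment recurses only below the depth cap", {
  members <- c(strrep("ACGT", 30), strrep("ACGT", 30))
  # oversize at depth 2: aligned directly, still valid
  rows <- align_segment(members, size_cap = 10, depth = 2, l_min = 8)
  expect_identical(degap(rows), members)
  # depth 0 takes the division path and still round-trips
  rows0 <- align_segment(members, size_cap = 10, depth = 0, l_min = 8)
  expect_identical(degap(rows0), members)
  expect_identical(degap(align_segment(c("AC", "AC"))), c("AC", "AC"))
})

test_that("external backend validates output and falls back when broken", {
  expect_warning(
    rows <- memalign:::backend_align(c("ACGTACGT", "ACGTCGT"),
                                     "external:false # {in} {out}"),
    "falling back")
  expect_identical(degap(rows), c("ACGTACGT", "ACGTCGT"))
})

test_that("mafft adapter round-trips a small segment", {
  has_mafft <- nzchar(Sys.which("mafft"))
  seqs <- c("ACGTACGTAAGG", "ACGTCGTAAGG", "ACGTACGTAAGC")
  rows <- if (has_mafft) memalign:::backend_align(seqs, "mafft")
          else suppressWarnings(memalign:::backend_align(seqs, "mafft"))
  expect_identical(degap(rows), seqs)
})

test_that("fragment insertion preserves the profile's internal alignment", {
  prof <- new_profile(c("ACGT-ACGT", "ACGTTACGT"))
  # exact consensus fit adds no columns
  out <- profile_align("ACGTTACGT", prof)
  expect_equal(out$width, 9)
  expect_identical(out$rows[1:2], prof$rows)
  # empty fragment becomes an all-gap row
  out2 <- profile_align("", prof)
  expect_equal(out2$rows[3], strrep("-", 9))
  # inserted columns are all-gap across the old rows (their mutual
  # alignment is unchanged)
  out3 <- profile_align("ACGTTTTACGT", prof)
  old <- do.call(rbind, strsplit(out3$rows[1:2], ""))
  keep <- colSums(old != "-") > 0
  expect_identical(apply(old[, keep], 1, paste0, collapse = ""), prof$rows)
  expect_identical(degap(out3$rows[3]), "ACGTTTTACGT")
})

test_that("saturating band equals the unbanded sequence-profile optimum", {
  set.seed(29)
  for (i in 1:25) {
    w <- sample(5:50, 1)
    prof <- new_profile(rand_gapped_rows(sample(1:4, 1), w))
    frag <- rand_dna(sample(1:50, 1))
    band <- max(nchar(frag), w)
    res <- memalign:::profile_pair_dp_cpp(
      memalign:::profile_freq(frag), prof$freq,
      as.integer(band + 2), 0L, 2, -3, 5, 2)
    expect_equal(res$score,
                 oracle_profile_score(memalign:::profile_freq(frag),
                                      prof$freq),
                 tolerance = 1e-9)
    out <- profile_align(frag, prof, band_k = band)
    expect_identical(degap(out$rows[length(out$rows)]), frag)
  }
})
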