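# Independent brute-force oracles and random-input generators used across
# the suite.  All oracles work by direct definition, never through the
# package's suffix-array / DP code paths.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(len, dash_prob = 0) {
  alph <- if (dash_prob > 0) c(BASES, "-") else BASES
  pr <- if (dash_prob > 0) c(rep((1 - dash_prob) / 4, 4), dash_prob) else NULL
  paste(sample(alph, len, replace = TRUE, prob = pr), collapse = "")
}

rand_seq_set <- function(n = NULL, max_len = 200, dash_prob = 0) {
  if (is.null(n)) n <- sample(2:5, 1)
  seqs <- vapply(seq_len(n), function(i)
    rand_dna(sample(10:max_len, 1), dash_prob), character(1))
  memalign:::new_sequence_set(paste0("s", seq_len(n)), seqs)
}

# ---- suffix array / LCP oracle -------------------------------------------

# lexicographic sort of all suffixes by explicit string comparison
# (codes mapped to unicode points, radix sort = C byte order = code order)
oracle_sa_lcp <- function(codes) {
  n <- length(codes)
  big <- intToUtf8(codes + 256L)
  suf <- substring(big, seq_len(n), n)
  sa <- order(suf, method = "radix")
  lcp <- integer(n)
  cpl <- function(a, b) {
    va <- utf8ToInt(a); vb <- utf8ToInt(b)
    k <- min(length(va), length(vb))
    if (k == 0) return(0L)
    neq <- which(va[seq_len(k)] != vb[seq_len(k)])
    if (length(neq) == 0) k else neq[1] - 1L
  }
  for (i in seq_len(n)[-1]) lcp[i] <- cpl(suf[sa[i - 1]], suf[sa[i]])
  list(sa = sa, lcp = lcp)
}

# ---- MEM oracle -----------------------------------------------------------

# all maximal exact matches of length >= l_min by direct substring
# grouping: a substring's occurrence group (all positions, across and within
# sequences) is a MEM iff the characters right of all occurrences are not
# all equal and likewise on the left, where a sequence boundary or a masked
# base counts as matching nothing
oracle_mems <- function(seqs, l_min) {
  n <- length(seqs)
  lens <- nchar(seqs)
  out <- list()
  for (l in l_min:max(lens)) {
    pos_seq <- integer(0); pos_start <- integer(0); subs <- character(0)
    for (i in seq_len(n)) {
      if (lens[i] < l) next
      st <- 1:(lens[i] - l + 1)
      pos_seq <- c(pos_seq, rep(i, length(st)))
      pos_start <- c(pos_start, st)
      subs <- c(subs, substring(seqs[i], st, st + l - 1))
    }
    ok <- !grepl("-", subs, fixed = TRUE)
    grp <- split(which(ok), subs[ok])
    for (g in grp) {
      if (length(g) < 2) next
      sq <- pos_seq[g]; st <- pos_start[g]
      lc <- ifelse(st == 1, NA, substring(seqs[sq], st - 1, st - 1))
      lc[lc == "-"] <- NA
      rc <- ifelse(st + l > lens[sq], NA, substring(seqs[sq], st + l, st + l))
      rc[rc == "-"] <- NA
      left_max <- anyNA(lc) || length(unique(lc)) > 1
      right_max <- anyNA(rc) || length(unique(rc)) > 1
      if (left_max && right_max) {
        o <- order(sq, st)
        out[[length(out) + 1]] <- list(length = l, seq = sq[o], start = st[o])
      }
    }
  }
  out
}

mem_key <- function(len, seq, start)
  paste(len, paste(seq, start, sep = ":", collapse = ","))

mem_keys_pkg <- function(mems)
  sort(vapply(mems, function(m)
    mem_key(m$length, m$occs$seq, m$occs$start), character(1)))

mem_keys_oracle <- function(mems)
  sort(vapply(mems, function(m)
    mem_key(m$length, m$seq, m$start), character(1)))

# ---- colinear selection oracle -------------------------------------------

# random MEM instance: occurrence tables over a few sequences
rand_mem_instance <- function(max_mems = 12, n_seq = NULL) {
  if (is.null(n_seq)) n_seq <- sample(2:5, 1)
  m <- sample(1:max_mems, 1)
  mems <- lapply(seq_len(m), function(i) {
    k <- sample(2:n_seq, 1)
    sq <- sort(sample(n_seq, k))
    len <- sample(2:10, 1)
    st <- sample(1:80, k, replace = TRUE)
    occs <- data.frame(seq = sq, start = st, end = st + len)
    list(length = len, occs = occs, k = k, size = len * k)
  })
  list(mems = mems, n_seq = n_seq)
}

oracle_before <- function(a, b) {
  sh <- intersect(a$occs$seq, b$occs$seq)
  all(a$occs$end[match(sh, a$occs$seq)] <= b$occs$start[match(sh, b$occs$seq)])
}

# can the set be totally ordered with every earlier mem before every later
# one?  greedy head-selection over the precomputed before-matrix is exact
# for this relation (any all-before element can be placed first)
oracle_orderable_mat <- function(B, idx) {
  remaining <- idx
  while (length(remaining) > 1) {
    head_ok <- FALSE
    for (x in remaining) {
      rest <- remaining[remaining != x]
      if (all(B[x, rest])) { remaining <- rest; head_ok <- TRUE; break }
    }
    if (!head_ok) return(FALSE)
  }
  TRUE
}

# maximum total size over all pairwise-colinear subsets, by exhaustive search
oracle_best_colinear <- function(mems) {
  m <- length(mems)
  sizes <- vapply(mems, function(x) x$size, numeric(1))
  B <- matrix(TRUE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) B[i, j] <- oracle_before(mems[[i]], mems[[j]])
  best <- 0
  bits <- 2^(seq_len(m) - 1)
  for (mask in seq_len(2^m - 1)) {
    idx <- which(bitwAnd(mask, bits) > 0)
    w <- sum(sizes[idx])
    if (w <= best) next
    if (length(idx) == 1 || oracle_orderable_mat(B, idx)) best <- w
  }
  best
}

# ---- sequence-profile DP oracle ------------------------------------------

# unbanded affine global DP between two profiles under the package scheme
oracle_profile_score <- function(f1, f2, sc = memalign:::ma_scoring()) {
  W1 <- ncol(f1); W2 <- ncol(f2); NEG <- -1e30
  nz1 <- colSums(f1[1:4, , drop = FALSE])
  nz2 <- colSums(f2[1:4, , drop = FALSE])
  H <- matrix(NEG, W1 + 1, W2 + 1)
  E <- matrix(NEG, W1 + 1, W2 + 1)
  FF <- matrix(NEG, W1 + 1, W2 + 1)
  H[1, 1] <- 0
  for (j in seq_len(W2)) {
    E[1, j + 1] <- max(E[1, j] - sc$gap_ext * nz2[j],
                       H[1, j] - (sc$gap_open + sc$gap_ext) * nz2[j])
    H[1, j + 1] <- E[1, j + 1]
  }
  for (i in seq_len(W1)) {
    FF[i + 1, 1] <- max(FF[i, 1] - sc$gap_ext * nz1[i],
                        H[i, 1] - (sc$gap_open + sc$gap_ext) * nz1[i])
    H[i + 1, 1] <- FF[i + 1, 1]
    for (j in seq_len(W2)) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - sc$gap_ext * nz2[j],
                             H[i + 1, j] - (sc$gap_open + sc$gap_ext) * nz2[j])
      FF[i + 1, j + 1] <- max(FF[i, j + 1] - sc$gap_ext * nz1[i],
                              H[i, j + 1] - (sc$gap_open + sc$gap_ext) * nz1[i])
      dot <- sum(f1[1:4, i] * f2[1:4, j])
      sub <- sc$match * dot + sc$mismatch * (nz1[i] * nz2[j] - dot)
      H[i + 1, j + 1] <- max(H[i, j] + sub, E[i + 1, j + 1], FF[i + 1, j + 1])
    }
  }
  H[W1 + 1, W2 + 1]
}

rand_gapped_rows <- function(nr, w, gap_prob = 0.15) {
  vapply(seq_len(nr), function(i)
    paste(sample(c(BASES, "-"), w, TRUE,
                 prob = c(rep((1 - gap_prob) / 4, 4), gap_prob)),
          collapse = ""), character(1))
}

as_msa <- function(rows, ids = paste0("s", seq_along(rows)))
  structure(list(ids = ids, rows = rows, width = nchar(rows[1])),
            class = "msa")

# re-score a local alignment op list by definition
rescore_local <- function(la, q, t, sc = memalign:::ma_scoring()) {
  qi <- la$q_start; ti <- la$t_start
  sc_total <- 0; gap_open_pending <- list(q = TRUE, t = TRUE)
  prev <- 0
  for (op in la$ops) {
    if (op == 1) {
      a <- substr(q, qi, qi); b <- substr(t, ti, ti)
      sc_total <- sc_total + if (a == b && a %in% BASES) sc$match else sc$mismatch
      qi <- qi + 1; ti <- ti + 1
    } else if (op == 2) {  # gap in query, consumes target
      sc_total <- sc_total - sc$gap_ext - if (prev == 2) 0 else sc$gap_open
      ti <- ti + 1
    } else {               # gap in target, consumes query
      sc_total <- sc_total - sc$gap_ext - if (prev == 3) 0 else sc$gap_open
      qi <- qi + 1
    }
    prev <- op
  }
  sc_total
}
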