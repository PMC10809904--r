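# Alignment kernels: exact local alignment, internal progressive MSA,
# external-aligner adapter, and banded sequence-profile alignment.

# default nucleotide scheme (match, mismatch as scores; gaps as positive
# costs, a gap of length g costing open + g * ext)
ma_scoring <- function() list(match = 2, mismatch = -3, gap_open = 5, gap_ext = 2)

encode_dna <- function(s) {
  v <- utf8ToInt(s)
  out <- integer(length(v))
  out[v == 65L] <- 1L  # A
  out[v == 67L] <- 2L  # C
  out[v == 71L] <- 3L  # G
  out[v == 84L] <- 4L  # T
  out  # anything else (masked '-') stays 0 and mismatches everything
}

#' Optimal local alignment of two sequences (Smith-Waterman contract)
#'
#' Affine-gap Smith-Waterman over `{A,C,G,T}`; masked positions (`-`) score
#' as mismatches.  Deterministic tie-break: among optimal cells, smallest
#' target end, then smallest query end.
#'
#' @param query,target non-empty nucleotide strings.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_ext`
#'   (default 2 / -3 / 5 / 2).
#' @return list with `score`, 1-based inclusive spans `q_start`,`q_end`,
#'   `t_start`,`t_end`, `ops` (1 = aligned pair, 2 = gap in query,
#'   3 = gap in target), `gap_fraction` (gap columns / alignment columns)
#'   and `identity` (matches / alignment columns).  Spans are `NA` when the
#'   best score is 0.
#' @export
local_align <- function(query, target, scoring = ma_scoring()) {
  if (nchar(query) == 0 || nchar(target) == 0) stop("empty input")
  r <- sw_align_cpp(encode_dna(query), encode_dna(target),
                    scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_ext)
  r$gap_fraction <- if (r$n_cols > 0) r$n_gap_cols / r$n_cols else 0
  r$identity <- if (r$n_cols > 0) r$n_match / r$n_cols else 0
  r
}

# ---- profiles -------------------------------------------------------------

profile_freq <- function(rows) {
  if (length(rows) == 0 || nchar(rows[1]) == 0)
    return(matrix(numeric(0), nrow = 5, ncol = 0,
                  dimnames = list(c("A", "C", "G", "T", "-"), NULL)))
  cm <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  f <- rbind(colMeans(cm == "A"), colMeans(cm == "C"),
             colMeans(cm == "G"), colMeans(cm == "T"),
             colMeans(cm == "-"))
  rownames(f) <- c("A", "C", "G", "T", "-")
  f
}

#' Construct an alignment profile from gapped rows
#' @param rows character vector of equal-width gapped rows.
#' @return a `profile`: list with `rows`, per-column `freq` (5 x width,
#'   rows A,C,G,T,-) and `width`.
#' @export
new_profile <- function(rows) {
  w <- unique(nchar(rows))
  if (length(w) > 1) stop("profile rows must have equal width")
  structure(list(rows = rows, freq = profile_freq(rows),
                 width = if (length(rows)) w else 0L),
            class = "profile")
}

# FFT cross-correlation of residue indicator/frequency channels; returns the
# diagonal offset d maximizing sum_a sum_i f1[a,i] * f2[a,i+d]
fft_offset <- function(f1, f2) {
  W1 <- ncol(f1); W2 <- ncol(f2)
  P <- 2^ceiling(log2(W1 + W2))
  acc <- numeric(P)
  for (a in 1:4) {
    x <- c(f1[a, ], numeric(P - W1))
    y <- c(f2[a, ], numeric(P - W2))
    acc <- acc + Re(fft(Conj(fft(x)) * fft(y), inverse = TRUE)) / P
  }
  # index p corresponds to offset d = p-1 (wrapping negatives to P+d+1)
  d <- seq_len(P) - 1L
  d[d > P / 2] <- d[d > P / 2] - P
  valid <- d > -W1 & d < W2
  d[valid][which.max(acc[valid])]
}

# Banded global alignment of two profiles with a doubling band schedule:
# start at band_k, double while the optimal path touches the band edge.
# FFT anchoring proposes the band's diagonal offset for wide profiles.
# With band_k >= max(width1, width2) the result is the unbanded optimum.
profile_pair_ops <- function(f1, f2, band_k = 16, scoring = ma_scoring(),
                             fft_anchor = TRUE) {
  W1 <- ncol(f1); W2 <- ncol(f2)
  if (W1 == 0) return(rep(3L, W2))
  if (W2 == 0) return(rep(2L, W1))
  off <- 0L
  if (fft_anchor && max(W1, W2) > 1000) off <- fft_offset(f1, f2)
  kmax <- max(W1, W2)
  k <- max(1, band_k)
  repeat {
    keff <- max(k, abs(off), abs(W2 - W1 - off)) + 1
    res <- profile_pair_dp_cpp(f1, f2, as.integer(keff), as.integer(off),
                               scoring$match, scoring$mismatch,
                               scoring$gap_open, scoring$gap_ext)
    if (!res$edge_hit || keff >= kmax) break
    k <- k * 2
  }
  res$ops
}

# insert gap columns into rows according to a consumption mask
expand_rows <- function(rows, consume) {
  if (length(rows) == 0) return(rows)
  W <- sum(consume)
  out <- matrix("-", length(rows), length(consume))
  if (W > 0) {
    cm <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out[, consume] <- cm
  }
  apply(out, 1, paste0, collapse = "")
}

#' Align a fragment into an existing profile
#'
#' Inserts a single sequence into an alignment profile by banded global
#' sequence-profile alignment (the sequence is a 1-row profile).  Existing
#' rows only gain shared gap columns, so their mutual alignment is
#' unchanged.  For profiles wider than 1 kb, FFT cross-correlation of
#' residue indicator channels proposes the band diagonal; the band then
#' doubles from `band_k` while the optimum touches the band edge.  An empty
#' fragment is appended as an all-gap row.
#'
#' @param fragment nucleotide string (possibly empty).
#' @param profile a `profile` (non-empty).
#' @param band_k initial band half-width; pass at least
#'   `max(nchar(fragment), profile$width)` for the exact unbanded optimum.
#' @param scoring scoring scheme, see [local_align()].
#' @return a `profile` whose last row is the aligned fragment.
#' @export
profile_align <- function(fragment, profile, band_k = 16,
                          scoring = ma_scoring()) {
  stopifnot(inherits(profile, "profile"))
  if (length(profile$rows) == 0) stop("profile must be non-empty")
  if (nchar(fragment) == 0)
    return(new_profile(c(profile$rows, strrep("-", profile$width))))
  if (profile$width == 0)
    return(new_profile(c(strrep("-", nchar(fragment))[rep(1, length(profile$rows))],
                         fragment)))
  f1 <- profile_freq(fragment)
  ops <- profile_pair_ops(f1, profile$freq, band_k, scoring)
  newrow <- expand_rows(fragment, ops != 3L)
  oldrows <- expand_rows(profile$rows, ops != 2L)
  new_profile(c(oldrows, newrow))
}

#' @export
print.profile <- function(x, ...) {
  cat("profile:", length(x$rows), "rows x", x$width, "columns\n")
  invisible(x)
}

# ---- internal progressive MSA --------------------------------------------

# shared k-mer distance between sequences (1 - |shared|/min count)
kmer_dist <- function(seqs, k = 8) {
  k <- max(1, min(k, min(nchar(seqs))))
  sets <- lapply(seqs, function(s) {
    L <- nchar(s)
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  m <- length(seqs)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / min(length(sets[[i]]), length(sets[[j]]))
  }
  d
}

#' Progressive multiple alignment (internal backend)
#'
#' Pairwise shared k-mer distances, a UPGMA guide tree, and banded
#' profile-profile merges with affine gaps.  Deterministic; exists so the
#' pipeline runs with no external binaries.
#'
#' @param seqs character vector of 2 or more sequences (empty strings
#'   become all-gap rows).
#' @param band_k initial band half-width for the profile merges.
#' @param scoring scoring scheme, see [local_align()].
#' @return character vector of gapped rows, same order as the input.
#' @export
msa_internal <- function(seqs, band_k = 16, scoring = ma_scoring()) {
  m <- length(seqs)
  if (m == 0) return(character(0))
  nonempty <- which(nchar(seqs) > 0)
  if (length(nonempty) <= 1) {
    w <- if (length(nonempty)) nchar(seqs[nonempty]) else 0L
    rows <- rep(strrep("-", w), m)
    if (length(nonempty)) rows[nonempty] <- seqs[nonempty]
    return(rows)
  }
  if (length(unique(seqs[nonempty])) == 1 &&
      length(nonempty) == m) return(seqs)
  act <- seqs[nonempty]
  if (length(act) == 2) {
    ops <- profile_pair_ops(profile_freq(act[1]), profile_freq(act[2]),
                            band_k, scoring)
    rows <- c(expand_rows(act[1], ops != 3L), expand_rows(act[2], ops != 2L))
    cl <- list(rows = rows, idx = nonempty)
  } else {
    d <- kmer_dist(act)
    hc <- hclust(as.dist(d), method = "average")
    nodes <- vector("list", nrow(hc$merge))
    getcl <- function(v) {
      if (v < 0) list(rows = act[-v], idx = nonempty[-v]) else nodes[[v]]
    }
    for (r in seq_len(nrow(hc$merge))) {
      A <- getcl(hc$merge[r, 1]); B <- getcl(hc$merge[r, 2])
      ops <- profile_pair_ops(profile_freq(A$rows), profile_freq(B$rows),
                              band_k, scoring)
      nodes[[r]] <- list(rows = c(expand_rows(A$rows, ops != 3L),
                                  expand_rows(B$rows, ops != 2L)),
                         idx = c(A$idx, B$idx))
    }
    cl <- nodes[[nrow(hc$merge)]]
  }
  width <- nchar(cl$rows[1])
  out <- rep(strrep("-", width), m)
  out[cl$idx] <- cl$rows
  out
}

# ---- external aligner adapter --------------------------------------------

run_external_aligner <- function(seqs, template) {
  dir <- tempfile("memalign_ext_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fin <- file.path(dir, "in.fasta")
  fout <- file.path(dir, "out.fasta")
  ids <- sprintf("s%06d", seq_along(seqs))
  write_fasta(new_sequence_set(ids, seqs), fin)
  cmd <- gsub("{out}", fout, gsub("{in}", fin, template, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd, ignore.stdout = FALSE, ignore.stderr = TRUE)
  if (status != 0 || !file.exists(fout)) stop("external aligner failed: ", cmd)
  res <- read_fasta(fout)
  rows <- toupper(res$seqs)[match(ids, res$ids)]
  if (anyNA(rows)) stop("external aligner dropped records")
  rows
}

backend_align <- function(seqs, backend = "internal", band_k = 16,
                          scoring = ma_scoring()) {
  if (backend == "internal")
    return(msa_internal(seqs, band_k, scoring))
  template <- if (backend == "mafft") {
    "mafft --quiet --auto {in} > {out}"
  } else if (startsWith(backend, "external:")) {
    sub("^external:", "", backend)
  } else stop("unknown backend: ", backend)
  rows <- tryCatch(run_external_aligner(seqs, template), error = function(e) e)
  if (inherits(rows, "error") || !identical(degap(rows), degap(seqs))) {
    warning("backend '", backend,
            "' failed validation; falling back to internal aligner")
    return(msa_internal(seqs, band_k, scoring))
  }
  rows
}

#' Align one segment block
#'
#' Aligns the member strings of a segment with the chosen backend.  If the
#' members' mean length exceeds `size_cap` and the recursion depth allows,
#' the segment is re-divided by the anchor pipeline with a halved minimum
#' MEM length (`max(ceil(l_min/2), 4)`); recursion is limited to two
#' iterations, after which the backend is called directly.
#'
#' @param members character vector of member strings (empty allowed).
#' @param backend `"internal"`, `"mafft"`, or `"external:<template>"` where
#'   the template contains `{in}` and `{out}` placeholders.
#' @param depth current recursion depth (0, 1 or 2).
#' @param l_min current minimum MEM length.
#' @param size_cap mean member length above which the segment is re-divided.
#' @param band_k band half-width for internal profile merges.
#' @return character vector of gapped rows, same order as `members`.
#' @export
align_segment <- function(members, backend = "internal", depth = 0,
                          l_min = 30, size_cap = 5e4, band_k = 16) {
  stopifnot(depth %in% 0:2)
  nonempty <- which(nchar(members) > 0)
  if (length(nonempty) >= 2 && depth < 2 &&
      mean(nchar(members[nonempty])) > size_cap) {
    sub_l <- max(ceiling(l_min / 2), 4)
    sub <- vertical_align(members, l_min = sub_l, backend = backend,
                          depth = depth + 1, size_cap = size_cap,
                          band_k = band_k)
    return(sub$rows)
  }
  backend_align(members, backend, band_k)
}
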