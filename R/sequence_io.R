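# FASTA I/O, preprocessing, and concatenation into a single indexed text.

new_sequence_set <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  structure(list(ids = as.character(ids), seqs = as.character(seqs)),
            class = "sequence_set")
}

#' Read a multi-FASTA file of nucleotide sequences
#'
#' Headers start with `>`; wrapped sequence lines are joined and whitespace
#' stripped.  Case and characters are preserved as read; call
#' [preprocess_seqs()] to normalize to the `{A,C,G,T,-}` alphabet.
#'
#' @param path path to a FASTA file.
#' @return a `sequence_set`: list with `ids` and `seqs` character vectors,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # validate record structure up front (headers with no sequence content
  # are silently mangled by lenient parsers)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("empty FASTA file: ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  for (h in seq_along(hdr)) {
    body <- if (ends[h] > hdr[h]) lines[(hdr[h] + 1L):ends[h]] else character(0)
    if (sum(nchar(gsub("[[:space:]]", "", body))) == 0)
      stop("record with empty sequence: ",
           sub("^>\\s*(\\S+).*", "\\1", lines[hdr[h]]))
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- vapply(recs, function(r) gsub("[[:space:]]", "", as.character(r)[1]),
                 character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  empty <- ids[nchar(seqs) == 0]
  if (length(empty) > 0)
    stop("record with empty sequence: ", paste(empty, collapse = ", "))
  new_sequence_set(ids, seqs)
}

#' Normalize sequences to the {A,C,G,T,-} alphabet
#'
#' Uppercases and replaces every character outside `{A,C,G,T}` (ambiguity
#' codes, `N`, anything else) with the gap character `-`.  Lengths are
#' unchanged.
#'
#' @param x a `sequence_set` (or plain character vector).
#' @return object of the same shape with normalized sequences.
#' @export
preprocess_seqs <- function(x) {
  norm <- function(s) gsub("[^ACGT]", "-", toupper(s))
  if (inherits(x, "sequence_set")) {
    x$seqs <- norm(x$seqs)
    x
  } else {
    norm(x)
  }
}

#' Concatenate preprocessed sequences into a single indexed text
#'
#' Builds the integer text `s1 sep1 s2 sep2 ... sn sepn` used for suffix-array
#' indexing.  Each separator is a distinct symbol smaller than every sequence
#' symbol, so no suffix comparison crosses a sequence boundary.  Each masked
#' position (`-`) also receives its own distinct symbol, ranked between the
#' separators and `A`; exact matches therefore never contain or extend across
#' a masked position.
#'
#' @param seqs a preprocessed `sequence_set` with `n >= 2` sequences.
#' @return a `concat_text`: list with `codes` (integer vector of length `N`),
#'   `N`, `n`, `seq_lens`, `starts` (1-based global start of each sequence),
#'   `boundaries` (data.frame seq/start/end, half-open global intervals),
#'   `seq_of` (sequence index per global position, `NA` at separators) and
#'   `decode` (character per code, `NA` for separators).
#' @export
concat_sequences <- function(seqs) {
  stopifnot(inherits(seqs, "sequence_set"))
  n <- length(seqs$seqs)
  if (n < 2) stop("need >= 2 sequences")
  if (any(grepl("[^ACGT-]", seqs$seqs)))
    stop("sequences must be preprocessed to the {A,C,G,T,-} alphabet")
  lens <- nchar(seqs$seqs)
  N <- sum(lens) + n
  starts <- cumsum(c(1, lens[-n] + 1L))
  chars <- unlist(strsplit(seqs$seqs, "", fixed = TRUE), use.names = FALSE)
  is_dash_all <- chars == "-"
  n_dash <- sum(is_dash_all)
  base <- n + n_dash
  code_of <- c(A = base + 1L, C = base + 2L, G = base + 3L, T = base + 4L)

  codes <- integer(N)
  seq_of <- rep(NA_integer_, N)
  pos <- 1L
  dash_next <- n + 1L
  for (i in seq_len(n)) {
    li <- lens[i]
    if (li > 0) {
      ci <- chars[(sum(lens[seq_len(i - 1)]) + 1L):(sum(lens[seq_len(i)]))]
      v <- unname(code_of[ci])
      dash_here <- which(ci == "-")
      if (length(dash_here) > 0) {
        v[dash_here] <- seq.int(dash_next, length.out = length(dash_here))
        dash_next <- dash_next + length(dash_here)
      }
      codes[pos:(pos + li - 1L)] <- v
      seq_of[pos:(pos + li - 1L)] <- i
    }
    codes[pos + li] <- i  # separator
    pos <- pos + li + 1L
  }
  decode <- rep(NA_character_, base + 4L)
  if (n_dash > 0) decode[(n + 1L):(n + n_dash)] <- "-"
  decode[base + 1:4] <- c("A", "C", "G", "T")
  structure(list(codes = codes, N = N, n = n, seq_lens = lens,
                 starts = starts,
                 boundaries = data.frame(seq = seq_len(n), start = starts,
                                         end = starts + lens),
                 seq_of = seq_of, decode = decode),
            class = "concat_text")
}

#' Map a global text position to (sequence, local) coordinates
#'
#' @param ct a `concat_text`.
#' @param pos 1-based global position(s).
#' @return data.frame with `seq` (NA at separators) and `local`
#'   (1-based position within the sequence).
#' @export
global_to_local <- function(ct, pos) {
  stopifnot(all(pos >= 1 & pos <= ct$N))
  s <- ct$seq_of[pos]
  data.frame(seq = s,
             local = ifelse(is.na(s), NA_integer_, pos - ct$starts[s] + 1L))
}

# Recover the input sequences from the coded text (used by invariants/tests).
extract_sequences <- function(ct) {
  vapply(seq_len(ct$n), function(i) {
    b <- ct$boundaries[i, ]
    if (b$end == b$start) return("")
    paste0(ct$decode[ct$codes[b$start:(b$end - 1L)]], collapse = "")
  }, character(1))
}

#' Write an alignment (or sequence set) to FASTA
#'
#' @param msa an `msa` object (see [concatenate_and_refine()]) or a
#'   `sequence_set`.
#' @param path output path.
#' @param width line-wrap width (default 80).
#' @export
write_fasta <- function(msa, path, width = 80) {
  if (inherits(msa, "msa")) {
    ids <- msa$ids; rows <- msa$rows
    if (length(unique(nchar(rows))) > 1) stop("ragged alignment rows")
  } else if (inherits(msa, "sequence_set")) {
    ids <- msa$ids; rows <- msa$seqs
  } else stop("expected an msa or sequence_set")
  seqinr::write.fasta(as.list(rows), names = ids, file.out = path,
                      nbchar = width)
  invisible(NULL)
}

#' Remove gap characters from sequences
#'
#' @param x character vector of (gapped) sequences.
#' @return character vector with all `-` removed.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set:", length(x$seqs), "sequences, lengths",
      paste(range(nchar(x$seqs)), collapse = "-"), "\n")
  invisible(x)
}
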