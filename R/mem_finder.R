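# MEM enumeration: LCP-interval detection, left extension, coverage filter.
#
# A MEM is a substring shared by at least two suffix positions (possibly in
# the same sequence) that cannot be extended left or right without a
# mismatch, a sequence boundary, or a masked base.  Its occurrence set is
# the set of *all* positions spelling it.

#' Find LCP intervals at or above a minimum match length
#'
#' Enumerates every node of the LCP-interval tree with lcp value at least
#' `l_min` by a stack traversal of the LCP array.  Each node is a maximal
#' rank range `[lo..hi]` whose suffixes share a prefix of exactly
#' `match_len` characters as a group; nested nodes (longer matches shared by
#' fewer suffixes) are reported as well so that all maximal exact matches of
#' length `>= l_min` are recovered, not only those at the threshold.
#'
#' @param index a `suffix_index`.
#' @param l_min minimum match length in bp (`>= 2`).
#' @return data.frame with columns `lo`, `hi` (1-based inclusive ranks in the
#'   suffix array) and `match_len`, sorted by `lo` then decreasing
#'   `match_len`.
#' @export
find_lcp_intervals <- function(index, l_min) {
  stopifnot(inherits(index, "suffix_index"))
  if (!is.numeric(l_min) || l_min < 2) stop("l_min must be >= 2")
  m <- lcp_interval_nodes_cpp(index$lcp, as.integer(l_min))
  df <- as.data.frame(m)
  df[order(df$lo, -df$match_len), , drop = FALSE]
}

#' Extend LCP intervals leftwards into MEMs
#'
#' The occurrence group of an interval is extended to the left as a whole:
#' extension proceeds while the characters immediately left of all
#' occurrences agree, and stops at a mismatch, a sequence start, or a masked
#' base (separator and masked symbols are pairwise distinct, so they can
#' never agree).  Because the left extension of a group is always itself an
#' LCP-interval tree node (the extended match is still right-maximal and has
#' the same occurrence set), the extension is realized by keeping exactly the
#' left-maximal nodes and discarding the rest as duplicates-in-waiting; the
#' result is identical to literal character-by-character extension followed
#' by deduplication, without the quadratic cost on near-identical inputs.
#'
#' @param index a `suffix_index` built on a `concat_text`.
#' @param intervals data.frame from [find_lcp_intervals()].
#' @return list of MEMs; each is a list with `length`, `occs` (data.frame
#'   `seq`, `start`, `end`; 1-based half-open local coordinates), `k` (number
#'   of distinct sequences covered) and `size` (`length * k`).
#' @export
extend_to_mems <- function(index, intervals) {
  stopifnot(inherits(index, "suffix_index"))
  ct <- index$concat
  if (is.null(ct)) stop("index must carry a concat_text for coordinate mapping")
  codes <- index$codes
  mems <- vector("list", nrow(intervals))
  keys <- character(nrow(intervals))
  kept <- logical(nrow(intervals))
  for (r in seq_len(nrow(intervals))) {
    lo <- intervals$lo[r]; hi <- intervals$hi[r]
    len <- intervals$match_len[r]
    pos <- sort(index$sa[lo:hi])  # global start positions
    # left-maximal iff some occurrence abuts the text start or the left
    # characters are not all equal
    if (all(pos > 1L)) {
      left <- codes[pos - 1L]
      if (all(left == left[1L])) next  # extensible: its extension is another node
    }
    s <- ct$seq_of[pos]
    local <- pos - ct$starts[s] + 1L
    occs <- data.frame(seq = s, start = local, end = local + len)
    occs <- occs[order(occs$seq, occs$start), , drop = FALSE]
    rownames(occs) <- NULL
    keys[r] <- paste(len, paste(occs$seq, occs$start, sep = ":", collapse = ","))
    mems[[r]] <- list(length = len, occs = occs,
                      k = length(unique(occs$seq)),
                      size = len * length(unique(occs$seq)))
    kept[r] <- TRUE
  }
  mems <- mems[kept]
  mems[!duplicated(keys[kept])]
}

#' Filter MEMs by sequence coverage
#'
#' Keeps a MEM iff the number of distinct sequences it covers exceeds
#' `floor(c * n)`.  Output is sorted by `size` (length x coverage)
#' descending, ties broken by length descending then leftmost occurrence.
#'
#' @param mems list of MEMs from [extend_to_mems()].
#' @param c coverage threshold in `[0, 1]`.
#' @param n total number of sequences.
#' @return filtered, sorted list of MEMs.
#' @export
filter_by_coverage <- function(mems, c, n) {
  if (c < 0 || c > 1) stop("coverage threshold must be in [0, 1]")
  thr <- floor(c * n)
  keep <- vapply(mems, function(m) m$k > thr, logical(1))
  mems <- mems[keep]
  if (length(mems) == 0) return(mems)
  size <- vapply(mems, function(m) m$size, numeric(1))
  len <- vapply(mems, function(m) m$length, numeric(1))
  fs <- vapply(mems, function(m) m$occs$seq[1], numeric(1))
  fp <- vapply(mems, function(m) m$occs$start[1], numeric(1))
  mems[order(-size, -len, fs, fp)]
}

#' Enumerate coverage-filtered MEMs of a sequence set
#'
#' Convenience wrapper: concatenate, index, find LCP intervals, extend, and
#' coverage-filter in one call.
#'
#' @param seqs a preprocessed `sequence_set`.
#' @param l_min minimum MEM length in bp.
#' @param coverage coverage threshold `c`; a MEM must cover more than
#'   `floor(c * n)` sequences.
#' @return sorted list of MEMs (see [extend_to_mems()]).
#' @export
find_mems <- function(seqs, l_min, coverage = 0) {
  ct <- concat_sequences(seqs)
  idx <- build_index(ct)
  iv <- find_lcp_intervals(idx, l_min)
  mems <- extend_to_mems(idx, iv)
  filter_by_coverage(mems, coverage, length(seqs$seqs))
}

# TSV report: length, k, size, then seq:start pairs.
mem_report <- function(mems, ids = NULL, path = NULL) {
  rows <- vapply(mems, function(m) {
    occ <- paste(if (is.null(ids)) m$occs$seq else ids[m$occs$seq],
                 m$occs$start, sep = ":", collapse = "\t")
    paste(m$length, m$k, m$size, occ, sep = "\t")
  }, character(1))
  if (!is.null(path)) writeLines(c("length\tk\tsize\toccurrences", rows), path)
  rows
}
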