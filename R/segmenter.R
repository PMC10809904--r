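# Cut every sequence at the partial-chain boundaries into anchor and
# inter-anchor pieces; classify multi-sequence pieces as segments and
# leftover single-sequence pieces as fragments.

#' Build the segmentation plan from a partial chain
#'
#' Every sequence is tiled, without gaps or overlaps, into: its anchor
#' occurrences (exact or approximate), inter-anchor pieces belonging to
#' segment blocks (pieces between two *consecutive* chain anchors that both
#' cover the sequence; the head/tail pieces of sequences covered by the
#' first/last anchor), and fragments (everything else: pieces spanning
#' anchors that skip the sequence, head/tail pieces of late-covered
#' sequences, and whole uncovered sequences).  A segment block needs at
#' least two member sequences; single-member pieces are reclassified as
#' fragments.  Zero-length members (abutting anchors) are preserved for the
#' tiling arithmetic.
#'
#' @param chains a `chain_set` from [augment_with_local_matches()].
#' @param seqs the preprocessed `sequence_set`.
#' @return a `segment_plan`: list with `columns` (ordered blocks, each
#'   `kind` = anchor/segment, `id`, `members` data.frame `seq`,`start`,`end`)
#'   and `fragments` (data.frame `seq`,`start`,`end`,`left_anchor`,
#'   `right_anchor`, NA at the open ends).
#' @export
build_segmentation <- function(chains, seqs) {
  stopifnot(inherits(chains, "chain_set"), inherits(seqs, "sequence_set"))
  n <- length(seqs$seqs)
  lens <- nchar(seqs$seqs)
  m <- length(chains$anchors)

  # per-sequence covered anchors, verified increasing and disjoint
  cov <- vector("list", n)
  for (s in seq_len(n)) {
    hit <- which(vapply(chains$anchors,
                        function(a) s %in% a$occs$seq, logical(1)))
    if (length(hit) > 1) {
      st <- vapply(hit, function(a) {
        o <- chains$anchors[[a]]$occs; o$start[match(s, o$seq)]
      }, numeric(1))
      en <- vapply(hit, function(a) {
        o <- chains$anchors[[a]]$occs; o$end[match(s, o$seq)]
      }, numeric(1))
      if (any(st[-1] < en[-length(en)]))
        stop("colinearity violation in chain at sequence ", s,
             " (upstream bug)")
    }
    cov[[s]] <- hit
  }
  anchor_occ <- function(a, s) {
    o <- chains$anchors[[a]]$occs
    o[match(s, o$seq), ]
  }

  columns <- list()
  fragments <- data.frame(seq = integer(0), start = integer(0),
                          end = integer(0), left_anchor = integer(0),
                          right_anchor = integer(0))
  add_frag <- function(s, st, en, la, ra) {
    fragments[nrow(fragments) + 1L, ] <<- list(s, st, en,
                                               ifelse(is.na(la), NA, la),
                                               ifelse(is.na(ra), NA, ra))
  }

  if (m == 0) {
    # no division: one segment holding every whole sequence
    columns[[1]] <- list(kind = "segment", id = "seg0",
                         members = data.frame(seq = seq_len(n), start = 1L,
                                              end = lens + 1L))
    return(structure(list(columns = columns, fragments = fragments,
                          n_anchors = 0L, n_seq = n),
                     class = "segment_plan"))
  }

  # inter-anchor column t sits between anchor t and t+1 (t = 0 head, t = m tail)
  seg_members <- vector("list", m + 1)
  for (t in 0:m) seg_members[[t + 1]] <- data.frame(seq = integer(0),
                                                    start = integer(0),
                                                    end = integer(0))
  for (s in seq_len(n)) {
    h <- cov[[s]]
    if (length(h) == 0) { add_frag(s, 1L, lens[s] + 1L, NA, NA); next }
    first <- h[1]; last <- h[length(h)]
    # head piece
    st <- 1L; en <- anchor_occ(first, s)$start
    if (first == 1L) {
      seg_members[[1]] <- rbind(seg_members[[1]],
                                data.frame(seq = s, start = st, end = en))
    } else add_frag(s, st, en, NA, first)
    # between consecutive covered anchors
    if (length(h) > 1) for (i in seq_len(length(h) - 1)) {
      a <- h[i]; b <- h[i + 1]
      st <- anchor_occ(a, s)$end; en <- anchor_occ(b, s)$start
      if (b == a + 1L) {
        seg_members[[a + 1]] <- rbind(seg_members[[a + 1]],
                                      data.frame(seq = s, start = st, end = en))
      } else add_frag(s, st, en, a, b)
    }
    # tail piece
    st <- anchor_occ(last, s)$end; en <- lens[s] + 1L
    if (last == m) {
      seg_members[[m + 1]] <- rbind(seg_members[[m + 1]],
                                    data.frame(seq = s, start = st, end = en))
    } else add_frag(s, st, en, last, NA)
  }

  # reclassify single-member segments as fragments
  for (t in 0:m) {
    mem <- seg_members[[t + 1]]
    if (nrow(mem) == 1) {
      add_frag(mem$seq, mem$start, mem$end,
               if (t == 0) NA else t, if (t == m) NA else t + 1L)
      seg_members[[t + 1]] <- mem[0, , drop = FALSE]
    }
  }

  for (t in 0:m) {
    columns[[length(columns) + 1]] <-
      list(kind = "segment", id = paste0("seg", t),
           members = seg_members[[t + 1]])
    if (t < m) {
      o <- chains$anchors[[t + 1]]$occs
      columns[[length(columns) + 1]] <-
        list(kind = "anchor", id = paste0("anchor", t + 1),
             anchor = t + 1L,
             members = data.frame(seq = o$seq, start = o$start, end = o$end))
    }
  }
  # column order: seg0, anchor1, seg1, ..., anchorm, segm
  columns <- columns[order(vapply(columns, function(b) {
    t <- as.integer(sub("^(seg|anchor)", "", b$id))
    if (b$kind == "segment") 2 * t else 2 * t - 1
  }, numeric(1)))]
  structure(list(columns = columns, fragments = fragments,
                 n_anchors = m, n_seq = n),
            class = "segment_plan")
}

#' Count of multi-sequence segment blocks in a plan
#' @param plan a `segment_plan`.
#' @return number of segment blocks with at least two members.
#' @export
segment_count <- function(plan) {
  sum(vapply(plan$columns, function(b)
    b$kind == "segment" && nrow(b$members) >= 2, logical(1)))
}

# does the plan tile every sequence exactly?  (used by tests and as the
# assembler's entry check)
plan_tiles_ok <- function(plan, seqs) {
  n <- length(seqs$seqs)
  lens <- nchar(seqs$seqs)
  for (s in seq_len(n)) {
    iv <- data.frame(start = integer(0), end = integer(0))
    for (b in plan$columns) {
      hit <- b$members[b$members$seq == s, , drop = FALSE]
      if (nrow(hit) > 0) iv <- rbind(iv, hit[, c("start", "end")])
    }
    fr <- plan$fragments[plan$fragments$seq == s, , drop = FALSE]
    if (nrow(fr) > 0) iv <- rbind(iv, fr[, c("start", "end")])
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    pos <- 1L
    for (r in seq_len(nrow(iv))) {
      if (iv$start[r] != pos) return(FALSE)
      pos <- iv$end[r]
    }
    if (pos != lens[s] + 1L) return(FALSE)
  }
  TRUE
}

#' @export
print.segment_plan <- function(x, ...) {
  cat("segment_plan:", x$n_anchors, "anchors,", segment_count(x),
      "segments,", nrow(x$fragments), "fragments\n")
  invisible(x)
}

# BED-like TSV export: seq_id, start, end, block_id, kind (0-based starts).
plan_export <- function(plan, seqs, path = NULL) {
  rows <- character(0)
  for (b in plan$columns) {
    if (nrow(b$members) == 0) next
    rows <- c(rows, paste(seqs$ids[b$members$seq], b$members$start - 1L,
                          b$members$end - 1L, b$id, b$kind, sep = "\t"))
  }
  fr <- plan$fragments
  if (nrow(fr) > 0)
    rows <- c(rows, paste(seqs$ids[fr$seq], fr$start - 1L, fr$end - 1L,
                          paste0("frag_", seq_len(nrow(fr))), "fragment",
                          sep = "\t"))
  if (!is.null(path)) writeLines(rows, path)
  rows
}
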