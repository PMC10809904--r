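# Colinear MEM selection and partial-chain formation.
#
# Two MEMs are colinear when, in every sequence containing both, their
# occurrences are disjoint and appear in the same relative order.  The goal
# is the pairwise-colinear subset of maximum total size (sum of length * k).
# Colinearity is not transitive when anchors cover different sequence
# subsets, so a longest-increasing-subsequence DP is not exact; selection is
# a branch-and-bound search over position-ordered candidates instead.

# Reduce a MEM to at most one occurrence per sequence: keep, per sequence,
# the occurrence closest to the MEM's median relative start position across
# single-occurrence sequences (fallback: leftmost).
reduce_multiplicity <- function(mem) {
  occs <- mem$occs
  if (!anyDuplicated(occs$seq)) return(mem)
  tab <- table(occs$seq)
  single <- as.integer(names(tab)[tab == 1])
  med <- if (length(single) > 0) median(occs$start[occs$seq %in% single]) else NA
  pick <- unlist(lapply(split(seq_len(nrow(occs)), occs$seq), function(ix) {
    if (length(ix) == 1) return(ix)
    if (is.na(med)) return(ix[which.min(occs$start[ix])])
    d <- abs(occs$start[ix] - med)
    ix[order(d, occs$start[ix])][1]
  }))
  occs <- occs[sort(pick), , drop = FALSE]
  rownames(occs) <- NULL
  k <- nrow(occs)
  list(length = mem$length, occs = occs, k = k, size = mem$length * k)
}

# start/end lookup tables: candidates x sequences, NA where absent
cand_tables <- function(cands, n_seq) {
  m <- length(cands)
  st <- matrix(NA_real_, m, n_seq)
  en <- matrix(NA_real_, m, n_seq)
  for (i in seq_len(m)) {
    o <- cands[[i]]$occs
    st[i, o$seq] <- o$start
    en[i, o$seq] <- o$end
  }
  list(st = st, en = en)
}

# is candidate i strictly before candidate j in every shared sequence?
# (vacuously true when they share no sequence)
cand_before <- function(tb, i, j) {
  sh <- !is.na(tb$st[i, ]) & !is.na(tb$st[j, ])
  all(tb$en[i, sh] <= tb$st[j, sh])
}

# same relation on raw occurrence tables
occs_before <- function(oa, ob) {
  sh <- intersect(oa$seq, ob$seq)
  all(oa$end[match(sh, oa$seq)] <= ob$start[match(sh, ob$seq)])
}

chain_is_colinear <- function(cands, n_seq) {
  m <- length(cands)
  if (m < 2) return(TRUE)
  tb <- cand_tables(cands, n_seq)
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    if (!cand_before(tb, i, j)) return(FALSE)
  TRUE
}

# deterministic ordering key: position in the reference sequence (the one
# covered by most candidates, ties lowest index), mean start where absent
cand_keys <- function(cands, n_seq) {
  cover <- integer(n_seq)
  for (cd in cands) cover[cd$occs$seq] <- cover[cd$occs$seq] + 1L
  ref <- which.max(cover)
  vapply(cands, function(cd) {
    hit <- match(ref, cd$occs$seq)
    if (!is.na(hit)) cd$occs$start[hit] else mean(cd$occs$start)
  }, numeric(1))
}

#' Select a maximum-size pairwise-colinear subset of MEMs
#'
#' Global mode keeps or drops whole MEMs, maximizing total size over all
#' pairwise-colinear subsets (exact branch-and-bound with suffix-weight
#' pruning; a node cap returns the best chain found on pathological
#' instances).  Local mode starts from the global optimum and re-admits
#' rejected MEMs by trimming their left edge uniformly across occurrences
#' (and removing irreconcilable occurrences), keeping a trimmed MEM iff its
#' remainder is at least `l_min` long and still above the coverage
#' threshold; local-mode total size is therefore never below global-mode.
#' Selection is exact (branch-and-bound) up to 25 candidates and a
#' deterministic two-pass greedy beyond that.
#'
#' @param mems list of MEMs (coverage-filtered); multiplicities are reduced
#'   to one occurrence per sequence before selection.
#' @param mode `"global"` or `"local"`.
#' @param l_min minimum surviving length for a trimmed MEM (local mode).
#' @param coverage coverage threshold `c` re-applied after occurrence
#'   removal (local mode).
#' @param n_seq total number of sequences (inferred from occurrences if
#'   omitted).
#' @param max_candidates cap on candidates entering selection; if exceeded,
#'   only the largest are considered.
#' @return list of selected (possibly trimmed) MEMs in chain order.
#' @export
select_colinear <- function(mems, mode = c("global", "local"), l_min = 2,
                            coverage = 0, n_seq = NULL,
                            max_candidates = 512) {
  mode <- match.arg(mode)
  if (length(mems) == 0) return(list())
  cands <- lapply(mems, reduce_multiplicity)
  if (is.null(n_seq))
    n_seq <- max(vapply(cands, function(cd) max(cd$occs$seq), numeric(1)))
  sizes <- vapply(cands, function(cd) cd$size, numeric(1))
  if (length(cands) > max_candidates) {
    keep <- order(-sizes)[seq_len(max_candidates)]
    cands <- cands[sort(keep)]
    sizes <- sizes[sort(keep)]
  }
  keys <- cand_keys(cands, n_seq)
  lens <- vapply(cands, function(cd) cd$length, numeric(1))
  ord <- order(keys, -sizes, -lens)
  cands <- cands[ord]; sizes <- sizes[ord]; keys <- keys[ord]
  m <- length(cands)
  tb <- cand_tables(cands, n_seq)

  # full before-relation (comp[i, j]: i strictly before j in every shared
  # sequence; vacuously true when none is shared)
  comp <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) comp[i, j] <- cand_before(tb, i, j)

  # exact search: candidates are visited in position-key order, but a new
  # candidate may be inserted at any chain position consistent with the
  # before-relation, so key/position disagreements cannot hide the optimum
  suffix <- rev(cumsum(rev(sizes)))
  env <- new.env()
  env$best_w <- -1; env$best <- integer(0); env$nodes <- 0L
  # greedy seed (append-in-key-order) gives a strong pruning bound
  greedy <- integer(0)
  for (j in seq_len(m)) {
    if (length(greedy) == 0 || all(comp[greedy, j])) greedy <- c(greedy, j)
  }
  env$best_w <- sum(sizes[greedy]); env$best <- greedy
  if (env$best_w < sum(sizes)) {
    if (m <= 25) {
      # exact branch-and-bound with suffix-weight pruning
      node_cap <- 3e6
      dfs <- function(chain, start_i, wcur) {
        if (wcur > env$best_w) { env$best_w <- wcur; env$best <- chain }
        if (start_i > m) return()
        for (j in start_i:m) {
          if (env$nodes > node_cap) return()
          if (wcur + suffix[j] <= env$best_w) break
          lc <- length(chain)
          for (p in lc:0) {
            ok <- (p == 0 || all(comp[chain[seq_len(p)], j])) &&
                  (p == lc || all(comp[j, chain[(p + 1):lc]]))
            if (ok) {
              env$nodes <- env$nodes + 1L
              dfs(append(chain, j, after = p), j + 1L, wcur + sizes[j])
            }
          }
        }
      }
      dfs(integer(0), 1L, 0)
    } else {
      # large instances: size-descending greedy with feasible insertion,
      # kept only if it beats the key-order greedy
      ins_chain <- integer(0)
      for (j in order(-sizes, keys)) {
        lc <- length(ins_chain)
        for (p in lc:0) {
          ok <- (p == 0 || all(comp[ins_chain[seq_len(p)], j])) &&
                (p == lc || all(comp[j, ins_chain[(p + 1):lc]]))
          if (ok) { ins_chain <- append(ins_chain, j, after = p); break }
        }
      }
      if (sum(sizes[ins_chain]) > env$best_w) {
        env$best_w <- sum(sizes[ins_chain]); env$best <- ins_chain
      }
    }
  }
  chain <- cands[env$best]
  chain_keys <- keys[env$best]

  if (mode == "local") {
    rejected <- setdiff(seq_len(m), env$best)
    rej_ord <- rejected[order(-sizes[rejected], -lens[rejected],
                              keys[rejected])]
    thr <- floor(coverage * n_seq)
    for (jj in rej_ord) {
      x <- cands[[jj]]
      # insertion position: after every chain anchor that must precede the
      # candidate or conflicts with it (conflicts are resolved by trimming
      # the candidate's left edge), and after free anchors with smaller keys
      p <- 0L
      if (length(chain) > 0) {
        prec <- vapply(seq_along(chain), function(b) {
          oa <- chain[[b]]$occs; ob <- x$occs
          sh <- intersect(oa$seq, ob$seq)
          if (length(sh) == 0) return(chain_keys[b] <= keys[jj])  # free
          ia <- match(sh, oa$seq); ib <- match(sh, ob$seq)
          before_b <- all(oa$end[ia] <= ob$start[ib])
          after_b <- all(ob$end[ib] <= oa$start[ia])
          before_b || (!before_b && !after_b)  # precedes, or conflict: trim left
        }, logical(1))
        p <- sum(prec)
      }
      occs <- x$occs
      keep_occ <- rep(TRUE, nrow(occs))
      trims <- numeric(nrow(occs))
      for (r in seq_len(nrow(occs))) {
        s <- occs$seq[r]
        prev_end <- 0; nxt_start <- Inf
        if (p >= 1) for (b in p:1) {
          o <- chain[[b]]$occs; hit <- match(s, o$seq)
          if (!is.na(hit)) { prev_end <- o$end[hit]; break }
        }
        if (p < length(chain)) for (b in (p + 1):length(chain)) {
          o <- chain[[b]]$occs; hit <- match(s, o$seq)
          if (!is.na(hit)) { nxt_start <- o$start[hit]; break }
        }
        if (occs$end[r] > nxt_start) { keep_occ[r] <- FALSE; next }
        trims[r] <- max(0, prev_end - occs$start[r])
      }
      if (!any(keep_occ)) next
      t <- max(trims[keep_occ])
      newlen <- x$length - t
      if (newlen < l_min) next
      occs <- occs[keep_occ, , drop = FALSE]
      occs$start <- occs$start + t
      k <- length(unique(occs$seq))
      if (k <= thr) next
      xt <- list(length = newlen, occs = occs, k = k, size = newlen * k)
      # verify the trimmed candidate against every current anchor
      ok <- TRUE
      if (p >= 1) for (b in 1:p)
        if (!occs_before(chain[[b]]$occs, occs)) { ok <- FALSE; break }
      if (ok && p < length(chain)) for (b in (p + 1):length(chain))
        if (!occs_before(occs, chain[[b]]$occs)) { ok <- FALSE; break }
      if (!ok) next
      chain <- append(chain, list(xt), after = p)
      chain_keys <- append(chain_keys, keys[jj], after = p)
    }
  }
  chain
}

#' Augment a colinear chain with approximate occurrences
#'
#' For each anchor and each sequence it does not cover, the anchor's exact
#' string is locally aligned (affine-gap Smith-Waterman, match 2,
#' mismatch -3, gap open 5, gap extend 2) against the window of that
#' sequence lying between its occurrences of the flanking anchors (or the
#' sequence ends).  The best local hit is accepted iff the fraction of gap
#' columns in the alignment is at most `gap_frac_max`; accepted hits become
#' approximate occurrences, turning the colinear set into partial chains.
#'
#' @param selected list of colinear MEMs from [select_colinear()].
#' @param seqs the preprocessed `sequence_set`.
#' @param gap_frac_max maximum tolerated gap-column fraction (default 0.8).
#' @return a `chain_set`: list with `anchors`, each carrying `length` and
#'   `occs` (`seq`, `start`, `end`, `type` = exact/approx, `identity`).
#' @export
augment_with_local_matches <- function(selected, seqs, gap_frac_max = 0.8) {
  stopifnot(inherits(seqs, "sequence_set"))
  n <- length(seqs$seqs)
  lens <- nchar(seqs$seqs)
  anchors <- lapply(selected, function(mm) {
    o <- mm$occs
    o$type <- "exact"; o$identity <- 1
    list(length = mm$length, occs = o)
  })
  m <- length(anchors)
  occ_of <- function(a, s) {
    hit <- match(s, anchors[[a]]$occs$seq)
    if (is.na(hit)) NULL else anchors[[a]]$occs[hit, ]
  }
  for (a in seq_len(m)) {
    o1 <- anchors[[a]]$occs[1, ]
    qstr <- substr(seqs$seqs[o1$seq], o1$start, o1$end - 1)
    for (s in setdiff(seq_len(n), anchors[[a]]$occs$seq)) {
      prev_end <- 1
      if (a > 1) for (b in (a - 1):1) {
        oc <- occ_of(b, s)
        if (!is.null(oc)) { prev_end <- oc$end; break }
      }
      nxt_start <- lens[s] + 1
      if (a < m) for (b in (a + 1):m) {
        oc <- occ_of(b, s)
        if (!is.null(oc)) { nxt_start <- oc$start; break }
      }
      if (nxt_start - prev_end < 1) next
      tstr <- substr(seqs$seqs[s], prev_end, nxt_start - 1)
      la <- local_align(qstr, tstr)
      if (is.na(la$t_start) || la$n_cols == 0) next
      if (la$gap_fraction > gap_frac_max) next
      occ <- data.frame(seq = s, start = prev_end + la$t_start - 1,
                        end = prev_end + la$t_end, type = "approx",
                        identity = la$identity)
      anchors[[a]]$occs <- rbind(anchors[[a]]$occs, occ)
    }
    o <- anchors[[a]]$occs
    anchors[[a]]$occs <- o[order(o$seq), , drop = FALSE]
    rownames(anchors[[a]]$occs) <- NULL
  }
  structure(list(anchors = anchors, n_seq = n), class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat("chain_set:", length(x$anchors), "anchors over", x$n_seq, "sequences\n")
  invisible(x)
}

# TSV chain report: anchor index, length, per-sequence occurrence coordinates.
chain_report <- function(chains, ids = NULL, path = NULL) {
  rows <- unlist(lapply(seq_along(chains$anchors), function(a) {
    o <- chains$anchors[[a]]$occs
    paste(a, chains$anchors[[a]]$length,
          if (is.null(ids)) o$seq else ids[o$seq],
          o$start, o$end, o$type, sep = "\t")
  }))
  if (!is.null(path))
    writeLines(c("anchor\tlength\tseq\tstart\tend\ttype", rows), path)
  rows
}
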