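# Attach fragments to the aligned backbone and concatenate all blocks with
# junction refinement into the final MSA.
#
# Internally the backbone is a character matrix (sequences x columns) with a
# block id per column; fragments are spliced in by sequence-profile
# alignment at the column range between their flanking anchors' columns.

new_aligned_block <- function(id, kind, seqs, rows) {
  w <- if (length(rows)) unique(nchar(rows)) else 0L
  if (length(w) > 1) stop("ragged rows in block ", id)
  list(id = id, kind = kind, seqs = seqs, rows = rows,
       width = if (length(rows)) w else 0L)
}

# materialize plan columns into aligned blocks (anchor occurrences verbatim;
# anchor blocks holding approximate occurrences are realigned since their
# members are similar but not identical)
align_plan_blocks <- function(plan, seqs, backend = "internal", l_min = 30,
                              size_cap = 5e4, band_k = 16, threads = 1) {
  member_strings <- function(members)
    substr(seqs$seqs[members$seq], members$start, members$end - 1)
  jobs <- lapply(plan$columns, function(b) {
    list(b = b, strings = member_strings(b$members))
  })
  worker <- function(job) {
    b <- job$b; str <- job$strings
    if (nrow(b$members) == 0)
      return(new_aligned_block(b$id, b$kind, integer(0), character(0)))
    if (b$kind == "anchor") {
      rows <- if (length(unique(str)) == 1) str
              else msa_internal(str, band_k)
    } else {
      rows <- align_segment(str, backend = backend, l_min = l_min,
                            size_cap = size_cap, band_k = band_k)
    }
    new_aligned_block(b$id, b$kind, b$members$seq, rows)
  }
  if (threads > 1 && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(jobs, worker, mc.cores = threads,
                              mc.preschedule = TRUE)
    bad <- vapply(res, inherits, logical(1), "try-error")
    if (any(bad)) res[bad] <- lapply(jobs[bad], worker)
    res
  } else {
    lapply(jobs, worker)
  }
}

# backbone state: matrix + per-column block id
backbone_state <- function(plan, blocks) {
  n <- plan$n_seq
  mats <- lapply(blocks, function(b) {
    M <- matrix("-", n, b$width)
    if (length(b$seqs) > 0 && b$width > 0)
      M[b$seqs, ] <- do.call(rbind, strsplit(b$rows, "", fixed = TRUE))
    M
  })
  mat <- do.call(cbind, mats)
  col_ids <- unlist(lapply(blocks, function(b) rep(b$id, b$width)))
  list(mat = mat, col_ids = col_ids)
}

#' Integrate fragments into the aligned backbone
#'
#' Sequences are processed in increasing order of total unaligned fragment
#' length (ties: input order), their fragments left to right.  Each fragment
#' is spliced in by sequence-profile alignment against the aligned columns
#' between its flanking anchors (the merged profile of the segments and
#' partial chains there); existing rows only gain shared gap columns.  After
#' processing, every sequence position lies inside some block.
#'
#' @param plan the `segment_plan`.
#' @param blocks aligned blocks for the plan's columns (anchor and segment),
#'   in column order.
#' @param seqs the preprocessed `sequence_set`.
#' @param band_k band half-width for the profile alignments.
#' @return list of aligned blocks (full row set per block) covering every
#'   sequence position, in global column order.
#' @export
integrate_fragments <- function(plan, blocks, seqs, band_k = 16) {
  st <- backbone_state(plan, blocks)
  mat <- st$mat; col_ids <- st$col_ids
  n <- plan$n_seq
  fr <- plan$fragments
  fr <- fr[fr$end > fr$start, , drop = FALSE]
  if (nrow(fr) > 0) {
    tot <- vapply(seq_len(n), function(s)
      sum(fr$end[fr$seq == s] - fr$start[fr$seq == s]), numeric(1))
    seq_order <- order(tot[fr$seq], fr$seq, fr$start)
    fr <- fr[seq_order, , drop = FALSE]
    ins_counter <- 0L
    for (r in seq_len(nrow(fr))) {
      s <- fr$seq[r]
      frag <- substr(seqs$seqs[s], fr$start[r], fr$end[r] - 1)
      la <- fr$left_anchor[r]; ra <- fr$right_anchor[r]
      c1 <- if (is.na(la)) 1L else {
        hit <- which(col_ids == paste0("anchor", la))
        if (length(hit) == 0) stop("fragment flanking anchor missing from plan")
        max(hit) + 1L
      }
      c2 <- if (is.na(ra)) ncol(mat) + 1L else {
        hit <- which(col_ids == paste0("anchor", ra))
        if (length(hit) == 0) stop("fragment flanking anchor missing from plan")
        min(hit)
      }
      if (c2 < c1) stop("fragment flanking anchors inconsistent with plan")
      rng <- if (c2 > c1) c1:(c2 - 1L) else integer(0)
      if (length(rng) > 0 && any(mat[s, rng] != "-"))
        stop("fragment region of sequence ", s,
             " already contains residues (inconsistent plan)")
      fchars <- strsplit(frag, "", fixed = TRUE)[[1]]
      ins_counter <- ins_counter + 1L
      ins_id <- paste0("ins", ins_counter)
      if (length(rng) == 0 ||
          sum(mat[, rng, drop = FALSE] != "-") == 0) {
        # nothing aligned here yet: insert the fragment verbatim
        newsub <- matrix("-", n, length(fchars))
        newsub[s, ] <- fchars
        new_ids <- rep(ins_id, length(fchars))
      } else {
        sub <- mat[, rng, drop = FALSE]
        content <- which(rowSums(sub != "-") > 0)
        prof_rows <- apply(sub[content, , drop = FALSE], 1, paste0,
                           collapse = "")
        ops <- profile_pair_ops(profile_freq(frag), profile_freq(prof_rows),
                                band_k)
        newsub <- matrix("-", n, length(ops))
        newsub[, ops != 2L] <- sub
        newsub[s, ops != 3L] <- fchars
        new_ids <- rep(ins_id, length(ops))
        new_ids[ops != 2L] <- col_ids[rng]
      }
      before <- if (c1 > 1) mat[, 1:(c1 - 1L), drop = FALSE] else NULL
      after <- if (c2 <= ncol(mat)) mat[, c2:ncol(mat), drop = FALSE] else NULL
      mat <- cbind(before, newsub, after)
      col_ids <- c(if (c1 > 1) col_ids[1:(c1 - 1L)], new_ids,
                   if (c2 <= length(col_ids)) col_ids[c2:length(col_ids)])
    }
  }
  # re-split into blocks by runs of column ids
  if (ncol(mat) == 0)
    return(list(new_aligned_block("seg0", "segment", seq_len(n),
                                  rep("", n))))
  rl <- rle(col_ids)
  out <- vector("list", length(rl$values))
  pos <- 1L
  for (i in seq_along(rl$values)) {
    w <- rl$lengths[i]
    sub <- mat[, pos:(pos + w - 1L), drop = FALSE]
    rows <- apply(sub, 1, paste0, collapse = "")
    kind <- if (startsWith(rl$values[i], "anchor")) "anchor"
            else if (startsWith(rl$values[i], "ins")) "fragment"
            else "segment"
    out[[i]] <- new_aligned_block(rl$values[i], kind, seq_len(n), rows)
    pos <- pos + w
  }
  out
}

# sum-of-pairs cost of one column given symbol counts c(A,C,G,T,gap)
sp_col_counts <- function(cnt) {
  nz <- sum(cnt[1:4]); g <- cnt[5]
  mism <- nz * (nz - 1) / 2 - sum(cnt[1:4] * (cnt[1:4] - 1) / 2)
  mism + 2 * g * nz
}

col_counts <- function(mat, col) {
  x <- mat[, col]
  c(sum(x == "A"), sum(x == "C"), sum(x == "G"), sum(x == "T"),
    sum(x == "-"))
}

# best strictly-improving residue slide across junction j within the window;
# NULL if none.  A move takes the residue flanking a gap run and slides it
# to the run's other end; only moves whose source/destination straddle the
# junction are considered.
best_junction_move <- function(mat, j, window = 10) {
  W <- ncol(mat)
  a <- max(1L, j - window + 1L); b <- min(W, j + window)
  best <- NULL; best_delta <- -1e-9
  for (r in seq_len(nrow(mat))) {
    rowc <- mat[r, a:b]
    rl <- rle(rowc == "-")
    pos <- a
    for (i in seq_along(rl$values)) {
      if (rl$values[i]) {
        g1 <- pos; g2 <- pos + rl$lengths[i] - 1L
        cand <- list()
        if (g1 - 1L >= a && mat[r, g1 - 1L] != "-" && (g1 - 1L) <= j && j < g2)
          cand <- c(cand, list(c(from = g1 - 1L, to = g2)))
        if (g2 + 1L <= b && mat[r, g2 + 1L] != "-" && g1 <= j && j < (g2 + 1L))
          cand <- c(cand, list(c(from = g2 + 1L, to = g1)))
        for (mv in cand) {
          x <- mat[r, mv["from"]]
          cf <- col_counts(mat, mv["from"]); ct <- col_counts(mat, mv["to"])
          old <- sp_col_counts(cf) + sp_col_counts(ct)
          xi <- match(x, c("A", "C", "G", "T"))
          cf2 <- cf; cf2[xi] <- cf2[xi] - 1; cf2[5] <- cf2[5] + 1
          ct2 <- ct; ct2[xi] <- ct2[xi] + 1; ct2[5] <- ct2[5] - 1
          delta <- sp_col_counts(cf2) + sp_col_counts(ct2) - old
          if (delta < best_delta) {
            best_delta <- delta
            best <- list(row = r, from = unname(mv["from"]),
                         to = unname(mv["to"]), char = x)
          }
        }
      }
      pos <- pos + rl$lengths[i]
    }
  }
  best
}

# Junction refinement to a fixed point: alternate (a) all-gap column
# removal with (b) strictly-improving residue slides across each junction,
# until neither applies.  Every slide strictly lowers the whole-alignment
# SP cost, so the procedure terminates and is idempotent.
refine_mat <- function(mat, junctions, window = 10) {
  repeat {
    allgap <- which(colSums(mat != "-") == 0)
    if (length(allgap) > 0) {
      junctions <- vapply(junctions, function(jj)
        jj - sum(allgap <= jj), numeric(1))
      mat <- mat[, -allgap, drop = FALSE]
    }
    jset <- unique(junctions[junctions >= 1 & junctions < ncol(mat)])
    moved <- FALSE
    for (j in jset) {
      repeat {
        mv <- best_junction_move(mat, j, window)
        if (is.null(mv)) break
        mat[mv$row, mv$from] <- "-"
        mat[mv$row, mv$to] <- mv$char
        moved <- TRUE
      }
    }
    if (!moved && length(allgap) == 0) break
  }
  list(mat = mat, junctions = junctions)
}

#' Concatenate aligned blocks and refine the junctions
#'
#' Blocks are concatenated horizontally in order.  Refinement then (a)
#' deletes all-gap columns and (b), within a fixed window each side of every
#' block junction, slides residues across the junction whenever doing so
#' strictly reduces the window's sum-of-pairs cost (match 0 / mismatch 1 /
#' gap 2), repeating to a fixed point.  Refinement never increases the
#' whole-alignment SP cost and is idempotent.
#'
#' @param blocks list of aligned blocks with full row sets (from
#'   [integrate_fragments()]).
#' @param ids sequence ids for the result (default `s1..sn`).
#' @param window refinement window half-width in columns (default 10).
#' @param refine set `FALSE` to concatenate only.
#' @return an `msa`: list with `ids`, `rows`, `width`.
#' @export
concatenate_and_refine <- function(blocks, ids = NULL, window = 10,
                                   refine = TRUE) {
  n <- length(blocks[[1]]$rows)
  for (b in blocks) {
    if (length(b$rows) != n) stop("blocks must carry a full row set")
  }
  mats <- lapply(blocks, function(b) {
    if (b$width == 0) matrix("-", n, 0)
    else do.call(rbind, strsplit(b$rows, "", fixed = TRUE))
  })
  mat <- do.call(cbind, mats)
  junctions <- cumsum(vapply(blocks, function(b) b$width, numeric(1)))
  junctions <- junctions[-length(junctions)]
  if (refine) {
    ref <- refine_mat(mat, junctions, window)
    mat <- ref$mat
  } else {
    allgap <- which(colSums(mat != "-") == 0)
    if (length(allgap) > 0) mat <- mat[, -allgap, drop = FALSE]
  }
  rows <- if (ncol(mat) > 0) apply(mat, 1, paste0, collapse = "")
          else rep("", n)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  structure(list(ids = ids, rows = unname(rows), width = ncol(mat)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$rows), "sequences x", x$width, "columns\n")
  invisible(x)
}
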