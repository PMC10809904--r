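# Synthetic homologous sequence families with a known true alignment.
#
# A random ancestor is drawn and each child is derived independently from it
# (star tree): point substitutions at a per-site probability solved from the
# target pairwise similarity, plus insertion/deletion events at a per-site
# rate with geometric lengths.  The true alignment is tracked through the
# edits; insertions from different children are never homologous and occupy
# separate columns.

# per-child substitution probability p such that two independent children
# match at a site with probability s: (1-p)^2 + p^2/3 = s
sub_prob_for_similarity <- function(similarity) {
  if (similarity >= 1) return(0)
  disc <- 4 - (16 / 3) * (1 - similarity)
  if (disc < 0) stop("similarity too low for the substitution model")
  (2 - sqrt(disc)) / (8 / 3)
}

#' Simulate a family of homologous sequences with a known true alignment
#'
#' @param ancestor_len ancestor length in bp.
#' @param n number of sequences (>= 2).
#' @param similarity target mean pairwise identity in `(0, 1]`, measured
#'   over true-alignment columns where both sequences have a residue.
#' @param indel_rate expected indel events per ancestor site (default
#'   0.005).
#' @param mean_indel_len mean indel length in bp, geometric (default 2).
#' @param seed integer seed; the family is a deterministic function of the
#'   parameters and the seed.
#' @return a `sim_family`: list with `seqs` (a `sequence_set`), `true_msa`
#'   (an `msa` that degaps to `seqs`) and `params`.
#' @examples
#' fam <- simulate_family(1000, 6, 0.95, seed = 7)
#' pairwise_identity(fam$true_msa)
#' @export
simulate_family <- function(ancestor_len, n, similarity,
                            indel_rate = 0.005, mean_indel_len = 2,
                            seed = 1) {
  if (similarity <= 0 || similarity > 1) stop("similarity must be in (0, 1]")
  if (n < 2) stop("n must be >= 2")
  if (ancestor_len < 1) stop("ancestor_len must be positive")
  if (indel_rate < 0 || mean_indel_len < 1) stop("invalid indel parameters")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, ancestor_len, replace = TRUE)
  p_sub <- sub_prob_for_similarity(similarity)

  kids <- vector("list", n)     # residue per ancestor site (NA = deleted)
  ins <- vector("list", n)      # insertions keyed by slot 0..ancestor_len
  for (i in seq_len(n)) {
    child <- anc
    nsub <- rbinom(1, ancestor_len, p_sub)
    if (nsub > 0) {
      at <- sample.int(ancestor_len, nsub)
      for (pos in at)
        child[pos] <- sample(setdiff(bases, child[pos]), 1)
    }
    nev <- rbinom(1, ancestor_len, indel_rate)
    ins_i <- list()
    if (nev > 0) {
      evpos <- sample.int(ancestor_len, nev)
      evins <- runif(nev) < 0.5
      evlen <- rgeom(nev, 1 / mean_indel_len) + 1L
      for (e in seq_len(nev)) {
        if (evins[e]) {
          slot <- as.character(evpos[e])
          ins_i[[slot]] <- c(ins_i[[slot]],
                             sample(bases, evlen[e], replace = TRUE))
        } else {
          del <- evpos[e]:min(ancestor_len, evpos[e] + evlen[e] - 1L)
          child[del] <- NA
        }
      }
    }
    kids[[i]] <- child
    ins[[i]] <- ins_i
  }

  # true-alignment columns: ancestor sites in order, with each child's
  # insertions at a slot occupying their own column runs (child order)
  slot_ids <- sort(unique(as.integer(unlist(lapply(ins, names)))))
  slot_strings <- function(i) {
    # the interleaved insertion block at each slot, from child i's view
    vapply(slot_ids, function(s) {
      paste0(vapply(seq_len(n), function(j) {
        v <- ins[[j]][[as.character(s)]]
        if (is.null(v)) "" else if (j == i) paste0(v, collapse = "")
        else strrep("-", length(v))
      }, character(1)), collapse = "")
    }, character(1))
  }
  aligned <- vapply(seq_len(n), function(i) {
    sites <- ifelse(is.na(kids[[i]]), "-", kids[[i]])
    site_str <- paste0(sites, collapse = "")
    bounds <- c(0L, slot_ids, ancestor_len)
    segs <- substring(site_str, head(bounds, -1) + 1L, c(slot_ids, ancestor_len))
    paste0(paste0(segs[-length(segs)], slot_strings(i), collapse = ""),
           segs[length(segs)])
  }, character(1))
  ids <- sprintf("seq%02d", seq_len(n))
  seqs <- new_sequence_set(ids, degap(aligned))
  true_msa <- structure(list(ids = ids, rows = aligned,
                             width = nchar(aligned[1])), class = "msa")
  structure(list(seqs = seqs, true_msa = true_msa,
                 params = list(ancestor_len = ancestor_len, n = n,
                               target_similarity = similarity,
                               indel_rate = indel_rate,
                               mean_indel_len = mean_indel_len,
                               seed = seed)),
            class = "sim_family")
}

#' Mean pairwise identity of an alignment
#'
#' Identity of a pair is the fraction of matching columns among columns
#' where both rows carry a residue; the mean is over all unordered pairs.
#'
#' @param msa an `msa` object.
#' @return mean pairwise identity in `[0, 1]`.
#' @export
pairwise_identity <- function(msa) {
  m <- msa_char_matrix(msa)
  n <- nrow(m)
  tot <- 0; cnt <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    both <- m[a, ] != "-" & m[b, ] != "-"
    if (any(both)) {
      tot <- tot + sum(m[a, both] == m[b, both]) / sum(both)
      cnt <- cnt + 1
    }
  }
  if (cnt == 0) NA_real_ else tot / cnt
}

#' @export
print.sim_family <- function(x, ...) {
  cat("sim_family:", x$params$n, "sequences from a", x$params$ancestor_len,
      "bp ancestor, target similarity", x$params$target_similarity, "\n")
  invisible(x)
}
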