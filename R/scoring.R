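# Alignment quality metrics: Q score, TC score, and average sum-of-pairs.

msa_char_matrix <- function(msa) {
  if (msa$width == 0) return(matrix(character(0), length(msa$rows), 0))
  do.call(rbind, strsplit(toupper(msa$rows), "", fixed = TRUE))
}

#' Q and TC score of a test alignment against a reference
#'
#' Q is the number of correctly aligned residue pairs divided by the number
#' of residue pairs in the reference; TC is the number of reference columns
#' whose residues are all reproduced in a single test column, divided by the
#' number of reference columns.
#'
#' @param test,ref `msa` objects with the same ids and the same degapped
#'   sequences.
#' @return list with `q` and `tc`, both in `[0, 1]`.
#' @export
q_tc_score <- function(test, ref) {
  stopifnot(inherits(test, "msa"), inherits(ref, "msa"))
  if (!identical(test$ids, ref$ids))
    stop("test and reference alignments have different ids")
  if (!identical(degap(toupper(test$rows)), degap(toupper(ref$rows))))
    stop("test and reference alignments hold different sequences")
  mt <- msa_char_matrix(test)
  mr <- msa_char_matrix(ref)
  n <- nrow(mr)
  # residue index per cell (NA at gaps)
  ridx <- function(m) {
    out <- matrix(NA_integer_, nrow(m), ncol(m))
    for (r in seq_len(nrow(m))) {
      ng <- m[r, ] != "-"
      out[r, ng] <- seq_len(sum(ng))
    }
    out
  }
  it <- ridx(mt); ir <- ridx(mr)
  nres <- vapply(seq_len(n), function(r) sum(!is.na(ir[r, ])), integer(1))
  total_pairs <- 0; common_pairs <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    # map residue index of a -> aligned residue index of b, in each alignment
    map_of <- function(im) {
      mm <- rep(NA_integer_, nres[a])
      both <- !is.na(im[a, ]) & !is.na(im[b, ])
      mm[im[a, both]] <- im[b, both]
      mm
    }
    mref <- map_of(ir); mtst <- map_of(it)
    total_pairs <- total_pairs + sum(!is.na(mref))
    common_pairs <- common_pairs +
      sum(!is.na(mref) & !is.na(mtst) & mref == mtst)
  }
  if (total_pairs == 0)
    stop("reference alignment contains no aligned residue pairs")
  # TC: a reference column is correct when all its residues share one test
  # column
  colkey <- function(im) {
    apply(im, 2, function(col) {
      nz <- which(!is.na(col))
      paste(nz, col[nz], sep = ":", collapse = ",")
    })
  }
  kr <- colkey(ir); kt <- colkey(it)
  tc <- sum(kr %in% kt) / length(kr)
  list(q = common_pairs / total_pairs, tc = tc)
}

#' Sum-of-pairs cost of an alignment
#'
#' For every unordered row pair and column: match 0, mismatch 1, residue
#' against gap 2, gap against gap 0.  The average divides the total by the
#' number of sequences; lower is better.
#'
#' @param msa an `msa` object (rectangular).
#' @return list with `sp_total` and `sp_average`.
#' @examples
#' m <- structure(list(ids = c("a", "b"), rows = c("AC-T", "ACGT"),
#'                     width = 4L), class = "msa")
#' sp_score(m)   # one residue-vs-gap column: total 2, average 1
#' @export
sp_score <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  m <- msa_char_matrix(msa)
  n <- nrow(m)
  if (ncol(m) == 0) return(list(sp_total = 0, sp_average = 0))
  cb <- sapply(c("A", "C", "G", "T"), function(b) colSums(m == b))
  if (is.null(dim(cb))) cb <- matrix(cb, nrow = 1)
  nz <- rowSums(cb)
  g <- n - nz
  mism <- nz * (nz - 1) / 2 - rowSums(cb * (cb - 1) / 2)
  total <- sum(mism + 2 * g * nz)
  list(sp_total = total, sp_average = total / n)
}

#' Score a test alignment (optionally against a reference)
#'
#' @param test an `msa` or path to an aligned FASTA.
#' @param ref optional reference `msa` or path for Q/TC.
#' @return list with `sp_total`, `sp_average` and, when a reference is
#'   given, `q` and `tc`.
#' @export
score_alignment <- function(test, ref = NULL) {
  as_msa <- function(x) {
    if (inherits(x, "msa")) return(x)
    ss <- read_fasta(x)
    structure(list(ids = ss$ids, rows = toupper(ss$seqs),
                   width = nchar(ss$seqs[1])), class = "msa")
  }
  test <- as_msa(test)
  out <- sp_score(test)
  if (!is.null(ref)) out <- c(out, q_tc_score(test, as_msa(ref)))
  out
}
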