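# End-to-end pipeline: preprocess -> concatenate -> index -> MEMs ->
# coverage filter -> colinear chain -> augmentation -> segmentation ->
# parallel segment alignment -> fragment integration -> concatenation with
# junction refinement.

#' Pipeline configuration
#'
#' @param in_path,out_path input/output FASTA paths (optional when calling
#'   [align_sequences()] directly).
#' @param l_min minimum MEM length in bp (default 30; use 39 for parity with
#'   k-mer-seeded vertical-division aligners).
#' @param coverage minimum sequence-coverage threshold `c` in `[0, 1]`
#'   (default 0.7): a MEM must cover more than `floor(c * n)` sequences.
#' @param mode chain selection mode, `"global"` (whole MEMs kept/dropped) or
#'   `"local"` (overlapping MEMs trimmed to fit).
#' @param backend segment aligner: `"internal"`, `"mafft"`, or
#'   `"external:<template>"`.
#' @param threads worker count for segment alignment (results are merged in
#'   plan order, so output is independent of thread count).
#' @param gap_frac_max gap-fraction threshold for accepting approximate
#'   occurrences (default 0.8).
#' @param size_cap mean segment length above which a segment is re-divided
#'   recursively (depth-capped at 2).
#' @param band_k initial band half-width for profile alignments.
#' @param refine_window junction refinement window half-width in columns.
#' @param seed integer seed recorded in the config (the pipeline itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(in_path = NULL, out_path = NULL, l_min = 30,
                       coverage = 0.7, mode = c("global", "local"),
                       backend = "internal", threads = 1,
                       gap_frac_max = 0.8, size_cap = 5e4, band_k = 16,
                       refine_window = 10, seed = 1) {
  mode <- match.arg(mode)
  if (l_min < 2) stop("l_min must be >= 2")
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  structure(list(in_path = in_path, out_path = out_path, l_min = l_min,
                 coverage = coverage, mode = mode, backend = backend,
                 threads = threads, gap_frac_max = gap_frac_max,
                 size_cap = size_cap, band_k = band_k,
                 refine_window = refine_window, seed = seed),
            class = "run_config")
}

# core vertical-division alignment of bare strings; also the recursion
# target for oversize segments (depth > 0)
vertical_align <- function(strings, l_min = 30, coverage = 0.7,
                           mode = "global", backend = "internal",
                           threads = 1, gap_frac_max = 0.8, size_cap = 5e4,
                           band_k = 16, refine_window = 10, depth = 0,
                           report = FALSE) {
  n <- length(strings)
  ids <- paste0("s", seq_len(n))
  nonempty <- which(nchar(strings) > 0)
  direct <- function() {
    rows <- backend_align(strings, backend, band_k)
    msa <- structure(list(ids = ids, rows = rows, width = nchar(rows[1])),
                     class = "msa")
    attr(msa, "report") <- list(mem_count = 0L, anchor_count = 0L,
                                segment_count = 1L, fragment_count = 0L)
    msa
  }
  if (n < 2 || length(nonempty) < 2) return(direct())
  seqs <- new_sequence_set(ids, strings)
  if (any(nchar(strings) == 0)) return(direct())
  ct <- concat_sequences(seqs)
  idx <- build_index(ct)
  iv <- find_lcp_intervals(idx, l_min)
  mems <- extend_to_mems(idx, iv)
  mems <- filter_by_coverage(mems, coverage, n)
  mem_count <- length(mems)
  chain <- select_colinear(mems, mode = mode, l_min = l_min,
                           coverage = coverage, n_seq = n)
  if (length(chain) == 0) return(direct())
  chains <- augment_with_local_matches(chain, seqs, gap_frac_max)
  plan <- build_segmentation(chains, seqs)
  blocks <- align_plan_blocks(plan, seqs, backend = backend, l_min = l_min,
                              size_cap = size_cap, band_k = band_k,
                              threads = threads)
  full <- integrate_fragments(plan, blocks, seqs, band_k = band_k)
  msa <- concatenate_and_refine(full, ids = ids, window = refine_window)
  attr(msa, "report") <- list(mem_count = mem_count,
                              anchor_count = length(chains$anchors),
                              segment_count = segment_count(plan),
                              fragment_count = sum(plan$fragments$end >
                                                   plan$fragments$start))
  msa
}

#' Align a set of sequences with the anchor pipeline
#'
#' @param seqs a `sequence_set` (raw sequences are preprocessed first) or a
#'   character vector.
#' @param cfg a [run_config()].
#' @return an `msa` with a `report` attribute (MEM/anchor/segment/fragment
#'   counts and the output's average SP cost).
#' @examples
#' fam <- simulate_family(800, 5, 0.95, seed = 1)
#' msa <- align_sequences(fam$seqs, run_config(l_min = 20))
#' attr(msa, "report")$segment_count
#' q_tc_score(msa, fam$true_msa)
#' @export
align_sequences <- function(seqs, cfg = run_config()) {
  if (is.character(seqs)) seqs <- new_sequence_set(paste0("s", seq_along(seqs)), seqs)
  stopifnot(inherits(seqs, "sequence_set"))
  if (length(seqs$seqs) < 2) stop("need >= 2 sequences")
  pre <- preprocess_seqs(seqs)
  msa <- vertical_align(pre$seqs, l_min = cfg$l_min, coverage = cfg$coverage,
                        mode = cfg$mode, backend = cfg$backend,
                        threads = cfg$threads,
                        gap_frac_max = cfg$gap_frac_max,
                        size_cap = cfg$size_cap, band_k = cfg$band_k,
                        refine_window = cfg$refine_window)
  msa$ids <- seqs$ids
  if (!identical(degap(msa$rows), degap(pre$seqs)))
    stop("internal error: alignment does not degap to its inputs")
  rep <- attr(msa, "report")
  rep$sp_average <- sp_score(msa)$sp_average
  rep$width <- msa$width
  attr(msa, "report") <- rep
  msa
}

#' Run the full alignment pipeline on FASTA files
#'
#' Reads the input, aligns it (see [align_sequences()]), writes the aligned
#' FASTA, and returns the alignment with a run report.
#'
#' @param cfg a [run_config()] with `in_path` (and optionally `out_path`).
#' @param quiet suppress per-stage log lines.
#' @return the `msa`, invisibly; its `report` attribute carries MEM, anchor,
#'   segment and fragment counts plus the output average SP cost.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$in_path)) stop("cfg$in_path is required")
  log_line <- function(...) if (!quiet) message("[memalign] ", ...)
  log_line("reading ", cfg$in_path)
  seqs <- read_fasta(cfg$in_path)
  if (length(seqs$seqs) < 2) stop("need >= 2 sequences")
  log_line(length(seqs$seqs), " sequences, lengths ",
           paste(range(nchar(seqs$seqs)), collapse = "-"))
  msa <- align_sequences(seqs, cfg)
  rep <- attr(msa, "report")
  log_line("MEMs after coverage filter: ", rep$mem_count)
  log_line("anchors: ", rep$anchor_count, ", segments: ", rep$segment_count,
           ", fragments: ", rep$fragment_count)
  log_line("alignment width: ", rep$width, ", average SP: ",
           format(rep$sp_average, digits = 6))
  if (!is.null(cfg$out_path)) {
    write_fasta(msa, cfg$out_path)
    log_line("wrote ", cfg$out_path)
  }
  invisible(msa)
}
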