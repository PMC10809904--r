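# Suffix array + LCP array of the concatenated text.

#' Build the suffix index of a concatenated text
#'
#' Constructs the suffix array (lexicographic order of all suffix start
#' positions) and the LCP array (`lcp[i]` is the longest common prefix of the
#' suffixes at ranks `i-1` and `i`; `lcp[1] = 0`) of the integer text.
#' Because separators and masked positions carry pairwise-distinct symbols,
#' no common prefix ever crosses a sequence boundary or a masked base.
#'
#' @param concat a `concat_text` from [concat_sequences()], or a bare integer
#'   vector of symbol codes.
#' @return a `suffix_index`: list with `concat`, `sa` (1-based permutation)
#'   and `lcp`.
#' @export
build_index <- function(concat) {
  codes <- if (inherits(concat, "concat_text")) concat$codes else as.integer(concat)
  if (length(codes) == 0) stop("empty text")
  sa <- sa_build_cpp(codes)
  lcp <- lcp_kasai_cpp(codes, sa)
  structure(list(concat = if (inherits(concat, "concat_text")) concat else NULL,
                 codes = codes, sa = sa, lcp = lcp),
            class = "suffix_index")
}

#' @export
print.suffix_index <- function(x, ...) {
  cat("suffix_index: N =", length(x$codes), "\n")
  invisible(x)
}

# Debug dump: rank, sa, lcp and the first chars of each sorted suffix.
index_dump <- function(index, path = NULL, prefix_len = 12) {
  stopifnot(inherits(index, "suffix_index"))
  dec <- if (!is.null(index$concat)) index$concat$decode else NULL
  pfx <- vapply(index$sa, function(p) {
    idx <- p:min(p + prefix_len - 1, length(index$codes))
    if (is.null(dec)) paste(index$codes[idx], collapse = ",")
    else paste0(ifelse(is.na(dec[index$codes[idx]]), "$",
                       dec[index$codes[idx]]), collapse = "")
  }, character(1))
  df <- data.frame(rank = seq_along(index$sa), sa = index$sa,
                   lcp = index$lcp, suffix = pfx)
  if (!is.null(path)) utils::write.table(df, path, sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  df
}
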