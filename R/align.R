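#' Global protein alignment
#'
#' Deterministic Needleman-Wunsch global alignment under BLOSUM62 with affine
#' gap costs (a gap of length L costs `gap_open + L * gap_extend`; terminal
#' gaps are penalized). Percent identity is identical columns divided by
#' alignment length.
#'
#' @param seq_a,seq_b amino-acid strings over the 20-letter alphabet plus
#'   `X` (and `*` for internal stops, scored as `X`).
#' @param gap_open,gap_extend affine gap parameters.
#' @return an object of class `nm_alignment`: list with `aligned_a`,
#'   `aligned_b` (gapped texts), `score`, `percent_identity`, and
#'   `map_a`/`map_b` (per alignment column, the 1-based residue index in each
#'   input, `NA` at gaps).
#' @export
align_proteins <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  for (nm in c("seq_a", "seq_b")) {
    s <- get(nm)
    if (!is.character(s) || length(s) != 1 || !nzchar(s)) {
      abort(paste0(nm, " must be a non-empty amino-acid string"))
    }
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX*]", str_to_upper(s))
    if (bad > 0) abort(paste0("illegal character in ", nm, " at position ", bad))
  }
  a <- gsub("\\*", "X", str_to_upper(seq_a))
  b <- gsub("\\*", "X", str_to_upper(seq_b))
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = gap_open, gapExtension = gap_extend,
                                       type = "global")
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  map_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  map_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  structure(list(aligned_a = pa, aligned_b = pb,
                 score = Biostrings::score(aln),
                 percent_identity = mean(ca == cb & ca != "-"),
                 map_a = as.integer(map_a), map_b = as.integer(map_b)),
            class = "nm_alignment")
}

#' @export
print.nm_alignment <- function(x, ...) {
  cat("<nm_alignment> score ", x$score, ", identity ",
      round(100 * x$percent_identity, 1), "%\n", sep = "")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  invisible(x)
}
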