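#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_dbl map_int map_chr map_lgl pmap imap keep
#' @importFrom stringr str_sub str_length str_to_upper str_detect str_split
NULL

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

# bases denoted by each IUPAC letter
iupac_expand <- function(code) {
  map_table <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  map_table[[str_to_upper(code)]]
}

# smallest IUPAC code covering a base set
iupac_code <- function(bases) {
  bases <- sort(unique(str_to_upper(bases)))
  key <- paste(bases, collapse = "")
  lookup <- c(A = "A", C = "C", G = "G", T = "T",
              AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
              CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
  out <- lookup[[key]]
  if (is.null(out)) "N" else out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of a DNA string
#'
#' Ambiguity characters (N, R, Y, ...) are excluded from both numerator and
#' denominator so that degenerate positions do not bias the estimate.
#'
#' @param seq character vector of DNA sequences (concatenated before counting).
#' @return a single fraction in `[0, 1]`; `NA` if no unambiguous base exists.
#' @export
gc_fraction <- function(seq) {
  seq <- paste(str_to_upper(seq), collapse = "")
  if (!nzchar(seq)) return(NA_real_)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                        letters = c("A", "C", "G", "T"))
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  unname((counts[["C"]] + counts[["G"]]) / total)
}

# draw a sub-seed for a named stream from a top-level seed
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# random DNA of a given GC content
random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}
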