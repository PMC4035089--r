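#' Detect near-identical sub-telomeric repeats
#'
#' Chlorarachniophyte nucleomorph chromosomes carry long, nearly identical
#' repeat blocks on every chromosome end, homogenized by recombination. This
#' detector compares all chromosome ends telomere-inward (right ends are
#' reverse-complemented so all ends read in the same orientation) and reports,
#' for each end, the maximal terminal interval over which every pair of
#' reported ends stays at or above `min_identity`, provided it reaches
#' `min_length`.
#'
#' @param genome an `nm_genome` with at least one chromosome (two ends).
#' @param min_length minimum repeat length to report (bp).
#' @param min_identity minimum pairwise identity over the reported interval.
#'   The default 0.995 tolerates a handful of substitutions over tens of kbp.
#' @return a tibble of class `nm_repeats` with columns `chromosome`, `end`
#'   (`"left"`/`"right"`), `start`, `end_pos` (1-based inclusive),
#'   `length`, `identity_to_consensus`; the majority-rule consensus of the
#'   oriented ends is in `attr(, "consensus")`. Zero rows when no end
#'   qualifies.
#' @export
detect_subtelomeric_repeats <- function(genome, min_length = 1000,
                                        min_identity = 0.995) {
  ch <- genome$chromosomes
  ends <- list()
  for (i in seq_len(nrow(ch))) {
    if (ch$length[i] < min_length) {
      warn(paste0("chromosome ", ch$name[i], " shorter than min_length; ends skipped"))
      next
    }
    ends[[length(ends) + 1]] <- list(chromosome = ch$name[i], end = "left",
                                     seq = ch$sequence[i], chrlen = ch$length[i])
    ends[[length(ends) + 1]] <- list(chromosome = ch$name[i], end = "right",
                                     seq = revcomp(ch$sequence[i]),
                                     chrlen = ch$length[i])
  }
  empty <- tibble(chromosome = character(), end = character(),
                  start = integer(), end_pos = integer(), length = integer(),
                  identity_to_consensus = double())
  class(empty) <- c("nm_repeats", class(empty))
  if (length(ends) < 2) return(empty)

  # compare ends over at most half the shortest chromosome
  max_l <- min(map_int(ends, ~ as.integer(.x$chrlen))) %/% 2L
  mats <- map(ends, ~ strsplit(str_sub(.x$seq, 1, max_l), "")[[1]])
  pairs <- utils::combn(length(ends), 2)
  # cumulative pairwise mismatches by prefix length
  ok_len <- rep(TRUE, max_l)
  for (p in seq_len(ncol(pairs))) {
    mm <- cumsum(mats[[pairs[1, p]]] != mats[[pairs[2, p]]])
    ok_len <- ok_len & (1 - mm / seq_len(max_l)) >= min_identity
  }
  cand <- which(ok_len)
  cand <- cand[cand >= min_length]
  if (length(cand) == 0) return(empty)
  L <- max(cand)

  cons_mat <- do.call(rbind, map(mats, ~ .x[seq_len(L)]))
  consensus <- apply(cons_mat, 2, function(col) names(which.max(table(col))))
  consensus <- paste(consensus, collapse = "")
  out <- bind_rows(map(ends, function(e) {
    ident <- mean(strsplit(str_sub(e$seq, 1, L), "")[[1]] ==
                    strsplit(consensus, "")[[1]])
    if (e$end == "left") {
      tibble(chromosome = e$chromosome, end = "left", start = 1L,
             end_pos = L, length = L, identity_to_consensus = ident)
    } else {
      tibble(chromosome = e$chromosome, end = "right",
             start = as.integer(e$chrlen - L + 1L), end_pos = as.integer(e$chrlen),
             length = L, identity_to_consensus = ident)
    }
  }))
  attr(out, "consensus") <- consensus
  class(out) <- c("nm_repeats", class(out))
  out
}

#' Detect a tandem repeat array and its degenerate consensus
#'
#' Scores every candidate unit length by periodicity (the fraction of
#' positions matching the base one unit downstream), picks the best-scoring
#' length (ties broken toward the smallest unit, the primitive period), and
#' builds a per-column consensus in which every base observed at >= 20% column
#' frequency is folded into the smallest covering IUPAC code. This reproduces
#' degenerate units such as the 36-nt R/Y-coded boundary repeat of the
#' nucleomorph sub-telomeres.
#'
#' @param sequence DNA text containing (only) the candidate array.
#' @param unit_range integer `c(min, max)` unit lengths to consider.
#' @param min_copies minimum number of unit copies required.
#' @param min_match minimum periodicity match fraction to call an array.
#' @param degeneracy_freq column frequency above which a base enters the
#'   consensus code.
#' @return a one-row tibble (`unit_length`, `consensus`, `copy_number`,
#'   `match_fraction`, `start`, `end`) or `NULL` when no periodicity
#'   qualifies.
#' @export
detect_tandem_array <- function(sequence, unit_range = c(2, 60), min_copies = 3,
                                min_match = 0.8, degeneracy_freq = 0.2) {
  sequence <- str_to_upper(sequence)
  n <- str_length(sequence)
  if (n < 2 * unit_range[1]) abort("sequence shorter than two minimal units")
  chars <- strsplit(sequence, "")[[1]]
  units <- seq(unit_range[1], min(unit_range[2], n %/% 2))
  units <- units[n / units >= min_copies]
  if (length(units) == 0) return(NULL)
  score <- map_dbl(units, function(u) {
    mean(chars[seq_len(n - u)] == chars[seq_len(n - u) + u])
  })
  best <- which(score == max(score))[1]   # smallest unit wins ties
  if (score[best] < min_match) return(NULL)
  u <- units[best]
  cols <- ((seq_len(n) - 1L) %% u) + 1L
  consensus <- map_chr(seq_len(u), function(j) {
    tab <- table(chars[cols == j])
    freq <- tab / sum(tab)
    iupac_code(names(freq)[freq >= degeneracy_freq])
  })
  tibble(unit_length = u,
         consensus = paste(consensus, collapse = ""),
         copy_number = n / u,
         match_fraction = score[best],
         start = 1L, end = n)
}

#' Sliding-window GC profile
#'
#' @param sequence DNA text.
#' @param window window size (bp); if larger than the sequence, a single
#'   whole-sequence window is returned.
#' @param step step between window starts (bp); must satisfy
#'   `window >= step >= 1`.
#' @return a tibble of class `nm_gc_profile` with `start`, `end` (1-based
#'   inclusive), `gc`, and `partial` flagging a final short window.
#' @export
gc_profile <- function(sequence, window = 1000, step = window) {
  n <- str_length(sequence)
  if (!(window >= step && step >= 1)) abort("need window >= step >= 1")
  if (window > n) {
    out <- tibble(start = 1L, end = as.integer(n),
                  gc = gc_fraction(sequence), partial = TRUE)
  } else {
    starts <- seq(1L, n, by = step)
    keep <- starts + window - 1L <= n
    full_starts <- starts[keep]
    ends <- full_starts + window - 1L
    partial <- rep(FALSE, length(full_starts))
    if (any(!keep)) {           # trailing short window, flagged
      full_starts <- c(full_starts, starts[!keep][1])
      ends <- c(ends, n)
      partial <- c(partial, TRUE)
    }
    out <- tibble(start = as.integer(full_starts), end = as.integer(ends),
                  gc = map_dbl(seq_along(full_starts),
                               ~ gc_fraction(str_sub(sequence, full_starts[.x], ends[.x]))),
                  partial = partial)
  }
  class(out) <- c("nm_gc_profile", class(out))
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' GC inside and outside a region set
#'
#' @param genome an `nm_genome`.
#' @param regions tibble with `chromosome`, `start`, `end` (1-based
#'   inclusive); overlapping regions are unioned.
#' @return a one-row tibble with `gc_inside`, `gc_outside`, `bp_inside`,
#'   `bp_outside`. `gc_inside` is `NA` for an empty region set.
#' @export
region_gc <- function(genome, regions) {
  region_gc_genome(genome, regions)
}

region_gc_genome <- function(genome, regions) {
  if (is.null(regions) || nrow(regions) == 0) {
    return(tibble(gc_inside = NA_real_, gc_outside = gc_fraction(genome$chromosomes$sequence),
                  bp_inside = 0L, bp_outside = sum(genome$chromosomes$length)))
  }
  inside <- character()
  outside <- character()
  for (i in seq_len(nrow(genome$chromosomes))) {
    nm <- genome$chromosomes$name[i]
    seq <- genome$chromosomes$sequence[i]
    len <- genome$chromosomes$length[i]
    rr <- filter(regions, .data$chromosome == nm)
    if (nrow(rr) == 0) {
      outside <- c(outside, seq)
      next
    }
    if (any(rr$start < 1 | rr$end > len)) abort("region outside chromosome bounds")
    ir <- IRanges::reduce(IRanges::IRanges(rr$start, rr$end))
    inside <- c(inside, as.character(Biostrings::extractAt(Biostrings::DNAString(seq), ir)))
    comp <- IRanges::setdiff(IRanges::IRanges(1, len), ir)
    if (length(comp)) {
      outside <- c(outside, as.character(Biostrings::extractAt(Biostrings::DNAString(seq), comp)))
    }
  }
  tibble(gc_inside = if (length(inside)) gc_fraction(inside) else NA_real_,
         gc_outside = if (length(outside)) gc_fraction(outside) else NA_real_,
         bp_inside = sum(str_length(inside)),
         bp_outside = sum(str_length(outside)))
}

#' Write repeat regions or tandem arrays as BED
#'
#' Output is 0-based half-open per the BED convention; the score column
#' carries identity (repeats) or match fraction (arrays) scaled to 0-1000.
#'
#' @param regions tibble with `chromosome`, `start`, `end_pos`/`end` and a
#'   score column.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  endcol <- if ("end_pos" %in% names(regions)) regions$end_pos else regions$end
  score <- if ("identity_to_consensus" %in% names(regions)) {
    regions$identity_to_consensus
  } else if ("match_fraction" %in% names(regions)) regions$match_fraction else 0
  name <- if ("end" %in% names(regions) && is.character(regions$end)) {
    paste0(regions$chromosome, "_", regions$end)
  } else regions$chromosome
  readr::write_tsv(tibble(chrom = regions$chromosome,
                          start = regions$start - 1L, end = endcol,
                          name = name,
                          score = round(1000 * score)),
                   path, col_names = FALSE)
  invisible(path)
}
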