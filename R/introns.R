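#' Catalogue introns from gene models
#'
#' Every gap between consecutive exons of a multi-exon gene is one intron.
#' Records carry genomic coordinates (1-based inclusive) plus
#' transcript-orientation quantities: `donor_offset` (number of spliced CDS
#' bases upstream of the intron), `phase` (`donor_offset mod 3`), and donor /
#' acceptor dinucleotides read from the genome in transcript orientation.
#' Gaps under 4 bp are flagged invalid and excluded from distributions.
#'
#' @param genome an `nm_genome`.
#' @param kinds gene kinds scanned.
#' @return a tibble of class `nm_introns`: `gene_id`, `chromosome`, `strand`,
#'   `start`, `end`, `length`, `index` (1 = 5'-most in transcript),
#'   `donor_offset`, `phase`, `donor`, `acceptor`, `valid`.
#' @export
catalog_introns <- function(genome, kinds = c("protein", "orf", "pseudogene")) {
  genes <- filter(genome$genes, .data$kind %in% kinds,
                  map_int(.data$exons, nrow) > 1)
  if (nrow(genes) == 0) return(empty_intron_table())
  recs <- map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    chrom <- chromosome_seq(genome, g$chromosome)
    ex <- g$exons[[1]]
    n_int <- nrow(ex) - 1L
    istart <- ex$end[-nrow(ex)] + 1L
    iend <- ex$start[-1] - 1L
    exlen <- ex$end - ex$start + 1L
    if (g$strand == "+") {
      donor_offset <- cumsum(exlen)[-nrow(ex)]
      idx <- seq_len(n_int)
      donor <- str_sub(chrom, istart, istart + 1L)
      acceptor <- str_sub(chrom, iend - 1L, iend)
    } else {
      donor_offset <- sum(exlen) - cumsum(exlen)[-nrow(ex)]
      idx <- rev(seq_len(n_int))
      donor <- revcomp(str_sub(chrom, iend - 1L, iend))
      acceptor <- revcomp(str_sub(chrom, istart, istart + 1L))
    }
    tibble(gene_id = g$gene_id, chromosome = g$chromosome, strand = g$strand,
           start = istart, end = iend, length = iend - istart + 1L,
           index = idx, donor_offset = as.integer(donor_offset),
           phase = as.integer(donor_offset %% 3L),
           donor = donor, acceptor = acceptor,
           valid = iend - istart + 1L >= 4L)
  })
  out <- arrange(bind_rows(recs), .data$gene_id, .data$index)
  class(out) <- c("nm_introns", class(out))
  out
}

empty_intron_table <- function() {
  out <- tibble(gene_id = character(), chromosome = character(),
                strand = character(), start = integer(), end = integer(),
                length = integer(), index = integer(), donor_offset = integer(),
                phase = integer(), donor = character(), acceptor = character(),
                valid = logical())
  class(out) <- c("nm_introns", class(out))
  out
}

#' Intron size distribution
#'
#' @param records an intron catalogue from [catalog_introns()]; invalid
#'   records are excluded.
#' @return a tibble of class `nm_intron_sizes` with `length`, `n`,
#'   `proportion`; attributes `max_length`, `prop_below_20` (fraction of
#'   introns shorter than 20 nt) and `n_total`.
#' @export
intron_size_distribution <- function(records) {
  records <- filter(records, .data$valid)
  if (nrow(records) == 0) {
    out <- tibble(length = integer(), n = integer(), proportion = double())
    attr(out, "max_length") <- NA_integer_
    attr(out, "prop_below_20") <- NA_real_
    attr(out, "n_total") <- 0L
    class(out) <- c("nm_intron_sizes", class(out))
    return(out)
  }
  out <- records |> count(.data$length) |> mutate(proportion = n / sum(n))
  attr(out, "max_length") <- max(records$length)
  attr(out, "prop_below_20") <- mean(records$length < 20)
  attr(out, "n_total") <- nrow(records)
  class(out) <- c("nm_intron_sizes", class(out))
  out
}

#' Classify splice boundary dinucleotides
#'
#' @param records intron catalogue (invalid records excluded).
#' @return tibble with `boundary` (`GT-AG`, `GC-AG`, `GA-AG`, `other`), `n`,
#'   `proportion`; `attr(, "canonical_fraction")` is the GT-AG fraction.
#' @export
classify_boundaries <- function(records) {
  records <- filter(records, .data$valid)
  cls <- case_when(
    records$donor == "GT" & records$acceptor == "AG" ~ "GT-AG",
    records$donor == "GC" & records$acceptor == "AG" ~ "GC-AG",
    records$donor == "GA" & records$acceptor == "AG" ~ "GA-AG",
    TRUE ~ "other")
  out <- tibble(boundary = factor(cls, levels = c("GT-AG", "GC-AG", "GA-AG", "other"))) |>
    count(.data$boundary, .drop = FALSE) |>
    mutate(boundary = as.character(.data$boundary),
           proportion = if (sum(n) > 0) n / sum(n) else 0)
  attr(out, "canonical_fraction") <-
    if (nrow(records)) out$n[out$boundary == "GT-AG"] / nrow(records) else NA_real_
  out
}

#' Splice-signal base-count matrix
#'
#' Per-position base counts across introns and their exonic flanks, in
#' transcript orientation, keyed by intron length (so positions are
#' comparable within each length class). Exonic positions are labelled
#' `-flank..-1` (upstream) and `+1..+flank` (downstream); intron positions
#' `i1..iL`.
#'
#' @param records intron catalogue.
#' @param genome the `nm_genome` the records refer to.
#' @param exon_flank exonic flank width (bp).
#' @return tibble with `length_class`, `position` (ordered factor), `base`,
#'   `count`, `freq`.
#' @export
splice_signal_matrix <- function(records, genome, exon_flank = 5) {
  records <- filter(records, .data$valid)
  if (nrow(records) == 0) {
    return(tibble(length_class = integer(), position = character(),
                  base = character(), count = integer(), freq = double()))
  }
  rows <- map(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    chrom <- chromosome_seq(genome, r$chromosome)
    if (r$strand == "+") {
      up <- str_sub(chrom, max(1, r$start - exon_flank), r$start - 1)
      intron <- str_sub(chrom, r$start, r$end)
      down <- str_sub(chrom, r$end + 1, min(str_length(chrom), r$end + exon_flank))
    } else {
      up <- revcomp(str_sub(chrom, r$end + 1, min(str_length(chrom), r$end + exon_flank)))
      intron <- revcomp(str_sub(chrom, r$start, r$end))
      down <- revcomp(str_sub(chrom, max(1, r$start - exon_flank), r$start - 1))
    }
    labs <- c(paste0(-(str_length(up):1)),
              paste0("i", seq_len(str_length(intron))),
              paste0("+", seq_len(str_length(down))))
    tibble(length_class = r$length, position = labs,
           base = strsplit(paste0(up, intron, down), "")[[1]])
  })
  bind_rows(rows) |>
    count(.data$length_class, .data$position, .data$base, name = "count") |>
    group_by(.data$length_class, .data$position) |>
    mutate(freq = .data$count / sum(.data$count)) |>
    ungroup()
}

#' Call splice junctions from spliced alignments
#'
#' Reads a SAM/BAM file of spliced alignments (gaps encoded as `N` CIGAR
#' operations), tallies unique gap coordinates, drops junctions below
#' `min_support`, and resolves ambiguously placed gaps (shiftable left/right
#' with identical sequence) to the placement whose boundary dinucleotides are
#' in `require_boundary`, else leftmost.
#'
#' @param sam_path path to a SAM (or BAM) file.
#' @param genome the reference `nm_genome`.
#' @param min_support minimum number of supporting reads.
#' @param require_boundary character vector of preferred boundary classes,
#'   e.g. `c("GT-AG", "GC-AG", "GA-AG")`; `NULL` for plain leftmost.
#' @return tibble with `chromosome`, `start`, `end` (intron coordinates,
#'   1-based inclusive), `length`, `support`, `donor`, `acceptor` (forward
#'   strand as read).
#' @export
call_junctions <- function(sam_path, genome, min_support = 1,
                           require_boundary = c("GT-AG", "GC-AG", "GA-AG")) {
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(sam_path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  aln <- GenomicAlignments::readGAlignments(bam)
  jx <- unlist(GenomicAlignments::junctions(aln))
  if (length(jx) == 0) {
    return(tibble(chromosome = character(), start = integer(), end = integer(),
                  length = integer(), support = integer(),
                  donor = character(), acceptor = character()))
  }
  tab <- tibble(chromosome = as.character(GenomicRanges::seqnames(jx)),
                start = GenomicRanges::start(jx),
                end = GenomicRanges::end(jx)) |>
    count(.data$chromosome, .data$start, .data$end, name = "support") |>
    filter(.data$support >= min_support)
  if (nrow(tab) == 0) {
    return(tibble(chromosome = character(), start = integer(), end = integer(),
                  length = integer(), support = integer(),
                  donor = character(), acceptor = character()))
  }
  shifted <- map(seq_len(nrow(tab)), function(i) {
    shift_junction(genome, tab$chromosome[i], tab$start[i], tab$end[i],
                   require_boundary)
  })
  tab$start <- map_int(shifted, "start")
  tab$end <- map_int(shifted, "end")
  tab <- tab |>
    group_by(.data$chromosome, .data$start, .data$end) |>
    summarise(support = sum(.data$support), .groups = "drop")
  chromseq <- stats::setNames(genome$chromosomes$sequence, genome$chromosomes$name)
  tab |>
    mutate(length = .data$end - .data$start + 1L,
           donor = str_sub(chromseq[.data$chromosome], .data$start, .data$start + 1L),
           acceptor = str_sub(chromseq[.data$chromosome], .data$end - 1L, .data$end)) |>
    arrange(.data$chromosome, .data$start)
}

# slide a gap over equivalent placements; prefer a boundary in `prefer`
shift_junction <- function(genome, chrom, start, end, prefer) {
  seq <- chromosome_seq(genome, chrom)
  n <- str_length(seq)
  cand <- list(c(start, end))
  s <- start; e <- end
  while (s > 1 && str_sub(seq, s - 1, s - 1) == str_sub(seq, e, e)) {
    s <- s - 1L; e <- e - 1L
    cand[[length(cand) + 1]] <- c(s, e)
  }
  s <- start; e <- end
  while (e < n && str_sub(seq, s, s) == str_sub(seq, e + 1, e + 1)) {
    s <- s + 1L; e <- e + 1L
    cand[[length(cand) + 1]] <- c(s, e)
  }
  cand <- cand[order(map_dbl(cand, 1))]
  if (!is.null(prefer)) {
    # boundaries may come from either strand: check the forward reading and
    # the reverse-complement (transcript) reading of each placement
    hit <- which(map_lgl(cand, function(p) {
      fwd <- paste0(str_sub(seq, p[1], p[1] + 1), "-", str_sub(seq, p[2] - 1, p[2]))
      rev <- paste0(revcomp(str_sub(seq, p[2] - 1, p[2])), "-",
                    revcomp(str_sub(seq, p[1], p[1] + 1)))
      any(c(fwd, rev) %in% prefer)
    }))
    if (length(hit)) cand <- cand[hit]
  }
  list(start = as.integer(cand[[1]][1]), end = as.integer(cand[[1]][2]))
}
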