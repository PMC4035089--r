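# chromosome assembly for the synthetic generator: sub-telomeric repeat
# copies at both ends, boundary tandem arrays, internal genes with geometric
# spacers, and the per-feature truth record

assemble_genome <- function(label, unit_lists, cfg, spacer_mean,
                            fam_category = NULL) {
  n_chr <- length(unit_lists)
  S <- cfg$subtel_length
  sampler_sub <- codon_sampler(cfg$subtel_gc)

  # --- sub-telomeric master with embedded ORFs and an rRNA placeholder ---
  # non-genic filler has exact compensating composition so the whole master
  # hits subtel_gc to rounding precision
  orf_len <- 3L * cfg$orf_codons
  starts <- 150L + (seq_len(cfg$orfs_per_repeat) - 1L) * (orf_len + 120L)
  if (cfg$orfs_per_repeat > 0 &&
      (utils::tail(starts, 1) + orf_len + 120L + 300L + 50L) > S) {
    abort("packing infeasible: sub-telomeric ORFs exceed subtel_length budget")
  }
  master <- character(S)
  master_genes <- list()
  for (j in seq_len(cfg$orfs_per_repeat)) {
    cds <- sample_cds(cfg$orf_codons, sampler_sub)
    master[starts[j]:(starts[j] + orf_len - 1L)] <- strsplit(cds, "")[[1]]
    master_genes[[j]] <- tibble(local_start = starts[j],
                                local_end = starts[j] + orf_len - 1L,
                                strand = "+", kind = "orf",
                                family_id = sprintf("%s_sub%02d", label, j))
  }
  filled <- nzchar(master)
  n_free <- sum(!filled)
  gc_have <- sum(master[filled] %in% c("G", "C"))
  gc_need <- max(0L, min(n_free, round(cfg$subtel_gc * S) - gc_have))
  n_g <- gc_need %/% 2L
  n_a <- (n_free - gc_need) %/% 2L
  filler <- sample(c(rep("G", n_g), rep("C", gc_need - n_g),
                     rep("A", n_a), rep("T", n_free - gc_need - n_a)))
  master[!filled] <- filler
  rrna <- tibble(local_start = S - 349L, local_end = S - 50L, strand = "+",
                 kind = "rRNA", family_id = NA_character_)
  master_genes <- bind_rows(c(master_genes, list(rrna)))
  genic <- unlist(map2(master_genes$local_start, master_genes$local_end, seq))
  nongenic <- setdiff(seq_len(S), genic)

  # distribute the configured total substitutions over the 2*n_chr copies
  copies <- rep(list(master), 2L * n_chr)
  if (cfg$subtel_mismatches > 0) {
    picks <- tibble(copy = sample(2L * n_chr, cfg$subtel_mismatches, replace = TRUE),
                    pos = sample(nongenic, cfg$subtel_mismatches))
    for (k in seq_len(nrow(picks))) {
      old <- copies[[picks$copy[k]]][picks$pos[k]]
      copies[[picks$copy[k]]][picks$pos[k]] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }

  chrom_names <- paste0("chr", seq_len(n_chr))
  chrom_seqs <- character(n_chr)
  genes_out <- list()
  repeat_truth <- list()
  array_truth <- list()
  intron_truth <- list()
  expr_truth <- list()
  sub_fam_rows <- list()
  gid <- 0L
  next_id <- function() { gid <<- gid + 1L; sprintf("%s_g%03d", label, gid) }

  for (c in seq_len(n_chr)) {
    chrom <- chrom_names[c]
    left <- paste(copies[[2L * c - 1L]], collapse = "")
    right_master <- paste(copies[[2L * c]], collapse = "")
    right <- revcomp(right_master)
    arr <- map(1:2, function(side) {
      k <- sample(seq(cfg$boundary_copies_range[1], cfg$boundary_copies_range[2]), 1)
      list(k = k,
           seq = paste(map_chr(seq_len(k), ~ resolve_iupac(cfg$boundary_unit)),
                       collapse = ""))
    })

    # internal units: proteins in planted order, tRNAs interleaved at random
    units <- unit_lists[[c]]
    prot_units <- map(units, function(u) {
      u$strand <- sample(c("+", "-"), 1)
      u$body <- build_gene_body(u$cds, u$spec, u$strand)
      u
    })
    trna_units <- map(seq_len(cfg$trnas_per_chromosome), function(t) {
      list(fam = NA_character_, kind = "tRNA", strand = sample(c("+", "-"), 1),
           body = list(body = random_dna(72L, cfg$internal_gc),
                       exons = tibble(start = 1L, end = 72L),
                       introns = tibble(), length = 72L))
    })
    n_slots <- length(prot_units) + length(trna_units)
    slot_is_trna <- rep(FALSE, n_slots)
    if (length(trna_units)) slot_is_trna[sample(n_slots, length(trna_units))] <- TRUE
    slots <- vector("list", n_slots)
    slots[slot_is_trna] <- trna_units
    slots[!slot_is_trna] <- prot_units

    spacers <- if (n_slots > 1) {
      stats::rgeom(n_slots - 1L, 1 / (spacer_mean + 1))
    } else integer()
    body_lens <- map_int(slots, ~ as.integer(.x$body$length))
    internal_space <- cfg$chromosome_length - 2L * S -
      str_length(arr[[1]]$seq) - str_length(arr[[2]]$seq)
    rem <- internal_space - sum(body_lens) - sum(spacers)
    if (rem < 2) {
      abort(paste0("packing infeasible on ", chrom, ": genes (", sum(body_lens),
                   " bp) + spacers (", sum(spacers), " bp) exceed internal space (",
                   internal_space, " bp)"))
    }
    pad_l <- rem %/% 2L
    pad_r <- rem - pad_l

    pieces <- c(left, arr[[1]]$seq, random_dna(pad_l, cfg$internal_gc))
    offset <- S + str_length(arr[[1]]$seq) + pad_l
    for (s in seq_len(n_slots)) {
      u <- slots[[s]]
      id <- next_id()
      body <- u$body
      kind <- u$kind %||% "protein"
      genes_out[[length(genes_out) + 1]] <- tibble(
        gene_id = id, chromosome = chrom, strand = u$strand,
        kind = kind,
        category = if (!is.null(u$fam) && !is.na(u$fam) && !is.null(fam_category))
          fam_category[[u$fam]] %||% "unassigned" else "unassigned",
        family_id = u$fam %||% NA_character_,
        product = NA_character_,
        exons = list(tibble(start = body$exons$start + offset,
                            end = body$exons$end + offset)))
      if (nrow(body$introns)) {
        intron_truth[[length(intron_truth) + 1]] <- tibble(
          genome = label, gene_id = id, family_id = u$fam, chromosome = chrom,
          strand = u$strand,
          start = body$introns$local_start + offset,
          end = body$introns$local_end + offset,
          length = body$introns$length,
          codon = body$introns$codon,
          donor_offset = body$introns$donor_offset,
          phase = body$introns$phase,
          donor = body$introns$donor, acceptor = body$introns$acceptor)
      }
      expr_truth[[length(expr_truth) + 1]] <- tibble(
        genome = label, gene_id = id, class = "internal")
      pieces <- c(pieces, body$body)
      offset <- offset + body$length
      if (s < n_slots) {
        pieces <- c(pieces, random_dna(spacers[s], cfg$internal_gc))
        offset <- offset + spacers[s]
      }
    }
    pieces <- c(pieces, random_dna(pad_r, cfg$internal_gc), arr[[2]]$seq, right)
    chrom_seqs[c] <- paste(pieces, collapse = "")
    L <- str_length(chrom_seqs[c])
    stopifnot(L == cfg$chromosome_length)

    # sub-telomeric gene copies (left: as master; right: mirrored)
    for (side in c("left", "right")) {
      for (j in seq_len(nrow(master_genes))) {
        mg <- master_genes[j, ]
        id <- next_id()
        if (side == "left") {
          gs <- mg$local_start; ge <- mg$local_end; st <- mg$strand
        } else {
          off_r <- L - S
          gs <- off_r + (S - mg$local_end + 1L)
          ge <- off_r + (S - mg$local_start + 1L)
          st <- if (mg$strand == "+") "-" else "+"
        }
        genes_out[[length(genes_out) + 1]] <- tibble(
          gene_id = id, chromosome = chrom, strand = st, kind = mg$kind,
          category = if (mg$kind == "orf") "nORFan" else "unassigned",
          family_id = mg$family_id, product = NA_character_,
          exons = list(tibble(start = as.integer(gs), end = as.integer(ge))))
        expr_truth[[length(expr_truth) + 1]] <- tibble(
          genome = label, gene_id = id, class = "subtelomeric")
        if (!is.na(mg$family_id)) {
          sub_fam_rows[[length(sub_fam_rows) + 1]] <- tibble(
            family_id = mg$family_id, genome = label, gene_id = id)
        }
      }
      repeat_truth[[length(repeat_truth) + 1]] <- tibble(
        genome = label, chromosome = chrom, end = side,
        start = if (side == "left") 1L else as.integer(L - S + 1L),
        stop = if (side == "left") as.integer(S) else as.integer(L))
      a <- arr[[if (side == "left") 1 else 2]]
      astart <- if (side == "left") S + 1L else
        as.integer(L - S - str_length(arr[[2]]$seq) + 1L)
      array_truth[[length(array_truth) + 1]] <- tibble(
        genome = label, chromosome = chrom, side = side,
        start = as.integer(astart),
        end = as.integer(astart + str_length(a$seq) - 1L),
        n_copies = a$k, unit_length = str_length(cfg$boundary_unit),
        consensus = cfg$boundary_unit)
    }
  }

  genome <- nm_genome(label,
                      tibble(name = chrom_names, sequence = chrom_seqs,
                             topology = "linear"),
                      bind_rows(genes_out), min_orf_codons = NULL)
  list(genome = genome,
       repeat_truth = bind_rows(repeat_truth),
       array_truth = bind_rows(array_truth),
       intron_truth = if (length(intron_truth)) bind_rows(intron_truth) else
         tibble(genome = character(), gene_id = character(), family_id = character(),
                chromosome = character(), strand = character(), start = integer(),
                end = integer(), length = integer(), codon = integer(),
                donor_offset = integer(), phase = integer(), donor = character(),
                acceptor = character()),
       expr_truth = bind_rows(expr_truth),
       subtel_families = if (length(sub_fam_rows)) bind_rows(sub_fam_rows) else
         tibble(family_id = character(), genome = character(), gene_id = character()))
}

#' Simulate a per-base coverage track
#'
#' Per-base depths are drawn independently (Poisson) with mean
#' `internal_depth` over internal-class genes,
#' `internal_depth / expression_ratio` over sub-telomeric-class genes, and
#' `intergenic_depth` elsewhere; the truth's collapsed multicopy region (if
#' any, for this genome) has its mean multiplied by its copy number, which is
#' what a repeat collapsed onto a single reference copy does to mapped depth.
#'
#' @param genome an `nm_genome` from [simulate_genome_pair()].
#' @param truth the simulation's `truth` element.
#' @param config the generator config.
#' @param seed integer seed.
#' @return an [coverage_track()] object.
#' @export
simulate_coverage <- function(genome, truth, config, seed = 1) {
  set.seed(substream_seed(seed, paste0("coverage-", genome$label)))
  cls <- filter(truth$expression, .data$genome == !!genome$label)
  cls_by_gene <- stats::setNames(cls$class, cls$gene_id)
  out <- list()
  for (i in seq_len(nrow(genome$chromosomes))) {
    chrom <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    mu <- rep(config$intergenic_depth, len)
    gg <- filter(genome$genes, .data$chromosome == chrom)
    for (k in seq_len(nrow(gg))) {
      cl <- cls_by_gene[[gg$gene_id[k]]] %||% "internal"
      m <- if (cl == "subtelomeric") {
        config$internal_depth / config$expression_ratio
      } else config$internal_depth
      mu[gg$start[k]:gg$end[k]] <- m
    }
    if (!is.null(truth$collapsed) &&
        nrow(truth$collapsed) > 0 &&
        truth$collapsed$genome[1] == genome$label &&
        truth$collapsed$chromosome[1] == chrom) {
      idx <- truth$collapsed$start[1]:truth$collapsed$end[1]
      mu[idx] <- mu[idx] * truth$collapsed$copy_number[1]
    }
    out[[chrom]] <- stats::rpois(len, mu)
  }
  coverage_track(out)
}

#' Simulate spliced-junction alignment records
#'
#' For every truth intron of the genome, emits `reads_per_junction` gapped
#' alignment records whose gap (`N` CIGAR operation) spans the intron
#' exactly, with jittered exonic flanks; read sequences are copied from the
#' reference (exonic parts only).
#'
#' @inheritParams simulate_coverage
#' @param reads_per_junction records per intron.
#' @return tibble of SAM fields (`qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`); write with [write_sam()].
#' @export
simulate_junction_reads <- function(genome, truth, config, reads_per_junction = 5,
                                    seed = 1) {
  set.seed(substream_seed(seed, paste0("junctions-", genome$label)))
  introns <- filter(truth$introns, .data$genome == !!genome$label)
  if (nrow(introns) == 0) {
    return(tibble(qname = character(), flag = integer(), rname = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  seq = character()))
  }
  flank <- config$read_flank
  chrom_len <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  rows <- list()
  for (i in seq_len(nrow(introns))) {
    r <- introns[i, ]
    chromseq <- chromosome_seq(genome, r$chromosome)
    for (k in seq_len(reads_per_junction)) {
      lf <- flank + sample(0:5, 1)
      rf <- flank + sample(0:5, 1)
      lf <- min(lf, r$start - 1L)
      rf <- min(rf, chrom_len[[r$chromosome]] - r$end)
      pos <- r$start - lf
      rows[[length(rows) + 1]] <- tibble(
        qname = sprintf("read_%s_%d_%d", r$gene_id, i, k),
        flag = 0L, rname = r$chromosome, pos = as.integer(pos), mapq = 60L,
        cigar = sprintf("%dM%dN%dM", lf, r$length, rf),
        seq = paste0(str_sub(chromseq, pos, r$start - 1L),
                     str_sub(chromseq, r$end + 1L, r$end + rf)))
    }
  }
  bind_rows(rows)
}

#' Write spliced-alignment records as SAM
#'
#' Minimal valid SAM: `@HD`/`@SQ` header plus one line per record with `*`
#' quality and unset mate fields.
#'
#' @param reads tibble from [simulate_junction_reads()].
#' @param genome the reference genome (for `@SQ` lines).
#' @param path output path ending in `.sam`.
#' @export
write_sam <- function(reads, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$chromosomes$name,
                      genome$chromosomes$length))
  body <- if (nrow(reads)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
            reads$cigar, reads$seq)
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}
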