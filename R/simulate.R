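#' Generator configuration for synthetic genome pairs
#'
#' Defaults encode the structure the comparative analysis assumes: three
#' linear chromosomes, near-identical high-GC sub-telomeric repeats on all
#' six ends differing by `subtel_mismatches` substitutions in total, a
#' degenerate 36-nt boundary tandem array at 5-29 copies inside each end,
#' low-GC internal regions with geometric intergenic spacers, tiny GT-AG
#' introns (18-23 nt, 19 nt modal, 58.3% phase 0, two GC-AG and one GA-AG
#' planted, one 32-nt longest intron), multicopy sub-telomeric ORF families,
#' planted synteny blocks shared with the partner genome, and a 2,500-fold
#' expression contrast between internal and sub-telomeric genes.
#'
#' The `"desk"` preset scales chromosome and repeat lengths down tenfold for
#' fast iteration; `"full"` uses genome-scale lengths (~200 kbp chromosomes,
#' ~35 kbp repeats).
#'
#' @param preset `"desk"` or `"full"`.
#' @param ... any config field to override (see Details/source for the full
#'   list).
#' @return a validated list of class `nm_generator_config`.
#' @export
generator_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_chromosomes = 3L,
    chromosome_length = 20000L,
    subtel_length = 3500L,
    subtel_gc = 0.494,
    internal_gc = 0.24,
    subtel_mismatches = 3L,
    boundary_unit = "RTAYCTRGTTRCCTTATCGTATGCCATGGCTTTATC",
    boundary_copies_range = c(5L, 29L),
    orfs_per_repeat = 8L,
    orf_codons = 70L,
    genes_per_chromosome = 13L,
    trnas_per_chromosome = 2L,
    mean_protein_length = 120,
    mean_spacer = 147.4,
    mean_spacer_b = 82.1,
    introns_per_gene = 1.7,
    intron_length_distribution = c(`18` = 0.076, `19` = 0.491, `20` = 0.15,
                                   `21` = 0.12, `22` = 0.09, `23` = 0.073),
    fraction_phase0 = 0.583,
    noncanonical = c(`GC-AG` = 2L, `GA-AG` = 1L),
    longest_intron = 32L,
    acceptor_a_bias = 0.7,
    intron_gc = 0.15,
    shared_fraction = 0.9,
    shared_intron_fraction = 0.9,
    unique_introns_b = 0.3,
    protein_divergence = 0.15,
    synteny_block_sizes = c(4L, 4L, 5L, 5L, 6L, 7L),
    invert_fraction = 0.25,
    category_probs = c(`eukaryotic-conserved` = 0.6, `plastid-associated` = 0.15,
                       spliceosomal = 0.05, nORFan = 0.1, other = 0.1),
    collapsed_copy_number = 5,
    expression_ratio = 2500,
    internal_depth = 100,
    intergenic_depth = 1,
    read_flank = 20L)
  if (preset == "full") {
    cfg$chromosome_length <- 200000L
    cfg$subtel_length <- 35000L
    cfg$genes_per_chromosome <- 60L
    cfg$mean_protein_length <- 247
    cfg$orfs_per_repeat <- 40L
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort(paste0("unknown config field: ", unknown[1]))
  cfg[names(over)] <- over
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  p <- cfg$intron_length_distribution
  if (length(p) > 0 && abs(sum(p) - 1) > 1e-8) {
    abort("intron_length_distribution probabilities must sum to 1")
  }
  if (abs(sum(cfg$category_probs) - 1) > 1e-8) {
    abort("category_probs must sum to 1")
  }
  if (2 * cfg$subtel_length >= cfg$chromosome_length) {
    abort("need 2 * subtel_length < chromosome_length")
  }
  fracs <- c(cfg$subtel_gc, cfg$internal_gc, cfg$fraction_phase0,
             cfg$shared_fraction, cfg$shared_intron_fraction,
             cfg$acceptor_a_bias, cfg$intron_gc)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must be in [0, 1]")
  structure(cfg, class = "nm_generator_config")
}

#' @rdname generator_config
#' @param path YAML file path.
#' @export
write_generator_config <- function(cfg, path) {
  out <- unclass(cfg)
  for (nm in c("intron_length_distribution", "noncanonical", "category_probs")) {
    if (!is.null(out[[nm]])) out[[nm]] <- as.list(out[[nm]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname generator_config
#' @param cfg a generator config.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("intron_length_distribution", "noncanonical", "category_probs")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(generator_config, c(list(preset = "desk"), raw))
}

# ---- sequence building helpers ----

codon_sampler <- function(gc) {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  gc_count <- map_dbl(codons, ~ sum(strsplit(.x, "")[[1]] %in% c("G", "C")))
  weights_for <- function(g) {
    bases <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    w <- map_dbl(codons, ~ prod(bases[strsplit(.x, "")[[1]]]))
    w / sum(w)
  }
  # excluding stop codons shifts the marginal GC upward; calibrate the base
  # composition so sampled codons hit the requested GC in expectation
  marginal <- function(g) sum(weights_for(g) * gc_count) / 3 - gc
  g_adj <- tryCatch(stats::uniroot(marginal, c(0.005, 0.995))$root,
                    error = function(e) gc)
  list(codons = codons, weights = weights_for(g_adj))
}

sample_cds <- function(n_codons, sampler) {
  body <- sample(sampler$codons, n_codons - 2L, replace = TRUE,
                 prob = sampler$weights)
  paste0("ATG", paste(body, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

# codon choices per amino acid, weighted by base composition
aa_codon_table <- function(gc) {
  bases <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  code <- Biostrings::GENETIC_CODE
  aas <- unique(code)
  out <- list()
  for (aa in aas) {
    cds <- names(code)[code == aa]
    w <- map_dbl(cds, ~ prod(bases[strsplit(.x, "")[[1]]]))
    out[[aa]] <- list(codons = cds, weights = w / sum(w))
  }
  out
}

back_translate <- function(protein, table) {
  aa <- strsplit(protein, "")[[1]]
  codons <- map_chr(aa, function(a) {
    t <- table[[a]]
    if (length(t$codons) == 1) t$codons else
      sample(t$codons, 1, prob = t$weights)
  })
  paste(codons, collapse = "")
}

resolve_iupac <- function(unit) {
  chars <- strsplit(str_to_upper(unit), "")[[1]]
  paste(map_chr(chars, function(ch) {
    opts <- iupac_expand(ch)
    if (length(opts) == 1) opts else sample(opts, 1)
  }), collapse = "")
}

# assemble one gene: CDS + introns -> genomic-forward pieces
build_gene_body <- function(cds, introns, strand) {
  # introns: tibble(donor_offset, length, donor, acceptor, seq)
  n <- str_length(cds)
  if (nrow(introns) == 0) {
    segs <- cds
    ex_tx <- tibble(start = 1L, end = n)
  } else {
    introns <- arrange(introns, .data$donor_offset)
    cuts <- c(0L, introns$donor_offset, n)
    ex_seq <- map_chr(seq_len(length(cuts) - 1),
                      ~ str_sub(cds, cuts[.x] + 1L, cuts[.x + 1]))
    segs <- character(0)
    for (i in seq_along(ex_seq)) {
      segs <- c(segs, ex_seq[i])
      if (i <= nrow(introns)) segs <- c(segs, introns$seq[i])
    }
    lens <- str_length(segs)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    is_exon <- seq_along(segs) %% 2L == 1L
    ex_tx <- tibble(start = starts[is_exon], end = ends[is_exon])
    intron_tx <- tibble(start = starts[!is_exon], end = ends[!is_exon])
  }
  body_tx <- paste(segs, collapse = "")
  L <- str_length(body_tx)
  if (strand == "+") {
    body <- body_tx
    exons <- ex_tx
    intron_local <- if (nrow(introns)) {
      mutate(introns, local_start = intron_tx$start, local_end = intron_tx$end)
    } else introns
  } else {
    body <- revcomp(body_tx)
    exons <- tibble(start = L - ex_tx$end + 1L, end = L - ex_tx$start + 1L) |>
      arrange(.data$start)
    intron_local <- if (nrow(introns)) {
      mutate(introns, local_start = L - intron_tx$end + 1L,
             local_end = L - intron_tx$start + 1L)
    } else introns
  }
  list(body = body, exons = exons, introns = intron_local, length = L)
}

sample_intron_spec <- function(n, cfg, min_codon, max_codon) {
  if (n == 0 || max_codon - min_codon + 1 < n) {
    return(tibble(codon = integer(), phase = integer(), donor_offset = integer(),
                  length = integer(), donor = character(), acceptor = character(),
                  seq = character()))
  }
  codons <- sort(sample(seq(min_codon, max_codon), n))
  phase <- ifelse(stats::runif(n) < cfg$fraction_phase0, 0L,
                  sample(1:2, n, replace = TRUE))
  d <- ifelse(phase == 0L, 3L * codons, 3L * (codons - 1L) + phase)
  lens <- as.integer(sample(as.integer(names(cfg$intron_length_distribution)),
                            n, replace = TRUE,
                            prob = cfg$intron_length_distribution))
  out <- tibble(codon = codons, phase = as.integer(phase),
                donor_offset = as.integer(d), length = lens,
                donor = "GT", acceptor = "AG",
                seq = map_chr(lens, ~ paste0("GT", random_dna(max(.x - 4L, 0L),
                                                              cfg$intron_gc), "AG")))
  filter(out, .data$length >= 4L)   # sub-minimal lengths mean "no intron"
}
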