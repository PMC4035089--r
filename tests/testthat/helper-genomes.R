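# small genome builders and a cached default simulation (seed 42 throughout)

TEST_SEED <- 42L

make_gene <- function(id, chromosome, exon_starts, exon_ends, strand = "+",
                      kind = "protein", category = "unassigned",
                      family_id = NA_character_) {
  tibble::tibble(gene_id = id, chromosome = chromosome, strand = strand,
                 kind = kind, category = category, family_id = family_id,
                 product = NA_character_,
                 exons = list(tibble::tibble(start = as.integer(exon_starts),
                                             end = as.integer(exon_ends))))
}

make_genome <- function(seqs, genes = NULL, label = "toy", ...) {
  nm_genome(label,
            tibble::tibble(name = names(seqs), sequence = unname(seqs),
                           topology = "linear"),
            genes, ...)
}

# deterministic random DNA for fixtures
fixture_dna <- function(n, seed, gc = 0.5) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}

.sim_cache <- new.env(parent = emptyenv())

# default desk-scale simulation, generated once per test run
desk_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_genome_pair(generator_config(), seed = TEST_SEED)
  }
  .sim_cache$sim
}

truth_regions <- function(sim, label, what = c("repeats", "arrays")) {
  out <- list()
  if ("repeats" %in% what) {
    r <- dplyr::filter(sim$truth$repeats, genome == label)
    out$rep <- tibble::tibble(chromosome = r$chromosome, start = r$start, end = r$stop)
  }
  if ("arrays" %in% what) {
    a <- dplyr::filter(sim$truth$arrays, genome == label)
    out$arr <- tibble::tibble(chromosome = a$chromosome, start = a$start, end = a$end)
  }
  dplyr::bind_rows(out)
}

# a two-ortholog pair sharing a phase-0 intron after a given codon
ortholog_pair_with_intron <- function(n_codons = 60, intron_codon = 20,
                                      shared = TRUE, seed = 7) {
  withr::with_seed(seed, {
    sampler_codons <- setdiff(names(Biostrings::GENETIC_CODE),
                              c("TAA", "TAG", "TGA"))
    cds <- paste0("ATG", paste(sample(sampler_codons, n_codons - 2, TRUE),
                               collapse = ""), "TAA")
    intron <- paste0("GT", fixture_dna(15, seed + 1, gc = 0.2), "AG")
    d <- 3L * intron_codon
    gene_seq_a <- paste0(substr(cds, 1, d), intron, substr(cds, d + 1, nchar(cds)))
    pad <- function(s) paste0(fixture_dna(30, seed + 2), s, fixture_dna(30, seed + 3))
    chrom_a <- pad(gene_seq_a)
    exons_a <- list(starts = c(31, 31 + d + nchar(intron)),
                    ends = c(30 + d, 30 + nchar(gene_seq_a)))
    ga <- make_genome(c(chr1 = chrom_a),
                      make_gene("A1", "chr1", exons_a$starts, exons_a$ends,
                                family_id = "fam1"),
                      label = "gA")
    if (shared) {
      chrom_b <- pad(gene_seq_a)
      gb <- make_genome(c(chr1 = chrom_b),
                        make_gene("B1", "chr1", exons_a$starts, exons_a$ends,
                                  family_id = "fam1"),
                        label = "gB")
    } else {
      chrom_b <- pad(cds)
      gb <- make_genome(c(chr1 = chrom_b),
                        make_gene("B1", "chr1", 31, 30 + nchar(cds),
                                  family_id = "fam1"),
                        label = "gB")
    }
    fams <- tibble::tibble(family_id = "fam1", category = "eukaryotic-conserved",
                           genome = c("gA", "gB"), gene_id = c("A1", "B1"))
    list(a = ga, b = gb, families = fams)
  })
}

# family-table fixture with a given shared / private structure
toy_families <- function(n_shared, n_only_a, n_only_b,
                         category = "eukaryotic-conserved") {
  mk <- function(ids, genomes) {
    dplyr::bind_rows(lapply(genomes, function(g) {
      tibble::tibble(family_id = ids, category = category, genome = g,
                     gene_id = paste0(g, "_", ids))
    }))
  }
  dplyr::bind_rows(
    mk(sprintf("s%03d", seq_len(n_shared)), c("A", "B")),
    if (n_only_a > 0) mk(sprintf("a%03d", seq_len(n_only_a)), "A"),
    if (n_only_b > 0) mk(sprintf("b%03d", seq_len(n_only_b)), "B"))
}

# a bare gene order from a family vector
order_from_families <- function(fams, chrom = "chr1", genome_tag = "x") {
  out <- tibble::tibble(chromosome = chrom, position = seq_along(fams),
                        family_id = fams, strand = "+",
                        gene_id = paste0(genome_tag, seq_along(fams)))
  class(out) <- c("nm_gene_order", class(out))
  out
}
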