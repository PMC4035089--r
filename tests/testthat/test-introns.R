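test_that("single-exon genomes have no introns", {
  g <- make_genome(c(chr1 = fixture_dna(300, 61)),
                   make_gene("g1", "chr1", 1, 90), min_orf_codons = NULL)
  expect_equal(nrow(catalog_introns(g)), 0)
})

test_that("the catalogue recovers the planted intron truth exactly", {
  sim <- desk_sim()
  for (gn in list(sim$genome_a, sim$genome_b)) {
    got <- catalog_introns(gn)
    truth <- dplyr::filter(sim$truth$introns, genome == gn$label)
    expect_equal(nrow(got), nrow(truth))
    j <- dplyr::inner_join(
      dplyr::select(got, gene_id, start, end, phase, donor_offset, donor, acceptor),
      dplyr::select(truth, gene_id, start, end, phase, donor_offset, donor, acceptor),
      by = c("gene_id", "start", "end"))
    expect_equal(nrow(j), nrow(truth))
    expect_equal(j$phase.x, j$phase.y)
    expect_equal(j$donor_offset.x, j$donor_offset.y)
    expect_equal(j$donor.x, j$donor.y)
    expect_equal(j$acceptor.x, j$acceptor.y)
  }
})

test_that("the planted longest intron dominates the size summary", {
  sim <- desk_sim()
  sizes <- intron_size_distribution(catalog_introns(sim$genome_a))
  expect_equal(attr(sizes, "max_length"), sim$config$longest_intron)
  expect_equal(sum(sizes$proportion), 1)
  expect_equal(sum(sizes$n), attr(sizes, "n_total"))
})

test_that("size distribution arithmetic matches reported proportions", {
  # a catalogue with 496 introns of 19 nt among 1,011 total
  lens <- c(rep(19L, 496), rep(18L, 77), rep(20L, 180), rep(21L, 130),
            rep(22L, 80), rep(23L, 47), 32L)
  stopifnot(length(lens) == 1011)
  recs <- tibble::tibble(length = lens, valid = TRUE)
  dist <- intron_size_distribution(recs)
  expect_equal(round(100 * dist$proportion[dist$length == 19], 1), 49.1)
  expect_equal(attr(dist, "max_length"), 32L)
  empty <- intron_size_distribution(tibble::tibble(length = integer(),
                                                   valid = logical()))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_total"), 0L)
})

test_that("boundary classification finds the planted non-canonical introns", {
  sim <- desk_sim()
  cat_a <- catalog_introns(sim$genome_a)
  cls <- classify_boundaries(cat_a)
  expect_equal(cls$n[cls$boundary == "GC-AG"],
               unname(sim$config$noncanonical[["GC-AG"]]))
  expect_equal(cls$n[cls$boundary == "GA-AG"],
               unname(sim$config$noncanonical[["GA-AG"]]))
  expect_equal(cls$n[cls$boundary == "other"], 0L)
  expect_equal(sum(cls$n), nrow(cat_a))
  # dinucleotides equal direct re-reads of the genome sequence
  seqs <- stats::setNames(sim$genome_a$chromosomes$sequence,
                          sim$genome_a$chromosomes$name)
  for (i in seq_len(nrow(cat_a))) {
    r <- cat_a[i, ]
    fwd_d <- unname(substr(seqs[r$chromosome], r$start, r$start + 1))
    fwd_a <- unname(substr(seqs[r$chromosome], r$end - 1, r$end))
    if (r$strand == "+") {
      expect_equal(r$donor, fwd_d); expect_equal(r$acceptor, fwd_a)
    } else {
      expect_equal(r$donor,
                   as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd_a))))
      expect_equal(r$acceptor,
                   as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd_d))))
    }
  }
  # all-canonical configuration
  cfg <- generator_config(noncanonical = NULL, longest_intron = NULL)
  sim2 <- simulate_genome_pair(cfg, seed = 5)
  cls2 <- classify_boundaries(catalog_introns(sim2$genome_a))
  expect_equal(sum(cls2$n[cls2$boundary != "GT-AG"]), 0L)
  expect_equal(attr(cls2, "canonical_fraction"), 1)
})

test_that("splice-signal matrices conserve counts and show the planted A bias", {
  g <- make_genome(c(chr1 = paste0(
    "ATGGCTGCA", "GTAAATTTTTTTTTTTAG", "GCTGCTTAA", fixture_dna(30, 62))),
    make_gene("g1", "chr1", c(1, 28), c(9, 36)), min_orf_codons = NULL)
  recs <- catalog_introns(g)
  mat <- splice_signal_matrix(recs, g, exon_flank = 3)
  # one intron: every occupied column is one-hot
  expect_true(all(mat$count == 1))
  expect_true(all(mat$freq == 1))
  sim <- desk_sim()
  cat_a <- catalog_introns(sim$genome_a)
  m <- splice_signal_matrix(cat_a, sim$genome_a, exon_flank = 5)
  sums <- m |> dplyr::group_by(length_class, position) |>
    dplyr::summarise(total = sum(count), .groups = "drop")
  per_class <- dplyr::count(dplyr::filter(cat_a, valid), length, name = "n_introns")
  j <- dplyr::inner_join(sums, per_class, by = c(length_class = "length"))
  expect_true(all(j$total == j$n_introns))
  # planted exonic A bias at position -2
  minus2 <- m |> dplyr::filter(position == "-2") |>
    dplyr::group_by(base) |> dplyr::summarise(n = sum(count))
  expect_equal(minus2$base[which.max(minus2$n)], "A")
})

test_that("junction calling recovers planted truth and honors support", {
  sim <- desk_sim()
  reads <- simulate_junction_reads(sim$genome_a, sim$truth, sim$config,
                                   reads_per_junction = 5, seed = 71)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, sim$genome_a, sam)
  truth <- dplyr::filter(sim$truth$introns, genome == sim$genome_a$label)
  called <- call_junctions(sam, sim$genome_a, min_support = 2)
  expect_setequal(paste(called$chromosome, called$start, called$end),
                  paste(truth$chromosome, truth$start, truth$end))
  expect_true(all(called$support == 5))
  # at min_support 1 on perfect evidence the call set is still the truth set
  called1 <- call_junctions(sam, sim$genome_a, min_support = 1)
  expect_setequal(paste(called1$chromosome, called1$start, called1$end),
                  paste(truth$chromosome, truth$start, truth$end))
  # junctions below min_support are dropped
  first_junction <- reads[1, ]
  sam1 <- withr::local_tempfile(fileext = ".sam")
  write_sam(first_junction, sim$genome_a, sam1)
  expect_equal(nrow(call_junctions(sam1, sim$genome_a, min_support = 2)), 0)
  expect_equal(nrow(call_junctions(sam1, sim$genome_a, min_support = 1)), 1)
  # no gapped records -> empty
  sam0 <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads[0, ], sim$genome_a, sam0)
  expect_equal(nrow(call_junctions(sam0, sim$genome_a)), 0)
})
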