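test_that("fixed config and seed reproduce byte-identical genomes", {
  s1 <- simulate_genome_pair(generator_config(), seed = 11)
  s2 <- simulate_genome_pair(generator_config(), seed = 11)
  expect_identical(s1$genome_a$chromosomes, s2$genome_a$chromosomes)
  expect_identical(s1$genome_b$chromosomes, s2$genome_b$chromosomes)
  expect_identical(s1$genome_a$genes, s2$genome_a$genes)
  expect_identical(s1$families, s2$families)
  expect_identical(s1$truth$introns, s2$truth$introns)
  s3 <- simulate_genome_pair(generator_config(), seed = 12)
  expect_false(identical(s1$genome_a$chromosomes$sequence,
                         s3$genome_a$chromosomes$sequence))
  c1 <- simulate_coverage(s1$genome_a, s1$truth, s1$config, seed = 5)
  c2 <- simulate_coverage(s2$genome_a, s2$truth, s2$config, seed = 5)
  expect_identical(c1, c2)
})

test_that("planted region GC converges to the configured values", {
  sim <- desk_sim()
  label <- sim$genome_a$label
  reps <- truth_regions(sim, label, "repeats")
  both <- truth_regions(sim, label, c("repeats", "arrays"))
  gc_in <- region_gc(sim$genome_a, reps)$gc_inside
  gc_out <- region_gc(sim$genome_a, both)$gc_outside
  expect_lt(abs(gc_in - sim$config$subtel_gc), 0.01)
  expect_lt(abs(gc_out - sim$config$internal_gc), 0.01)
})

test_that("observed mean spacer matches the configured mean over seeds", {
  cfg <- generator_config()
  lens <- unlist(lapply(1:20, function(s) {
    sim <- simulate_genome_pair(cfg, seed = s)
    sp <- intergenic_spacers(sim$genome_a,
                             exclude_regions = truth_regions(sim, sim$genome_a$label,
                                                             c("repeats", "arrays")))
    sp$length
  }))
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - cfg$mean_spacer), 3 * se)
})

test_that("the full-scale preset plants six ~35 kbp terminal repeats", {
  sim <- simulate_genome_pair(generator_config("full"), seed = 3)
  tr <- dplyr::filter(sim$truth$repeats, genome == sim$genome_a$label)
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$stop - tr$start + 1 == 35000))
})

test_that("an intronless configuration yields empty intron truth", {
  cfg <- generator_config(introns_per_gene = 0, longest_intron = NULL,
                          unique_introns_b = 0)
  sim <- simulate_genome_pair(cfg, seed = 4)
  expect_equal(nrow(sim$truth$introns), 0)
  expect_equal(nrow(catalog_introns(sim$genome_a)), 0)
  expect_equal(nrow(catalog_introns(sim$genome_b)), 0)
  # probability mass on a sub-minimal length behaves the same way
  cfg0 <- generator_config(intron_length_distribution = c(`0` = 1),
                           longest_intron = NULL, unique_introns_b = 0)
  sim0 <- simulate_genome_pair(cfg0, seed = 4)
  expect_equal(nrow(sim0$truth$introns), 0)
})

test_that("infeasible packing fails naming the violated budget", {
  cfg <- generator_config(genes_per_chromosome = 40L,
                          synteny_block_sizes = c(4L, 5L))
  expect_error(simulate_genome_pair(cfg, seed = 1), "packing infeasible")
})

test_that("generated junction records span planted introns with GT boundaries", {
  sim <- desk_sim()
  reads <- simulate_junction_reads(sim$genome_a, sim$truth, sim$config,
                                   reads_per_junction = 3, seed = 9)
  tr <- dplyr::filter(sim$truth$introns, genome == sim$genome_a$label)
  expect_equal(nrow(reads), 3 * nrow(tr))
  expect_true(all(grepl("^\\d+M\\d+N\\d+M$", reads$cigar)))
  # gap extents encoded in the CIGAR match the planted introns
  gap_len <- as.integer(sub("^\\d+M(\\d+)N.*$", "\\1", reads$cigar))
  left <- as.integer(sub("^(\\d+)M.*$", "\\1", reads$cigar))
  gap_start <- reads$pos + left
  key_reads <- unique(paste(reads$rname, gap_start, gap_len))
  key_truth <- unique(paste(tr$chromosome, tr$start, tr$length))
  expect_setequal(key_reads, key_truth)
  # canonical truth introns read GT..AG in transcript orientation
  canon <- dplyr::filter(tr, donor == "GT")
  seqs <- stats::setNames(sim$genome_a$chromosomes$sequence,
                          sim$genome_a$chromosomes$name)
  fwd <- substr(seqs[canon$chromosome], canon$start, canon$start + 1)
  rev_ <- substr(seqs[canon$chromosome], canon$end - 1, canon$end)
  plus <- canon$strand == "+"
  expect_true(all(fwd[plus] == "GT" & rev_[plus] == "AG"))
  expect_true(all(fwd[!plus] == "CT" & rev_[!plus] == "AC"))
})

test_that("generator configs round-trip through YAML", {
  cfg <- generator_config(subtel_gc = 0.51, genes_per_chromosome = 10L,
                          synteny_block_sizes = c(4L, 5L))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$subtel_gc, 0.51)
  expect_equal(back$genes_per_chromosome, 10L)
  expect_equal(unclass(back)[order(names(back))],
               unclass(cfg)[order(names(cfg))], tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(intron_length_distribution = c(`19` = 0.5)),
               "sum to 1")
  expect_error(generator_config(subtel_length = 15000L), "subtel_length")
  expect_error(generator_config(subtel_gc = 1.4), "fractions")
  expect_error(generator_config(nonsense_field = 1), "unknown config field")
})
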