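test_that("sub-telomeric repeats are recovered on all six ends within 50 bp", {
  sim <- desk_sim()
  reps <- detect_subtelomeric_repeats(sim$genome_a)
  expect_equal(nrow(reps), 6)
  truth <- dplyr::filter(sim$truth$repeats, genome == sim$genome_a$label)
  j <- dplyr::inner_join(reps, truth, by = c("chromosome", "end"))
  expect_equal(nrow(j), 6)
  expect_true(all(abs(j$start.x - j$start.y) <= 50))
  expect_true(all(abs(j$end_pos - j$stop) <= 50))
  expect_true(all(j$identity_to_consensus >= 0.99))
})

test_that("independently random chromosome ends yield no repeat regions", {
  g <- make_genome(c(chr1 = fixture_dna(5000, 21), chr2 = fixture_dna(5000, 22)))
  expect_equal(nrow(detect_subtelomeric_repeats(g)), 0)
})

test_that("detection is invariant under reverse-complementing a chromosome", {
  sim <- desk_sim()
  g <- sim$genome_a
  flipped <- g
  flipped$chromosomes$sequence[1] <-
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(g$chromosomes$sequence[1])))
  flipped$genes <- dplyr::filter(flipped$genes, chromosome != "chr1")
  r1 <- detect_subtelomeric_repeats(g)
  r2 <- detect_subtelomeric_repeats(flipped)
  expect_equal(nrow(r2), nrow(r1))
  expect_setequal(r2$length, r1$length)
  # chr1 left end becomes the right end and vice versa
  e1 <- dplyr::filter(r1, chromosome == "chr1")
  e2 <- dplyr::filter(r2, chromosome == "chr1")
  expect_setequal(e2$end, e1$end)
  # chromosome order does not matter
  reordered <- g
  reordered$chromosomes <- g$chromosomes[c(3, 1, 2), ]
  r3 <- detect_subtelomeric_repeats(reordered)
  expect_setequal(paste(r3$chromosome, r3$end, r3$start),
                  paste(r1$chromosome, r1$end, r1$start))
})

test_that("chromosomes shorter than min_length are skipped with a warning", {
  g <- make_genome(c(chr1 = fixture_dna(500, 23), chr2 = fixture_dna(5000, 24)))
  expect_warning(r <- detect_subtelomeric_repeats(g, min_length = 1000),
                 "skipped")
  expect_equal(nrow(r), 0)
})

test_that("the printed 36-nt boundary unit is recovered from a pure array", {
  unit <- "RTAYCTRGTTRCCTTATCGTATGCCATGGCTTTATC"
  fixed <- chartr("RY", "AC", unit)
  arr <- detect_tandem_array(strrep(fixed, 10), unit_range = c(2, 60),
                             min_copies = 3)
  expect_equal(arr$unit_length, 36L)
  expect_equal(arr$copy_number, 10.0)
  expect_equal(arr$consensus, fixed)
  expect_equal(arr$match_fraction, 1.0)
})

test_that("degenerate positions fold into IUPAC codes in the consensus", {
  sim <- desk_sim()
  a <- dplyr::filter(sim$truth$arrays, genome == sim$genome_a$label)
  a <- dplyr::filter(a, n_copies == max(n_copies))[1, ]
  seq <- substr(sim$genome_a$chromosomes$sequence[
    match(a$chromosome, sim$genome_a$chromosomes$name)], a$start, a$end)
  got <- detect_tandem_array(seq, unit_range = c(2, 60), min_copies = 3)
  expect_equal(got$unit_length, 36L)
  expect_equal(got$copy_number, a$n_copies)
  # consensus matches the planted unit up to rotation; with enough copies the
  # two-state degenerate letters are reproduced
  rotations <- vapply(seq_len(36), function(k) {
    paste0(substr(a$consensus, k, 36), substr(a$consensus, 1, k - 1))
  }, character(1))
  expect_true(got$consensus %in% rotations)
})

test_that("homopolymers collapse to the primitive unit", {
  arr <- detect_tandem_array(strrep("A", 50), unit_range = c(1, 10),
                             min_copies = 3)
  expect_equal(arr$unit_length, 1L)
})

test_that("unit length matches the autocorrelation oracle on random units", {
  withr::with_seed(31, {
    for (k in 1:8) {
      u <- sample(5:40, 1)
      unit <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE), collapse = "")
      seq <- strrep(unit, 6)
      got <- detect_tandem_array(seq, unit_range = c(2, 60), min_copies = 3)
      expect_equal(got$unit_length, oracle_tandem_unit(seq, c(2, 60)))
      # a primitive unit should be recovered exactly unless it is itself
      # periodic, in which case the smaller period wins
      expect_true(u %% got$unit_length == 0)
    }
  })
})

test_that("array detection is invariant under rotation of the array start", {
  unit <- "ACGTTGCAGGTAT"
  seq <- strrep(unit, 7)
  rot <- paste0(substr(seq, 6, nchar(seq)), substr(seq, 1, 5))
  a1 <- detect_tandem_array(seq, c(2, 30), 3)
  a2 <- detect_tandem_array(rot, c(2, 30), 3)
  expect_equal(a2$unit_length, a1$unit_length)
})

test_that("no array is reported for aperiodic sequence", {
  expect_null(detect_tandem_array(fixture_dna(300, 33), c(2, 60), 3))
})

test_that("GC profile windows behave and conserve whole-sequence GC", {
  expect_true(all(gc_profile(strrep("G", 100), window = 10)$gc == 1))
  seq <- fixture_dna(1050, 34, gc = 0.4)
  prof <- gc_profile(seq, window = 100, step = 100)
  expect_equal(sum(prof$end - prof$start + 1), 1050)
  expect_true(prof$partial[nrow(prof)])
  expect_equal(weighted.mean(prof$gc, prof$end - prof$start + 1),
               gc_fraction(seq))
  # window larger than the sequence: one whole-sequence window
  whole <- gc_profile(seq, window = 5000)
  expect_equal(nrow(whole), 1)
  expect_equal(whole$gc, gc_fraction(seq))
  expect_error(gc_profile(seq, window = 10, step = 20), "window >= step")
})

test_that("windows inside the planted repeat average the sub-telomeric GC", {
  sim <- desk_sim()
  seq <- sim$genome_a$chromosomes$sequence[1]
  prof <- gc_profile(seq, window = 500, step = 500)
  tr <- dplyr::filter(sim$truth$repeats, genome == sim$genome_a$label,
                      chromosome == "chr1", end == "left")
  inside <- dplyr::filter(prof, end <= tr$stop)
  expect_lt(abs(weighted.mean(inside$gc, inside$end - inside$start + 1) -
                  sim$config$subtel_gc), 0.01)
})

test_that("region GC splits and recombines consistently", {
  seq <- fixture_dna(2000, 35, gc = 0.45)
  g <- make_genome(c(chr1 = seq))
  whole <- region_gc(g, tibble::tibble(chromosome = "chr1", start = 1, end = 2000))
  expect_equal(whole$gc_inside, gc_fraction(seq))
  halves <- region_gc(g, tibble::tibble(chromosome = "chr1", start = 1, end = 1000))
  recombined <- (halves$gc_inside * halves$bp_inside +
                   halves$gc_outside * halves$bp_outside) /
    (halves$bp_inside + halves$bp_outside)
  expect_equal(recombined, gc_fraction(seq))
  empty <- region_gc(g, tibble::tibble(chromosome = character(),
                                       start = integer(), end = integer()))
  expect_true(is.na(empty$gc_inside))
})
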