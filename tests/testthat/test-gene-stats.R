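test_that("adjacent genes yield the expected spacer", {
  seq <- fixture_dna(300, 41)
  g <- make_genome(c(chr1 = seq),
                   dplyr::bind_rows(make_gene("a", "chr1", 1, 100),
                                    make_gene("b", "chr1", 151, 200)),
                   min_orf_codons = NULL, validate = FALSE)
  sp <- intergenic_spacers(g)
  expect_equal(sp$length, 50L)
  expect_equal(attr(sp, "mean"), 50)
  expect_equal(attr(sp, "n"), 1L)
})

test_that("overlapping genes contribute zero-length flagged spacers", {
  seq <- fixture_dna(300, 42)
  g <- make_genome(c(chr1 = seq),
                   dplyr::bind_rows(make_gene("a", "chr1", 1, 120),
                                    make_gene("b", "chr1", 100, 200)),
                   min_orf_codons = NULL, validate = FALSE)
  sp <- intergenic_spacers(g)
  expect_equal(sp$length, 0L)
  expect_true(sp$overlapping)
})

test_that("spacer lists equal a brute-force gap scan", {
  sim <- desk_sim()
  sp <- intergenic_spacers(sim$genome_a)
  manual <- unlist(lapply(split(sim$genome_a$genes,
                                sim$genome_a$genes$chromosome), function(g) {
    g <- g[order(g$start), ]
    if (nrow(g) < 2) return(integer())
    pmax(g$start[-1] - g$end[-nrow(g)] - 1L, 0L)
  }), use.names = FALSE)
  expect_setequal(sp$length, manual)
  expect_equal(sort(sp$length), sort(manual))
  # count identity: genes minus chromosomes-with-genes, absent exclusions
  n_chrom_with <- length(unique(sim$genome_a$genes$chromosome))
  expect_equal(attr(sp, "n"), nrow(sim$genome_a$genes) - n_chrom_with)
})

test_that("Welch test matches the closed form and is antisymmetric", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  got <- welch_t_test(a, b)
  exp <- oracle_welch(a, b)
  expect_equal(got$statistic, exp$statistic)
  expect_equal(got$df, exp$df)
  expect_equal(got$p_value, exp$p)
  swapped <- welch_t_test(b, a)
  expect_equal(swapped$statistic, -got$statistic)
  expect_equal(swapped$p_value, got$p_value)
  same <- welch_t_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
  expect_error(welch_t_test(c(2, 2, 2), c(3, 3, 3)), "zero variance")
})

test_that("spacer contrast between the two synthetic genomes is significant", {
  # spacer counts comparable to real annotated genomes (hundreds per genome)
  # are needed to resolve the contrast at the reported significance
  cfg <- generator_config(chromosome_length = 80000L,
                          genes_per_chromosome = 60L)
  sim <- simulate_genome_pair(cfg, seed = TEST_SEED)
  sa <- intergenic_spacers(sim$genome_a,
                           truth_regions(sim, sim$genome_a$label, c("repeats", "arrays")))
  sb <- intergenic_spacers(sim$genome_b,
                           truth_regions(sim, sim$genome_b$label, c("repeats", "arrays")))
  res <- welch_t_test(sa$length, sb$length)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$mean_a, res$mean_b)
})

test_that("protein lengths come from translated CDS with stop excluded", {
  cds_nostop <- paste0("ATG", strrep("GCT", 29))       # 90 bp, no stop codon
  g1 <- make_genome(c(chr1 = paste0(cds_nostop, fixture_dna(60, 43))),
                    make_gene("p1", "chr1", 1, 90), min_orf_codons = NULL)
  expect_equal(protein_sequences(g1)$length, 30L)
  cds_stop <- paste0("ATG", strrep("GCT", 28), "TAA")  # 90 bp with stop
  g2 <- make_genome(c(chr1 = paste0(cds_stop, fixture_dna(60, 44))),
                    make_gene("p2", "chr1", 1, 90), min_orf_codons = NULL)
  expect_equal(protein_sequences(g2)$length, 29L)
})

test_that("protein length stats equal direct recomputation", {
  sim <- desk_sim()
  res <- protein_length_stats(sim$genome_a, sim$genome_b, mode = "all")
  means <- attr(res, "means")
  direct_a <- mean(protein_sequences(sim$genome_a)$length)
  direct_b <- mean(protein_sequences(sim$genome_b)$length)
  expect_equal(unname(means[sim$genome_a$label]), direct_a)
  expect_equal(unname(means[sim$genome_b$label]), direct_b)
  shared <- protein_length_stats(sim$genome_a, sim$genome_b,
                                 mode = "shared_only", families = sim$families)
  # shared mode pairs families across genomes and drops excluded categories
  counts <- dplyr::count(shared, family_id)
  expect_true(all(counts$n == 2))
  cats <- sim$families$category[match(shared$family_id, sim$families$family_id)]
  expect_false(any(cats %in% c("nORFan", "other")))
})

test_that("identical proteins collapse into one cluster", {
  cds <- paste0("ATG", strrep("GCTTGGAAA", 20), "TAA")
  seq <- paste0(cds, fixture_dna(50, 45), cds, fixture_dna(30, 46))
  off <- nchar(cds) + 50
  g <- make_genome(c(chr1 = seq),
                   dplyr::bind_rows(
                     make_gene("c1", "chr1", 1, nchar(cds)),
                     make_gene("c2", "chr1", off + 1, off + nchar(cds))),
                   min_orf_codons = NULL)
  cl <- collapse_redundant(g)
  expect_equal(attr(cl, "n_nonredundant"), 1L)
})

test_that("redundancy collapse matches planted sub-telomeric multiplicity", {
  sim <- desk_sim()
  cl <- collapse_redundant(sim$genome_a)
  raw <- nrow(cl)
  # each sub-telomeric ORF family has 6 byte-identical copies -> 5 removed
  expected <- raw - 5L * sim$config$orfs_per_repeat
  expect_equal(attr(cl, "n_nonredundant"), expected)
  # cluster membership equals brute-force all-pairs single linkage on a subset
  prot <- protein_sequences(sim$genome_a)
  sub <- prot[1:10, ]
  n <- nrow(sub)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (min(sub$length[i], sub$length[j]) / max(sub$length[i], sub$length[j]) < 0.95) next
      adj[i, j] <- if (sub$protein[i] == sub$protein[j]) TRUE else
        align_proteins(sub$protein[i], sub$protein[j])$percent_identity >= 0.98
    }
  }
  comp <- igraph_free_components(adj)
  subg <- sim$genome_a
  subg$genes <- dplyr::filter(subg$genes, gene_id %in% sub$gene_id)
  cl_sub <- collapse_redundant(subg)
  got <- cl_sub$cluster_id[match(sub$gene_id, cl_sub$gene_id)]
  expect_equal(length(unique(got)), length(unique(comp)))
  expect_true(all(outer(comp, comp, "==") == outer(got, got, "==")))
})
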