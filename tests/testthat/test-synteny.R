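test_that("identical orders form a single block covering all genes", {
  fams <- sprintf("f%02d", 1:10)
  bl <- detect_synteny_blocks(order_from_families(fams),
                              order_from_families(fams, genome_tag = "y"),
                              min_genes = 3)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$n_genes, 10L)
  expect_equal(bl$orientation, "same")
  expect_equal(bl$families[[1]], fams)
})

test_that("gene order follows start coordinates (sort oracle)", {
  sim <- desk_sim()
  ord <- gene_order(sim$genome_a, sim$families, shared_only = TRUE)
  manual <- sim$genome_a$genes |>
    dplyr::inner_join(
      dplyr::filter(sim$families, genome == sim$genome_a$label) |>
        dplyr::semi_join(dplyr::filter(sim$families, genome == sim$genome_b$label),
                         by = "family_id") |>
        dplyr::select(family_id, gene_id),
      by = "gene_id", suffix = c(".anno", "")) |>
    dplyr::arrange(chromosome, start)
  expect_equal(ord$gene_id, manual$gene_id)
  expect_equal(ord$family_id, manual$family_id)
  # shared_only drops families private to one genome
  ord_all <- gene_order(sim$genome_a, sim$families, shared_only = FALSE)
  priv <- setdiff(ord_all$family_id, ord$family_id)
  in_b <- unique(sim$families$family_id[sim$families$genome == sim$genome_b$label])
  expect_true(all(!priv %in% in_b))
})

test_that("planted synteny blocks are recovered exactly", {
  sim <- desk_sim()
  oa <- gene_order(sim$genome_a, sim$families, shared_only = TRUE)
  ob <- gene_order(sim$genome_b, sim$families, shared_only = TRUE)
  got <- detect_synteny_blocks(oa, ob, min_genes = 3)
  truth <- sim$truth$blocks
  expect_equal(nrow(got), nrow(truth))
  canon <- function(f) {
    paste(if (f[1] > f[length(f)]) rev(f) else f, collapse = ",")
  }
  expect_setequal(vapply(got$families, canon, character(1)),
                  vapply(truth$families, canon, character(1)))
  j <- dplyr::inner_join(
    dplyr::mutate(got, key = vapply(families, canon, character(1))),
    dplyr::mutate(truth, key = vapply(families, canon, character(1))),
    by = "key")
  expect_equal(j$orientation.x, j$orientation.y)
  expect_equal(j$n_genes.x, j$n_genes.y)
  expect_equal(j$chrom_a.x, j$chrom_a.y)
  expect_equal(j$chrom_b.x, j$chrom_b.y)
})

test_that("detection matches a brute-force maximal-run oracle on permutations", {
  withr::with_seed(81, {
    for (k in 1:15) {
      n <- sample(6:10, 1)
      fams <- sprintf("f%02d", seq_len(n))
      perm <- sample(fams)
      oa <- order_from_families(fams)
      ob <- order_from_families(perm, genome_tag = "y")
      got <- detect_synteny_blocks(oa, ob, min_genes = 2)
      exp <- oracle_common_runs(fams, perm, min_genes = 2)
      expect_equal(nrow(got), length(exp), info = paste(perm, collapse = " "))
      canon <- function(f) paste(sort(f), collapse = ",")
      expect_setequal(vapply(got$families, canon, character(1)),
                      vapply(exp, function(e) canon(e$families), character(1)))
    }
  })
})

test_that("a 14-block fixture averages 5.5 genes per block", {
  sizes <- c(4, 4, 4, 5, 5, 5, 5, 6, 6, 6, 6, 7, 7, 7)
  withr::with_seed(82, {
    fams <- sprintf("f%03d", seq_len(sum(sizes) + 20))
    block_members <- split(fams[seq_len(sum(sizes))],
                           rep(seq_along(sizes), sizes))
    background <- fams[(sum(sizes) + 1):length(fams)]
    order_a <- order_from_families(fams)
    # partner order: blocks as units shuffled with background singletons
    units <- c(block_members, as.list(background))
    repeat {
      shuffled <- units[sample(length(units))]
      flat <- unlist(shuffled)
      pos_a <- match(flat, fams)
      breaks <- which(diff(pos_a) == 1 | diff(pos_a) == -1)
      unit_of <- rep(seq_along(shuffled), lengths(shuffled))
      if (!any(unit_of[breaks] != unit_of[breaks + 1])) break
    }
    order_b <- order_from_families(flat, genome_tag = "y")
    got <- detect_synteny_blocks(order_a, order_b, min_genes = 3)
    expect_equal(nrow(got), 14)
    st <- synteny_stats(got)
    expect_equal(st$n_blocks, 14L)
    expect_equal(st$mean_genes, 5.5)
    expect_equal(st$total_genes, 77L)
  })
})

test_that("block detection is symmetric under swapping genomes", {
  sim <- desk_sim()
  oa <- gene_order(sim$genome_a, sim$families, shared_only = TRUE)
  ob <- gene_order(sim$genome_b, sim$families, shared_only = TRUE)
  ab <- detect_synteny_blocks(oa, ob, min_genes = 3)
  ba <- detect_synteny_blocks(ob, oa, min_genes = 3)
  canon <- function(f) paste(sort(f), collapse = ",")
  expect_setequal(vapply(ab$families, canon, character(1)),
                  vapply(ba$families, canon, character(1)))
  j <- dplyr::inner_join(
    dplyr::mutate(ab, key = vapply(families, canon, character(1))),
    dplyr::mutate(ba, key = vapply(families, canon, character(1))), by = "key")
  expect_equal(j$orientation.x, j$orientation.y)
})

test_that("identical orders partition the shared set at min_genes 1", {
  fams <- sprintf("f%02d", 1:7)
  bl <- detect_synteny_blocks(order_from_families(fams),
                              order_from_families(fams, genome_tag = "y"),
                              min_genes = 1, max_gap = 0)
  expect_equal(sort(unlist(bl$families)), sort(fams))
  expect_equal(sum(bl$n_genes), length(fams))
})

test_that("synteny stats handle the empty case", {
  fams <- sprintf("f%02d", 1:6)
  none <- detect_synteny_blocks(order_from_families(fams),
                                order_from_families(rev(fams)[c(2, 4, 6, 1, 3, 5)],
                                                    genome_tag = "y"),
                                min_genes = 3, allow_inversion = FALSE)
  st <- synteny_stats(none)
  expect_equal(st$n_blocks, 0L)
  expect_true(is.na(st$mean_genes))
})
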