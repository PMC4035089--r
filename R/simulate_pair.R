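#' Generate a synthetic annotated genome pair with ground truth
#'
#' Builds two annotated genomes with the statistical structure the
#' comparative pipeline assumes (see [generator_config()]), an ortholog
#' family table, and a truth record sufficient to score every detector:
#' planted repeat intervals, tandem-array coordinates and copy numbers,
#' per-gene intron lists with sharing status, planted synteny blocks, and
#' per-gene expression classes. Output is deterministic for a fixed
#' `(config, seed)`.
#'
#' @param config an `nm_generator_config`.
#' @param seed integer seed; all randomness flows from it.
#' @param labels genome labels, length 2.
#' @return a list of class `nm_simulation` with elements `genome_a`,
#'   `genome_b`, `families`, `truth`, `config`, `seed`.
#' @export
simulate_genome_pair <- function(config = generator_config(), seed = 1,
                                 labels = c("genomeA", "genomeB")) {
  cfg <- config
  set.seed(substream_seed(seed, "pair"))
  n_chr <- cfg$n_chromosomes
  g_per <- cfg$genes_per_chromosome
  n_int <- g_per * n_chr
  sampler_int <- codon_sampler(cfg$internal_gc)
  aa_tab <- aa_codon_table(cfg$internal_gc)

  fam_ids <- sprintf("fam%03d", seq_len(n_int))
  fam_chrom <- rep(seq_len(n_chr), each = g_per)
  fam_cat <- sample(names(cfg$category_probs), n_int, replace = TRUE,
                    prob = cfg$category_probs)

  # ---- genome A internal protein genes ----
  genes_a <- map(seq_len(n_int), function(i) {
    m <- max(51L, round(stats::rnorm(1, cfg$mean_protein_length,
                                     0.2 * cfg$mean_protein_length)))
    cds <- sample_cds(m, sampler_int)
    n_i <- stats::rpois(1, cfg$introns_per_gene)
    spec <- sample_intron_spec(n_i, cfg, 17L, m - 17L)
    spec$a_only <- rep(FALSE, nrow(spec))
    list(fam = fam_ids[i], codons = m, cds = cds, spec = spec)
  })

  # plant the single longest intron (genome A only)
  if (!is.null(cfg$longest_intron) && cfg$longest_intron >= 4) {
    with_introns <- which(map_int(genes_a, ~ nrow(.x$spec)) > 0)
    if (length(with_introns)) {
      gi <- sample(with_introns, 1)
      ri <- sample(nrow(genes_a[[gi]]$spec), 1)
      genes_a[[gi]]$spec$length[ri] <- as.integer(cfg$longest_intron)
      genes_a[[gi]]$spec$seq[ri] <-
        paste0("GT", random_dna(cfg$longest_intron - 4L, cfg$intron_gc), "AG")
      genes_a[[gi]]$spec$a_only[ri] <- TRUE
    }
  }

  # plant non-canonical donors (genome A only)
  all_pos <- bind_rows(map(seq_along(genes_a), function(i) {
    s <- genes_a[[i]]$spec
    if (nrow(s) == 0) return(NULL)
    tibble(gene = i, row = seq_len(nrow(s)), a_only = s$a_only)
  }))
  nc <- cfg$noncanonical
  if (!is.null(nc) && sum(nc) > 0 && nrow(all_pos) > 0) {
    cand <- filter(all_pos, !.data$a_only)
    pick <- cand[sample(nrow(cand), min(sum(nc), nrow(cand))), ]
    donors <- rep(sub("-AG$", "", names(nc)), nc)[seq_len(nrow(pick))]
    for (k in seq_len(nrow(pick))) {
      gi <- pick$gene[k]; ri <- pick$row[k]
      genes_a[[gi]]$spec$donor[ri] <- donors[k]
      old <- genes_a[[gi]]$spec$seq[ri]
      genes_a[[gi]]$spec$seq[ri] <- paste0(donors[k], str_sub(old, 3))
    }
  }

  # exonic -2 A bias upstream of donors
  genes_a <- map(genes_a, function(g) {
    if (nrow(g$spec)) g$cds <- apply_acceptor_bias(g$cds, g$spec, cfg)
    g
  })

  # ---- sharing and synteny planting ----
  blocks <- allocate_blocks(cfg$synteny_block_sizes, n_chr, g_per)
  block_fams <- map(blocks, ~ fam_ids[.x$index])
  forced_shared <- unlist(block_fams)
  n_shared <- max(length(forced_shared), round(cfg$shared_fraction * n_int))
  extra <- setdiff(fam_ids, forced_shared)
  shared_fams <- c(forced_shared,
                   sample(extra, min(n_shared - length(forced_shared), length(extra))))
  private_b_n <- n_int - length(shared_fams)
  fam_ids_b <- if (private_b_n > 0) sprintf("famB%03d", seq_len(private_b_n)) else character()
  fam_cat_b <- sample(names(cfg$category_probs), private_b_n, replace = TRUE,
                      prob = cfg$category_probs)

  # ---- genome B orthologs ----
  genes_b <- list()
  intron_share <- list()
  for (i in seq_len(n_int)) {
    fam <- fam_ids[i]
    if (!fam %in% shared_fams) next
    ga <- genes_a[[i]]
    prot_a <- as.character(Biostrings::translate(Biostrings::DNAString(
      str_sub(ga$cds, 1, 3 * (ga$codons - 1)))))
    prot_b <- mutate_protein(prot_a, cfg$protein_divergence)
    cds_b <- paste0(back_translate(prot_b, aa_tab), sample(c("TAA", "TAG", "TGA"), 1))
    keep <- if (nrow(ga$spec)) !ga$spec$a_only &
      stats::runif(nrow(ga$spec)) < cfg$shared_intron_fraction else logical()
    spec_b <- ga$spec[keep, ]
    if (nrow(spec_b)) {
      spec_b$donor <- "GT"; spec_b$acceptor <- "AG"
      spec_b$length <- as.integer(sample(
        as.integer(names(cfg$intron_length_distribution)), nrow(spec_b),
        replace = TRUE, prob = cfg$intron_length_distribution))
      spec_b <- filter(spec_b, .data$length >= 4)
      spec_b$seq <- map_chr(spec_b$length,
                            ~ paste0("GT", random_dna(.x - 4L, cfg$intron_gc), "AG"))
    }
    n_u <- stats::rpois(1, cfg$unique_introns_b)
    if (n_u > 0) {
      avail <- setdiff(seq(17L, ga$codons - 17L), ga$spec$codon)
      uniq <- sample_intron_spec_at(sample(avail, min(n_u, length(avail))), cfg)
      spec_b <- bind_rows(spec_b, uniq)
    }
    spec_b$a_only <- NULL
    genes_b[[fam]] <- list(fam = fam, codons = ga$codons, cds = cds_b,
                           spec = arrange(spec_b, .data$donor_offset))
    if (nrow(ga$spec)) {
      intron_share[[length(intron_share) + 1]] <-
        tibble(family_id = fam, codon = ga$spec$codon, phase = ga$spec$phase,
               donor_offset = ga$spec$donor_offset,
               in_a = TRUE, in_b = keep)
    }
    if (nrow(spec_b)) {
      new_b <- !spec_b$donor_offset %in% ga$spec$donor_offset
      if (any(new_b)) {
        intron_share[[length(intron_share) + 1]] <-
          tibble(family_id = fam, codon = spec_b$codon[new_b],
                 phase = spec_b$phase[new_b],
                 donor_offset = spec_b$donor_offset[new_b],
                 in_a = FALSE, in_b = TRUE)
      }
    }
  }
  for (j in seq_len(private_b_n)) {
    m <- max(51L, round(stats::rnorm(1, cfg$mean_protein_length,
                                     0.2 * cfg$mean_protein_length)))
    cds <- sample_cds(m, sampler_int)
    spec <- sample_intron_spec(stats::rpois(1, cfg$introns_per_gene), cfg,
                               17L, m - 17L)
    spec$a_only <- NULL
    genes_b[[fam_ids_b[j]]] <- list(fam = fam_ids_b[j], codons = m, cds = cds,
                                    spec = spec)
  }

  # ---- arrange genome B gene order (plant blocks, avoid spurious runs) ----
  order_b <- arrange_b_order(fam_ids, fam_chrom, block_fams, shared_fams,
                             fam_ids_b, n_chr, cfg$invert_fraction)

  # ---- assemble chromosomes ----
  fam_category <- c(stats::setNames(fam_cat, fam_ids),
                    stats::setNames(fam_cat_b, fam_ids_b))
  asm_a <- assemble_genome(labels[1], map(seq_len(n_chr), function(c) {
    genes_a[fam_chrom == c]
  }), cfg, spacer_mean = cfg$mean_spacer, fam_category = fam_category)
  unit_lists_b <- map(order_b$chrom_order, function(fams) genes_b[fams])
  asm_b <- assemble_genome(labels[2], unit_lists_b, cfg,
                           spacer_mean = cfg$mean_spacer_b,
                           fam_category = fam_category)

  # ---- family table ----
  fam_tbl <- bind_rows(
    tibble(family_id = fam_ids, category = fam_cat, genome = labels[1]),
    tibble(family_id = shared_fams,
           category = fam_cat[match(shared_fams, fam_ids)], genome = labels[2]),
    if (private_b_n > 0) tibble(family_id = fam_ids_b, category = fam_cat_b,
                                genome = labels[2]))
  gene_map <- bind_rows(
    select(asm_a$genome$genes, "gene_id", "family_id") |> mutate(genome = labels[1]),
    select(asm_b$genome$genes, "gene_id", "family_id") |> mutate(genome = labels[2]))
  families <- fam_tbl |>
    inner_join(gene_map, by = c("genome", "family_id")) |>
    select("family_id", "category", "genome", "gene_id") |>
    bind_rows(
      asm_a$subtel_families |> mutate(category = "nORFan"),
      asm_b$subtel_families |> mutate(category = "nORFan")) |>
    arrange(.data$family_id, .data$genome, .data$gene_id)

  # ---- truth ----
  share_tbl <- if (length(intron_share)) bind_rows(intron_share) else
    tibble(family_id = character(), codon = integer(), phase = integer(),
           donor_offset = integer(), in_a = logical(), in_b = logical())
  blocks_truth <- bind_rows(map(seq_along(blocks), function(k) {
    tibble(block_id = k, chrom_a = asm_a$genome$chromosomes$name[blocks[[k]]$chrom],
           chrom_b = order_b$block_chrom_b[k],
           orientation = order_b$block_orientation[k],
           n_genes = length(block_fams[[k]]),
           families = list(block_fams[[k]]))
  }))
  collapsed <- NULL
  first_gene <- asm_a$genome$genes |>
    filter(.data$kind == "protein",
           .data$chromosome == asm_a$genome$chromosomes$name[1],
           !.data$gene_id %in% asm_a$subtel_families$gene_id) |>
    arrange(.data$start) |> slice(1)
  if (nrow(first_gene)) {
    collapsed <- tibble(genome = labels[1], chromosome = first_gene$chromosome,
                        start = first_gene$start, end = first_gene$end,
                        copy_number = cfg$collapsed_copy_number)
  }
  expr_truth <- bind_rows(asm_a$expr_truth, asm_b$expr_truth)
  if (!is.null(collapsed)) {
    # the collapsed-repeat gene is multicopy, not a single-copy internal gene
    expr_truth$class[expr_truth$genome == labels[1] &
                       expr_truth$gene_id == first_gene$gene_id] <- "multicopy"
  }
  truth <- list(
    repeats = bind_rows(asm_a$repeat_truth, asm_b$repeat_truth),
    arrays = bind_rows(asm_a$array_truth, asm_b$array_truth),
    introns = bind_rows(asm_a$intron_truth, asm_b$intron_truth),
    intron_sharing = share_tbl,
    blocks = blocks_truth,
    expression = expr_truth,
    collapsed = collapsed)
  structure(list(genome_a = asm_a$genome, genome_b = asm_b$genome,
                 families = families, truth = truth, config = cfg, seed = seed),
            class = "nm_simulation")
}

#' @export
print.nm_simulation <- function(x, ...) {
  cat("<nm_simulation> seed ", x$seed, "\n", sep = "")
  print(x$genome_a); print(x$genome_b)
  cat("  families: ", length(unique(x$families$family_id)),
      "; truth introns: ", nrow(x$truth$introns), "\n", sep = "")
  invisible(x)
}

apply_acceptor_bias <- function(cds, spec, cfg) {
  chars <- strsplit(cds, "")[[1]]
  for (k in seq_len(nrow(spec))) {
    if (stats::runif(1) >= cfg$acceptor_a_bias) next
    p <- spec$donor_offset[k] - 1L
    if (p < 4) next
    old <- chars[p]
    chars[p] <- "A"
    cstart <- 3L * ((p - 1L) %/% 3L) + 1L
    codon <- paste(chars[cstart:(cstart + 2L)], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) chars[p] <- old
  }
  paste(chars, collapse = "")
}

mutate_protein <- function(protein, divergence) {
  aa <- strsplit(protein, "")[[1]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hit <- which(stats::runif(length(aa)) < divergence)
  hit <- hit[hit > 1]                        # keep the initiator Met
  for (i in hit) aa[i] <- sample(setdiff(alphabet, aa[i]), 1)
  paste(aa, collapse = "")
}

sample_intron_spec_at <- function(codons, cfg) {
  n <- length(codons)
  if (n == 0) {
    return(tibble(codon = integer(), phase = integer(), donor_offset = integer(),
                  length = integer(), donor = character(), acceptor = character(),
                  seq = character()))
  }
  phase <- ifelse(stats::runif(n) < cfg$fraction_phase0, 0L,
                  sample(1:2, n, replace = TRUE))
  d <- ifelse(phase == 0L, 3L * codons, 3L * (codons - 1L) + phase)
  lens <- as.integer(sample(as.integer(names(cfg$intron_length_distribution)), n,
                            replace = TRUE, prob = cfg$intron_length_distribution))
  out <- tibble(codon = as.integer(codons), phase = as.integer(phase),
                donor_offset = as.integer(d), length = lens,
                donor = "GT", acceptor = "AG",
                seq = map_chr(lens, ~ paste0("GT", random_dna(max(.x - 4L, 0L),
                                                              cfg$intron_gc), "AG")))
  filter(out, .data$length >= 4)
}

# assign planted block sizes to consecutive index runs on chromosomes
allocate_blocks <- function(sizes, n_chr, g_per) {
  ptr <- rep(1L, n_chr)
  out <- list()
  cc <- 1L
  for (s in sizes) {
    tries <- 0L
    while (ptr[cc] + s - 1L > g_per) {
      cc <- cc %% n_chr + 1L
      tries <- tries + 1L
      if (tries > n_chr) abort("synteny_block_sizes exceed genes_per_chromosome capacity")
    }
    idx <- (cc - 1L) * g_per + seq(ptr[cc], ptr[cc] + s - 1L)
    out[[length(out) + 1]] <- list(chrom = cc, index = idx)
    ptr[cc] <- ptr[cc] + s + 1L            # leave one singleton between runs
    cc <- cc %% n_chr + 1L
  }
  out
}

# compose genome B order: blocks as units + singletons + private families,
# shuffled so no cross-block pair adjacent in A ends up adjacent in B
arrange_b_order <- function(fam_ids, fam_chrom, block_fams, shared_fams,
                            fam_ids_b, n_chr, invert_fraction) {
  in_block <- unlist(block_fams)
  singles <- c(setdiff(shared_fams, in_block), fam_ids_b)
  # A-adjacent unordered pairs among shared families (shared-only order)
  adj <- character()
  for (c in seq_len(n_chr)) {
    ord <- fam_ids[fam_chrom == c]
    ord <- ord[ord %in% shared_fams]
    if (length(ord) > 1) {
      adj <- c(adj, paste(pmin(ord[-length(ord)], ord[-1]),
                          pmax(ord[-length(ord)], ord[-1])))
    }
  }
  block_of <- stats::setNames(rep(seq_along(block_fams), lengths(block_fams)),
                              unlist(block_fams))
  for (attempt in seq_len(500)) {
    inverted <- stats::runif(length(block_fams)) < invert_fraction
    units <- c(map(seq_along(block_fams), function(k) {
      if (inverted[k]) rev(block_fams[[k]]) else block_fams[[k]]
    }), as.list(singles))
    units <- units[sample(length(units))]
    # round-robin chromosomes balanced by gene count
    chrom_genes <- rep(list(character()), n_chr)
    unit_chrom <- integer(length(units))
    for (u in seq_along(units)) {
      tgt <- which.min(lengths(chrom_genes))
      chrom_genes[[tgt]] <- c(chrom_genes[[tgt]], units[[u]])
      unit_chrom[u] <- tgt
    }
    ok <- TRUE
    for (c in seq_len(n_chr)) {
      ord <- chrom_genes[[c]]
      ord_sh <- ord[ord %in% shared_fams]
      if (length(ord_sh) < 2) next
      p1 <- ord_sh[-length(ord_sh)]; p2 <- ord_sh[-1]
      same_block <- !is.na(block_of[p1]) & !is.na(block_of[p2]) &
        block_of[p1] == block_of[p2]
      pair_key <- paste(pmin(p1, p2), pmax(p1, p2))
      if (any(pair_key %in% adj & !same_block)) { ok <- FALSE; break }
    }
    if (ok) {
      block_chrom <- map_int(seq_along(block_fams), function(k) {
        unit_chrom[k0_block_index(units, block_fams[[k]], inverted[k])]
      })
      return(list(chrom_order = chrom_genes,
                  block_chrom_b = paste0("chr", block_chrom),
                  block_orientation = ifelse(inverted, "inverted", "same")))
    }
  }
  abort("could not arrange genome B without spurious adjacency; relax config")
}

k0_block_index <- function(units, fams, inverted) {
  target <- if (inverted) rev(fams) else fams
  which(map_lgl(units, ~ identical(.x, target)))[1]
}
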