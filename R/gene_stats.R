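#' Intergenic spacer lengths
#'
#' Spacers are the gaps between the transcriptional-unit extents (all exons
#' and introns) of adjacent genes on the same chromosome, sorted by start and
#' taken regardless of strand. Overlapping genes contribute a spacer of 0 and
#' are flagged; spacers spanning an excluded region are dropped.
#'
#' @param genome an `nm_genome`.
#' @param exclude_regions optional tibble (`chromosome`, `start`, `end`);
#'   spacers overlapping these intervals are dropped.
#' @param kinds gene kinds considered; default all.
#' @return a tibble of class `nm_spacers` with `chromosome`, `upstream_gene`,
#'   `downstream_gene`, `length`, `overlapping`; attributes `mean` and `n`.
#' @export
intergenic_spacers <- function(genome, exclude_regions = NULL, kinds = NULL) {
  genes <- genome$genes
  if (!is.null(kinds)) genes <- filter(genes, .data$kind %in% kinds)
  out <- list()
  for (chrom in unique(genes$chromosome)) {
    g <- arrange(filter(genes, .data$chromosome == chrom), .data$start)
    if (nrow(g) < 2) next
    gap <- g$start[-1] - g$end[-nrow(g)] - 1L
    out[[chrom]] <- tibble(chromosome = chrom,
                           upstream_gene = g$gene_id[-nrow(g)],
                           downstream_gene = g$gene_id[-1],
                           gap_start = g$end[-nrow(g)] + 1L,
                           gap_end = g$start[-1] - 1L,
                           length = pmax(gap, 0L),
                           overlapping = gap < 0L)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(chromosome = character(), upstream_gene = character(),
                  downstream_gene = character(), gap_start = integer(),
                  gap_end = integer(), length = integer(), overlapping = logical())
  }
  if (!is.null(exclude_regions) && nrow(res) > 0 && nrow(exclude_regions) > 0) {
    hits <- map_lgl(seq_len(nrow(res)), function(i) {
      rr <- filter(exclude_regions, .data$chromosome == res$chromosome[i])
      nrow(rr) > 0 && any(rr$start <= res$gap_end[i] & rr$end >= res$gap_start[i] &
                            res$gap_start[i] <= res$gap_end[i])
    })
    res <- res[!hits, ]
  }
  res <- select(res, -"gap_start", -"gap_end")
  attr(res, "mean") <- if (nrow(res)) mean(res$length) else NA_real_
  attr(res, "n") <- nrow(res)
  class(res) <- c("nm_spacers", class(res))
  res
}

#' Protein length statistics for a genome pair
#'
#' In `"all"` mode every translated protein/ORF gene contributes. In
#' `"shared_only"` mode only families with members in both genomes count,
#' excluding nORFan and motif-only categories (the convention for comparing
#' shared protein repertoires); within a family the longest member represents
#' each genome (with a warning when a family is multicopy).
#'
#' @param genome_a,genome_b `nm_genome` objects.
#' @param mode `"all"` or `"shared_only"`.
#' @param families ortholog family table (required for `"shared_only"`), a
#'   tibble with `family_id`, `genome`, `gene_id`, `category`.
#' @param exclude_categories categories dropped in shared mode.
#' @return a tibble with one row per protein (`genome`, `gene_id`,
#'   `family_id`, `length`); per-genome means in `attr(, "means")`.
#' @export
protein_length_stats <- function(genome_a, genome_b, mode = c("all", "shared_only"),
                                 families = NULL,
                                 exclude_categories = c("nORFan", "other")) {
  mode <- match.arg(mode)
  pa <- mutate(protein_sequences(genome_a), genome = genome_a$label)
  pb <- mutate(protein_sequences(genome_b), genome = genome_b$label)
  all_p <- bind_rows(pa, pb)
  if (mode == "shared_only") {
    if (is.null(families)) abort("shared_only mode needs a family table")
    fams <- filter(families, !.data$category %in% exclude_categories)
    present <- fams |>
      distinct(.data$family_id, .data$genome) |>
      count(.data$family_id) |>
      filter(.data$n >= 2)
    fams <- filter(fams, .data$family_id %in% present$family_id)
    all_p <- inner_join(select(all_p, -"family_id"),
                        select(fams, "family_id", "genome", "gene_id"),
                        by = c("genome", "gene_id"))
    multi <- count(all_p, .data$family_id, .data$genome) |> filter(.data$n > 1)
    if (nrow(multi) > 0) {
      warn(paste0(nrow(multi), " family/genome pair(s) with multiple members;",
                  " using the longest"))
      all_p <- all_p |>
        group_by(.data$family_id, .data$genome) |>
        slice_max(.data$length, n = 1, with_ties = FALSE) |>
        ungroup()
    }
  }
  out <- select(all_p, "genome", "gene_id", "family_id", "length")
  means <- out |> group_by(.data$genome) |> summarise(mean = mean(.data$length))
  attr(out, "means") <- stats::setNames(means$mean, means$genome)
  out
}

#' Collapse near-identical multicopy proteins
#'
#' Single-linkage clustering of a genome's proteins: two proteins link when
#' their global-alignment identity is at least `identity_threshold` over at
#' least `coverage_threshold` of the longer sequence. The non-redundant gene
#' count is the number of clusters (each multicopy gene counted once). The
#' defaults are tuned to collapse recombination-homogenized sub-telomeric
#' copies while leaving diverged paralogs apart.
#'
#' @param genome an `nm_genome`.
#' @param identity_threshold minimum pairwise identity (identical columns /
#'   alignment length).
#' @param coverage_threshold minimum shorter/longer length ratio considered.
#' @param kinds gene kinds clustered.
#' @return a tibble (`gene_id`, `cluster_id`) with
#'   `attr(, "n_nonredundant")` = number of clusters.
#' @export
collapse_redundant <- function(genome, identity_threshold = 0.98,
                               coverage_threshold = 0.95,
                               kinds = c("protein", "orf")) {
  prot <- protein_sequences(genome, kinds = kinds)
  n <- nrow(prot)
  if (n == 0) {
    out <- tibble(gene_id = character(), cluster_id = integer())
    attr(out, "n_nonredundant") <- 0L
    return(out)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # shared 8-mer fraction bounds achievable identity; near-identical
  # sequences must share most of their 8-mers
  kmers <- map(prot$protein, function(p) {
    L <- str_length(p)
    if (L < 8) return(p)
    unique(str_sub(p, seq_len(L - 7), seq_len(L - 7) + 7))
  })
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      li <- prot$length[i]; lj <- prot$length[j]
      if (min(li, lj) / max(li, lj) < coverage_threshold) next
      if (prot$protein[i] == prot$protein[j]) {
        ident <- 1
      } else {
        shared <- length(intersect(kmers[[i]], kmers[[j]])) /
          max(length(kmers[[i]]), length(kmers[[j]]))
        if (shared < 0.5) next
        aln <- align_proteins(prot$protein[i], prot$protein[j])
        ident <- aln$percent_identity
      }
      if (ident >= identity_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- map_int(seq_len(n), find)
  cluster <- match(roots, unique(roots))
  out <- tibble(gene_id = prot$gene_id, cluster_id = cluster)
  attr(out, "n_nonredundant") <- length(unique(cluster))
  out
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch test (Welch-Satterthwaite degrees of freedom) for group
#' contrasts such as intergenic spacer lengths between two genomes.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2; at least one
#'   must have nonzero variance.
#' @return a one-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2) abort("sample_a needs >= 2 observations")
  if (length(sample_b) < 2) abort("sample_b needs >= 2 observations")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(tibble(statistic = 0, df = NA_real_, p_value = 1,
                    mean_a = mean(sample_a), mean_b = mean(sample_b)))
    }
    abort("both samples have zero variance (sample_a, sample_b degenerate)")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value,
         mean_a = mean(sample_a), mean_b = mean(sample_b))
}
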