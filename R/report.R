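#' Run the full genome-pair comparison
#'
#' Executes every analysis stage in dependency order on a pair of annotated
#' genomes: genome summaries, sub-telomeric repeat and tandem-array
#' detection, GC inside/outside repeats, intergenic spacer statistics with a
#' Welch test, protein-length statistics, redundancy collapse, intron
#' catalogues with size/boundary distributions and cross-species position
#' comparison, synteny blocks over the family table, gene-content overlap and
#' core set, and (when coverage is supplied) per-gene depth and the
#' sub-telomeric vs internal expression contrast. Every number in the report
#' equals the output of the corresponding single verb on the same inputs.
#'
#' @param genome_a,genome_b `nm_genome` objects.
#' @param families ortholog family table.
#' @param coverage_a,coverage_b optional [coverage_track()] objects.
#' @param subtel_genes_a optional character vector of sub-telomeric gene ids
#'   in genome A for the expression contrast (defaults to genes lying inside
#'   detected repeat regions).
#' @param params named list overriding stage parameters: `min_repeat_length`,
#'   `min_repeat_identity`, `unit_range`, `min_copies`, `min_block_genes`,
#'   `max_block_gap`, `flank_residues`, `flank_identity`, `identity_threshold`,
#'   `coverage_threshold`.
#' @return a list of class `nm_report` with one element per stage.
#' @export
run_comparison <- function(genome_a, genome_b, families,
                           coverage_a = NULL, coverage_b = NULL,
                           subtel_genes_a = NULL, params = list()) {
  p <- utils::modifyList(list(
    min_repeat_length = 1000, min_repeat_identity = 0.995,
    unit_range = c(2, 60), min_copies = 3,
    min_block_genes = 3, max_block_gap = 0,
    flank_residues = 15, flank_identity = 0.5,
    identity_threshold = 0.98, coverage_threshold = 0.95), params)

  rep_a <- detect_subtelomeric_repeats(genome_a, p$min_repeat_length,
                                       p$min_repeat_identity)
  rep_b <- detect_subtelomeric_repeats(genome_b, p$min_repeat_length,
                                       p$min_repeat_identity)
  reg_a <- if (nrow(rep_a)) tibble(chromosome = rep_a$chromosome,
                                   start = rep_a$start, end = rep_a$end_pos) else NULL
  reg_b <- if (nrow(rep_b)) tibble(chromosome = rep_b$chromosome,
                                   start = rep_b$start, end = rep_b$end_pos) else NULL

  summary_a <- genome_summary(genome_a, exclude_regions = reg_a, nonredundant = TRUE)
  summary_b <- genome_summary(genome_b, exclude_regions = reg_b, nonredundant = TRUE)

  gc_a <- if (!is.null(reg_a)) region_gc(genome_a, reg_a) else NULL
  gc_b <- if (!is.null(reg_b)) region_gc(genome_b, reg_b) else NULL

  spacers_a <- intergenic_spacers(genome_a)
  spacers_b <- intergenic_spacers(genome_b)
  spacer_test <- if (nrow(spacers_a) >= 2 && nrow(spacers_b) >= 2) {
    welch_t_test(spacers_a$length, spacers_b$length)
  } else NULL

  lengths_all <- protein_length_stats(genome_a, genome_b, mode = "all")
  lengths_shared <- protein_length_stats(genome_a, genome_b,
                                         mode = "shared_only", families = families)

  introns_a <- catalog_introns(genome_a)
  introns_b <- catalog_introns(genome_b)
  comparison <- compare_intron_positions(genome_a, genome_b, families,
                                         flank_residues = p$flank_residues,
                                         flank_identity = p$flank_identity,
                                         introns_a = introns_a,
                                         introns_b = introns_b)

  order_a <- gene_order(genome_a, families, shared_only = TRUE)
  order_b <- gene_order(genome_b, families, shared_only = TRUE)
  blocks <- detect_synteny_blocks(order_a, order_b,
                                  min_genes = p$min_block_genes,
                                  max_gap = p$max_block_gap)

  venn <- set_overlap_by_category(families, genome_a$label, genome_b$label)
  core_a <- core_set(families, genome_a$label)

  expression <- NULL
  if (!is.null(coverage_a)) {
    depths_a <- gene_depth(coverage_a, genome_a)
    sub_genes <- subtel_genes_a
    if (is.null(sub_genes) && !is.null(reg_a)) {
      sub_genes <- genome_a$genes |>
        inner_join(rename(reg_a, rstart = "start", rend = "end"),
                   by = "chromosome", relationship = "many-to-many") |>
        filter(.data$start >= .data$rstart, .data$end <= .data$rend,
               .data$kind %in% c("orf", "protein")) |>
        pull(.data$gene_id)
    }
    int_genes <- setdiff(
      genome_a$genes$gene_id[genome_a$genes$kind %in% c("protein", "orf")],
      sub_genes)
    expression <- list(depths_a = depths_a)
    if (length(sub_genes) && length(int_genes)) {
      expression$contrast <- expression_contrast(depths_a, int_genes, sub_genes)
    }
    if (!is.null(coverage_b)) expression$depths_b <- gene_depth(coverage_b, genome_b)
  }

  structure(list(
    labels = c(genome_a$label, genome_b$label),
    summaries = bind_rows(summary_a, summary_b),
    repeats = list(a = rep_a, b = rep_b),
    repeat_gc = list(a = gc_a, b = gc_b),
    spacers = list(a = spacers_a, b = spacers_b, test = spacer_test),
    protein_lengths = list(all = lengths_all, shared = lengths_shared),
    introns = list(a = introns_a, b = introns_b,
                   sizes_a = intron_size_distribution(introns_a),
                   sizes_b = intron_size_distribution(introns_b),
                   boundaries_a = classify_boundaries(introns_a),
                   boundaries_b = classify_boundaries(introns_b),
                   comparison = comparison),
    synteny = list(blocks = blocks, stats = synteny_stats(blocks)),
    gene_content = list(venn = venn, core_a = core_a),
    expression = expression,
    params = p), class = "nm_report")
}

#' @export
print.nm_report <- function(x, ...) {
  cat("<nm_report> ", x$labels[1], " vs ", x$labels[2], "\n", sep = "")
  s <- x$summaries
  for (i in 1:2) {
    cat(sprintf("  %s: %s bp, GC %.1f%%, %d genes, %d introns, mean spacer %.1f bp\n",
                s$label[i], format(s$total_size[i], big.mark = ","),
                100 * s$gc_overall[i], s$n_genes[i], s$n_introns[i],
                s$mean_spacer[i]))
  }
  cat("  repeats: ", nrow(x$repeats$a), " + ", nrow(x$repeats$b), " regions\n", sep = "")
  cm <- attr(x$introns$comparison, "summary")
  if (!is.null(cm)) {
    cat("  introns shared/comparable: ", cm$n_shared, " of ",
        cm$n_comparable_a, "/", cm$n_comparable_b, "\n", sep = "")
  }
  cat("  synteny blocks: ", x$synteny$stats$n_blocks,
      " (mean ", round(x$synteny$stats$mean_genes, 2), " genes)\n", sep = "")
  invisible(x)
}

#' Write a comparison report as a TSV bundle
#'
#' One TSV per stage under `dir`; reruns with identical inputs produce
#' byte-identical files.
#'
#' @param report an `nm_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x) >= 0) {
      x <- select(x, where(~ !is.list(.x)))
      readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")))
    }
  }
  w(select(report$summaries, -"chromosome_sizes"), "summaries")
  w(report$repeats$a, "repeats_a"); w(report$repeats$b, "repeats_b")
  w(report$spacers$a, "spacers_a"); w(report$spacers$b, "spacers_b")
  w(report$spacers$test, "spacer_welch_test")
  w(report$protein_lengths$all, "protein_lengths_all")
  w(report$introns$sizes_a, "intron_sizes_a")
  w(report$introns$sizes_b, "intron_sizes_b")
  w(report$introns$boundaries_a, "intron_boundaries_a")
  w(report$introns$boundaries_b, "intron_boundaries_b")
  w(report$introns$comparison, "intron_comparison")
  blocks <- report$synteny$blocks
  if (nrow(blocks)) {
    blocks <- mutate(blocks, families = map_chr(.data$families, paste, collapse = ","))
  }
  w(blocks, "synteny_blocks")
  w(report$synteny$stats, "synteny_stats")
  w(report$gene_content$venn, "gene_content_venn")
  if (!is.null(report$expression)) {
    w(report$expression$depths_a, "gene_depth_a")
    if (!is.null(report$expression$contrast)) w(report$expression$contrast,
                                                "expression_contrast")
  }
  invisible(dir)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-stage headline numbers of a comparison report
#'
#' @param x an `nm_report`.
#' @param ... unused.
#' @return a long tibble with `stage`, `metric`, `genome`, `value`.
#' @method tidy nm_report
#' @export
tidy.nm_report <- function(x, ...) {
  s <- x$summaries
  rows <- list()
  add <- function(stage, metric, genome, value) {
    rows[[length(rows) + 1]] <<- tibble(stage = stage, metric = metric,
                                        genome = genome, value = as.numeric(value))
  }
  for (i in 1:2) {
    g <- s$label[i]
    add("summary", "total_size", g, s$total_size[i])
    add("summary", "gc_overall", g, s$gc_overall[i])
    add("summary", "gc_excluding_repeats", g, s$gc_excluding[i])
    add("summary", "n_genes", g, s$n_genes[i])
    add("summary", "n_introns", g, s$n_introns[i])
    add("summary", "n_nonredundant_genes", g, s$n_nonredundant_genes[i])
    add("summary", "mean_spacer", g, s$mean_spacer[i])
  }
  add("repeats", "n_regions", x$labels[1], nrow(x$repeats$a))
  add("repeats", "n_regions", x$labels[2], nrow(x$repeats$b))
  if (!is.null(x$spacers$test)) {
    add("spacers", "welch_p", NA_character_, x$spacers$test$p_value)
  }
  cm <- attr(x$introns$comparison, "summary")
  if (!is.null(cm)) {
    add("introns", "n_shared", NA_character_, cm$n_shared)
    add("introns", "n_comparable", x$labels[1], cm$n_comparable_a)
    add("introns", "n_comparable", x$labels[2], cm$n_comparable_b)
  }
  add("synteny", "n_blocks", NA_character_, x$synteny$stats$n_blocks)
  add("synteny", "mean_block_genes", NA_character_, x$synteny$stats$mean_genes)
  if (!is.null(x$expression$contrast)) {
    add("expression", "internal_vs_subtelomeric_ratio", x$labels[1],
        x$expression$contrast$ratio)
  }
  bind_rows(rows)
}

#' One-row overview of a comparison report
#'
#' @inheritParams tidy.nm_report
#' @method glance nm_report
#' @export
glance.nm_report <- function(x, ...) {
  cm <- attr(x$introns$comparison, "summary")
  tibble(genome_a = x$labels[1], genome_b = x$labels[2],
         total_size_a = x$summaries$total_size[1],
         total_size_b = x$summaries$total_size[2],
         n_repeat_regions = nrow(x$repeats$a) + nrow(x$repeats$b),
         n_shared_introns = if (is.null(cm)) NA_integer_ else cm$n_shared,
         n_synteny_blocks = x$synteny$stats$n_blocks,
         expression_ratio = if (is.null(x$expression$contrast)) NA_real_ else
           x$expression$contrast$ratio)
}
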