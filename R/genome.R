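#' Annotated genome container
#'
#' An `nm_genome` bundles chromosome sequences with gene models. It is a light
#' list of two tibbles so every downstream verb can work with ordinary
#' dplyr/tidyr operations:
#'
#' * `chromosomes`: `name`, `sequence` (IUPAC DNA), `topology`
#'   (`"linear"`/`"circular"`), `length`.
#' * `genes`: `gene_id`, `chromosome`, `strand` (`"+"`/`"-"`), `start`, `end`
#'   (1-based inclusive gene extent), `kind` (`protein`, `tRNA`, `rRNA`,
#'   `pseudogene`, `orf`), `category` (annotation-supplied functional label),
#'   `family_id`, `product`, `short_orf` (flag: protein/ORF under 50 codons),
#'   and `exons`, a list-column of tibbles with `start`/`end` per exon in
#'   genome-forward coordinates.
#'
#' Coordinates are 1-based inclusive throughout (the GFF3 and Bioconductor
#' convention); BED/bedGraph writers convert on output.
#'
#' @param label genome label used in reports and family tables.
#' @param chromosomes tibble as described above (`length` is filled in).
#' @param genes tibble as described above; missing optional columns are added.
#' @param validate logical; run [validate_genome()] checks.
#' @param min_orf_codons warn when a protein/ORF gene is shorter than this
#'   many codons (the >=50 aa annotation convention); `NULL` disables.
#' @return an object of class `nm_genome`.
#' @export
nm_genome <- function(label, chromosomes, genes = NULL, validate = TRUE,
                      min_orf_codons = 50) {
  chromosomes <- as_tibble(chromosomes)
  if (!"topology" %in% names(chromosomes)) chromosomes$topology <- "linear"
  chromosomes <- mutate(chromosomes,
                        sequence = str_to_upper(.data$sequence),
                        length = str_length(.data$sequence))
  if (is.null(genes) || nrow(as_tibble(genes)) == 0) {
    genes <- empty_gene_table()
  } else {
    genes <- as_tibble(genes)
    for (col in c("family_id", "product")) {
      if (!col %in% names(genes)) genes[[col]] <- NA_character_
    }
    if (!"category" %in% names(genes)) genes$category <- "unassigned"
    if (!"kind" %in% names(genes)) genes$kind <- "protein"
    genes$category[is.na(genes$category)] <- "unassigned"
    genes <- mutate(genes,
                    start = map_int(.data$exons, ~ as.integer(min(.x$start))),
                    end = map_int(.data$exons, ~ as.integer(max(.x$end))))
    if (!"short_orf" %in% names(genes)) genes$short_orf <- FALSE
  }
  g <- structure(list(label = label, chromosomes = chromosomes, genes = genes),
                 class = "nm_genome")
  if (validate) g <- validate_genome(g, min_orf_codons = min_orf_codons)
  g
}

empty_gene_table <- function() {
  tibble(gene_id = character(), chromosome = character(), strand = character(),
         start = integer(), end = integer(), kind = character(),
         category = character(), family_id = character(), product = character(),
         short_orf = logical(), exons = list())
}

#' @export
print.nm_genome <- function(x, ...) {
  cat("<nm_genome> ", x$label, "\n", sep = "")
  cat("  chromosomes: ", nrow(x$chromosomes),
      " (", format(sum(x$chromosomes$length), big.mark = ","), " bp)\n", sep = "")
  cat("  genes: ", nrow(x$genes), "\n", sep = "")
  invisible(x)
}

#' Validate an annotated genome
#'
#' Checks chromosome sequences are non-empty IUPAC DNA, gene chromosome
#' references resolve, gene ids are unique, exons are sorted, non-overlapping
#' and in bounds. A protein gene whose summed exon length is not divisible by
#' 3 is downgraded to `pseudogene` with a warning; protein/ORF genes shorter
#' than `min_orf_codons` codons get `short_orf = TRUE` with a warning.
#'
#' @param genome an `nm_genome`.
#' @inheritParams nm_genome
#' @return the (possibly adjusted) genome.
#' @export
validate_genome <- function(genome, min_orf_codons = 50) {
  ch <- genome$chromosomes
  if (any(ch$length == 0)) abort("chromosome with empty sequence")
  bad <- str_detect(ch$sequence, paste0("[^", paste(IUPAC_DNA, collapse = ""), "]"))
  if (any(bad)) abort(paste0("non-IUPAC characters in chromosome ", ch$name[bad][1]))
  genes <- genome$genes
  if (nrow(genes) == 0) return(genome)
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene ids")
  unresolved <- setdiff(genes$chromosome, ch$name)
  if (length(unresolved)) abort(paste0("gene references unknown chromosome: ",
                                       unresolved[1]))
  len_by_chr <- stats::setNames(ch$length, ch$name)
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (is.unsorted(ex$start) || any(ex$end < ex$start) ||
        (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))) {
      abort(paste0("exons of ", genes$gene_id[i], " unsorted or overlapping"))
    }
    if (min(ex$start) < 1 || max(ex$end) > len_by_chr[[genes$chromosome[i]]]) {
      abort(paste0("exon outside chromosome bounds for ", genes$gene_id[i]))
    }
  }
  cds_len <- map_int(genes$exons, ~ as.integer(sum(.x$end - .x$start + 1L)))
  frame_bad <- genes$kind == "protein" & cds_len %% 3L != 0L
  if (any(frame_bad)) {
    warn(paste0(sum(frame_bad), " protein gene(s) with CDS length not divisible",
                " by 3 downgraded to pseudogene: ",
                paste(utils::head(genes$gene_id[frame_bad], 3), collapse = ", ")))
    genes$kind[frame_bad] <- "pseudogene"
  }
  if (!is.null(min_orf_codons)) {
    short <- genes$kind %in% c("protein", "orf") &
      cds_len < 3L * min_orf_codons
    if (any(short)) {
      warn(paste0(sum(short), " gene(s) shorter than ", min_orf_codons,
                  " codons flagged short_orf"))
    }
    genes$short_orf <- genes$short_orf | short
  }
  genome$genes <- genes
  genome
}

#' Read a genome from FASTA + GFF3
#'
#' GFF3 `gene` features carry attributes `ID`, and optionally `kind`,
#' `category`, `family` and `product`; exon structure comes from `CDS`
#' features linked by `Parent`. A gene with no CDS children is treated as
#' single-exon over its own extent. Functional categories are read from the
#' `category` attribute only (default `unassigned`); they are never inferred.
#'
#' @param fasta_path path to a (multi-)FASTA file of chromosome sequences.
#' @param gff3_path path to a GFF3 annotation file.
#' @param label genome label; defaults to the FASTA file stem.
#' @inheritParams nm_genome
#' @return an `nm_genome`.
#' @export
read_genome <- function(fasta_path, gff3_path, label = NULL, validate = TRUE,
                        min_orf_codons = 50) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  chromosomes <- tibble(name = names(seqs),
                        sequence = as.character(seqs),
                        topology = "linear")
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  meta <- as_tibble(as.data.frame(gff))
  meta$seqnames <- as.character(meta$seqnames)
  meta$strand <- as.character(meta$strand)
  gene_rows <- filter(meta, .data$type == "gene")
  cds_rows <- filter(meta, .data$type == "CDS")
  if (nrow(cds_rows) > 0) {
    cds_rows$parent <- map_chr(cds_rows$Parent, ~ if (length(.x)) .x[[1]] else NA_character_)
  }
  genes <- pmap(gene_rows, function(...) NULL)
  genes <- map(seq_len(nrow(gene_rows)), function(i) {
    row <- gene_rows[i, ]
    id <- row$ID
    ex <- if (nrow(cds_rows) > 0) filter(cds_rows, .data$parent == id) else cds_rows
    exons <- if (nrow(ex) > 0) {
      arrange(tibble(start = as.integer(ex$start), end = as.integer(ex$end)), .data$start)
    } else {
      tibble(start = as.integer(row$start), end = as.integer(row$end))
    }
    tibble(gene_id = id, chromosome = row$seqnames,
           strand = if (row$strand %in% c("+", "-")) row$strand else "+",
           kind = attr_or(row, "kind", "protein"),
           category = attr_or(row, "category", "unassigned"),
           family_id = attr_or(row, "family", NA_character_),
           product = attr_or(row, "product", NA_character_),
           exons = list(exons))
  })
  genes <- bind_rows(genes)
  nm_genome(label %||% sub("\\.[^.]*$", "", basename(fasta_path)),
            chromosomes, genes, validate = validate,
            min_orf_codons = min_orf_codons)
}

attr_or <- function(row, name, default) {
  if (!name %in% names(row)) return(default)
  v <- row[[name]]
  if (is.list(v)) v <- if (length(v[[1]])) v[[1]][[1]] else NA
  if (is.na(v)) default else as.character(v)
}

#' Write a genome to FASTA + GFF3
#'
#' FASTA is wrapped at 60 columns; the GFF3 carries one `gene` feature per
#' gene (attributes `ID`, `kind`, `category`, `family`, `product`) and one
#' `CDS` feature per exon with a `Parent` link. [read_genome()] of the output
#' reproduces the genome exactly.
#'
#' @param genome an `nm_genome`.
#' @param fasta_path,gff3_path output paths.
#' @return the input genome, invisibly.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  seqs <- Biostrings::DNAStringSet(genome$chromosomes$sequence)
  names(seqs) <- genome$chromosomes$name
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60)
  genes <- genome$genes
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genome$chromosomes))) {
    lines <- c(lines, paste("##sequence-region", genome$chromosomes$name[i],
                            1, genome$chromosomes$length[i]))
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrs <- paste0("ID=", g$gene_id, ";kind=", g$kind, ";category=", g$category)
    if (!is.na(g$family_id)) attrs <- paste0(attrs, ";family=", g$family_id)
    if (!is.na(g$product)) attrs <- paste0(attrs, ";product=", g$product)
    lines <- c(lines,
               paste(g$chromosome, "nucleomorphr", "gene", g$start, g$end, ".",
                     g$strand, ".", attrs, sep = "\t"))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
                 paste(g$chromosome, "nucleomorphr", "CDS", ex$start[j], ex$end[j],
                       ".", g$strand, "0",
                       paste0("ID=", g$gene_id, ".cds", j, ";Parent=", g$gene_id),
                       sep = "\t"))
    }
  }
  writeLines(lines, gff3_path)
  invisible(genome)
}

chromosome_seq <- function(genome, name) {
  genome$chromosomes$sequence[match(name, genome$chromosomes$name)]
}

# spliced gene sequence in transcript orientation
gene_transcript_seq <- function(genome, gene_row) {
  chrom <- chromosome_seq(genome, gene_row$chromosome)
  ex <- gene_row$exons[[1]]
  s <- paste(str_sub(chrom, ex$start, ex$end), collapse = "")
  if (gene_row$strand == "-") s <- revcomp(s)
  s
}

#' Protein sequences of a genome's coding genes
#'
#' Translates spliced CDS sequences (standard genetic code; minus-strand genes
#' are reverse-complemented first). A trailing stop is removed; internal stops
#' are reported as `*`.
#'
#' @param genome an `nm_genome`.
#' @param kinds gene kinds to translate.
#' @return tibble with `gene_id`, `family_id`, `category`, `protein`, `length`
#'   (amino acids, stop excluded).
#' @export
protein_sequences <- function(genome, kinds = c("protein", "orf")) {
  genes <- filter(genome$genes, .data$kind %in% kinds)
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), family_id = character(),
                  category = character(), protein = character(),
                  length = integer()))
  }
  cds <- map_chr(seq_len(nrow(genes)),
                 function(i) gene_transcript_seq(genome, genes[i, ]))
  cds <- str_sub(cds, 1, 3 * (str_length(cds) %/% 3))
  prot <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                             if.fuzzy.codon = "X"))
  prot <- sub("\\*$", "", prot)
  tibble(gene_id = genes$gene_id, family_id = genes$family_id,
         category = genes$category, protein = prot,
         length = str_length(prot))
}

#' Whole-genome summary statistics
#'
#' Mirrors the genome-level summary table of nucleomorph genome reports:
#' total and per-chromosome sizes, overall GC (and GC excluding a supplied
#' region set, e.g. sub-telomeric repeats), gene counts by kind, intron count,
#' mean intergenic spacer and gene density.
#'
#' @param genome an `nm_genome`.
#' @param exclude_regions optional tibble (`chromosome`, `start`, `end`,
#'   1-based inclusive) whose complement is used for `gc_excluding`.
#' @param nonredundant logical; also collapse near-identical proteins via
#'   [collapse_redundant()] to report a non-redundant gene count (slower).
#' @return a one-row tibble; `chromosome_sizes` is a list-column.
#' @export
genome_summary <- function(genome, exclude_regions = NULL, nonredundant = FALSE) {
  ch <- genome$chromosomes
  total <- sum(ch$length)
  gc_all <- if (total > 0) gc_fraction(ch$sequence) else NA_real_
  gc_ex <- NA_real_
  if (!is.null(exclude_regions) && nrow(exclude_regions) > 0 && total > 0) {
    gc_ex <- region_gc_genome(genome, exclude_regions)$gc_outside
  }
  genes <- genome$genes
  n_introns <- if (nrow(genes) > 0) sum(map_int(genes$exons, nrow) - 1L) else 0L
  spacers <- if (nrow(genes) >= 2) intergenic_spacers(genome) else NULL
  n_nr <- NA_integer_
  if (nonredundant && nrow(genes) > 0) {
    n_nr <- attr(collapse_redundant(genome), "n_nonredundant")
  }
  tibble(label = genome$label,
         total_size = total,
         n_chromosomes = nrow(ch),
         chromosome_sizes = list(stats::setNames(ch$length, ch$name)),
         gc_overall = gc_all,
         gc_excluding = gc_ex,
         n_genes = nrow(genes),
         n_protein_genes = sum(genes$kind == "protein"),
         n_orf_genes = sum(genes$kind == "orf"),
         n_trna_genes = sum(genes$kind == "tRNA"),
         n_rrna_genes = sum(genes$kind == "rRNA"),
         n_nonredundant_genes = n_nr,
         n_introns = n_introns,
         mean_spacer = if (is.null(spacers)) NA_real_ else attr(spacers, "mean"),
         gene_density = if (total > 0) nrow(genes) / (total / 1000) else NA_real_)
}
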