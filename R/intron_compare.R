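#' Compare intron positions between orthologous genes
#'
#' For each ortholog family with protein members in both genomes, the two
#' proteins are globally aligned and every intron is mapped to an alignment
#' column via its host residue: for phase 1/2 introns the residue whose codon
#' contains the intron; for phase 0 (between-codon) introns the preceding
#' residue. An intron is *comparable* when the `flank_residues` alignment
#' columns on both sides of that column are gap-free in both sequences and
#' each flanking window has more than `flank_identity` identical columns
#' (the Roy-Penny comparability filter). Two comparable introns are *shared*
#' when they sit in the same alignment column with the same phase.
#'
#' @param genome_a,genome_b `nm_genome` objects.
#' @param families ortholog family table (`family_id`, `genome`, `gene_id`);
#'   families with one protein member per genome are compared (multicopy
#'   families are represented by their longest member, with a warning).
#' @param flank_residues flank window width (alignment columns) on each side.
#' @param flank_identity minimum window identity (strict inequality).
#' @param min_alignment_identity pairs aligning below this overall identity
#'   are skipped with a warning.
#' @param introns_a,introns_b optional pre-computed catalogues from
#'   [catalog_introns()].
#' @return a tibble of class `nm_intron_comparison`: `family_id`, `genome`,
#'   `gene_id`, `intron_index`, `column`, `phase`, `comparable`, `status`
#'   (`shared`/`unique`/`not_comparable`), `partner` (row genome label +
#'   intron index of the shared partner, `NA` otherwise). Summary counts in
#'   `attr(, "summary")`.
#' @export
compare_intron_positions <- function(genome_a, genome_b, families,
                                     flank_residues = 15, flank_identity = 0.5,
                                     min_alignment_identity = 0.2,
                                     introns_a = NULL, introns_b = NULL) {
  la <- genome_a$label; lb <- genome_b$label
  if (identical(la, lb)) { la <- paste0(la, ".A"); lb <- paste0(lb, ".B") }
  prot_a <- protein_sequences(genome_a)
  prot_b <- protein_sequences(genome_b)
  introns_a <- introns_a %||% catalog_introns(genome_a)
  introns_b <- introns_b %||% catalog_introns(genome_b)
  fams <- families |>
    filter(.data$gene_id %in% c(prot_a$gene_id, prot_b$gene_id)) |>
    distinct(.data$family_id, .data$genome, .data$gene_id)
  shared_fams <- fams |>
    distinct(.data$family_id, .data$genome) |>
    count(.data$family_id) |>
    filter(.data$n >= 2)
  rows <- list()
  skipped <- 0L
  for (fid in shared_fams$family_id) {
    ga <- pick_representative(fams, fid, genome_a$label, prot_a)
    gb <- pick_representative(fams, fid, genome_b$label, prot_b)
    if (is.null(ga) || is.null(gb)) next
    aln <- align_proteins(ga$protein, gb$protein)
    if (aln$percent_identity < min_alignment_identity) {
      skipped <- skipped + 1L
      next
    }
    ia <- filter(introns_a, .data$gene_id == ga$gene_id, .data$valid)
    ib <- filter(introns_b, .data$gene_id == gb$gene_id, .data$valid)
    ra <- map_introns_to_columns(ia, aln, which = "a", flank_residues, flank_identity)
    rb <- map_introns_to_columns(ib, aln, which = "b", flank_residues, flank_identity)
    # pair shared introns: same column, same phase, both comparable
    ra$status <- as.character(ifelse(ra$comparable, "unique", "not_comparable"))
    rb$status <- as.character(ifelse(rb$comparable, "unique", "not_comparable"))
    ra$partner <- NA_character_
    rb$partner <- NA_character_
    if (nrow(ra) && nrow(rb)) {
      for (i in seq_len(nrow(ra))) {
        if (!ra$comparable[i]) next
        j <- which(rb$comparable & rb$column == ra$column[i] &
                     rb$phase == ra$phase[i] & is.na(rb$partner))
        if (length(j)) {
          j <- j[1]
          ra$status[i] <- "shared"; rb$status[j] <- "shared"
          ra$partner[i] <- paste0(lb, ":", rb$intron_index[j])
          rb$partner[j] <- paste0(la, ":", ra$intron_index[i])
        }
      }
    }
    ra$genome <- la; ra$gene_id <- ga$gene_id; ra$family_id <- fid
    rb$genome <- lb; rb$gene_id <- gb$gene_id; rb$family_id <- fid
    rows[[length(rows) + 1]] <- bind_rows(ra, rb)
  }
  if (skipped > 0) warn(paste0(skipped, " family pair(s) below the alignment",
                               " identity floor skipped"))
  out <- if (length(rows)) bind_rows(rows) else
    tibble(intron_index = integer(), column = integer(), phase = integer(),
           comparable = logical(), status = character(), partner = character(),
           genome = character(), gene_id = character(), family_id = character())
  out <- select(out, "family_id", "genome", "gene_id", "intron_index",
                "column", "phase", "comparable", "status", "partner")
  attr(out, "summary") <- tibble(
    n_families_compared = length(unique(out$family_id)),
    n_comparable_a = sum(out$genome == la & out$comparable),
    n_comparable_b = sum(out$genome == lb & out$comparable),
    n_shared = sum(out$genome == la & out$status == "shared"))
  attr(out, "labels") <- c(a = la, b = lb)
  class(out) <- c("nm_intron_comparison", class(out))
  out
}

pick_representative <- function(fams, fid, label, prot) {
  ids <- fams$gene_id[fams$family_id == fid & fams$genome == label]
  p <- filter(prot, .data$gene_id %in% ids)
  if (nrow(p) == 0) return(NULL)
  if (nrow(p) > 1) {
    warn(paste0("family ", fid, " has ", nrow(p), " members in ", label,
                "; using the longest"))
    p <- slice_max(p, .data$length, n = 1, with_ties = FALSE)
  }
  p[1, ]
}

map_introns_to_columns <- function(introns, aln, which, flank_residues,
                                   flank_identity) {
  if (nrow(introns) == 0) {
    return(tibble(intron_index = integer(), column = integer(),
                  phase = integer(), comparable = logical()))
  }
  mp <- if (which == "a") aln$map_a else aln$map_b
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  ncol_aln <- length(ca)
  res <- map(seq_len(nrow(introns)), function(i) {
    d <- introns$donor_offset[i]
    phase <- introns$phase[i]
    residue <- if (phase == 0L) d %/% 3L else d %/% 3L + 1L
    col <- if (residue >= 1) match(residue, mp) else NA_integer_
    comparable <- FALSE
    if (!is.na(col)) {
      lw <- (col - flank_residues):(col - 1)
      rw <- (col + 1):(col + flank_residues)
      if (min(lw) >= 1 && max(rw) <= ncol_aln) {
        gapfree <- !any(ca[c(lw, rw)] == "-") && !any(cb[c(lw, rw)] == "-")
        if (gapfree) {
          id_l <- mean(ca[lw] == cb[lw])
          id_r <- mean(ca[rw] == cb[rw])
          comparable <- id_l > flank_identity && id_r > flank_identity
        }
      }
    }
    tibble(intron_index = introns$index[i], column = col,
           phase = phase, comparable = comparable)
  })
  bind_rows(res)
}

#' Polarize unshared introns with outgroup presence
#'
#' An intron position present in one ingroup genome and at least one outgroup
#' gene, but absent from the other ingroup genome, is inferred as a loss in
#' the lacking genome; positions absent from all outgroups stay ambiguous.
#'
#' @param comparison an `nm_intron_comparison`.
#' @param outgroup_presence tibble with `family_id`, `column`, `phase`,
#'   `outgroup`, `present` (logical), built with the same comparability
#'   filter (conventionally with a relaxed 40% identity variant).
#' @return tibble with `family_id`, `column`, `phase`, `present_in`, `call`
#'   (`loss-in-<label>` or `ambiguous`) for each unshared comparable position.
#' @export
polarize_introns <- function(comparison, outgroup_presence) {
  labs <- attr(comparison, "labels")
  uniq <- filter(comparison, .data$status == "unique")
  if (nrow(uniq) == 0) {
    return(tibble(family_id = character(), column = integer(), phase = integer(),
                  present_in = character(), call = character()))
  }
  out <- map(seq_len(nrow(uniq)), function(i) {
    r <- uniq[i, ]
    og <- filter(outgroup_presence, .data$family_id == r$family_id,
                 .data$column == r$column, .data$phase == r$phase,
                 .data$present)
    lacking <- if (r$genome == labs[["a"]]) labs[["b"]] else labs[["a"]]
    tibble(family_id = r$family_id, column = r$column, phase = r$phase,
           present_in = r$genome,
           call = if (nrow(og) > 0) paste0("loss-in-", lacking) else "ambiguous")
  })
  bind_rows(out)
}
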