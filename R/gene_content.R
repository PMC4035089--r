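#' Read / write ortholog family tables
#'
#' A family table is a tibble with columns `family_id`, `category`, `genome`,
#' `gene_id`: one row per gene placement. Homology assignment itself is an
#' input, not computed here.
#'
#' @param path TSV path with those four columns.
#' @return the family table tibble.
#' @export
read_family_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname read_family_table
#' @param families a family table.
#' @export
write_family_table <- function(families, path) {
  readr::write_tsv(families, path)
  invisible(path)
}

#' Pairwise gene-content overlap (Venn counts)
#'
#' A family counts as shared when it has members in both genomes (presence,
#' not copy number). Percentages are per side: shared families divided by
#' that genome's family total, so the two sides can differ.
#'
#' @param families family table.
#' @param label_a,label_b genome labels present in the table.
#' @param category optional category filter (character vector).
#' @return one-row tibble: `n_shared`, `n_unique_a`, `n_unique_b`,
#'   `total_a`, `total_b`, `pct_shared_a`, `pct_shared_b`.
#' @export
set_overlap <- function(families, label_a, label_b, category = NULL) {
  if (!label_a %in% families$genome) abort(paste0("unknown genome label: ", label_a))
  if (!label_b %in% families$genome) abort(paste0("unknown genome label: ", label_b))
  fams <- families
  if (!is.null(category)) fams <- filter(fams, .data$category %in% !!category)
  in_a <- unique(fams$family_id[fams$genome == label_a])
  in_b <- unique(fams$family_id[fams$genome == label_b])
  shared <- intersect(in_a, in_b)
  tibble(n_shared = length(shared),
         n_unique_a = length(setdiff(in_a, in_b)),
         n_unique_b = length(setdiff(in_b, in_a)),
         total_a = length(in_a), total_b = length(in_b),
         pct_shared_a = if (length(in_a)) 100 * length(shared) / length(in_a) else NA_real_,
         pct_shared_b = if (length(in_b)) 100 * length(shared) / length(in_b) else NA_real_)
}

#' Per-category overlap breakdown
#'
#' @inheritParams set_overlap
#' @return tibble with one row per category plus an `all` row.
#' @export
set_overlap_by_category <- function(families, label_a, label_b) {
  cats <- sort(unique(families$category))
  bind_rows(
    mutate(set_overlap(families, label_a, label_b), category = "all",
           .before = 1),
    bind_rows(map(cats, function(cc) {
      mutate(set_overlap(families, label_a, label_b, category = cc),
             category = cc, .before = 1)
    })))
}

#' Core gene set of a genome group
#'
#' The core set is the families present in *every* genome of the group after
#' removing excluded categories (plastid-associated and spliceosomal genes
#' are conventionally excluded when comparing nucleomorph cores across
#' lineages).
#'
#' @param families family table.
#' @param group character vector of genome labels.
#' @param exclude_categories categories removed before intersecting.
#' @return character vector of core family ids.
#' @export
core_set <- function(families, group,
                     exclude_categories = c("plastid-associated", "spliceosomal")) {
  fams <- filter(families, !.data$category %in% exclude_categories,
                 .data$genome %in% group)
  present <- fams |> distinct(.data$family_id, .data$genome) |>
    count(.data$family_id)
  sort(present$family_id[present$n == length(unique(group))])
}

#' Overlap of a core set with a second genome group
#'
#' @param core character vector of family ids (e.g. from [core_set()]).
#' @param families family table.
#' @param group_b labels of the partner group; a core family is shared when
#'   present in at least one of them.
#' @return one-row tibble: `n_core`, `n_shared`, `pct_shared`.
#' @export
core_overlap <- function(core, families, group_b) {
  if (length(core) == 0) {
    warn("empty core set; overlap is 0")
    return(tibble(n_core = 0L, n_shared = 0L, pct_shared = NA_real_))
  }
  in_b <- unique(families$family_id[families$genome %in% group_b])
  shared <- intersect(core, in_b)
  tibble(n_core = length(core), n_shared = length(shared),
         pct_shared = 100 * length(shared) / length(core))
}
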