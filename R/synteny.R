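#' Gene order of a genome over an ortholog family table
#'
#' @param genome an `nm_genome`.
#' @param families family table (`family_id`, `genome`, `gene_id`).
#' @param shared_only drop families private to this genome (present in no
#'   other genome of the table).
#' @return a tibble of class `nm_gene_order`: `chromosome`, `position`
#'   (rank by start within chromosome, over retained genes), `family_id`,
#'   `strand`, `gene_id`. Multicopy families keep every placement.
#' @export
gene_order <- function(genome, families, shared_only = FALSE) {
  fams <- filter(families, .data$genome == !!genome$label)
  if (shared_only) {
    other <- filter(families, .data$genome != !!genome$label)
    fams <- filter(fams, .data$family_id %in% other$family_id)
  }
  out <- genome$genes |>
    inner_join(select(fams, "family_id", "gene_id"), by = "gene_id",
               suffix = c(".anno", "")) |>
    arrange(.data$chromosome, .data$start) |>
    group_by(.data$chromosome) |>
    mutate(position = row_number()) |>
    ungroup() |>
    select("chromosome", "position", "family_id", "strand", "gene_id")
  class(out) <- c("nm_gene_order", class(out))
  out
}

#' Detect synteny blocks between two gene orders
#'
#' A synteny block is a maximal run of shared families appearing
#' consecutively (allowing at most `max_gap` intervening genes whose family
#' is absent from the partner genome) and in conserved order in both genomes;
#' inverted runs are reported when `allow_inversion`. Runs shorter than
#' `min_genes` are discarded. Each gene placement joins at most one block;
#' overlapping candidates are resolved greedily by length, then leftmost.
#'
#' @param order_a,order_b `nm_gene_order` tibbles over a common family
#'   universe.
#' @param min_genes minimum genes per reported block.
#' @param allow_inversion report order-reversed runs.
#' @param max_gap maximum number of unshared intervening genes tolerated
#'   within a run (0 = strictly consecutive).
#' @return a tibble of class `nm_synteny_blocks`: `block_id`, `chrom_a`,
#'   `chrom_b`, `orientation` (`same`/`inverted`), `n_genes`, `families`
#'   (list-column), `start_a`, `end_a`, `start_b`, `end_b` (gene positions).
#' @export
detect_synteny_blocks <- function(order_a, order_b, min_genes = 3,
                                  allow_inversion = TRUE, max_gap = 0) {
  fams_a <- unique(order_a$family_id)
  fams_b <- unique(order_b$family_id)
  shared <- intersect(fams_a, fams_b)
  A <- mutate(order_a, anchor = .data$family_id %in% shared, idx = row_number())
  B <- mutate(order_b, anchor = .data$family_id %in% shared, idx = row_number())
  cands <- list()
  Aanch <- filter(A, .data$anchor)
  Banch <- filter(B, .data$anchor)
  for (i in seq_len(nrow(Aanch))) {
    js <- which(Banch$family_id == Aanch$family_id[i])
    for (j in js) {
      for (dir in c(1L, if (allow_inversion) -1L else NULL)) {
        run <- extend_run(A, B, Aanch$idx[i], Banch$idx[j], dir, max_gap)
        if (length(run$a) >= min_genes) cands[[length(cands) + 1]] <- c(run, dir = dir)
      }
    }
  }
  empty <- tibble(block_id = integer(), chrom_a = character(), chrom_b = character(),
                  orientation = character(), n_genes = integer(), families = list(),
                  start_a = integer(), end_a = integer(),
                  start_b = integer(), end_b = integer())
  class(empty) <- c("nm_synteny_blocks", class(empty))
  if (length(cands) == 0) return(empty)
  # deduplicate identical runs, keep maximal ones, resolve greedily
  key <- map_chr(cands, ~ paste(paste(.x$a, collapse = ","),
                                paste(.x$b, collapse = ","), sep = "|"))
  cands <- cands[!duplicated(key)]
  lens <- map_int(cands, ~ length(.x$a))
  ord <- order(-lens, map_int(cands, ~ min(.x$a)), map_int(cands, ~ min(.x$b)))
  cands <- cands[ord]
  used_a <- rep(FALSE, nrow(A))
  used_b <- rep(FALSE, nrow(B))
  blocks <- list()
  for (cand in cands) {
    if (length(cand$a) < min_genes) next
    if (any(used_a[cand$a]) || any(used_b[cand$b])) next
    used_a[cand$a] <- TRUE
    used_b[cand$b] <- TRUE
    blocks[[length(blocks) + 1]] <- cand
  }
  if (length(blocks) == 0) return(empty)
  out <- bind_rows(map(seq_along(blocks), function(k) {
    bl <- blocks[[k]]
    tibble(block_id = k,
           chrom_a = A$chromosome[bl$a[1]],
           chrom_b = B$chromosome[bl$b[1]],
           orientation = if (bl$dir == 1L) "same" else "inverted",
           n_genes = length(bl$a),
           families = list(A$family_id[bl$a]),
           start_a = as.integer(min(A$position[bl$a])),
           end_a = as.integer(max(A$position[bl$a])),
           start_b = as.integer(min(B$position[bl$b])),
           end_b = as.integer(max(B$position[bl$b])))
  }))
  class(out) <- c("nm_synteny_blocks", class(out))
  out
}

# walk outward from a seed anchor pair in both directions along A,
# with B advancing by `dir`; gaps of non-anchor genes up to max_gap allowed
extend_run <- function(A, B, ia, jb, dir, max_gap) {
  run_a <- ia; run_b <- jb
  step <- function(tbl, pos, delta, chrom) {
    gaps <- 0
    p <- pos + delta
    while (p >= 1 && p <= nrow(tbl) && tbl$chromosome[p] == chrom) {
      if (tbl$anchor[p]) return(p)
      gaps <- gaps + 1
      if (gaps > max_gap) return(NA_integer_)
      p <- p + delta
    }
    NA_integer_
  }
  chrom_a <- A$chromosome[ia]; chrom_b <- B$chromosome[jb]
  # extend forward in A
  pa <- ia; pb <- jb
  repeat {
    na <- step(A, pa, 1L, chrom_a)
    nb <- step(B, pb, dir, chrom_b)
    if (is.na(na) || is.na(nb) || A$family_id[na] != B$family_id[nb]) break
    run_a <- c(run_a, na); run_b <- c(run_b, nb)
    pa <- na; pb <- nb
  }
  # extend backward in A
  pa <- ia; pb <- jb
  repeat {
    na <- step(A, pa, -1L, chrom_a)
    nb <- step(B, pb, -dir, chrom_b)
    if (is.na(na) || is.na(nb) || A$family_id[na] != B$family_id[nb]) break
    run_a <- c(na, run_a); run_b <- c(nb, run_b)
    pa <- na; pb <- nb
  }
  list(a = run_a, b = run_b)
}

#' Summaries over a set of synteny blocks
#'
#' @param blocks an `nm_synteny_blocks` tibble.
#' @return one-row tibble: `n_blocks`, `mean_genes`, `total_genes`.
#' @export
synteny_stats <- function(blocks) {
  tibble(n_blocks = nrow(blocks),
         mean_genes = if (nrow(blocks)) mean(blocks$n_genes) else NA_real_,
         total_genes = if (nrow(blocks)) sum(blocks$n_genes) else 0L)
}
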