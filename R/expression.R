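#' Coverage track container and bedGraph I/O
#'
#' A coverage track is a named list of non-negative numeric vectors, one per
#' chromosome, holding per-base depth. bedGraph intervals are 0-based
#' half-open on disk; overlapping intervals are an input error.
#'
#' @param depths named list of numeric vectors (names = chromosome names).
#' @return an object of class `nm_coverage`.
#' @export
coverage_track <- function(depths) {
  if (is.null(names(depths)) || any(!nzchar(names(depths)))) {
    abort("coverage track needs chromosome names")
  }
  if (any(unlist(depths, use.names = FALSE) < 0)) abort("negative depth")
  structure(depths, class = "nm_coverage")
}

#' @export
print.nm_coverage <- function(x, ...) {
  cat("<nm_coverage> ", length(x), " chromosome(s), ",
      format(sum(lengths(x)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' @rdname coverage_track
#' @param track an `nm_coverage`.
#' @param path bedGraph path.
#' @export
write_bedgraph <- function(track, path) {
  lines <- character()
  for (chrom in names(track)) {
    v <- track[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths          # already 0-based
    lines <- c(lines, paste(chrom, starts, ends, r$values, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname coverage_track
#' @param chrom_lengths named integer vector of chromosome lengths used to
#'   expand the intervals; positions not covered by an interval get depth 0.
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- as_tibble(as.data.frame(gr))
  out <- map(names(chrom_lengths), function(chrom) {
    v <- numeric(chrom_lengths[[chrom]])
    d <- filter(df, as.character(.data$seqnames) == chrom)
    if (nrow(d)) {
      covered <- logical(length(v))
      for (i in seq_len(nrow(d))) {
        idx <- d$start[i]:d$end[i]
        if (any(covered[idx])) abort("overlapping bedGraph intervals")
        covered[idx] <- TRUE
        v[idx] <- d$score[i]
      }
    }
    v
  })
  names(out) <- names(chrom_lengths)
  coverage_track(out)
}

#' Mean per-gene depth from a coverage track
#'
#' Mean depth is the per-base depth summed over the gene's positions (all
#' bases of the gene extent, or exonic bases only) divided by the number of
#' positions — coverage normalized for gene length.
#'
#' @param track an `nm_coverage` covering every gene's chromosome.
#' @param genome an `nm_genome`.
#' @param exonic_only use exonic positions only.
#' @return tibble with `gene_id`, `mean_depth`, `n_positions`, `zero_coverage`
#'   (TRUE iff every base is 0).
#' @export
gene_depth <- function(track, genome, exonic_only = FALSE) {
  genes <- genome$genes
  rows <- map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    v <- track[[g$chromosome]]
    if (is.null(v)) abort(paste0("no coverage for chromosome ", g$chromosome))
    if (g$end > length(v)) abort(paste0("gene ", g$gene_id, " beyond track extent"))
    pos <- if (exonic_only) {
      unlist(map2(g$exons[[1]]$start, g$exons[[1]]$end, seq))
    } else {
      g$start:g$end
    }
    d <- v[pos]
    tibble(gene_id = g$gene_id, mean_depth = mean(d),
           n_positions = length(pos), zero_coverage = all(d == 0))
  })
  bind_rows(rows)
}

#' Expression contrast between two gene groups
#'
#' @param depths output of [gene_depth()].
#' @param group_a,group_b character vectors of gene ids (both non-empty).
#' @return one-row tibble: `mean_a`, `mean_b`, `ratio` (A:B group mean
#'   ratio; `Inf` with `ratio_infinite = TRUE` when the B mean is 0),
#'   `n_zero_a`, `n_zero_b`.
#' @export
expression_contrast <- function(depths, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) abort("empty gene group")
  da <- filter(depths, .data$gene_id %in% group_a)
  db <- filter(depths, .data$gene_id %in% group_b)
  if (nrow(da) == 0 || nrow(db) == 0) abort("gene group absent from depth table")
  ma <- mean(da$mean_depth); mb <- mean(db$mean_depth)
  tibble(mean_a = ma, mean_b = mb,
         ratio = if (mb > 0) ma / mb else Inf,
         ratio_infinite = mb == 0,
         n_zero_a = sum(da$zero_coverage), n_zero_b = sum(db$zero_coverage))
}

#' Estimate copy number of a region from coverage depth
#'
#' When several near-identical repeat copies collapse onto one reference
#' copy, mapped depth over the collapsed region scales with copy number.
#' The estimate is the mean region depth divided by a single-copy baseline.
#'
#' @param track an `nm_coverage`.
#' @param region one-row tibble/list with `chromosome`, `start`, `end`.
#' @param baseline `"genome-median"` (median per-base depth over
#'   `single_copy_regions`, or over everything outside `region` when those
#'   are not given) or a positive number.
#' @param single_copy_regions optional tibble (`chromosome`, `start`, `end`)
#'   of known single-copy intervals for the baseline.
#' @param floor_report round the estimate down and report it as a lower
#'   bound (`at_least`).
#' @return one-row tibble: `region_depth`, `baseline_depth`, `copy_number`
#'   (and `at_least` when `floor_report`).
#' @export
estimate_copy_number <- function(track, region, baseline = "genome-median",
                                 single_copy_regions = NULL,
                                 floor_report = FALSE) {
  v <- track[[region$chromosome]]
  if (is.null(v) || region$end > length(v)) abort("region outside track")
  region_depth <- mean(v[region$start:region$end])
  if (is.numeric(baseline)) {
    base <- baseline
  } else {
    if (!is.null(single_copy_regions)) {
      vals <- unlist(map(seq_len(nrow(single_copy_regions)), function(i) {
        r <- single_copy_regions[i, ]
        track[[r$chromosome]][r$start:r$end]
      }))
    } else {
      vals <- unlist(map(names(track), function(chrom) {
        w <- track[[chrom]]
        if (chrom == region$chromosome) w <- w[-(region$start:region$end)]
        w
      }))
    }
    base <- stats::median(vals)
  }
  if (base == 0) abort("zero baseline depth")
  out <- tibble(region_depth = region_depth, baseline_depth = base,
                copy_number = region_depth / base)
  if (floor_report) out$at_least <- floor(out$copy_number)
  out
}
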