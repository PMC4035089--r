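#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_hline
#'   labs theme_minimal facet_wrap scale_y_continuous
#' @export
ggplot2::autoplot

#' Plot a sliding-window GC profile
#'
#' @param object an `nm_gc_profile` from [gc_profile()].
#' @param ... unused.
#' @return a ggplot: GC fraction along the sequence, with the whole-sequence
#'   mean as a dashed reference line.
#' @method autoplot nm_gc_profile
#' @export
autoplot.nm_gc_profile <- function(object, ...) {
  mid <- (object$start + object$end) / 2
  ggplot(mutate(object, mid = mid), aes(x = .data$mid, y = .data$gc)) +
    geom_line(colour = "firebrick") +
    geom_hline(yintercept = stats::weighted.mean(object$gc,
                                                 object$end - object$start + 1),
               linetype = "dashed", colour = "grey40") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "position (bp)", y = "GC fraction",
         title = paste0("GC profile (window ", attr(object, "window"), " bp)")) +
    theme_minimal()
}

#' Plot an intron size distribution
#'
#' @param object an `nm_intron_sizes` from [intron_size_distribution()].
#' @param ... unused.
#' @return a ggplot bar chart of intron counts per length.
#' @method autoplot nm_intron_sizes
#' @export
autoplot.nm_intron_sizes <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$length), y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "intron length (nt)", y = "introns",
         subtitle = paste0("n = ", attr(object, "n_total"),
                           ", max ", attr(object, "max_length"), " nt")) +
    theme_minimal()
}

#' Plot synteny blocks as paired position ranges
#'
#' @param object an `nm_synteny_blocks` from [detect_synteny_blocks()].
#' @param ... unused.
#' @return a ggplot of block extents in both genomes, faceted by chromosome
#'   pair.
#' @method autoplot nm_synteny_blocks
#' @export
autoplot.nm_synteny_blocks <- function(object, ...) {
  if (nrow(object) == 0) {
    return(ggplot() + labs(title = "no synteny blocks") + theme_minimal())
  }
  long <- bind_rows(
    tibble(block = object$block_id, genome = "A",
           start = object$start_a, end = object$end_a,
           pair = paste(object$chrom_a, object$chrom_b, sep = " / "),
           orientation = object$orientation),
    tibble(block = object$block_id, genome = "B",
           start = object$start_b, end = object$end_b,
           pair = paste(object$chrom_a, object$chrom_b, sep = " / "),
           orientation = object$orientation))
  ggplot(long, aes(x = .data$start, xend = .data$end,
                   y = factor(.data$block), yend = factor(.data$block),
                   colour = .data$orientation)) +
    ggplot2::geom_segment(linewidth = 3) +
    facet_wrap(~ pair + genome, scales = "free_x") +
    labs(x = "gene position (rank)", y = "block") +
    theme_minimal()
}
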