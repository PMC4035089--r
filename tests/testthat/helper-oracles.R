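# independent brute-force oracles, kept free of the implementation paths

# exhaustive affine-gap global alignment score by plain recursion
# (gap of length L costs open + L * ext; terminal gaps penalized)
oracle_align_score <- function(a, b, open = 10, ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  m <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, m[av[i], bv[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {
      cost <- if (prev == "ga") ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, "ga"))
    }
    if (j <= length(bv)) {
      cost <- if (prev == "gb") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, "gb"))
    }
    best
  }
  rec(1, 1, "m")
}

# best tandem unit length by direct autocorrelation matching
oracle_tandem_unit <- function(seq, unit_range) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  units <- seq(unit_range[1], min(unit_range[2], n %/% 2))
  frac <- vapply(units, function(u) {
    mean(chars[seq_len(n - u)] == chars[seq_len(n - u) + u])
  }, numeric(1))
  units[which(frac == max(frac))[1]]
}

# Welch statistic / df / p from the closed form
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# maximal common runs between two family sequences (no multicopy, one
# chromosome each), forward and reversed, greedy-resolved by length then
# leftmost — checked by direct window enumeration
oracle_common_runs <- function(va, vb, min_genes = 2, allow_inversion = TRUE) {
  runs <- list()
  is_run <- function(w) {
    hit <- match(w, vb)
    if (anyNA(hit)) return(NA)
    if (all(diff(hit) == 1)) return("same")
    if (allow_inversion && all(diff(hit) == -1)) return("inverted")
    NA
  }
  for (i in seq_along(va)) {
    for (j in i:length(va)) {
      if (j - i + 1 < min_genes) next
      w <- va[i:j]
      dir <- is_run(w)
      if (!is.na(dir)) {
        runs[[length(runs) + 1]] <- list(start = i, end = j, dir = dir)
      }
    }
  }
  if (!length(runs)) return(list())
  # maximality: drop runs contained in a longer run
  keep <- vapply(seq_along(runs), function(k) {
    !any(vapply(seq_along(runs), function(l) {
      l != k && runs[[l]]$start <= runs[[k]]$start && runs[[l]]$end >= runs[[k]]$end &&
        (runs[[l]]$end - runs[[l]]$start) > (runs[[k]]$end - runs[[k]]$start)
    }, logical(1)))
  }, logical(1))
  runs <- runs[keep]
  lens <- vapply(runs, function(r) r$end - r$start + 1L, integer(1))
  runs <- runs[order(-lens, vapply(runs, function(r) r$start, integer(1)))]
  used <- rep(FALSE, length(va))
  out <- list()
  for (r in runs) {
    idx <- r$start:r$end
    if (any(used[idx])) next
    used[idx] <- TRUE
    out[[length(out) + 1]] <- list(families = va[idx], dir = r$dir)
  }
  out
}

# per-gene mean depth by direct per-base summation
oracle_gene_depth <- function(track, genome) {
  genes <- genome$genes
  vapply(seq_len(nrow(genes)), function(i) {
    v <- track[[genes$chromosome[i]]]
    s <- 0
    for (p in genes$start[i]:genes$end[i]) s <- s + v[p]
    s / (genes$end[i] - genes$start[i] + 1)
  }, numeric(1))
}

# GC by direct character tabulation
oracle_gc <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  sum(chars %in% c("G", "C")) / length(chars)
}

# connected components of a symmetric adjacency matrix by repeated expansion
igraph_free_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- k
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      frontier <- nxt
    }
  }
  comp
}
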