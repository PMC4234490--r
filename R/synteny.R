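#' Chain anchor hits into synteny blocks
#'
#' Anchor hits are homologous gene pairs indexed by gene rank along
#' their chromosomes. Hits on the same chromosome pair are chained
#' greedily in rank order: a hit extends a chain when it lies within
#' `chain_gap_genes` ranks of the chain's last hit on both axes and
#' continues the chain's direction (collinear or antiparallel, fixed
#' by the chain's second hit); ranks must stay strictly monotonic on
#' both axes. Chains with fewer than `min_block_pairs` pairs are
#' discarded.
#'
#' @param hits data frame `gene_a`, `chrom_a`, `rank_a`, `gene_b`,
#'   `chrom_b`, `rank_b`, `score` (optional, default 1), `ks`
#'   (optional).
#' @param config a [pipeline_config()].
#' @return list of `SyntenyBlock`s; each is a list with `chrom_a`,
#'   `chrom_b`, `orientation`, `pairs` (data frame), `n_pairs`,
#'   `score`, `a_range`, `b_range` (rank intervals).
#' @export
chain_hits <- function(hits, config = NULL) {
  config <- as_config(config)
  if (is.null(hits$score)) hits$score <- 1
  hits <- hits[!duplicated(hits[c("gene_a", "gene_b")]), , drop = FALSE]
  blocks <- list()
  for (key in unique(paste(hits$chrom_a, hits$chrom_b, sep = "\r"))) {
    h <- hits[paste(hits$chrom_a, hits$chrom_b, sep = "\r") == key, ,
              drop = FALSE]
    h <- h[order(h$rank_a, h$rank_b), , drop = FALSE]
    chains <- list() # each: list(rows = indices, dir = 0/+1/-1)
    for (i in seq_len(nrow(h))) {
      best <- 0L; best_d <- Inf
      for (ci in seq_along(chains)) {
        ch <- chains[[ci]]
        j <- ch$rows[[length(ch$rows)]]
        da <- h$rank_a[[i]] - h$rank_a[[j]]
        db <- h$rank_b[[i]] - h$rank_b[[j]]
        if (da <= 0 || da > config$chain_gap_genes) next
        if (abs(db) > config$chain_gap_genes || db == 0) next
        dir <- sign(db)
        if (ch$dir != 0 && dir != ch$dir) next
        d <- da + abs(db)
        if (d < best_d) { best <- ci; best_d <- d }
      }
      if (best > 0) {
        ch <- chains[[best]]
        j <- ch$rows[[length(ch$rows)]]
        ch$dir <- sign(h$rank_b[[i]] - h$rank_b[[j]])
        ch$rows <- c(ch$rows, i)
        chains[[best]] <- ch
      } else {
        chains[[length(chains) + 1L]] <- list(rows = i, dir = 0L)
      }
    }
    for (ch in chains) {
      if (length(ch$rows) < config$min_block_pairs) next
      rows <- h[ch$rows, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- list(
        chrom_a = rows$chrom_a[[1]], chrom_b = rows$chrom_b[[1]],
        orientation = if (ch$dir >= 0) "collinear" else "antiparallel",
        pairs = rows, n_pairs = nrow(rows), score = nrow(rows),
        a_range = range(rows$rank_a), b_range = range(rows$rank_b))
    }
  }
  blocks
}

blocks_conflict <- function(b1, b2) {
  (b1$chrom_a == b2$chrom_a &&
     b1$a_range[[1]] <= b2$a_range[[2]] &&
     b2$a_range[[1]] <= b1$a_range[[2]]) ||
    (b1$chrom_b == b2$chrom_b &&
       b1$b_range[[1]] <= b2$b_range[[2]] &&
       b2$b_range[[1]] <= b1$b_range[[2]])
}

## exact max-weight independent set by branch and bound on one
## connected conflict component
mwis_exact <- function(conflict, weights) {
  n <- length(weights)
  best <- list(score = -Inf, sel = integer(0))
  ord <- order(-weights)
  suffix <- rev(cumsum(rev(weights[ord])))
  recurse <- function(k, sel, score) {
    if (score > best$score) best <<- list(score = score, sel = sel)
    if (k > n) return()
    if (score + suffix[[k]] <= best$score) return()
    i <- ord[[k]]
    if (!any(conflict[i, sel])) recurse(k + 1L, c(sel, i),
                                        score + weights[[i]])
    recurse(k + 1L, sel, score)
  }
  recurse(1L, integer(0), 0)
  best
}

#' Filter synteny blocks to a 1:1 syntenic depth
#'
#' Selects the maximum-total-score subset of blocks such that no two
#' selected blocks overlap in their genome-A rank interval (on the
#' same chromosome) or their genome-B rank interval — i.e. no block
#' overlaps another vertically or horizontally on the dot plot,
#' isolating a single duplication layer. The search is exact (branch
#' and bound per connected conflict component) up to
#' `exact_limit` blocks per component; larger components fall back to
#' greedy-by-score with verification and are flagged approximate.
#'
#' @param blocks list from [chain_hits()].
#' @param exact_limit component size up to which the search is exact.
#' @return list with `blocks` (selected), `total_score` and `exact`
#'   (logical: all components solved exactly).
#' @export
quota_filter_1to1 <- function(blocks, exact_limit = 30L) {
  n <- length(blocks)
  if (!n) return(list(blocks = list(), total_score = 0, exact = TRUE))
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && blocks_conflict(blocks[[i]], blocks[[j]]))
      conflict[i, j] <- conflict[j, i] <- TRUE
  }
  weights <- vapply(blocks, `[[`, numeric(1), "score")
  ## connected components of the conflict graph
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[[s]])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- cid
      queue <- c(queue, which(conflict[v, ] & is.na(comp)))
    }
  }
  sel <- integer(0); exact <- TRUE
  for (c0 in seq_len(cid)) {
    idx <- which(comp == c0)
    if (length(idx) == 1) { sel <- c(sel, idx); next }
    if (length(idx) <= exact_limit) {
      r <- mwis_exact(conflict[idx, idx, drop = FALSE], weights[idx])
      sel <- c(sel, idx[r$sel])
    } else {
      exact <- FALSE
      ord <- idx[order(-weights[idx])]
      chosen <- integer(0)
      for (i in ord) {
        if (!any(conflict[i, chosen])) chosen <- c(chosen, i)
      }
      sel <- c(sel, chosen)
    }
  }
  sel <- sort(sel)
  list(blocks = blocks[sel], total_score = sum(weights[sel]),
       exact = exact)
}

#' Summarize a set of synteny blocks
#'
#' @param blocks list of synteny blocks.
#' @return list with `n_blocks`, `n_pairs`, `mean_pairs` (rounded to
#'   the nearest integer), `largest_block_pairs` and `by_chrom_pair`
#'   (data frame inventory).
#' @export
block_summary <- function(blocks) {
  if (!length(blocks))
    return(list(n_blocks = 0L, n_pairs = 0L, mean_pairs = 0L,
                largest_block_pairs = 0L,
                by_chrom_pair = data.frame()))
  np <- vapply(blocks, `[[`, numeric(1), "n_pairs")
  key <- vapply(blocks, function(b) paste(b$chrom_a, b$chrom_b),
                character(1))
  inv <- aggregate(list(n_blocks = np), by = list(chrom_pair = key),
                   FUN = length)
  inv$n_pairs <- as.integer(
    aggregate(list(x = np), by = list(k = key), FUN = sum)$x)
  list(n_blocks = length(blocks), n_pairs = as.integer(sum(np)),
       mean_pairs = as.integer(round(mean(np))),
       largest_block_pairs = as.integer(max(np)),
       by_chrom_pair = inv)
}

#' Histogram of synonymous divergence (Ks) over anchor pairs
#'
#' Bins Ks into half-open bins of width `ks_bin` and reports the
#' proportion of pairs per bin (summing to one over non-missing
#' values), the modal bin and its midpoint.
#'
#' @param ks numeric vector of Ks values (NA allowed).
#' @param config a [pipeline_config()].
#' @return list with `table` (data frame `bin_start`, `bin_mid`,
#'   `count`, `proportion`), `mode_bin_start`, `mode_mid`.
#' @export
ks_histogram <- function(ks, config = NULL) {
  config <- as_config(config)
  ks <- ks[!is.na(ks)]
  if (!length(ks)) stop("no non-missing Ks values", call. = FALSE)
  if (any(ks < 0)) stop("Ks must be non-negative", call. = FALSE)
  w <- config$ks_bin
  bin <- floor(ks / w)
  tab <- table(bin)
  bin_start <- as.integer(names(tab)) * w
  out <- data.frame(bin_start = bin_start,
                    bin_mid = bin_start + w / 2,
                    count = as.integer(tab),
                    proportion = as.integer(tab) / length(ks))
  mode_i <- which.max(out$count)
  list(table = out, mode_bin_start = out$bin_start[[mode_i]],
       mode_mid = out$bin_mid[[mode_i]])
}

#' Local maxima of a Ks histogram
#'
#' Finds bins whose count exceeds both neighbours (over the filled
#' 0..max bin grid), useful for locating mixture components such as a
#' speciation peak and a whole-genome-duplication peak.
#'
#' @param hist result of [ks_histogram()].
#' @param min_prop ignore maxima below this proportion.
#' @return data frame of local-maximum bins.
#' @export
ks_local_maxima <- function(hist, min_prop = 0.01) {
  tab <- hist$table
  step <- round(2 * (tab$bin_mid[[1]] - tab$bin_start[[1]]), 10)
  k <- as.integer(round(tab$bin_start / step))
  n <- max(k) + 1L
  grid <- (seq_len(n) - 1L) * step
  counts <- rep(0L, n)
  counts[k + 1L] <- tab$count
  ismax <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) counts[[i - 1]] else -1
    right <- if (i < n) counts[[i + 1]] else -1
    counts[[i]] > left && counts[[i]] > right
  }, logical(1))
  sel <- which(ismax & counts / sum(counts) >= min_prop)
  data.frame(bin_start = grid[sel], bin_mid = grid[sel] + step / 2,
             count = as.integer(counts[sel]),
             proportion = as.numeric(counts[sel] / sum(counts)))
}
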