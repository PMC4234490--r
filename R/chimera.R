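#' Discordance flag threshold for adjacent segregation patterns
#'
#' Adjacent markers are flagged when their segregation patterns differ
#' in strictly more than 10 percent of the mapping individuals; the
#' count threshold is `ceiling(frac * n)` (14 individuals for a
#' population of 139).
#'
#' @param n_individuals number of mapping individuals.
#' @param frac discordance fraction (default 0.10).
#' @return integer threshold; a pair is flagged when its discordance
#'   count exceeds this value.
#' @export
#' @examples
#' discordance_threshold(139) # 14
discordance_threshold <- function(n_individuals, frac = 0.10) {
  as.integer(ceiling(frac * n_individuals))
}

breakpoint_table <- function(scaffold_id = character(0),
                             start = integer(0), end = integer(0),
                             source = character(0),
                             support = character(0)) {
  data.frame(scaffold_id = scaffold_id, start = as.integer(start),
             end = as.integer(end), source = source,
             support = as.character(support), stringsAsFactors = FALSE)
}

#' Genetic-map breakpoints from segregation discordance
#'
#' For each pair of adjacent markers on a scaffold, the discordance is
#' the number of individuals with non-missing, unequal calls at the
#' two markers. Pairs whose discordance exceeds
#' [discordance_threshold()] are flagged; runs of consecutive flagged
#' pairs are merged into one breakpoint interval spanning from the
#' leftmost flagged marker to the rightmost.
#'
#' @param gm a `GenotypeMatrix` (markers sorted by position).
#' @param config a [pipeline_config()].
#' @return breakpoint data frame (`scaffold_id`, `start`, `end`,
#'   `source = "gbs"`, `support` = max discordance in the run).
#' @export
gbs_breakpoints <- function(gm, config = NULL) {
  config <- as_config(config)
  thr <- discordance_threshold(length(gm$individuals),
                               config$discord_frac)
  out <- list()
  for (sc in unique(gm$markers$scaffold_id)) {
    rows <- which(gm$markers$scaffold_id == sc)
    if (length(rows) < 2) next
    calls <- gm$calls[rows, , drop = FALSE]
    pos <- gm$markers$position[rows]
    disc <- integer(length(rows) - 1L)
    for (i in seq_len(length(rows) - 1L)) {
      a <- calls[i, ]; b <- calls[i + 1L, ]
      ok <- a != "-" & b != "-"
      disc[[i]] <- sum(ok & a != b)
    }
    flagged <- disc > thr
    if (!any(flagged)) next
    r <- rle(flagged)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- starts[[k]]; i2 <- ends[[k]]
      out[[length(out) + 1L]] <-
        breakpoint_table(sc, pos[[i1]], pos[[i2 + 1L]], "gbs",
                         max(disc[i1:i2]))
    }
  }
  if (!length(out)) return(breakpoint_table())
  do.call(rbind, out)
}

#' Placement breakpoints within chimeric scaffolds
#'
#' A scaffold placed on two or more chromosomes is chimeric; each
#' change-point between scaffold-coordinate-sorted placements of
#' different chromosomes yields one breakpoint whose interval is the
#' unplaced region between the two placements (a zero-length point at
#' the midpoint when they abut).
#'
#' @param placements placement data frame (see [read_tsv_tables()]).
#' @return breakpoint data frame with `source = "placement"`.
#' @export
placement_breakpoints <- function(placements) {
  out <- list()
  for (sc in unique(placements$scaffold_id)) {
    p <- placements[placements$scaffold_id == sc, , drop = FALSE]
    p <- p[order(p$scaffold_start), , drop = FALSE]
    if (length(unique(p$chrom_id)) < 2) next
    for (i in seq_len(nrow(p) - 1L)) {
      if (p$chrom_id[[i]] == p$chrom_id[[i + 1L]]) next
      s <- p$scaffold_end[[i]]
      e <- p$scaffold_start[[i + 1L]]
      if (e < s)
        stop("placements on different chromosomes overlap on scaffold ",
             sc, call. = FALSE)
      if (e == s) { s <- e } # zero-length point at the junction
      out[[length(out) + 1L]] <-
        breakpoint_table(sc, s, e, "placement",
                         paste0(p$chrom_id[[i]], "|", p$chrom_id[[i + 1L]]))
    }
  }
  if (!length(out)) return(breakpoint_table())
  do.call(rbind, out)
}

interval_dist <- function(s1, e1, s2, e2) {
  if (e1 >= s2 && e2 >= s1) return(0L) # overlap or touch
  if (s2 > e1) s2 - e1 else s1 - e2
}

#' Consensus breakpoints supported by both evidence types
#'
#' Pairs genetic-map breakpoints with placement breakpoints on the
#' same scaffold when their intervals overlap or lie within
#' `consensus_tol`. Pairing is greedy by increasing distance and each
#' input breakpoint is used at most once. The consensus interval is
#' the intersection of overlapping intervals, or the hull spanning the
#' gap when they only fall within tolerance.
#'
#' @param gbs_bps,placement_bps breakpoint data frames.
#' @param config a [pipeline_config()].
#' @return breakpoint data frame with `source = "consensus"`.
#' @export
consensus_breakpoints <- function(gbs_bps, placement_bps, config = NULL) {
  config <- as_config(config)
  if (!nrow(gbs_bps) || !nrow(placement_bps)) return(breakpoint_table())
  cand <- list()
  for (i in seq_len(nrow(gbs_bps))) {
    for (j in seq_len(nrow(placement_bps))) {
      if (gbs_bps$scaffold_id[[i]] != placement_bps$scaffold_id[[j]])
        next
      d <- interval_dist(gbs_bps$start[[i]], gbs_bps$end[[i]],
                         placement_bps$start[[j]], placement_bps$end[[j]])
      if (d <= config$consensus_tol)
        cand[[length(cand) + 1L]] <- c(i = i, j = j, d = d)
    }
  }
  if (!length(cand)) return(breakpoint_table())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "d"]), , drop = FALSE]
  used_i <- used_j <- integer(0)
  out <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, "i"]; j <- cand[k, "j"]
    if (i %in% used_i || j %in% used_j) next
    used_i <- c(used_i, i); used_j <- c(used_j, j)
    s <- max(gbs_bps$start[[i]], placement_bps$start[[j]])
    e <- min(gbs_bps$end[[i]], placement_bps$end[[j]])
    if (s > e) { # within tolerance but disjoint: span the gap
      s2 <- min(gbs_bps$end[[i]], placement_bps$end[[j]])
      e2 <- max(gbs_bps$start[[i]], placement_bps$start[[j]])
      s <- s2; e <- e2
    }
    out[[length(out) + 1L]] <-
      breakpoint_table(gbs_bps$scaffold_id[[i]], s, e, "consensus",
                       paste0("gbs=", gbs_bps$support[[i]],
                              ";placement=", placement_bps$support[[j]]))
  }
  do.call(rbind, out)
}

#' Split scaffolds at consensus breakpoints
#'
#' Each scaffold is split at every consensus breakpoint. The split
#' point is the midpoint of an N-gap lying inside the breakpoint
#' interval when one exists (the whole gap is dropped, so no junction
#' base is fabricated); otherwise the interval midpoint. Children are
#' named `<scaffold>_1 .. _k` left to right and all edits are logged.
#'
#' @param set `ScaffoldSet` to split.
#' @param bps consensus breakpoint data frame.
#' @param config a [pipeline_config()].
#' @return list with `set` (new `ScaffoldSet`) and `edits`
#'   (`edit_log`).
#' @export
split_scaffolds <- function(set, bps, config = NULL) {
  config <- as_config(config)
  seqs <- set$seqs
  out_seqs <- character(0)
  edits <- list()
  for (id in names(seqs)) {
    my <- bps[bps$scaffold_id == id, , drop = FALSE]
    if (!nrow(my)) {
      out_seqs[[id]] <- seqs[[id]]
      next
    }
    len <- nchar(seqs[[id]])
    if (any(my$start < 0) || any(my$end > len))
      stop("breakpoint interval outside scaffold ", id, call. = FALSE)
    gaps <- set$gaps[set$gaps$record_id == id &
                       set$gaps$n_count >= config$min_gap_len, ,
                     drop = FALSE]
    cuts <- list()
    for (b in seq_len(nrow(my))) {
      s <- my$start[[b]]; e <- my$end[[b]]
      mid <- (s + e) %/% 2L
      inside <- gaps[gaps$start >= s & gaps$end <= e, , drop = FALSE]
      if (nrow(inside)) {
        gm <- (inside$start + inside$end) %/% 2L
        pick <- which.min(abs(gm - mid))
        cuts[[b]] <- c(inside$start[[pick]], inside$end[[pick]])
      } else {
        cuts[[b]] <- c(mid, mid)
      }
    }
    cuts <- do.call(rbind, cuts)
    cuts <- cuts[order(cuts[, 1]), , drop = FALSE]
    bounds <- c(0L, as.vector(t(cuts)), len)
    k <- 0L
    for (p in seq(1, length(bounds) - 1, by = 2)) {
      s <- bounds[[p]]; e <- bounds[[p + 1L]]
      if (e <= s) next
      k <- k + 1L
      child <- sprintf("%s_%d", id, k)
      out_seqs[[child]] <- subseq0(seqs[[id]], s, e)
      edits[[length(edits) + 1L]] <-
        edit_log("split", id, s, e, child, 0L, e - s, "+",
                 "chimera-split")
    }
  }
  list(set = scaffold_set(out_seqs),
       edits = do.call(bind_edits, edits))
}
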