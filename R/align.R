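#' Seeded alignment of a query against a sequence set
#'
#' Finds exact seed matches of `word_size` bases on both strands,
#' groups co-linear seeds within a diagonal band, extends each group
#' across the full query, and reports identity (matching columns /
#' alignment columns) and aligned length. Groups on a single diagonal
#' are scored by direct column comparison; groups spanning several
#' diagonals (indels) are re-aligned with Needleman-Wunsch via
#' Biostrings. Matches passing the configured identity and length
#' floors are returned best first (identity, then aligned length, then
#' lowest target coordinate).
#'
#' @param query DNA string (>= `word_size` bases).
#' @param target_set `ScaffoldSet` to search.
#' @param config a [pipeline_config()]; `word_size` and `min_identity`
#'   are used.
#' @param min_identity optional override of the identity floor.
#' @param band diagonal band (bp) within which seeds are merged.
#' @return data frame `target_id`, `t_start`, `t_end` (0-based
#'   half-open, forward strand of the target), `orientation`,
#'   `identity`, `aligned_length`, sorted best first.
#' @export
seeded_align <- function(query, target_set, config = NULL,
                         min_identity = NULL, band = 20L) {
  config <- as_config(config)
  if (is.null(min_identity)) min_identity <- config$min_identity
  w <- as.integer(config$word_size)
  query <- toupper(query)
  qlen <- nchar(query)
  if (qlen < w)
    stop("query shorter than word_size (", qlen, " < ", w, ")",
         call. = FALSE)
  hits <- list()
  for (orient in c("+", "-")) {
    q <- if (orient == "+") query else revcomp(query)
    ## non-overlapping seed tiles plus a final tile flush with the end
    starts <- unique(c(seq(0L, qlen - w, by = w), qlen - w))
    seeds <- data.frame(q_start = starts, q_end = starts + w)
    for (tid in names(target_set$seqs)) {
      tseq <- target_set$seqs[[tid]]
      found <- list()
      for (si in seq_len(nrow(seeds))) {
        pat <- subseq0(q, seeds$q_start[[si]], seeds$q_end[[si]])
        if (grepl("N", pat, fixed = TRUE)) next
        m <- gregexpr(pat, tseq, fixed = TRUE)[[1]]
        if (m[[1]] == -1) next
        found[[length(found) + 1L]] <-
          data.frame(q_start = seeds$q_start[[si]],
                     q_end = seeds$q_end[[si]],
                     t_start = as.integer(m) - 1L)
      }
      if (!length(found)) next
      sd <- do.call(rbind, found)
      sd$diag <- sd$t_start - sd$q_start
      sd <- sd[order(sd$q_start, sd$t_start), , drop = FALSE]
      ## greedy co-linear chaining within the band
      cluster <- rep(0L, nrow(sd))
      last_of <- list() # cluster -> row index of last seed
      nclust <- 0L
      for (i in seq_len(nrow(sd))) {
        assigned <- FALSE
        for (cl in rev(seq_len(nclust))) {
          j <- last_of[[cl]]
          if (sd$q_start[[i]] >= sd$q_end[[j]] &&
              sd$t_start[[i]] >= sd$t_start[[j]] + w &&
              abs(sd$diag[[i]] - sd$diag[[j]]) <= band) {
            cluster[[i]] <- cl; last_of[[cl]] <- i; assigned <- TRUE
            break
          }
        }
        if (!assigned) {
          nclust <- nclust + 1L
          cluster[[i]] <- nclust; last_of[[nclust]] <- i
        }
      }
      tlen <- nchar(tseq)
      for (cl in seq_len(nclust)) {
        cs <- sd[cluster == cl, , drop = FALSE]
        first <- cs[1, ]; last <- cs[nrow(cs), ]
        t0 <- first$t_start - first$q_start
        t1 <- last$t_start + w + (qlen - last$q_end)
        t0c <- max(0L, t0); t1c <- min(tlen, t1)
        if (t1c - t0c < w) next
        tsub <- subseq0(tseq, t0c, t1c)
        ## the query region actually covered after clipping
        q0 <- t0c - t0
        q1 <- qlen - (t1 - t1c)
        qsub <- subseq0(q, q0, q1)
        if (length(unique(cs$diag)) == 1 && nchar(qsub) == nchar(tsub)) {
          a <- strsplit(qsub, "")[[1]]; b <- strsplit(tsub, "")[[1]]
          nmatch <- sum(a == b)
          cols <- length(a)
        } else {
          pa <- Biostrings::pairwiseAlignment(qsub, tsub,
                                              type = "global")
          nmatch <- Biostrings::nmatch(pa)
          cols <- Biostrings::nchar(pa)
        }
        identity <- nmatch / cols
        if (identity >= min_identity && cols >= w) {
          hits[[length(hits) + 1L]] <-
            data.frame(target_id = tid, t_start = t0c, t_end = t1c,
                       orientation = orient, identity = identity,
                       aligned_length = as.integer(cols),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(target_id = character(0), t_start = integer(0),
                      t_end = integer(0), orientation = character(0),
                      identity = numeric(0), aligned_length = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[c("target_id", "t_start", "t_end",
                               "orientation")]), , drop = FALSE]
  out[order(-out$identity, -out$aligned_length, out$target_id,
            out$t_start), , drop = FALSE]
}
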