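#' Emit a UCSC liftOver chain file from an edit log
#'
#' Replays the edit log at coordinate level, verifies that the result
#' is consistent with the supplied new assembly, and writes one chain
#' per maximal colinear run of surviving old-assembly blocks. The
#' chain's target side is the old assembly and its query side the new
#' one, so the file translates old coordinates to new coordinates, as
#' the UCSC liftOver tool expects. Every old base that survives the
#' upgrade maps to exactly one new coordinate.
#'
#' @param edits an [edit_log()] consistent with `old_set`.
#' @param old_set input assembly (`ScaffoldSet`).
#' @param new_set output assembly (`ScaffoldSet`); sequences absent
#'   from it (e.g. dropped scaffolds) get no chains.
#' @param path output file path, or `NULL` to return lines.
#' @return invisibly, the chain table used (data frame of aligned
#'   blocks); the formatted file is written to `path`.
#' @export
emit_chain <- function(edits, old_set, new_set, path = NULL) {
  rep <- apply_edits(old_set, edits, bytes = FALSE)
  for (id in names(new_set$seqs)) {
    if (!id %in% names(rep$lengths))
      stop("new sequence '", id, "' is not produced by the edit log",
           call. = FALSE)
    if (rep$lengths[[id]] != nchar(new_set$seqs[[id]]))
      stop("edit log length for '", id, "' (", rep$lengths[[id]],
           ") differs from new assembly (", nchar(new_set$seqs[[id]]),
           ")", call. = FALSE)
  }
  old_sizes <- seq_lengths(old_set)
  new_sizes <- seq_lengths(new_set)
  blocks <- list()
  for (id in names(new_set$seqs)) {
    sm <- rep$segmaps[[id]]
    sm <- sm[!is.na(sm$old_id), , drop = FALSE]
    if (!nrow(sm)) next
    sm$new_id <- id
    blocks[[id]] <- sm
  }
  blocks <- do.call(rbind, blocks)
  lines <- character(0)
  chain_tab <- list()
  chain_id <- 0L
  if (!is.null(blocks)) {
    ## maximal colinear runs per (old, new, strand)
    blocks <- blocks[order(blocks$new_id, blocks$new_start), ]
    run_id <- integer(nrow(blocks))
    cur <- 0L
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      extend <- FALSE
      if (i > 1) {
        p <- blocks[i - 1L, ]
        if (run_id[[i - 1L]] == cur && p$new_id == b$new_id &&
            p$old_id == b$old_id && p$strand == b$strand) {
          if (b$strand == "+" && b$old_start >= p$old_end) extend <- TRUE
          if (b$strand == "-" && b$old_end <= p$old_start) extend <- TRUE
        }
      }
      if (!extend) cur <- cur + 1L
      run_id[[i]] <- cur
    }
    for (r in unique(run_id)) {
      bs <- blocks[run_id == r, , drop = FALSE]
      chain_id <- chain_id + 1L
      strand <- bs$strand[[1]]
      old_id <- bs$old_id[[1]]
      new_id <- bs$new_id[[1]]
      q_size <- new_sizes[[new_id]]
      ## express query coordinates on the chain strand
      if (strand == "+") {
        bs$q_start <- bs$new_start
        bs$q_end <- bs$new_end
      } else {
        bs$q_start <- q_size - bs$new_end
        bs$q_end <- q_size - bs$new_start
      }
      bs <- bs[order(bs$old_start), , drop = FALSE]
      score <- sum(bs$old_end - bs$old_start)
      header <- paste("chain", score, old_id, old_sizes[[old_id]], "+",
                      bs$old_start[[1]], bs$old_end[[nrow(bs)]],
                      new_id, q_size, strand,
                      bs$q_start[[1]], bs$q_end[[nrow(bs)]], chain_id)
      body <- character(nrow(bs))
      for (j in seq_len(nrow(bs))) {
        size <- bs$old_end[[j]] - bs$old_start[[j]]
        if (j < nrow(bs)) {
          dt <- bs$old_start[[j + 1L]] - bs$old_end[[j]]
          dq <- bs$q_start[[j + 1L]] - bs$q_end[[j]]
          body[[j]] <- paste(size, dt, dq, sep = "\t")
        } else {
          body[[j]] <- as.character(size)
        }
      }
      lines <- c(lines, header, body, "")
      bs$chain_id <- chain_id
      chain_tab[[chain_id]] <- bs
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  out <- if (length(chain_tab)) do.call(rbind, chain_tab) else NULL
  attr(out, "lines") <- lines
  invisible(out)
}

#' Read a UCSC chain file
#'
#' @param path chain file path.
#' @return list of chains; each has `header` (named list) and `blocks`
#'   (data frame with `size`, `dt`, `dq`).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(lines[[i]])) { i <- i + 1L; next }
    f <- strsplit(lines[[i]], "\\s+")[[1]]
    if (f[[1]] != "chain") stop("malformed chain header at line ", i,
                                call. = FALSE)
    header <- list(score = as.numeric(f[[2]]), t_name = f[[3]],
                   t_size = as.integer(f[[4]]), t_strand = f[[5]],
                   t_start = as.integer(f[[6]]), t_end = as.integer(f[[7]]),
                   q_name = f[[8]], q_size = as.integer(f[[9]]),
                   q_strand = f[[10]], q_start = as.integer(f[[11]]),
                   q_end = as.integer(f[[12]]),
                   id = as.integer(f[[13]]))
    i <- i + 1L
    sizes <- integer(0); dts <- integer(0); dqs <- integer(0)
    repeat {
      if (i > length(lines) || !nzchar(lines[[i]])) break
      g <- as.integer(strsplit(lines[[i]], "\\s+")[[1]])
      sizes <- c(sizes, g[[1]])
      if (length(g) == 3) { dts <- c(dts, g[[2]]); dqs <- c(dqs, g[[3]]) }
      i <- i + 1L
      if (length(g) == 1) break
    }
    chains[[length(chains) + 1L]] <-
      list(header = header,
           blocks = data.frame(size = sizes,
                               dt = c(dts, NA), dq = c(dqs, NA)))
  }
  chains
}

#' Lift old-assembly positions through a chain file
#'
#' @param chains output of [read_chain()].
#' @param ids,pos vectors of old sequence ids and 0-based positions.
#' @return data frame with `id`, `pos`, `new_id`, `new_pos` (0-based,
#'   forward strand of the new assembly; NA when the base was deleted)
#'   and `strand`.
#' @export
lift_positions <- function(chains, ids, pos) {
  out <- data.frame(id = ids, pos = as.integer(pos),
                    new_id = NA_character_, new_pos = NA_integer_,
                    strand = NA_character_, stringsAsFactors = FALSE)
  for (ch in chains) {
    h <- ch$header
    sel <- which(out$id == h$t_name & out$pos >= h$t_start &
                   out$pos < h$t_end & is.na(out$new_id))
    if (!length(sel)) next
    t_cur <- h$t_start
    q_cur <- h$q_start
    b <- ch$blocks
    for (j in seq_len(nrow(b))) {
      inblk <- sel[out$pos[sel] >= t_cur & out$pos[sel] < t_cur + b$size[[j]]]
      if (length(inblk)) {
        off <- out$pos[inblk] - t_cur
        qp <- q_cur + off
        if (h$q_strand == "+") {
          out$new_pos[inblk] <- qp
        } else {
          out$new_pos[inblk] <- h$q_size - 1L - qp
        }
        out$new_id[inblk] <- h$q_name
        out$strand[inblk] <- h$q_strand
      }
      if (!is.na(b$dt[[j]])) {
        t_cur <- t_cur + b$size[[j]] + b$dt[[j]]
        q_cur <- q_cur + b$size[[j]] + b$dq[[j]]
      }
    }
  }
  out
}
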