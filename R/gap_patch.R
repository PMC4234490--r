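#' Close sequencing gaps using legacy-assembly sequence
#'
#' For every N-gap of at least `min_gap_len` bases, extracts up to
#' `flank_len` of ungapped sequence on each side and aligns both
#' flanks against the legacy assembly with [seeded_align()]. A gap is
#' closeable iff both flanks match the same legacy record in the same
#' orientation, the inner-edge distance between the two matches is at
#' most `span_max`, and the intervening legacy sequence contains
#' strictly fewer N bases than the gap it replaces. Closed gaps are
#' spliced with the intervening legacy sequence
#' (reverse-complemented for minus-orientation matches) and logged.
#'
#' Reason codes: `no-left-match`, `no-right-match`,
#' `different-records`, `orientation-mismatch`, `span-exceeded`,
#' `not-fewer-Ns`, `closed`.
#'
#' @param assembly `ScaffoldSet` being patched.
#' @param legacy_set legacy `ScaffoldSet`.
#' @param config a [pipeline_config()].
#' @return list with `set` (patched assembly), `decisions` (data
#'   frame), `edits` (`edit_log`).
#' @export
close_gaps <- function(assembly, legacy_set, config = NULL) {
  config <- as_config(config)
  seqs <- assembly$seqs
  decisions <- list(); edits <- list()
  for (id in names(seqs)) {
    gaps <- assembly$gaps[assembly$gaps$record_id == id &
                            assembly$gaps$n_count >= config$min_gap_len, ,
                          drop = FALSE]
    if (!nrow(gaps)) next
    gaps <- gaps[order(gaps$start), , drop = FALSE]
    orig <- assembly$seqs[[id]]
    delta <- 0L # accumulated length change from earlier patches
    for (g in seq_len(nrow(gaps))) {
      gs <- gaps$start[[g]]; ge <- gaps$end[[g]]
      gap_id <- sprintf("%s:%d-%d", id, gs, ge)
      dec <- list(gap_id = gap_id, record_id = id, start = gs, end = ge,
                  n_count = ge - gs, closeable = FALSE, reason = NA,
                  legacy_id = NA, span = NA_integer_,
                  patch_len = NA_integer_)
      res <- close_one_gap(orig, gs, ge, legacy_set, config)
      dec$reason <- res$reason
      if (res$reason == "closed") {
        dec$closeable <- TRUE
        dec$legacy_id <- res$legacy_id
        dec$span <- res$span
        dec$patch_len <- nchar(res$patch)
        s <- seqs[[id]]
        seqs[[id]] <- paste0(substr(s, 1, gs + delta),
                             res$patch,
                             substr(s, ge + delta + 1L, nchar(s)))
        edits[[length(edits) + 1L]] <-
          edit_log("insert", res$legacy_id, res$legacy_start,
                   res$legacy_end, id, gs + delta, ge + delta,
                   res$orientation, "gap-patch")
        delta <- delta + nchar(res$patch) - (ge - gs)
      }
      decisions[[length(decisions) + 1L]] <-
        as.data.frame(dec, stringsAsFactors = FALSE)
    }
  }
  decisions <- if (length(decisions)) do.call(rbind, decisions)
    else data.frame(gap_id = character(0), reason = character(0))
  list(set = scaffold_set(seqs), decisions = decisions,
       edits = do.call(bind_edits, edits))
}

## flank extraction trimmed back to ungapped sequence
trim_flank <- function(seq, s, e, side) {
  f <- subseq0(seq, s, e)
  if (side == "left") {
    ## keep the part after the last N
    m <- regexpr("N[^N]*$", f)
    if (m > 0) { s <- s + m; f <- substr(f, m + 1L, nchar(f)) }
  } else {
    m <- regexpr("N", f, fixed = TRUE)
    if (m > 0) { e <- s + m - 1L; f <- substr(f, 1, m - 1L) }
  }
  list(seq = f, start = s, end = e)
}

close_one_gap <- function(orig, gs, ge, legacy_set, config) {
  len <- nchar(orig)
  lf <- trim_flank(orig, max(0L, gs - config$flank_len), gs, "left")
  if (nchar(lf$seq) < config$word_size)
    return(list(reason = "no-left-match"))
  rf <- trim_flank(orig, ge, min(len, ge + config$flank_len), "right")
  if (nchar(rf$seq) < config$word_size)
    return(list(reason = "no-right-match"))
  lm <- seeded_align(lf$seq, legacy_set, config)
  if (!nrow(lm)) return(list(reason = "no-left-match"))
  rm <- seeded_align(rf$seq, legacy_set, config)
  if (!nrow(rm)) return(list(reason = "no-right-match"))
  lm <- lm[1, ]; rm <- rm[1, ]
  if (lm$target_id != rm$target_id)
    return(list(reason = "different-records"))
  if (lm$orientation != rm$orientation)
    return(list(reason = "orientation-mismatch"))
  if (lm$orientation == "+") {
    ps <- lm$t_end; pe <- rm$t_start
  } else {
    ps <- rm$t_end; pe <- lm$t_start
  }
  if (pe < ps) return(list(reason = "orientation-mismatch"))
  span <- pe - ps
  if (span > config$span_max) return(list(reason = "span-exceeded"))
  patch <- subseq0(legacy_set$seqs[[lm$target_id]], ps, pe)
  patch_n <- nchar(patch) - nchar(gsub("N", "", patch, fixed = TRUE))
  if (patch_n >= ge - gs) return(list(reason = "not-fewer-Ns"))
  if (lm$orientation == "-") patch <- revcomp(patch)
  list(reason = "closed", legacy_id = lm$target_id,
       legacy_start = ps, legacy_end = pe, span = span,
       orientation = lm$orientation, patch = patch)
}

#' Replace assembly regions with high-quality legacy segments
#'
#' For each high-quality legacy segment (e.g. finished BAC or
#' multi-BAC contigs), the `bac_flank_len` end flankers are located in
#' the assembly with [seeded_align()]. When both flankers land on the
#' same sequence, in the same orientation and in consistent order, the
#' enclosed assembly range is replaced by the full legacy segment
#' (reverse-complemented for minus-orientation matches). Segments are
#' processed longest first; a segment whose replacement range overlaps
#' an already-applied replacement is skipped.
#'
#' @param assembly `ScaffoldSet`.
#' @param hq_segments `ScaffoldSet` of high-quality legacy segments.
#' @param config a [pipeline_config()].
#' @return list with `set`, `decisions`, `edits`.
#' @export
replace_bac_regions <- function(assembly, hq_segments, config = NULL) {
  config <- as_config(config)
  ord <- names(hq_segments$seqs)[order(-nchar(hq_segments$seqs))]
  plans <- list(); decisions <- list()
  taken <- list() # per chrom, list of applied [s, e)
  for (sid in ord) {
    seg <- hq_segments$seqs[[sid]]
    slen <- nchar(seg)
    fl <- min(config$bac_flank_len, slen %/% 2L)
    dec <- list(segment_id = sid, action = "skipped", reason = NA,
                target_id = NA, start = NA_integer_, end = NA_integer_)
    if (fl < config$word_size) {
      dec$reason <- "segment-too-short"
      decisions[[length(decisions) + 1L]] <- as.data.frame(dec)
      next
    }
    lm <- seeded_align(subseq0(seg, 0L, fl), assembly, config)
    rm <- seeded_align(subseq0(seg, slen - fl, slen), assembly, config)
    reason <- NULL
    if (!nrow(lm)) reason <- "no-left-flanker"
    else if (!nrow(rm)) reason <- "no-right-flanker"
    else {
      lm <- lm[1, ]; rm <- rm[1, ]
      if (lm$target_id != rm$target_id) reason <- "different-chromosomes"
      else if (lm$orientation != rm$orientation)
        reason <- "orientation-mismatch"
      else {
        if (lm$orientation == "+") { rs <- lm$t_start; re <- rm$t_end }
        else { rs <- rm$t_start; re <- lm$t_end }
        if (re <= rs) reason <- "flankers-out-of-order"
        else {
          prior <- taken[[lm$target_id]]
          clash <- FALSE
          if (!is.null(prior))
            clash <- any(vapply(prior, function(iv)
              iv[[1]] < re && rs < iv[[2]], logical(1)))
          if (clash) reason <- "overlaps-prior-replacement"
          else {
            taken[[lm$target_id]] <-
              c(taken[[lm$target_id]], list(c(rs, re)))
            plans[[length(plans) + 1L]] <-
              list(segment_id = sid, target_id = lm$target_id,
                   start = rs, end = re,
                   orientation = lm$orientation, seg_len = slen)
            dec$action <- "replaced"; reason <- "applied"
            dec$target_id <- lm$target_id
            dec$start <- rs; dec$end <- re
          }
        }
      }
    }
    dec$reason <- reason
    decisions[[length(decisions) + 1L]] <- as.data.frame(dec)
  }
  ## apply per target right-to-left so earlier edits do not shift
  ## the coordinates of later ones; the log stays sequentially valid
  seqs <- assembly$seqs
  edits <- list()
  if (length(plans)) {
    ordp <- order(vapply(plans, `[[`, character(1), "target_id"),
                  -vapply(plans, `[[`, numeric(1), "start"))
    for (p in plans[ordp]) {
      seg <- hq_segments$seqs[[p$segment_id]]
      if (p$orientation == "-") seg <- revcomp(seg)
      s <- seqs[[p$target_id]]
      seqs[[p$target_id]] <- paste0(substr(s, 1, p$start), seg,
                                    substr(s, p$end + 1L, nchar(s)))
      edits[[length(edits) + 1L]] <-
        edit_log("replace", p$segment_id, 0L, p$seg_len, p$target_id,
                 p$start, p$end, p$orientation, "bac-replacement")
    }
  }
  list(set = scaffold_set(seqs),
       decisions = do.call(rbind, decisions),
       edits = do.call(bind_edits, edits))
}

#' Summarize gap-patching decisions
#'
#' @param decisions decision table from [close_gaps()].
#' @return list with `examined`, `closed` and `reasons` (named counts
#'   of rejection reasons); `examined = closed + sum(reasons)`.
#' @export
patch_report <- function(decisions) {
  if (!nrow(decisions))
    return(list(examined = 0L, closed = 0L,
                reasons = integer(0)))
  closed <- sum(decisions$reason == "closed")
  reasons <- table(decisions$reason[decisions$reason != "closed"])
  list(examined = nrow(decisions), closed = closed,
       reasons = setNames(as.integer(reasons), names(reasons)))
}
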