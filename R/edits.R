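#' Edit logs: a replayable record of every assembly edit
#'
#' Every operation that changes sequence content — splitting a chimeric
#' scaffold, anchoring a component into a pseudomolecule, inserting a
#' legacy segment, patching a gap, replacing a region with a
#' high-quality legacy segment — appends rows to an edit log. Replaying
#' the log against the input sequences reproduces the output assembly
#' byte-for-byte, and the log is the sole source for liftOver chain
#' generation (see [emit_chain()]).
#'
#' Edit kinds:
#' \describe{
#'   \item{split}{extract `source_id[source_start, source_end)` from a
#'     working sequence into a new sequence `target_id`. All split rows
#'     for one parent together consume it.}
#'   \item{anchor}{append a whole working sequence (possibly
#'     reverse-complemented) to object `target_id` at
#'     `[target_start, target_end)`, padding any preceding uncovered
#'     region with N. Consumes the component.}
#'   \item{insert, replace}{splice external sequence (from a named
#'     auxiliary set, e.g. a legacy assembly) over
#'     `target_id[target_start, target_end)`; target length changes by
#'     the length difference. `insert` tags gap patches and recruited
#'     segments, `replace` tags region replacement; the coordinate
#'     semantics are identical.}
#' }
#' Coordinates are 0-based half-open and always refer to the state of
#' the working set at the time the edit is applied (edits are strictly
#' ordered).
#'
#' @param kind,source_id,source_start,source_end,target_id,target_start,target_end,orientation,provenance
#'   vectors of equal length describing the edits.
#' @return a data frame of class `edit_log`.
#' @export
edit_log <- function(kind = character(0), source_id = character(0),
                     source_start = integer(0), source_end = integer(0),
                     target_id = character(0), target_start = integer(0),
                     target_end = integer(0), orientation = character(0),
                     provenance = character(0)) {
  df <- data.frame(kind = as.character(kind),
                   source_id = as.character(source_id),
                   source_start = as.integer(source_start),
                   source_end = as.integer(source_end),
                   target_id = as.character(target_id),
                   target_start = as.integer(target_start),
                   target_end = as.integer(target_end),
                   orientation = as.character(orientation),
                   provenance = as.character(provenance),
                   stringsAsFactors = FALSE)
  if (nrow(df) && !all(df$kind %in% c("split", "anchor", "insert",
                                      "replace")))
    stop("unknown edit kind", call. = FALSE)
  class(df) <- c("edit_log", "data.frame")
  df
}

#' Concatenate edit logs in pipeline order
#' @param ... `edit_log` objects.
#' @return a single `edit_log`.
#' @export
bind_edits <- function(...) {
  logs <- Filter(Negate(is.null), list(...))
  out <- do.call(rbind, lapply(logs, as.data.frame))
  if (is.null(out)) return(edit_log())
  class(out) <- c("edit_log", "data.frame")
  rownames(out) <- NULL
  out
}

## one segment map row per contiguous provenance run of a working
## sequence; old_id NA marks novel sequence (N padding or spliced-in
## external sequence)
seg_identity <- function(id, len) {
  data.frame(new_start = 0L, new_end = as.integer(len), old_id = id,
             old_start = 0L, old_end = as.integer(len), strand = "+",
             stringsAsFactors = FALSE)
}

seg_novel <- function(len) {
  if (len == 0) return(seg_identity("x", 0)[0, ])
  data.frame(new_start = 0L, new_end = as.integer(len),
             old_id = NA_character_, old_start = NA_integer_,
             old_end = NA_integer_, strand = "+",
             stringsAsFactors = FALSE)
}

seg_len <- function(sm) if (nrow(sm)) max(sm$new_end) else 0L

seg_shift <- function(sm, by) {
  sm$new_start <- sm$new_start + as.integer(by)
  sm$new_end <- sm$new_end + as.integer(by)
  sm
}

## clip a segment map to [s, e) and rebase to 0
seg_slice <- function(sm, s, e) {
  keep <- sm[sm$new_end > s & sm$new_start < e, , drop = FALSE]
  if (!nrow(keep)) return(sm[0, ])
  for (i in seq_len(nrow(keep))) {
    cs <- max(keep$new_start[[i]], s)
    ce <- min(keep$new_end[[i]], e)
    if (!is.na(keep$old_id[[i]])) {
      if (keep$strand[[i]] == "+") {
        keep$old_start[[i]] <- keep$old_start[[i]] +
          (cs - keep$new_start[[i]])
        keep$old_end[[i]] <- keep$old_end[[i]] -
          (keep$new_end[[i]] - ce)
      } else {
        keep$old_start[[i]] <- keep$old_start[[i]] +
          (keep$new_end[[i]] - ce)
        keep$old_end[[i]] <- keep$old_end[[i]] -
          (cs - keep$new_start[[i]])
      }
    }
    keep$new_start[[i]] <- cs
    keep$new_end[[i]] <- ce
  }
  seg_shift(keep, -s)
}

## reverse-complement a segment map of total length len
seg_reverse <- function(sm, len) {
  if (!nrow(sm)) return(sm)
  ns <- len - sm$new_end
  ne <- len - sm$new_start
  sm$new_start <- ns
  sm$new_end <- ne
  flip <- !is.na(sm$old_id)
  sm$strand[flip] <- ifelse(sm$strand[flip] == "+", "-", "+")
  sm[order(sm$new_start), , drop = FALSE]
}

seg_concat <- function(a, b) {
  b <- seg_shift(b, seg_len(a))
  rbind(a, b)
}

edit_err <- function(i, msg) {
  stop(sprintf("edit %d: %s", i, msg), call. = FALSE)
}

#' Replay an edit log
#'
#' Applies an [edit_log()] to the input assembly, reproducing the
#' output assembly and the provenance map of every output base. With
#' `bytes = TRUE`, actual sequence is carried (auxiliary sets must then
#' supply any external `insert`/`replace` source sequence); with
#' `bytes = FALSE` only coordinates are tracked, which is all that
#' chain generation needs.
#'
#' @param old_set input `ScaffoldSet`.
#' @param edits an `edit_log`.
#' @param sources named list of auxiliary `ScaffoldSet`s resolving
#'   external source ids (e.g. `list(legacy = legacy_set)`).
#' @param bytes carry sequence bytes (TRUE) or coordinates only.
#' @return list with `set` (the replayed `ScaffoldSet`; only when
#'   `bytes = TRUE`), `lengths` (named lengths of all surviving
#'   sequences) and `segmaps` (per-sequence provenance maps keyed on
#'   input coordinates).
#' @export
apply_edits <- function(old_set, edits, sources = list(), bytes = TRUE) {
  stopifnot(inherits(old_set, "ScaffoldSet"))
  seqs <- as.list(old_set$seqs)
  segmaps <- lapply(names(seqs),
                    function(id) seg_identity(id, nchar(seqs[[id]])))
  names(segmaps) <- names(seqs)
  consumed <- character(0)
  lookup_external <- function(id) {
    for (s in sources) {
      if (id %in% names(s$seqs)) return(s$seqs[[id]])
    }
    NULL
  }
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$kind == "split") {
      if (is.null(segmaps[[e$source_id]]))
        edit_err(i, paste0("split source '", e$source_id, "' not in working set"))
      plen <- seg_len(segmaps[[e$source_id]])
      if (e$source_start < 0 || e$source_end > plen ||
          e$source_start >= e$source_end)
        edit_err(i, "split interval outside source sequence")
      segmaps[[e$target_id]] <-
        seg_slice(segmaps[[e$source_id]], e$source_start, e$source_end)
      if (bytes)
        seqs[[e$target_id]] <- subseq0(seqs[[e$source_id]],
                                       e$source_start, e$source_end)
      consumed <- union(consumed, e$source_id)
    } else if (e$kind == "anchor") {
      if (is.null(segmaps[[e$source_id]]))
        edit_err(i, paste0("anchor source '", e$source_id, "' not in working set"))
      comp_map <- segmaps[[e$source_id]]
      clen <- seg_len(comp_map)
      if (e$target_end - e$target_start != clen)
        edit_err(i, "anchor target interval length != component length")
      if (e$orientation == "-") comp_map <- seg_reverse(comp_map, clen)
      cur <- segmaps[[e$target_id]]
      if (is.null(cur)) {
        cur <- seg_novel(0)
        if (bytes) seqs[[e$target_id]] <- ""
      }
      cur_len <- seg_len(cur)
      if (e$target_start < cur_len)
        edit_err(i, "anchor rows for an object must be appended left to right")
      pad <- e$target_start - cur_len
      if (pad > 0) cur <- seg_concat(cur, seg_novel(pad))
      segmaps[[e$target_id]] <- seg_concat(cur, comp_map)
      if (bytes) {
        comp_seq <- seqs[[e$source_id]]
        if (e$orientation == "-") comp_seq <- revcomp(comp_seq)
        seqs[[e$target_id]] <- paste0(seqs[[e$target_id]], n_run(pad),
                                      comp_seq)
      }
      consumed <- union(consumed, e$source_id)
    } else { # insert / replace
      if (is.null(segmaps[[e$target_id]])) {
        segmaps[[e$target_id]] <- seg_novel(0)
        if (bytes) seqs[[e$target_id]] <- ""
      }
      cur <- segmaps[[e$target_id]]
      cur_len <- seg_len(cur)
      if (e$target_start > cur_len) {
        ## appending beyond the current end: pad with N first
        pad <- e$target_start - cur_len
        cur <- seg_concat(cur, seg_novel(pad))
        if (bytes) seqs[[e$target_id]] <- paste0(seqs[[e$target_id]],
                                                 n_run(pad))
        cur_len <- e$target_start
      }
      if (e$target_start < 0 || e$target_end > cur_len ||
          e$target_start > e$target_end)
        edit_err(i, "splice interval outside target sequence")
      ins_len <- e$source_end - e$source_start
      if (ins_len < 0) edit_err(i, "negative source interval")
      left <- seg_slice(cur, 0L, e$target_start)
      right <- seg_slice(cur, e$target_end, cur_len)
      segmaps[[e$target_id]] <-
        seg_concat(seg_concat(left, seg_novel(ins_len)), right)
      if (bytes) {
        src <- lookup_external(e$source_id)
        if (is.null(src))
          edit_err(i, paste0("external source '", e$source_id,
                             "' not found in auxiliary sets"))
        if (e$source_end > nchar(src))
          edit_err(i, "source interval outside external sequence")
        piece <- subseq0(src, e$source_start, e$source_end)
        if (e$orientation == "-") piece <- revcomp(piece)
        s <- seqs[[e$target_id]]
        seqs[[e$target_id]] <- paste0(substr(s, 1, e$target_start),
                                      piece,
                                      substr(s, e$target_end + 1, nchar(s)))
      }
    }
  }
  keep <- setdiff(names(segmaps), consumed)
  segmaps <- segmaps[keep]
  lens <- vapply(segmaps, seg_len, integer(1))
  out <- list(lengths = lens, segmaps = segmaps)
  if (bytes) {
    out$set <- scaffold_set(unlist(seqs[keep]))
  }
  out
}
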