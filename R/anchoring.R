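#' Tile placed scaffolds into chromosome layouts
#'
#' Orders and orients scaffolds along each chromosome from their
#' placement records. The estimated gap after each part is the
#' distance to the next part's placement (floored at zero). Scaffolds
#' with no placement are returned separately; a scaffold still placed
#' on two chromosomes is an error (chimeras must be split first).
#'
#' @param set `ScaffoldSet` of (post-split) scaffolds.
#' @param placements placement data frame.
#' @param config a [pipeline_config()].
#' @return list with `layout` (data frame `chrom_id`, `component_id`,
#'   `source`, `orientation`, `chrom_start`, `chrom_end`,
#'   `est_gap_after`) and `unplaced` (character vector of scaffold
#'   ids).
#' @export
tile_by_placements <- function(set, placements, config = NULL) {
  config <- as_config(config)
  placements <- placements[placements$scaffold_id %in% names(set$seqs), ,
                           drop = FALSE]
  multi <- tapply(placements$chrom_id, placements$scaffold_id,
                  function(x) length(unique(x)))
  if (any(multi > 1))
    stop("scaffold ", names(multi)[multi > 1][1],
         " is placed on several chromosomes; split it first",
         call. = FALSE)
  rows <- list()
  for (chrom in sort(unique(placements$chrom_id))) {
    p <- placements[placements$chrom_id == chrom, , drop = FALSE]
    p <- p[order(p$chrom_start), , drop = FALSE]
    if (nrow(p) > 1) {
      for (i in seq_len(nrow(p) - 1L)) {
        ov <- p$chrom_end[[i]] - p$chrom_start[[i + 1L]]
        shorter <- min(p$chrom_end[[i]] - p$chrom_start[[i]],
                       p$chrom_end[[i + 1L]] - p$chrom_start[[i + 1L]])
        if (ov > config$tile_overlap_frac * shorter)
          stop("tiling conflict on ", chrom, ": placements of ",
               p$scaffold_id[[i]], " and ", p$scaffold_id[[i + 1L]],
               " overlap", call. = FALSE)
      }
    }
    gap_after <- c(pmax(0L, p$chrom_start[-1] - p$chrom_end[-nrow(p)]), 0L)
    rows[[chrom]] <- data.frame(
      chrom_id = chrom, component_id = p$scaffold_id, source = "wgs",
      orientation = p$orientation,
      chrom_start = p$chrom_start, chrom_end = p$chrom_end,
      est_gap_after = as.integer(gap_after), stringsAsFactors = FALSE)
  }
  layout <- do.call(rbind, rows)
  if (is.null(layout))
    layout <- data.frame(chrom_id = character(0),
                         component_id = character(0),
                         source = character(0), orientation = character(0),
                         chrom_start = integer(0), chrom_end = integer(0),
                         est_gap_after = integer(0),
                         stringsAsFactors = FALSE)
  rownames(layout) <- NULL
  list(layout = layout,
       unplaced = setdiff(names(set$seqs), layout$component_id))
}

recompute_gaps <- function(layout) {
  out <- list()
  for (chrom in unique(layout$chrom_id)) {
    p <- layout[layout$chrom_id == chrom, , drop = FALSE]
    p <- p[order(p$chrom_start), , drop = FALSE]
    p$est_gap_after <-
      c(pmax(0L, p$chrom_start[-1] - p$chrom_end[-nrow(p)]), 0L)
    out[[chrom]] <- p
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Recruit legacy-assembly segments into layout gaps
#'
#' A legacy segment is inserted iff its placement lies entirely within
#' an inter-part gap of the layout, overlapping neither flanking part
#' by more than `legacy_overlap_tol`. Segments spanning a layout part
#' are skipped with a logged reason.
#'
#' @param layout chromosome layout from [tile_by_placements()].
#' @param legacy_set legacy `ScaffoldSet` (for segment lengths).
#' @param legacy_placements placement data frame for legacy segments.
#' @param config a [pipeline_config()].
#' @return list with `layout` (updated) and `decisions` (data frame
#'   `segment_id`, `action`, `reason`).
#' @export
recruit_legacy_segments <- function(layout, legacy_set, legacy_placements,
                                    config = NULL) {
  config <- as_config(config)
  tol <- config$legacy_overlap_tol
  decisions <- list()
  for (k in seq_len(nrow(legacy_placements))) {
    lp <- legacy_placements[k, ]
    parts <- layout[layout$chrom_id == lp$chrom_id, , drop = FALSE]
    parts <- parts[order(parts$chrom_start), , drop = FALSE]
    action <- "skipped"; reason <- "no-gap"
    if (nrow(parts)) {
      ## gap slots: before first, between parts, after last
      slot_lo <- c(-Inf, parts$chrom_end)
      slot_hi <- c(parts$chrom_start, Inf)
      fits <- which(lp$chrom_start >= slot_lo - tol &
                      lp$chrom_end <= slot_hi + tol)
      spans <- any(lp$chrom_start < parts$chrom_end - tol &
                     lp$chrom_end > parts$chrom_start + tol)
      if (spans) {
        reason <- "spans-layout-part"
      } else if (length(fits)) {
        layout <- rbind(layout, data.frame(
          chrom_id = lp$chrom_id, component_id = lp$scaffold_id,
          source = "legacy", orientation = lp$orientation,
          chrom_start = lp$chrom_start, chrom_end = lp$chrom_end,
          est_gap_after = 0L, stringsAsFactors = FALSE))
        action <- "inserted"; reason <- "in-gap"
      }
    }
    decisions[[k]] <- data.frame(segment_id = lp$scaffold_id,
                                 action = action, reason = reason,
                                 stringsAsFactors = FALSE)
  }
  list(layout = recompute_gaps(layout),
       decisions = do.call(rbind, decisions))
}

#' Anchor leftover scaffolds by dual genetic / clone-link evidence
#'
#' An unplaced scaffold is anchored iff at least `min_snp_links` of its
#' markers co-segregate (r-squared at or above `r2_link_min`) with
#' markers on placed components of one chromosome AND at least
#' `min_clone_links` clone-end links connect it to placed parts of the
#' same chromosome. Both evidence types must agree; conflicts leave the
#' scaffold unplaced with the conflict logged. The procedure is run in
#' rounds until no further scaffold is anchored, so a scaffold linking
#' only to a previously anchored scaffold is picked up in a later
#' round. The anchored position is the midpoint of the link-implied
#' interval; orientation is chosen to satisfy clone-link geometry
#' (end separation within mean +/- 3 sd of the library), defaulting to
#' `+` with a low-confidence tag when unresolvable.
#'
#' @param layout chromosome layout.
#' @param unplaced_set `ScaffoldSet` holding the unplaced scaffolds.
#' @param gm `GenotypeMatrix` with markers on both placed and unplaced
#'   scaffolds.
#' @param clone_links clone-link data frame.
#' @param config a [pipeline_config()].
#' @return list with `layout`, `anchored` (data frame of decisions,
#'   incl. round and confidence) and `conflicts`.
#' @export
anchor_by_links <- function(layout, unplaced_set, gm, clone_links,
                            config = NULL) {
  config <- as_config(config)
  anchored <- list(); conflicts <- list()
  todo <- names(unplaced_set$seqs)
  round <- 0L
  repeat {
    round <- round + 1L
    progressed <- FALSE
    ## evidence is evaluated against the layout as of the round start,
    ## so dependency chains resolve over successive rounds
    snap <- layout
    placed_ids <- snap$component_id
    for (u in todo) {
      ulen <- nchar(unplaced_set$seqs[[u]])
      ## genetic evidence: markers on u co-segregating with placed markers
      mu <- gm$markers$marker_id[gm$markers$scaffold_id == u]
      mp <- gm$markers[gm$markers$scaffold_id %in% placed_ids, ,
                       drop = FALSE]
      snp_chrom <- NULL; n_snp <- 0L
      if (length(mu) && nrow(mp)) {
        pairs <- expand.grid(m1 = mu, m2 = mp$marker_id,
                             stringsAsFactors = FALSE)
        ld <- ld_r2(gm, pairs)
        ld <- ld[!is.na(ld$r2) & ld$r2 >= config$r2_link_min, ,
                 drop = FALSE]
        if (nrow(ld)) {
          sc_of <- setNames(mp$scaffold_id, mp$marker_id)
          ch_of <- setNames(snap$chrom_id, snap$component_id)
          votes <- ch_of[sc_of[ld$marker2]]
          best <- names(sort(table(votes), decreasing = TRUE))[1]
          n_snp <- length(unique(ld$marker1[votes == best]))
          snp_chrom <- best
        }
      }
      ## clone-link evidence
      cl <- clone_links[clone_links$end1_scaffold == u |
                          clone_links$end2_scaffold == u, , drop = FALSE]
      link_chrom <- NULL; n_link <- 0L; link_pos <- numeric(0)
      link_rows <- list()
      if (nrow(cl)) {
        ch_of <- setNames(snap$chrom_id, snap$component_id)
        st_of <- setNames(snap$chrom_start, snap$component_id)
        en_of <- setNames(snap$chrom_end, snap$component_id)
        or_of <- setNames(snap$orientation, snap$component_id)
        other <- ifelse(cl$end1_scaffold == u, cl$end2_scaffold,
                        cl$end1_scaffold)
        other_pos <- ifelse(cl$end1_scaffold == u, cl$end2_pos,
                            cl$end1_pos)
        keep <- other %in% names(ch_of)
        if (any(keep)) {
          cl <- cl[keep, , drop = FALSE]
          other <- other[keep]; other_pos <- other_pos[keep]
          votes <- ch_of[other]
          best <- names(sort(table(votes), decreasing = TRUE))[1]
          sel <- votes == best
          n_link <- sum(sel)
          link_chrom <- best
          ## chromosome coordinate of the partner clone end
          opos <- ifelse(or_of[other[sel]] == "+",
                         st_of[other[sel]] + other_pos[sel],
                         en_of[other[sel]] - other_pos[sel])
          link_pos <- as.numeric(opos)
          link_rows <- cl[sel, , drop = FALSE]
          link_upos <- ifelse(link_rows$end1_scaffold == u,
                              link_rows$end1_pos, link_rows$end2_pos)
        }
      }
      if (n_snp >= config$min_snp_links &&
          n_link >= config$min_clone_links) {
        if (!identical(snp_chrom, link_chrom)) {
          conflicts[[length(conflicts) + 1L]] <-
            data.frame(scaffold_id = u, snp_chrom = snp_chrom,
                       link_chrom = link_chrom,
                       stringsAsFactors = FALSE)
          next
        }
        ## link-implied interval midpoint
        centre <- stats::median(link_pos)
        est_start <- as.integer(round(centre - ulen / 2))
        est_start <- max(0L, est_start)
        ## orientation satisfying link geometry
        orient <- "+"; confidence <- "low"
        for (cand in c("+", "-")) {
          upos_chrom <- if (cand == "+") est_start + link_upos
            else est_start + (ulen - link_upos)
          sep <- abs(upos_chrom - link_pos)
          ok <- abs(sep - link_rows$library_mean) <=
            3 * link_rows$library_sd
          if (all(ok)) { orient <- cand; confidence <- "high"; break }
        }
        layout <- rbind(layout, data.frame(
          chrom_id = link_chrom, component_id = u, source = "wgs",
          orientation = orient, chrom_start = est_start,
          chrom_end = est_start + ulen, est_gap_after = 0L,
          stringsAsFactors = FALSE))
        anchored[[length(anchored) + 1L]] <-
          data.frame(scaffold_id = u, chrom_id = link_chrom,
                     n_snp = n_snp, n_link = n_link, round = round,
                     orientation = orient, confidence = confidence,
                     stringsAsFactors = FALSE)
        todo <- setdiff(todo, u)
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  list(layout = recompute_gaps(layout),
       anchored = if (length(anchored)) do.call(rbind, anchored) else NULL,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else NULL)
}

#' Build pseudomolecule sequences, AGP and summary from a layout
#'
#' Joins layout parts left to right with N-gaps of the estimated
#' inter-part distance (never below `join_gap_min`), emits one AGP row
#' per component and gap, logs an anchor edit for every WGS component
#' and an insert edit for every legacy segment, and reports the
#' per-chromosome assembly statistics: real (non-N) bases, N count,
#' total length and percent real bases.
#'
#' @param layout chromosome layout.
#' @param set `ScaffoldSet` holding WGS components.
#' @param legacy_set `ScaffoldSet` holding legacy components (may be
#'   `NULL` when the layout has none).
#' @param config a [pipeline_config()].
#' @return list with `set` (pseudomolecule `ScaffoldSet`), `agp`,
#'   `edits` (`edit_log`) and `summary` (data frame `seqid`, `real`,
#'   `ns`, `total`, `pct_real`).
#' @export
build_pseudomolecules <- function(layout, set, legacy_set = NULL,
                                  config = NULL) {
  config <- as_config(config)
  chrom_seqs <- character(0)
  agp <- list(); edits <- list()
  for (chrom in unique(layout$chrom_id)) {
    parts <- layout[layout$chrom_id == chrom, , drop = FALSE]
    parts <- parts[order(parts$chrom_start), , drop = FALSE]
    pieces <- character(0)
    cur <- 0L; part_no <- 0L
    for (i in seq_len(nrow(parts))) {
      p <- parts[i, ]
      if (p$source == "legacy") {
        if (is.null(legacy_set) ||
            !p$component_id %in% names(legacy_set$seqs))
          stop("legacy component ", p$component_id,
               " absent from legacy set", call. = FALSE)
        comp <- legacy_set$seqs[[p$component_id]]
      } else {
        if (!p$component_id %in% names(set$seqs))
          stop("component ", p$component_id, " absent from scaffold set",
               call. = FALSE)
        comp <- set$seqs[[p$component_id]]
      }
      clen <- nchar(comp)
      if (p$orientation == "-") comp <- revcomp(comp)
      part_no <- part_no + 1L
      agp[[length(agp) + 1L]] <- data.frame(
        object_id = chrom, object_beg = cur + 1L,
        object_end = cur + clen, part_number = part_no,
        component_type = "W", component_id = p$component_id,
        component_beg = 1L, component_end = clen,
        orientation = p$orientation, gap_length = NA_integer_,
        stringsAsFactors = FALSE)
      if (p$source == "legacy") {
        edits[[length(edits) + 1L]] <-
          edit_log("insert", p$component_id, 0L, clen, chrom, cur,
                   cur, p$orientation, "legacy-recruit")
      } else {
        edits[[length(edits) + 1L]] <-
          edit_log("anchor", p$component_id, 0L, clen, chrom, cur,
                   cur + clen, p$orientation, "anchored")
      }
      pieces <- c(pieces, comp)
      cur <- cur + clen
      if (i < nrow(parts)) {
        known <- !is.na(p$est_gap_after)
        glen <- if (known) max(config$join_gap_min,
                               as.integer(p$est_gap_after))
          else config$unknown_gap_len
        part_no <- part_no + 1L
        agp[[length(agp) + 1L]] <- data.frame(
          object_id = chrom, object_beg = cur + 1L,
          object_end = cur + glen, part_number = part_no,
          component_type = if (known) "N" else "U",
          component_id = NA_character_, component_beg = NA_integer_,
          component_end = NA_integer_, orientation = NA_character_,
          gap_length = as.integer(glen), stringsAsFactors = FALSE)
        pieces <- c(pieces, n_run(glen))
        cur <- cur + glen
      }
    }
    chrom_seqs[[chrom]] <- paste(pieces, collapse = "")
  }
  pseudo <- scaffold_set(chrom_seqs)
  summary <- assembly_summary(pseudo)
  list(set = pseudo, agp = agp_rows(do.call(rbind, agp)),
       edits = do.call(bind_edits, edits), summary = summary)
}

#' Per-sequence assembly statistics
#'
#' @param set a `ScaffoldSet`.
#' @return data frame `seqid`, `real` (non-N bases), `ns`, `total`,
#'   `pct_real` (percent, rounded to one decimal).
#' @export
assembly_summary <- function(set) {
  real <- real_base_count(set)
  total <- seq_lengths(set)
  data.frame(seqid = names(total), real = as.numeric(real),
             ns = as.numeric(total - real), total = as.numeric(total),
             pct_real = pct_real(real, total),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percent of real (non-N) bases, rounded to one decimal
#' @param real,total base counts.
#' @return numeric percentage(s).
#' @export
pct_real <- function(real, total) round(100 * real / total, 1)

#' Summarize a per-chromosome statistics table with a total row
#'
#' Recomputes the percent-real column of an assembly statistics table
#' (columns `seqid`, `real`, `ns` and/or `total`) and appends a total
#' row over the selected rows.
#'
#' @param df data frame with `seqid`, `real` and `ns` or `total`.
#' @param rows which rows enter the total (default all).
#' @param total_label label of the appended total row.
#' @return data frame with recomputed `total` and `pct_real`.
#' @export
summarize_assembly_table <- function(df, rows = seq_len(nrow(df)),
                                     total_label = "total") {
  if (is.null(df$total)) df$total <- df$real + df$ns
  if (is.null(df$ns)) df$ns <- df$total - df$real
  tot <- data.frame(seqid = total_label,
                    real = sum(df$real[rows]), ns = sum(df$ns[rows]),
                    total = sum(df$total[rows]),
                    stringsAsFactors = FALSE)
  out <- rbind(df[c("seqid", "real", "ns", "total")], tot)
  out$pct_real <- pct_real(out$real, out$total)
  rownames(out) <- NULL
  out
}
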