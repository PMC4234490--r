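#' Gene sets: loci, transcripts and exon/CDS features
#'
#' A light container for annotation sets. Coordinates are 0-based
#' half-open genome coordinates; GFF3 conversion happens at the I/O
#' boundary.
#'
#' @param genes data frame `locus_id`, `chrom`, `start`, `end`,
#'   `strand`, `source`.
#' @param transcripts data frame `transcript_id`, `locus_id`.
#' @param features data frame `transcript_id`, `type` (`exon` or
#'   `CDS`), `start`, `end`.
#' @return an object of class `GeneSet`.
#' @export
gene_set <- function(genes, transcripts, features) {
  if (is.null(genes$source)) genes$source <- "unknown"
  stopifnot(all(c("locus_id", "chrom", "start", "end", "strand") %in%
                  names(genes)),
            all(c("transcript_id", "locus_id") %in% names(transcripts)),
            all(c("transcript_id", "type", "start", "end") %in%
                  names(features)))
  if (anyDuplicated(genes$locus_id))
    stop("duplicated locus_id", call. = FALSE)
  if (!all(transcripts$locus_id %in% genes$locus_id))
    stop("transcript with unknown locus", call. = FALSE)
  if (!all(features$transcript_id %in% transcripts$transcript_id))
    stop("feature with unknown transcript", call. = FALSE)
  structure(list(genes = genes, transcripts = transcripts,
                 features = features), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet: %d loci, %d transcripts\n",
              nrow(x$genes), nrow(x$transcripts)))
  invisible(x)
}

## per-locus CDS intervals (union over transcripts), genome coords
locus_cds <- function(gs) {
  cds <- gs$features[gs$features$type == "CDS", , drop = FALSE]
  if (!nrow(cds))
    return(data.frame(locus_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0)))
  loc <- setNames(gs$transcripts$locus_id, gs$transcripts$transcript_id)
  cds$locus_id <- loc[cds$transcript_id]
  gmeta <- gs$genes[match(cds$locus_id, gs$genes$locus_id), ]
  cds$chrom <- gmeta$chrom
  cds$strand <- gmeta$strand
  cds[c("locus_id", "chrom", "strand", "start", "end")]
}

## locus ids in set `a` with same-strand CDS overlap against set `b`
cds_overlapping_loci <- function(a_cds, b_cds) {
  hits <- character(0)
  for (key in unique(paste(a_cds$chrom, a_cds$strand))) {
    av <- a_cds[paste(a_cds$chrom, a_cds$strand) == key, , drop = FALSE]
    bv <- b_cds[paste(b_cds$chrom, b_cds$strand) == key, , drop = FALSE]
    if (!nrow(av) || !nrow(bv)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(av$start + 1L, av$end),
      IRanges::IRanges(bv$start + 1L, bv$end))
    hits <- c(hits, unique(av$locus_id[S4Vectors::queryHits(ov)]))
  }
  unique(hits)
}

subset_gene_set <- function(gs, locus_ids) {
  genes <- gs$genes[gs$genes$locus_id %in% locus_ids, , drop = FALSE]
  tr <- gs$transcripts[gs$transcripts$locus_id %in% locus_ids, ,
                       drop = FALSE]
  fe <- gs$features[gs$features$transcript_id %in% tr$transcript_id, ,
                    drop = FALSE]
  gene_set(genes, tr, fe)
}

combine_gene_sets <- function(...) {
  sets <- Filter(Negate(is.null), list(...))
  gene_set(do.call(rbind, lapply(sets, function(s) s$genes)),
           do.call(rbind, lapply(sets, function(s) s$transcripts)),
           do.call(rbind, lapply(sets, function(s) s$features)))
}

validate_no_self_overlap <- function(gs, label) {
  cds <- locus_cds(gs)
  for (key in unique(paste(cds$chrom, cds$strand))) {
    v <- cds[paste(cds$chrom, cds$strand) == key, , drop = FALSE]
    ir <- IRanges::IRanges(v$start + 1L, v$end)
    ov <- IRanges::findOverlaps(ir, ir)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    bad <- which(q < s & v$locus_id[q] != v$locus_id[s])
    if (length(bad))
      stop("input set '", label, "' has overlapping loci: ",
           v$locus_id[q[bad[[1]]]], " / ", v$locus_id[s[bad[[1]]]],
           call. = FALSE)
  }
  invisible(gs)
}

#' Consolidate gene sets by source precedence
#'
#' Takes all primary (EVM) models; adds secondary (MAKER) models with
#' no same-strand CDS base overlap against the kept set; then adds
#' manual sets (community annotations, SPADA short-peptide models),
#' which override any overlapping computed model. Provenance is
#' retained in the `source` column.
#'
#' @param evm,maker,community,spada `GeneSet`s on the same assembly
#'   (`community` and `spada` may be `NULL`).
#' @return consolidated `GeneSet`.
#' @export
merge_gene_sets <- function(evm, maker, community = NULL, spada = NULL) {
  validate_no_self_overlap(evm, "evm")
  validate_no_self_overlap(maker, "maker")
  kept <- evm
  kept_cds <- locus_cds(kept)
  maker_cds <- locus_cds(maker)
  clash <- cds_overlapping_loci(maker_cds, kept_cds)
  add <- setdiff(maker$genes$locus_id, clash)
  kept <- combine_gene_sets(kept, subset_gene_set(maker, add))
  for (manual in Filter(Negate(is.null), list(community, spada))) {
    validate_no_self_overlap(manual, "manual")
    kept_cds <- locus_cds(kept)
    override <- cds_overlapping_loci(kept_cds, locus_cds(manual))
    kept <- subset_gene_set(kept,
                            setdiff(kept$genes$locus_id, override))
    kept <- combine_gene_sets(kept, manual)
  }
  kept
}

#' Deduplicate isoforms sharing an identical coding region
#'
#' Groups the transcripts of every locus by their ordered CDS interval
#' chain and retains only the longest (total exon length) transcript
#' in each group; ties keep the first in input order. Transcripts
#' without CDS form their own group each, with a warning.
#'
#' @param gs a `GeneSet`.
#' @return list with `set` (deduplicated `GeneSet`) and `summary`
#'   (per-locus data frame `locus_id`, `n_in`, `n_out` = number of
#'   distinct CDS chains).
#' @export
dedup_isoforms <- function(gs) {
  fe <- gs$features
  cds_key <- vapply(gs$transcripts$transcript_id, function(tid) {
    v <- fe[fe$transcript_id == tid & fe$type == "CDS", , drop = FALSE]
    if (!nrow(v)) return(NA_character_)
    v <- v[order(v$start), ]
    paste(v$start, v$end, sep = "-", collapse = ",")
  }, character(1))
  exon_len <- vapply(gs$transcripts$transcript_id, function(tid) {
    v <- fe[fe$transcript_id == tid & fe$type == "exon", , drop = FALSE]
    sum(v$end - v$start)
  }, numeric(1))
  if (any(is.na(cds_key))) {
    warning("transcript(s) without CDS kept as their own group: ",
            paste(gs$transcripts$transcript_id[is.na(cds_key)],
                  collapse = ", "))
    cds_key[is.na(cds_key)] <-
      paste0("nocds:", gs$transcripts$transcript_id[is.na(cds_key)])
  }
  keep <- logical(nrow(gs$transcripts))
  summaries <- list()
  for (lid in unique(gs$transcripts$locus_id)) {
    idx <- which(gs$transcripts$locus_id == lid)
    groups <- split(idx, cds_key[idx])
    for (grp in groups) {
      best <- grp[order(-exon_len[grp], grp)][[1]]
      keep[[best]] <- TRUE
    }
    summaries[[lid]] <- data.frame(locus_id = lid,
                                   n_in = length(idx),
                                   n_out = length(groups),
                                   stringsAsFactors = FALSE)
  }
  tr <- gs$transcripts[keep, , drop = FALSE]
  fe2 <- fe[fe$transcript_id %in% tr$transcript_id, , drop = FALSE]
  list(set = gene_set(gs$genes, tr, fe2),
       summary = do.call(rbind, summaries))
}

#' Protein length (aa) per locus
#'
#' Longest-transcript CDS length divided by three.
#' @param gs a `GeneSet`.
#' @return named numeric vector.
#' @export
protein_lengths <- function(gs) {
  cds <- gs$features[gs$features$type == "CDS", , drop = FALSE]
  loc <- setNames(gs$transcripts$locus_id, gs$transcripts$transcript_id)
  per_tr <- tapply(cds$end - cds$start, cds$transcript_id, sum)
  out <- setNames(rep(0, nrow(gs$genes)), gs$genes$locus_id)
  if (length(per_tr)) {
    per_loc <- tapply(as.numeric(per_tr), loc[names(per_tr)], max)
    out[names(per_loc)] <- per_loc / 3
  }
  out
}

#' Drop short predictions
#'
#' Removes models whose protein is shorter than `min_protein_aa`
#' (default 50 aa), except models from sources in `exempt` (SPADA
#' peptides are known to be short).
#'
#' @param gs a `GeneSet`.
#' @param config a [pipeline_config()].
#' @param exempt sources never dropped.
#' @return filtered `GeneSet`.
#' @export
length_filter <- function(gs, config = NULL, exempt = "spada") {
  config <- as_config(config)
  aa <- protein_lengths(gs)
  drop <- names(aa)[aa < config$min_protein_aa]
  src <- setNames(gs$genes$source, gs$genes$locus_id)
  drop <- drop[!src[drop] %in% exempt]
  subset_gene_set(gs, setdiff(gs$genes$locus_id, drop))
}

#' Default evidence thresholds for confidence classes
#' @return list of floors used by [classify_confidence()].
#' @export
confidence_thresholds <- function() {
  list(transcript_cov = 0.90, transcript_id = 0.95,
       protein_cov = 0.70, protein_id = 0.60)
}

#' Bin gene models into confidence classes
#'
#' A locus is high-confidence (`HC`) when its best transcript
#' alignment reaches the transcript coverage and identity floors or
#' its best protein alignment reaches the protein floors;
#' low-confidence (`LC`) when it has some evidence but below the
#' floors; `unsupported` when it has none. A transposable-element flag
#' (supplied, since repeat classification is a separate pipeline)
#' overrides the class to `TE`. The summary mirrors the usual
#' per-class characteristics: gene counts, single/multi-exon counts,
#' mean locus span, mean exons per gene and mean transcripts per gene.
#'
#' @param gs a `GeneSet`.
#' @param evidence data frame `locus_id`, `transcript_cov`,
#'   `transcript_id`, `protein_cov`, `protein_id` (fractions; missing
#'   loci count as zero support, with a warning).
#' @param thresholds list as from [confidence_thresholds()].
#' @param te_loci locus ids flagged as transposable elements.
#' @return list with `calls` (data frame `locus_id`, `class`,
#'   `criteria`) and `summary` (per-class data frame).
#' @export
classify_confidence <- function(gs, evidence,
                                thresholds = confidence_thresholds(),
                                te_loci = character(0)) {
  ev <- evidence[match(gs$genes$locus_id, evidence$locus_id), ,
                 drop = FALSE]
  missing <- is.na(ev$locus_id)
  if (any(missing))
    warning(sum(missing), " locus/loci without evidence record; ",
            "treated as zero support")
  for (col in c("transcript_cov", "transcript_id", "protein_cov",
                "protein_id")) {
    ev[[col]][is.na(ev[[col]])] <- 0
  }
  tr_ok <- ev$transcript_cov >= thresholds$transcript_cov &
    ev$transcript_id >= thresholds$transcript_id
  pr_ok <- ev$protein_cov >= thresholds$protein_cov &
    ev$protein_id >= thresholds$protein_id
  any_ev <- ev$transcript_cov > 0 | ev$protein_cov > 0
  class <- ifelse(tr_ok | pr_ok, "HC",
                  ifelse(any_ev, "LC", "unsupported"))
  criteria <- ifelse(tr_ok, "transcript",
                     ifelse(pr_ok, "protein",
                            ifelse(any_ev, "partial", "none")))
  class[gs$genes$locus_id %in% te_loci] <- "TE"
  calls <- data.frame(locus_id = gs$genes$locus_id, class = class,
                      criteria = criteria, stringsAsFactors = FALSE)
  ## per-class characteristics
  loc <- setNames(gs$transcripts$locus_id, gs$transcripts$transcript_id)
  ex <- gs$features[gs$features$type == "exon", , drop = FALSE]
  ex_per_tr <- table(ex$transcript_id)
  ex_per_loc <- tapply(as.integer(ex_per_tr),
                       loc[names(ex_per_tr)], max)
  tr_per_loc <- table(gs$transcripts$locus_id)
  span <- setNames(gs$genes$end - gs$genes$start, gs$genes$locus_id)
  summ <- lapply(c("HC", "LC", "unsupported", "TE"), function(cl) {
    ids <- calls$locus_id[calls$class == cl]
    if (!length(ids))
      return(data.frame(class = cl, n_genes = 0L, single_exon = 0L,
                        multi_exon = 0L, mean_span = NA_real_,
                        mean_exons = NA_real_,
                        mean_transcripts = NA_real_))
    nex <- ex_per_loc[ids]; nex[is.na(nex)] <- 0
    data.frame(class = cl, n_genes = length(ids),
               single_exon = sum(nex == 1),
               multi_exon = sum(nex > 1),
               mean_span = mean(span[ids]),
               mean_exons = mean(nex),
               mean_transcripts = mean(as.integer(tr_per_loc[ids])),
               stringsAsFactors = FALSE)
  })
  list(calls = calls, summary = do.call(rbind, summ))
}

#' Read gene models from GFF3
#'
#' Expects the conventional three-level gene / mRNA / exon+CDS
#' hierarchy linked by `ID` and `Parent` attributes; imported with
#' rtracklayer and converted to 0-based half-open coordinates.
#'
#' @param path GFF3 file.
#' @param source value for the `source` column (defaults to the GFF
#'   source of each gene).
#' @return a `GeneSet`.
#' @export
read_gff_genes <- function(path, source = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$ID <- as.character(df$ID)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[[1]] else NA_character_, character(1))
  g <- df[df$type == "gene", ]
  genes <- data.frame(locus_id = g$ID, chrom = as.character(g$seqnames),
                      start = g$start - 1L, end = g$end,
                      strand = as.character(g$strand),
                      source = if (is.null(source))
                        as.character(g$source) else source,
                      stringsAsFactors = FALSE)
  m <- df[df$type == "mRNA", ]
  transcripts <- data.frame(transcript_id = m$ID, locus_id = m$Parent,
                            stringsAsFactors = FALSE)
  f <- df[df$type %in% c("exon", "CDS"), ]
  features <- data.frame(transcript_id = f$Parent,
                         type = as.character(f$type),
                         start = f$start - 1L, end = f$end,
                         stringsAsFactors = FALSE)
  gene_set(genes, transcripts, features)
}

#' Write a GeneSet as GFF3
#' @param gs a `GeneSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(gs, path) {
  lines <- c("##gff-version 3")
  tr_by_locus <- split(gs$transcripts$transcript_id,
                       gs$transcripts$locus_id)
  for (i in seq_len(nrow(gs$genes))) {
    g <- gs$genes[i, ]
    lines <- c(lines, paste(g$chrom, "uplift", "gene", g$start + 1L,
                            g$end, ".", g$strand, ".",
                            paste0("ID=", g$locus_id), sep = "\t"))
    for (tid in tr_by_locus[[g$locus_id]]) {
      fe <- gs$features[gs$features$transcript_id == tid, , drop = FALSE]
      lines <- c(lines, paste(g$chrom, "uplift", "mRNA",
                              min(fe$start) + 1L, max(fe$end), ".",
                              g$strand, ".",
                              paste0("ID=", tid, ";Parent=", g$locus_id),
                              sep = "\t"))
      fe <- fe[order(fe$start), ]
      for (j in seq_len(nrow(fe))) {
        lines <- c(lines, paste(g$chrom, "uplift", fe$type[[j]],
                                fe$start[[j]] + 1L, fe$end[[j]], ".",
                                g$strand,
                                if (fe$type[[j]] == "CDS") "0" else ".",
                                paste0("Parent=", tid), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
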