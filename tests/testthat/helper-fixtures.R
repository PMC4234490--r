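## shared fixture builders and independent oracles

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_str <- function(s) uplift:::revcomp(s)

## tiny genotype matrix from explicit call strings, one per marker
gm_from_strings <- function(calls, scaffold = "s1",
                            positions = NULL) {
  mat <- do.call(rbind, lapply(calls, function(x) strsplit(x, "")[[1]]))
  n <- ncol(mat)
  colnames(mat) <- sprintf("I%02d", seq_len(n))
  if (is.null(positions)) positions <- seq_len(nrow(mat)) * 1000L
  genotype_matrix(
    data.frame(marker_id = sprintf("m%02d", seq_len(nrow(mat))),
               scaffold_id = scaffold, position = positions,
               type = "SNP", stringsAsFactors = FALSE),
    mat)
}

## brute-force LD oracle: haplotype counting over complete pairs
ld_oracle <- function(a, b) {
  ok <- a != "-" & b != "-"
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) return(NA_real_)
  nA <- sum(a == "B"); nB <- sum(b == "B")
  pA <- nA / n; pB <- nB / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  pAB <- sum(a == "B" & b == "B") / n
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

## exhaustive-score Needleman-Wunsch oracle for proteins:
## match +1, mismatch/gap 0 band-free DP returning matches on the best
## global path (longest common subsequence formulation), independent
## of the Biostrings-based implementation route
nw_matches_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- max(d[i, j] + (a[[i]] == b[[j]]),
                           d[i, j + 1], d[i + 1, j])
  }
  d[n + 1, m + 1]
}

## brute-force max-weight non-overlapping block subset (bitmask
## enumeration) for quota-filter verification
quota_oracle <- function(blocks) {
  n <- length(blocks)
  if (!n) return(0)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && uplift:::blocks_conflict(blocks[[i]], blocks[[j]]))
      conflict[i, j] <- conflict[j, i] <- TRUE
  }
  w <- vapply(blocks, `[[`, numeric(1), "score")
  cmask <- integer(n)
  for (i in seq_len(n))
    cmask[[i]] <- sum(bitwShiftL(1L, which(conflict[i, ]) - 1L))
  best <- 0
  for (s in 0:(bitwShiftL(1L, n) - 1L)) {
    bits <- which(bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    ok <- TRUE
    for (i in bits) {
      if (bitwAnd(cmask[[i]], s) != 0L) { ok <- FALSE; break }
    }
    if (ok) best <- max(best, sum(w[bits]))
  }
  best
}

## random synteny-block instance for quota testing
random_block_instance <- function(n_blocks, n_chroms = 2L,
                                  rank_max = 100L) {
  blocks <- list()
  for (i in seq_len(n_blocks)) {
    ca <- sprintf("A%d", sample.int(n_chroms, 1))
    cb <- sprintf("B%d", sample.int(n_chroms, 1))
    a0 <- sample.int(rank_max, 1); b0 <- sample.int(rank_max, 1)
    blocks[[i]] <- list(chrom_a = ca, chrom_b = cb,
                        orientation = "collinear",
                        n_pairs = NA_integer_,
                        score = sample(5:30, 1),
                        a_range = c(a0, a0 + sample.int(30, 1)),
                        b_range = c(b0, b0 + sample.int(30, 1)))
  }
  blocks
}

## placement records for the children produced by splitting the
## injected chimeras of a fragment_into_scaffolds() result (exact,
## jitter-free: the truth layout itself)
child_placements <- function(fr) {
  lay <- fr$layout
  chim <- fr$chimeras
  rows <- list()
  for (i in seq_len(nrow(lay))) {
    L <- lay[i, ]
    sid <- L$scaffold_id
    if (!is.null(chim) && sid %in% chim$scaffold_id) {
      cj <- chim[chim$scaffold_id == sid, ]
      if (L$part == 1L) {
        sid <- paste0(sid, "_1")
        s0 <- 0L; s1 <- cj$junction_start
      } else {
        sid <- paste0(sid, "_2")
        s0 <- 0L; s1 <- L$scaf_end - L$scaf_start
      }
    } else {
      s0 <- L$scaf_start; s1 <- L$scaf_end
    }
    rows[[i]] <- data.frame(scaffold_id = sid, scaffold_start = s0,
                            scaffold_end = s1, chrom_id = L$chrom,
                            chrom_start = L$chrom_start,
                            chrom_end = L$chrom_end,
                            orientation = L$orientation,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## small annotation set builder: loci as list(locus_id, chrom, strand,
## source, exons = list of c(start, end), cds = list of c(start, end))
gs_from_loci <- function(loci) {
  genes <- list(); trs <- list(); fes <- list()
  for (L in loci) {
    ntr <- if (is.null(L$transcripts)) 1L else length(L$transcripts)
    exon_sets <- if (is.null(L$transcripts)) list(L$exons)
      else lapply(L$transcripts, `[[`, "exons")
    cds_sets <- if (is.null(L$transcripts)) list(L$cds)
      else lapply(L$transcripts, `[[`, "cds")
    span <- range(unlist(exon_sets))
    genes[[length(genes) + 1L]] <- data.frame(
      locus_id = L$locus_id, chrom = L$chrom, start = span[[1]],
      end = span[[2]], strand = L$strand,
      source = if (is.null(L$source)) "evm" else L$source,
      stringsAsFactors = FALSE)
    for (t in seq_len(ntr)) {
      tid <- sprintf("%s.%d", L$locus_id, t)
      trs[[length(trs) + 1L]] <- data.frame(
        transcript_id = tid, locus_id = L$locus_id,
        stringsAsFactors = FALSE)
      ex <- exon_sets[[t]]
      for (iv in ex)
        fes[[length(fes) + 1L]] <- data.frame(
          transcript_id = tid, type = "exon", start = iv[[1]],
          end = iv[[2]], stringsAsFactors = FALSE)
      for (iv in cds_sets[[t]])
        fes[[length(fes) + 1L]] <- data.frame(
          transcript_id = tid, type = "CDS", start = iv[[1]],
          end = iv[[2]], stringsAsFactors = FALSE)
    }
  }
  gene_set(do.call(rbind, genes), do.call(rbind, trs),
           do.call(rbind, fes))
}
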