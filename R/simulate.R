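#' Parameters for the synthetic truth genome and derived evidence
#'
#' The generator emulates the upgrade scenario at desk scale: a truth
#' genome of `n_chromosomes` chromosomes of `chrom_length` bp is
#' fragmented into scaffolds (a known fraction of them chimeric), a
#' recombinant-inbred-line population of `n_individuals` is genotyped
#' at `markers_per_chrom` markers per chromosome via a read-depth
#' model, and map placements, clone-end links and a variant-bearing
#' legacy assembly are derived from the known layout. The defaults
#' mirror the study conditions of the real workflow where stated
#' (139 mapping individuals, mean read depth 8, fosmid-style
#' 35 kb +/- 7 kb link library, duplication divergence centred on a
#' Ks mode of 0.64) and desk-scale choices elsewhere.
#'
#' @param n_chromosomes number of truth chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param n_individuals mapping-population size.
#' @param markers_per_chrom markers per chromosome.
#' @param missing_rate per-site probability of a missing (zero-depth)
#'   observation.
#' @param distortion_region_fraction fraction of chromosome 1 (its
#'   left arm) under segregation distortion.
#' @param distortion_strength probability that an individual carrying
#'   the alternative allele in the distorted region is resampled
#'   (emulating selection against one parental genotype).
#' @param scaffolds_per_chrom scaffolds each chromosome is cut into.
#' @param chimera_rate fraction of scaffolds that wrongly join
#'   segments from two chromosomes.
#' @param gaps_per_scaffold interior N-gaps masked into each scaffold.
#' @param gap_len length (bp) of each masked gap.
#' @param legacy_variant_rate per-base substitution rate of the legacy
#'   assembly relative to truth.
#' @param depth_mean mean Poisson read depth per called site.
#' @param residual_het residual heterozygosity rate per site per
#'   individual (an inbred line is not perfectly homozygous).
#' @param map_length_morgan genetic map length per chromosome.
#' @param library_mean,library_sd clone-link insert-size model (bp).
#' @param links_per_chrom simulated clone links per chromosome.
#' @param placement_jitter placement coordinate jitter (bp, uniform
#'   within +/- this value).
#' @param genes_per_chrom gene models per chromosome.
#' @param n_dup_blocks,dup_block_genes segmental-duplication blocks
#'   and gene pairs per block planted in the truth genome.
#' @param ks_mode,ks_sd centre and spread of the synonymous
#'   divergence drawn for duplication gene pairs.
#' @param seed random seed recorded in all outputs.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_chromosomes = 10L,
                              chrom_length = 1000000L,
                              n_individuals = 139L,
                              markers_per_chrom = 100L,
                              missing_rate = 0.05,
                              distortion_region_fraction = 0.25,
                              distortion_strength = 0.7,
                              scaffolds_per_chrom = 10L,
                              chimera_rate = 0.2,
                              gaps_per_scaffold = 2L,
                              gap_len = 100L,
                              legacy_variant_rate = 0.001,
                              depth_mean = 8,
                              residual_het = 0.005,
                              map_length_morgan = 1,
                              library_mean = 35000,
                              library_sd = 7000,
                              links_per_chrom = 50L,
                              placement_jitter = 1000L,
                              genes_per_chrom = 100L,
                              n_dup_blocks = 3L,
                              dup_block_genes = 30L,
                              ks_mode = 0.64,
                              ks_sd = 0.06,
                              seed = 1L) {
  p <- as.list(environment())
  rates <- c("missing_rate", "distortion_region_fraction",
             "distortion_strength", "chimera_rate",
             "legacy_variant_rate", "residual_het")
  for (r in rates) {
    if (p[[r]] < 0 || p[[r]] > 1)
      stop(r, " must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

chrom_names <- function(p) sprintf("chr%02d", seq_len(p$n_chromosomes))

#' Simulate a truth genome
#'
#' Generates chromosome sequences, evenly laid-out gene models,
#' sorted marker positions, and planted segmental-duplication blocks
#' whose gene pairs carry synonymous divergence drawn around
#' `ks_mode`. Deterministic given `seed`.
#'
#' @param params a [simulation_params()].
#' @return list of class `TruthGenome` with `chromosomes`
#'   (`ScaffoldSet`), `gene_coords`, `marker_positions`,
#'   `duplication_blocks` (data frame of gene pairs with `block_id`
#'   and `ks`) and `params`.
#' @export
simulate_truth <- function(params) {
  p <- params
  if (p$chrom_length < 10L * p$markers_per_chrom)
    stop("chrom_length too small for markers_per_chrom", call. = FALSE)
  set.seed(p$seed)
  chroms <- chrom_names(p)
  seqs <- setNames(vapply(chroms, function(x) random_dna(p$chrom_length),
                          character(1)), chroms)
  ## genes: evenly spaced, 1 kb models, alternating strand
  genes <- list()
  glen <- min(1000L, p$chrom_length %/% (2L * p$genes_per_chrom))
  for (ci in seq_along(chroms)) {
    starts <- round(seq(0, p$chrom_length - glen,
                        length.out = p$genes_per_chrom))
    genes[[ci]] <- data.frame(
      gene_id = sprintf("%s.g%04d", chroms[[ci]],
                        seq_len(p$genes_per_chrom)),
      chrom = chroms[[ci]], start = as.integer(starts),
      end = as.integer(starts + glen),
      strand = rep_len(c("+", "-"), p$genes_per_chrom),
      rank = seq_len(p$genes_per_chrom) - 1L,
      stringsAsFactors = FALSE)
  }
  gene_coords <- do.call(rbind, genes)
  ## markers: sorted uniform positions per chromosome
  markers <- list()
  for (ci in seq_along(chroms)) {
    pos <- sort(sample.int(p$chrom_length - 1L, p$markers_per_chrom))
    markers[[ci]] <- data.frame(
      marker_id = sprintf("%s.m%04d", chroms[[ci]],
                          seq_len(p$markers_per_chrom)),
      chrom = chroms[[ci]], pos = as.integer(pos),
      stringsAsFactors = FALSE)
  }
  marker_positions <- do.call(rbind, markers)
  ## segmental duplications in gene-rank space: block k pairs a run of
  ## genes on one chromosome with a run on another, collinear
  dup <- list()
  if (p$n_dup_blocks > 0 && p$n_chromosomes >= 2) {
    n <- p$n_chromosomes
    for (b in seq_len(p$n_dup_blocks)) {
      ## chromosome pairs cycle; rank windows advance one slot per
      ## cycle so planted blocks never overlap on either axis
      ca <- chroms[[((b - 1L) %% n) + 1L]]
      cb <- chroms[[(b %% n) + 1L]]
      slot <- (b - 1L) %/% n
      ra <- slot * (p$dup_block_genes + 2L)
      rb <- ra + 3L
      if (rb + p$dup_block_genes > p$genes_per_chrom)
        stop("genes_per_chrom too small for the requested duplication blocks",
             call. = FALSE)
      ks <- abs(rnorm(p$dup_block_genes, p$ks_mode, p$ks_sd))
      dup[[b]] <- data.frame(
        block_id = b,
        gene_a = sprintf("%s.g%04d", ca, ra + seq_len(p$dup_block_genes)),
        chrom_a = ca, rank_a = ra + seq_len(p$dup_block_genes) - 1L,
        gene_b = sprintf("%s.g%04d", cb, rb + seq_len(p$dup_block_genes)),
        chrom_b = cb, rank_b = rb + seq_len(p$dup_block_genes) - 1L,
        ks = ks, stringsAsFactors = FALSE)
    }
  }
  structure(list(chromosomes = scaffold_set(seqs),
                 gene_coords = gene_coords,
                 marker_positions = marker_positions,
                 duplication_blocks = if (length(dup)) do.call(rbind, dup)
                   else NULL,
                 params = p),
            class = "TruthGenome")
}

#' Fragment the truth genome into scaffolds with injected chimeras
#'
#' Cuts every chromosome into `scaffolds_per_chrom` segments, masks
#' `gaps_per_scaffold` interior N-gaps into each (the gap positions
#' stay aligned to truth coordinates, emulating sequencing gaps), and
#' joins a `chimera_rate` fraction of segment pairs from different
#' chromosomes into chimeric scaffolds with an N-gap at the junction.
#'
#' @param truth a `TruthGenome`.
#' @param params a [simulation_params()].
#' @return list with `set` (`ScaffoldSet`), `layout` (data frame
#'   `scaffold_id`, `part`, `chrom`, `chrom_start`, `chrom_end`,
#'   `scaf_start`, `scaf_end`, `orientation`) and `chimeras` (data
#'   frame `scaffold_id`, `junction_start`, `junction_end`,
#'   `chrom_left`, `chrom_right`).
#' @export
fragment_into_scaffolds <- function(truth, params = truth$params) {
  p <- params
  set.seed(p$seed + 1L)
  chroms <- names(truth$chromosomes$seqs)
  segs <- list()
  for (chrom in chroms) {
    len <- nchar(truth$chromosomes$seqs[[chrom]])
    n_s <- p$scaffolds_per_chrom
    cuts <- round(seq(0, len, length.out = n_s + 1L))[-c(1L, n_s + 1L)]
    wig <- max(1L, len %/% (10L * n_s))
    cuts <- sort(cuts + sample(seq(-wig, wig), length(cuts),
                               replace = TRUE))
    bounds <- as.integer(c(0L, cuts, len))
    for (i in seq_len(p$scaffolds_per_chrom)) {
      segs[[length(segs) + 1L]] <-
        list(chrom = chrom, start = bounds[[i]], end = bounds[[i + 1L]])
    }
  }
  n_seg <- length(segs)
  ## c chimeras consume 2c segments, leaving n_seg - c scaffolds in
  ## total; solve c / (n_seg - c) = chimera_rate
  n_chim <- max(0L, round(p$chimera_rate * n_seg /
                            (1 + p$chimera_rate)))
  seg_chrom <- vapply(segs, `[[`, character(1), "chrom")
  pool <- seq_len(n_seg)
  pairs <- list()
  while (length(pairs) < n_chim && length(pool) >= 2) {
    a <- sample(pool, 1L)
    cand <- pool[seg_chrom[pool] != seg_chrom[[a]] & pool != a]
    if (!length(cand)) break
    b <- if (length(cand) == 1) cand else sample(cand, 1L)
    pairs[[length(pairs) + 1L]] <- c(a, b)
    pool <- setdiff(pool, c(a, b))
  }
  mask_gaps <- function(seq, n_gaps, gap_len) {
    len <- nchar(seq)
    if (len < (n_gaps + 2L) * (gap_len + 2000L)) return(seq)
    pos <- sort(sample(seq(2000L, len - 2000L - gap_len), n_gaps))
    ## drop overlapping picks
    keep <- c(TRUE, diff(pos) > gap_len + 2000L)
    for (s in pos[keep]) {
      seq <- paste0(substr(seq, 1, s), n_run(gap_len),
                    substr(seq, s + gap_len + 1L, len))
    }
    seq
  }
  seqs <- character(0)
  layout <- list(); chimeras <- list()
  k <- 0L
  add_part <- function(layout, sid, part, seg, scaf_off) {
    layout[[length(layout) + 1L]] <- data.frame(
      scaffold_id = sid, part = part, chrom = seg$chrom,
      chrom_start = seg$start, chrom_end = seg$end,
      scaf_start = scaf_off, scaf_end = scaf_off + (seg$end - seg$start),
      orientation = "+", stringsAsFactors = FALSE)
    layout
  }
  paired <- unlist(pairs)
  for (pr in pairs) {
    k <- k + 1L
    sid <- sprintf("scaffold%04d", k)
    s1 <- segs[[pr[[1]]]]; s2 <- segs[[pr[[2]]]]
    seq1 <- subseq0(truth$chromosomes$seqs[[s1$chrom]], s1$start, s1$end)
    seq2 <- subseq0(truth$chromosomes$seqs[[s2$chrom]], s2$start, s2$end)
    seq1 <- mask_gaps(seq1, p$gaps_per_scaffold, p$gap_len)
    seq2 <- mask_gaps(seq2, p$gaps_per_scaffold, p$gap_len)
    l1 <- nchar(seq1)
    seqs[[sid]] <- paste0(seq1, n_run(p$gap_len), seq2)
    layout <- add_part(layout, sid, 1L, s1, 0L)
    layout <- add_part(layout, sid, 2L, s2, l1 + p$gap_len)
    chimeras[[length(chimeras) + 1L]] <- data.frame(
      scaffold_id = sid, junction_start = l1,
      junction_end = l1 + p$gap_len, chrom_left = s1$chrom,
      chrom_right = s2$chrom, stringsAsFactors = FALSE)
  }
  for (si in setdiff(seq_len(n_seg), paired)) {
    k <- k + 1L
    sid <- sprintf("scaffold%04d", k)
    seg <- segs[[si]]
    sq <- subseq0(truth$chromosomes$seqs[[seg$chrom]], seg$start, seg$end)
    seqs[[sid]] <- mask_gaps(sq, p$gaps_per_scaffold, p$gap_len)
    layout <- add_part(layout, sid, 1L, seg, 0L)
  }
  list(set = scaffold_set(seqs), layout = do.call(rbind, layout),
       chimeras = if (length(chimeras)) do.call(rbind, chimeras)
         else NULL)
}

## map truth (chrom, pos) onto scaffold coordinates via the layout
map_to_scaffold <- function(layout, chrom, pos) {
  out <- data.frame(scaffold_id = NA_character_,
                    position = NA_integer_,
                    chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(layout))) {
    L <- layout[i, ]
    sel <- which(out$chrom == L$chrom & out$pos >= L$chrom_start &
                   out$pos < L$chrom_end & is.na(out$scaffold_id))
    if (length(sel)) {
      out$scaffold_id[sel] <- L$scaffold_id
      out$position[sel] <- L$scaf_start + (out$pos[sel] - L$chrom_start)
    }
  }
  out
}

#' Simulate RIL genotypes with a read-depth model
#'
#' Individuals are recombinant mosaics of the two parental haplotypes
#' (Markov crossover process, `map_length_morgan` per chromosome) with
#' a small residual heterozygosity. The left arm of chromosome 1 is
#' put under segregation distortion by resampling individuals that
#' carry the alternative allele there. Read depths are Poisson with
#' mean `depth_mean`; sites are dropped to zero depth at
#' `missing_rate`; residual heterozygous sites emit both alleles.
#'
#' @param truth a `TruthGenome`.
#' @param params a [simulation_params()].
#' @param layout optional scaffold layout from
#'   [fragment_into_scaffolds()]; when given, the marker table carries
#'   scaffold ids and scaffold positions (markers falling into no
#'   scaffold part are dropped), otherwise chromosome coordinates.
#' @return list with `ref_depth`, `alt_depth` (matrices), `markers`
#'   (marker table matching the rows), `truth_calls` (A/B/- matrix:
#'   the mosaic with residual-heterozygous sites as `-`) and
#'   `distorted_markers` (ids under distortion).
#' @export
simulate_ril_genotypes <- function(truth, params = truth$params,
                                   layout = NULL) {
  p <- params
  set.seed(p$seed + 2L)
  mk <- truth$marker_positions
  chroms <- unique(mk$chrom)
  n_ind <- p$n_individuals
  geno <- matrix(NA_integer_, nrow(mk), n_ind) # 0 = A, 1 = B
  dist_chrom <- chroms[[1]]
  dist_limit <- p$distortion_region_fraction *
    nchar(truth$chromosomes$seqs[[dist_chrom]])
  mosaic_chrom <- function(pos, len) {
    m <- length(pos)
    r <- pmin(0.5, diff(pos) / len * p$map_length_morgan)
    g <- integer(m)
    g[[1]] <- rbinom(1, 1, 0.5)
    if (m > 1) {
      sw <- rbinom(m - 1L, 1, r)
      g <- (g[[1]] + cumsum(c(0L, sw))) %% 2L
    }
    g
  }
  for (chrom in chroms) {
    rows <- which(mk$chrom == chrom)
    pos <- mk$pos[rows]
    len <- nchar(truth$chromosomes$seqs[[chrom]])
    focal <- if (chrom == dist_chrom)
      which(pos <= dist_limit) else integer(0)
    focal <- if (length(focal)) focal[[ceiling(length(focal) / 2)]]
      else NA_integer_
    for (ind in seq_len(n_ind)) {
      g <- mosaic_chrom(pos, len)
      if (!is.na(focal)) {
        ## selection against the alternative parent on the distorted arm
        while (g[[focal]] == 1L && runif(1) < p$distortion_strength)
          g <- mosaic_chrom(pos, len)
      }
      geno[rows, ind] <- g
    }
  }
  het <- matrix(runif(length(geno)) < p$residual_het, nrow(geno))
  miss <- matrix(runif(length(geno)) < p$missing_rate, nrow(geno))
  depth <- matrix(rpois(length(geno), p$depth_mean), nrow(geno))
  depth[miss] <- 0L
  ref <- matrix(0L, nrow(geno), n_ind)
  alt <- matrix(0L, nrow(geno), n_ind)
  hom_a <- !het & geno == 0L
  hom_b <- !het & geno == 1L
  ref[hom_a] <- depth[hom_a]
  alt[hom_b] <- depth[hom_b]
  if (any(het)) {
    hr <- rbinom(sum(het), depth[het], 0.5)
    ref[het] <- hr
    alt[het] <- depth[het] - hr
  }
  truth_calls <- matrix("-", nrow(geno), n_ind)
  truth_calls[!het & geno == 0L] <- "A"
  truth_calls[!het & geno == 1L] <- "B"
  ind_ids <- sprintf("RIL%03d", seq_len(n_ind))
  colnames(ref) <- colnames(alt) <- colnames(truth_calls) <- ind_ids
  if (!is.null(layout)) {
    mapped <- map_to_scaffold(layout, mk$chrom, mk$pos)
    keep <- !is.na(mapped$scaffold_id)
    markers <- data.frame(marker_id = mk$marker_id[keep],
                          scaffold_id = mapped$scaffold_id[keep],
                          position = mapped$position[keep],
                          type = "SNP", chrom = mk$chrom[keep],
                          chrom_pos = mk$pos[keep],
                          stringsAsFactors = FALSE)
    ref <- ref[keep, , drop = FALSE]
    alt <- alt[keep, , drop = FALSE]
    truth_calls <- truth_calls[keep, , drop = FALSE]
  } else {
    markers <- data.frame(marker_id = mk$marker_id,
                          scaffold_id = mk$chrom, position = mk$pos,
                          type = "SNP", chrom = mk$chrom,
                          chrom_pos = mk$pos, stringsAsFactors = FALSE)
  }
  rownames(ref) <- rownames(alt) <- rownames(truth_calls) <-
    markers$marker_id
  distorted <- mk$marker_id[mk$chrom == dist_chrom &
                              mk$pos <= dist_limit]
  list(ref_depth = ref, alt_depth = alt, markers = markers,
       truth_calls = truth_calls, distorted_markers = distorted,
       individuals = ind_ids)
}

#' Derive placement, clone-link and legacy evidence from the layout
#'
#' Placements are the true scaffold part positions with uniform
#' coordinate jitter (chimeric scaffolds therefore receive placements
#' on two chromosomes); clone links are drawn by sampling insert
#' sizes from the library model around random chromosome positions
#' and mapping both ends back to scaffolds; the legacy assembly is
#' the truth genome with point substitutions at
#' `legacy_variant_rate` (so gaps masked in the scaffolds are intact
#' in the legacy sequence), carrying legacy gene models with stable
#' `Medtr`-style identifiers spaced by a stride of 10.
#'
#' @param truth a `TruthGenome`.
#' @param layout scaffold layout from [fragment_into_scaffolds()].
#' @param params a [simulation_params()].
#' @return list with `placements`, `clone_links`, `legacy_set`,
#'   `legacy_genes` (`GeneSet`).
#' @export
derive_evidence <- function(truth, layout, params = truth$params) {
  p <- params
  set.seed(p$seed + 3L)
  jit <- function(n) if (p$placement_jitter > 0)
    sample(seq(-p$placement_jitter, p$placement_jitter), n,
           replace = TRUE) else rep(0L, n)
  placements <- data.frame(
    scaffold_id = layout$scaffold_id,
    scaffold_start = layout$scaf_start,
    scaffold_end = layout$scaf_end,
    chrom_id = layout$chrom,
    chrom_start = pmax(0L, layout$chrom_start + jit(nrow(layout))),
    chrom_end = layout$chrom_end + jit(nrow(layout)),
    orientation = layout$orientation, stringsAsFactors = FALSE)
  placements$chrom_end <- pmax(placements$chrom_end,
                               placements$chrom_start + 1L)
  ## clone links
  links <- list()
  for (chrom in names(truth$chromosomes$seqs)) {
    len <- nchar(truth$chromosomes$seqs[[chrom]])
    n <- p$links_per_chrom
    a <- sample.int(max(1L, len - as.integer(p$library_mean) - 1L), n)
    span <- pmax(1000, round(rnorm(n, p$library_mean, p$library_sd)))
    b <- pmin(len - 1L, a + as.integer(span))
    m1 <- map_to_scaffold(layout, rep(chrom, n), a)
    m2 <- map_to_scaffold(layout, rep(chrom, n), b)
    ok <- !is.na(m1$scaffold_id) & !is.na(m2$scaffold_id)
    if (!any(ok)) next
    links[[chrom]] <- data.frame(
      end1_scaffold = m1$scaffold_id[ok], end1_pos = m1$position[ok],
      end2_scaffold = m2$scaffold_id[ok], end2_pos = m2$position[ok],
      library_mean = p$library_mean, library_sd = p$library_sd,
      stringsAsFactors = FALSE)
  }
  clone_links <- do.call(rbind, links)
  rownames(clone_links) <- NULL
  ## legacy assembly: truth with point substitutions
  legacy <- vapply(names(truth$chromosomes$seqs), function(chrom) {
    s <- truth$chromosomes$seqs[[chrom]]
    mutate_sequence(s, p$legacy_variant_rate)
  }, character(1))
  names(legacy) <- sub("^chr", "legacy_chr", names(legacy))
  legacy_set <- scaffold_set(legacy)
  ## legacy gene models with stable Medtr-style identifiers
  gc <- truth$gene_coords
  chrom_no <- match(gc$chrom, names(truth$chromosomes$seqs))
  ids <- format_gene_id(chrom_no, 10000L + 10L * gc$rank)
  genes <- data.frame(locus_id = ids,
                      chrom = sub("^chr", "legacy_chr", gc$chrom),
                      start = gc$start, end = gc$end,
                      strand = gc$strand, source = "legacy",
                      stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = paste0(ids, ".1"),
                            locus_id = ids, stringsAsFactors = FALSE)
  features <- rbind(
    data.frame(transcript_id = paste0(ids, ".1"), type = "exon",
               start = gc$start, end = gc$end, stringsAsFactors = FALSE),
    data.frame(transcript_id = paste0(ids, ".1"), type = "CDS",
               start = gc$start, end = gc$end, stringsAsFactors = FALSE))
  list(placements = placements, clone_links = clone_links,
       legacy_set = legacy_set,
       legacy_genes = gene_set(genes, transcripts, features))
}

## substitute bases at the given per-base rate (never to the same base)
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  len <- nchar(seq)
  n_mut <- rbinom(1, len, rate)
  if (n_mut == 0) return(seq)
  pos <- sample.int(len, n_mut)
  ch <- strsplit(seq, "")[[1]]
  sub_map <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"),
                  N = "N")
  for (i in pos) {
    alts <- sub_map[[ch[[i]]]]
    ch[[i]] <- alts[[sample.int(length(alts), 1)]]
  }
  paste(ch, collapse = "")
}

#' Derive anchor hits from the planted duplication blocks
#'
#' Emits one anchor hit per duplication gene pair (carrying its Ks
#' value) plus `n_noise` uniformly random background pairs, emulating
#' the all-against-all homology search whose output the synteny
#' module consumes.
#'
#' @param truth a `TruthGenome`.
#' @param n_noise random background hits.
#' @param seed random seed.
#' @return anchor-hit data frame.
#' @export
derive_anchor_hits <- function(truth, n_noise = 0L,
                               seed = truth$params$seed + 4L) {
  set.seed(seed)
  db <- truth$duplication_blocks
  hits <- db[c("gene_a", "chrom_a", "rank_a", "gene_b", "chrom_b",
               "rank_b", "ks")]
  hits$score <- 1
  if (n_noise > 0) {
    gc <- truth$gene_coords
    a <- gc[sample.int(nrow(gc), n_noise, replace = TRUE), ]
    b <- gc[sample.int(nrow(gc), n_noise, replace = TRUE), ]
    noise <- data.frame(gene_a = a$gene_id, chrom_a = a$chrom,
                        rank_a = a$rank, gene_b = b$gene_id,
                        chrom_b = b$chrom, rank_b = b$rank,
                        ks = NA_real_, score = 1,
                        stringsAsFactors = FALSE)
    noise <- noise[noise$gene_a != noise$gene_b, , drop = FALSE]
    hits <- rbind(hits, noise)
  }
  hits <- hits[!duplicated(hits[c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
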