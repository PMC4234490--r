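#' Pipeline configuration
#'
#' Collects every numeric threshold used across the pipeline in one
#' validated object. Defaults reproduce the published workflow: SNP
#' calls require `depth_min` supporting reads; segregating markers need
#' a minor-allele frequency of at least `maf_min` and at most
#' `missing_max` missing data; adjacent-marker segregation discordance
#' above 10 percent of individuals flags a candidate chimera; gap
#' patching extracts 2 kb flanks, requires 99 percent identity seeds of
#' at least 100 bp, and accepts patches spanning at most 200 kb;
#' synteny chaining uses a 20-gene gap cutoff and 5-pair minimum block
#' size; new gene identifiers are minted with strides of 10, 5, 3 or 2.
#'
#' @param maf_min minimum minor-allele frequency among non-missing
#'   calls for a marker to be kept.
#' @param missing_max maximum fraction of missing calls per marker.
#' @param depth_min minimum read depth supporting an allele call.
#' @param discord_frac fraction of individuals above which adjacent
#'   segregation patterns are flagged as discordant.
#' @param flank_len gap-flank length (bp) extracted for gap patching.
#' @param bac_flank_len end-flanker length (bp) for high-quality
#'   legacy segment replacement.
#' @param span_max maximum legacy span (bp, inner-edge distance between
#'   the two flank matches) for a gap to be closeable.
#' @param min_identity minimum alignment identity for flank matches.
#' @param word_size exact-seed length (bp) for the seeded aligner.
#' @param min_clone_links minimum clone-end links to anchor a scaffold.
#' @param min_snp_links minimum co-segregating markers to anchor a
#'   scaffold.
#' @param chain_gap_genes maximum rank gap (genes) between chained
#'   anchor hits on either axis.
#' @param min_block_pairs minimum anchor pairs per synteny block.
#' @param ks_bin Ks histogram bin width.
#' @param min_protein_aa minimum protein length (aa); shorter models
#'   are dropped unless exempted by source.
#' @param id_strides candidate identifier strides, tried largest first.
#' @param min_gap_len minimum run of N treated as a patchable gap (a
#'   single ambiguous base is not a gap).
#' @param consensus_tol tolerance (bp) within which a genetic-map and a
#'   placement breakpoint on the same scaffold are considered shared.
#' @param r2_link_min minimum r-squared for a marker to count as
#'   co-segregating with a placed marker.
#' @param tile_overlap_frac placements overlapping by more than this
#'   fraction on the chromosome are a tiling conflict.
#' @param legacy_overlap_tol tolerance (bp) by which a recruited legacy
#'   segment may overlap a flanking layout part.
#' @param join_gap_min minimum N-gap (bp) inserted between joined
#'   pseudomolecule parts.
#' @param unknown_gap_len AGP gap length used when placement evidence
#'   gives no inter-component distance (AGP type U convention).
#'
#' @return A `pipeline_config` list.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$span_max
pipeline_config <- function(maf_min = 0.1,
                            missing_max = 0.25,
                            depth_min = 3,
                            discord_frac = 0.10,
                            flank_len = 2000,
                            bac_flank_len = 5000,
                            span_max = 200000,
                            min_identity = 0.99,
                            word_size = 100,
                            min_clone_links = 1,
                            min_snp_links = 1,
                            chain_gap_genes = 20,
                            min_block_pairs = 5,
                            ks_bin = 0.05,
                            min_protein_aa = 50,
                            id_strides = c(10, 5, 3, 2),
                            min_gap_len = 10,
                            consensus_tol = 50000,
                            r2_link_min = 0.8,
                            tile_overlap_frac = 0.5,
                            legacy_overlap_tol = 10000,
                            join_gap_min = 100,
                            unknown_gap_len = 100) {
  cfg <- list(
    maf_min = maf_min, missing_max = missing_max, depth_min = depth_min,
    discord_frac = discord_frac, flank_len = flank_len,
    bac_flank_len = bac_flank_len, span_max = span_max,
    min_identity = min_identity, word_size = word_size,
    min_clone_links = min_clone_links, min_snp_links = min_snp_links,
    chain_gap_genes = chain_gap_genes, min_block_pairs = min_block_pairs,
    ks_bin = ks_bin, min_protein_aa = min_protein_aa,
    id_strides = sort(as.integer(id_strides), decreasing = TRUE),
    min_gap_len = min_gap_len, consensus_tol = consensus_tol,
    r2_link_min = r2_link_min, tile_overlap_frac = tile_overlap_frac,
    legacy_overlap_tol = legacy_overlap_tol, join_gap_min = join_gap_min,
    unknown_gap_len = unknown_gap_len
  )
  fracs <- c("maf_min", "missing_max", "discord_frac", "min_identity",
             "r2_link_min", "tile_overlap_frac")
  for (f in fracs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("config field '", f, "' must lie in (0, 1)", call. = FALSE)
  }
  pos <- setdiff(names(cfg), c(fracs, "id_strides"))
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive scalar", call. = FALSE)
  }
  if (any(cfg$id_strides <= 0)) stop("id_strides must be positive")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("uplift pipeline configuration\n")
  for (f in names(x)) {
    cat(sprintf("  %-18s %s\n", f, paste(x[[f]], collapse = ", ")))
  }
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be created by pipeline_config()", call. = FALSE)
  config
}
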