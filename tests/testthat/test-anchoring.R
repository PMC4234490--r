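mk_placements <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(scaffold_id = r[[1]], scaffold_start = 0L,
               scaffold_end = as.integer(r[[2]]), chrom_id = r[[3]],
               chrom_start = as.integer(r[[4]]),
               chrom_end = as.integer(r[[5]]), orientation = r[[6]],
               stringsAsFactors = FALSE)))
}

test_that("tiling orders, orients and spaces scaffolds from placements", {
  set.seed(41)
  set <- scaffold_set(c(s1 = random_dna_str(1000),
                        s2 = random_dna_str(950),
                        s3 = random_dna_str(500)))
  plc <- mk_placements(list("s2", 950, "chr1", 1050000, 2000000, "-"),
                       list("s1", 1000, "chr1", 0, 1000000, "+"))
  tl <- tile_by_placements(set, plc)
  expect_equal(tl$layout$component_id, c("s1", "s2"))
  expect_equal(tl$layout$orientation, c("+", "-"))
  expect_equal(tl$layout$est_gap_after, c(50000L, 0L))
  expect_equal(tl$unplaced, "s3")
  ## single placement: one-part layout
  tl1 <- tile_by_placements(set, plc[2, ])
  expect_equal(nrow(tl1$layout), 1L)
  ## heavy overlap on the chromosome is a tiling conflict
  bad <- mk_placements(list("s1", 1000, "chr1", 0, 1000000, "+"),
                       list("s2", 950, "chr1", 100000, 900000, "+"))
  expect_error(tile_by_placements(set, bad), "conflict")
})

test_that("scaffold order recovery on synthetic placements is exact", {
  p <- simulation_params(n_chromosomes = 3L, chrom_length = 150000L,
                         markers_per_chrom = 20L,
                         scaffolds_per_chrom = 5L, chimera_rate = 0,
                         placement_jitter = 200L, seed = 23L)
  truth <- simulate_truth(p)
  fr <- fragment_into_scaffolds(truth, p)
  ev <- derive_evidence(truth, fr$layout, p)
  tl <- tile_by_placements(fr$set, ev$placements)
  for (chrom in unique(tl$layout$chrom_id)) {
    got <- tl$layout$component_id[tl$layout$chrom_id == chrom]
    want <- fr$layout[fr$layout$chrom == chrom, ]
    want <- want$scaffold_id[order(want$chrom_start)]
    expect_identical(got, want) # Kendall tau = 1
  }
})

test_that("legacy segments are recruited only into genuine layout gaps", {
  layout <- data.frame(chrom_id = "chr1", component_id = c("s1", "s2"),
                       source = "wgs", orientation = "+",
                       chrom_start = c(0L, 500000L),
                       chrom_end = c(200000L, 800000L),
                       est_gap_after = c(300000L, 0L),
                       stringsAsFactors = FALSE)
  legacy <- scaffold_set(c(L1 = strrep("A", 100), L2 = strrep("C", 100)))
  lp <- mk_placements(list("L1", 100, "chr1", 250000, 450000, "+"),
                      list("L2", 100, "chr1", 150000, 420000, "+"))
  out <- recruit_legacy_segments(layout, legacy, lp)
  dec <- setNames(out$decisions$action, out$decisions$segment_id)
  expect_equal(unname(dec[c("L1", "L2")]), c("inserted", "skipped"))
  expect_equal(out$decisions$reason[out$decisions$segment_id == "L2"],
               "spans-layout-part")
  mid <- out$layout[out$layout$component_id == "L1", ]
  expect_equal(mid$source, "legacy")
  ## inserted between the flanking parts
  ord <- out$layout$component_id[order(out$layout$chrom_start)]
  expect_equal(ord, c("s1", "L1", "s2"))
})

test_that("anchoring requires both genetic and clone-link evidence and runs in rounds", {
  set.seed(51)
  ## placed scaffold sp1 on chr1; u1 linkable by markers+links; u2 only
  ## links to u1 (anchorable in round 2); u3 has markers but no links
  n_ind <- 60L
  haplo <- sample(c("A", "B"), n_ind, TRUE)
  noise <- function(h, k) {
    i <- sample(seq_along(h), k)
    h[i] <- ifelse(h[i] == "A", "B", "A")
    h
  }
  calls <- rbind(haplo, noise(haplo, 2), haplo, noise(haplo, 1),
                 noise(haplo, 2), haplo)
  colnames(calls) <- sprintf("I%02d", seq_len(n_ind))
  markers <- data.frame(
    marker_id = sprintf("m%d", 1:6),
    scaffold_id = c("sp1", "sp1", "u1", "u1", "u3", "u3"),
    position = c(1000L, 5000L, 500L, 1500L, 100L, 900L),
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(markers, calls)
  layout <- data.frame(chrom_id = "chr1", component_id = "sp1",
                       source = "wgs", orientation = "+",
                       chrom_start = 0L, chrom_end = 100000L,
                       est_gap_after = 0L, stringsAsFactors = FALSE)
  unplaced <- scaffold_set(c(u1 = random_dna_str(2000),
                             u2 = random_dna_str(1500),
                             u3 = random_dna_str(1000)))
  links <- data.frame(
    end1_scaffold = c("sp1", "u1"), end1_pos = c(99000L, 1900L),
    end2_scaffold = c("u1", "u2"), end2_pos = c(100L, 50L),
    library_mean = 35000, library_sd = 7000,
    stringsAsFactors = FALSE)
  ## u2 has a marker co-segregating with u1 (round-2 dependency)
  gm2 <- genotype_matrix(
    rbind(markers, data.frame(marker_id = "m7", scaffold_id = "u2",
                              position = 700L)),
    rbind(calls, noise(haplo, 1)))
  out <- anchor_by_links(layout, unplaced, gm2, links)
  a <- out$anchored
  expect_true(all(c("u1", "u2") %in% a$scaffold_id))
  expect_false("u3" %in% a$scaffold_id) # markers but no clone link
  expect_equal(a$round[a$scaffold_id == "u1"], 1L)
  expect_equal(a$round[a$scaffold_id == "u2"], 2L)
  expect_true(all(a$chrom_id == "chr1"))
})

test_that("pseudomolecule building conserves real bases and emits consistent AGP", {
  set.seed(61)
  s1 <- random_dna_str(4000)
  s2 <- paste0(random_dna_str(1000), strrep("N", 50),
               random_dna_str(1950))
  set <- scaffold_set(c(s1 = s1, s2 = s2))
  plc <- mk_placements(list("s1", 4000, "chr1", 0, 4000, "+"),
                       list("s2", 3000, "chr1", 4500, 7500, "-"))
  tl <- tile_by_placements(set, plc)
  built <- build_pseudomolecules(tl$layout, set)
  expect_equal(sum(built$summary$real),
               sum(real_base_count(set)))
  expect_equal(unname(agp_object_lengths(built$agp)),
               unname(seq_lengths(built$set)))
  expect_equal(built$summary$ns, 50 + 500) # internal gap + join gap
  ## orientation honoured: end of chr1 is the reverse complement of s2 start
  chr <- built$set$seqs[["chr1"]]
  expect_identical(substr(chr, nchar(chr) - 999L, nchar(chr)),
                   rc_str(substr(s2, 1, 1000)))
  ## replaying the build edits reproduces the sequences
  rep <- apply_edits(set, built$edits)
  expect_identical(rep$set$seqs[["chr1"]], chr)
  ## single-part layout: no join gaps
  one <- build_pseudomolecules(tl$layout[1, ], set)
  expect_equal(one$summary$total, 4000)
  expect_equal(one$summary$ns, 0)
})

test_that("percent-real recomputation reproduces every printed statistic", {
  path <- system.file("extdata", "mt4_assembly_stats.tsv",
                      package = "uplift")
  tab <- read.delim(path, check.names = FALSE)
  chr_rows <- grepl("^chr[0-9]+$", tab$seqid)
  out <- summarize_assembly_table(tab[chr_rows, ],
                                  total_label = "chr total")
  expect_equal(out$pct_real,
               tab$pct_real_printed[match(out$seqid, tab$seqid)])
  expect_equal(out$total[out$seqid == "chr total"], 384467214)
  unpl <- tab[tab$seqid == "Unplaced", ]
  expect_equal(pct_real(unpl$real, unpl$total), 84.8)
})
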