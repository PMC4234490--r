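test_that("the discordance threshold reproduces the printed population value", {
  expect_equal(discordance_threshold(139), 14L)
  expect_equal(discordance_threshold(100), 10L)
})

test_that("adjacent-pair discordance is counted over non-missing calls and flagged strictly above threshold", {
  n <- 139L
  base <- paste(rep(c("A", "B"), length.out = n), collapse = "")
  flip <- function(pattern, k) {
    v <- strsplit(pattern, "")[[1]]
    v[seq_len(k)] <- ifelse(v[seq_len(k)] == "A", "B", "A")
    paste(v, collapse = "")
  }
  ## identical patterns: no flag
  gm0 <- gm_from_strings(c(base, base))
  expect_equal(nrow(gbs_breakpoints(gm0)), 0L)
  ## 14 of 139 differ: not flagged ("more than" is strict)
  gm14 <- gm_from_strings(c(base, flip(base, 14)))
  expect_equal(nrow(gbs_breakpoints(gm14)), 0L)
  ## 15 of 139 differ: flagged
  gm15 <- gm_from_strings(c(base, flip(base, 15)),
                          positions = c(5000L, 9000L))
  bp <- gbs_breakpoints(gm15)
  expect_equal(nrow(bp), 1L)
  expect_equal(c(bp$start, bp$end), c(5000L, 9000L))
  expect_equal(bp$support, "15")
  ## missing calls at either marker carry no signal
  v <- strsplit(flip(base, 15), "")[[1]]
  v[seq_len(15)] <- "-"
  gm_miss <- gm_from_strings(c(base, paste(v, collapse = "")))
  expect_equal(nrow(gbs_breakpoints(gm_miss)), 0L)
})

test_that("placement breakpoints appear only at chromosome change-points", {
  one <- data.frame(scaffold_id = "s1", scaffold_start = 0L,
                    scaffold_end = 1000L, chrom_id = "chr1",
                    chrom_start = 0L, chrom_end = 1000L,
                    orientation = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(placement_breakpoints(one)), 0L)
  two <- data.frame(scaffold_id = "s1",
                    scaffold_start = c(0L, 450000L),
                    scaffold_end = c(400000L, 900000L),
                    chrom_id = c("chr1", "chr5"),
                    chrom_start = c(0L, 0L),
                    chrom_end = c(400000L, 450000L),
                    orientation = "+", stringsAsFactors = FALSE)
  bp <- placement_breakpoints(two)
  expect_equal(nrow(bp), 1L)
  expect_equal(c(bp$start, bp$end), c(400000L, 450000L))
  bad <- two
  bad$scaffold_start[[2]] <- 300000L
  expect_error(placement_breakpoints(bad), "overlap")
})

test_that("consensus breakpoints are intersections of paired evidence", {
  gbs <- data.frame(scaffold_id = "s1", start = 100000L, end = 150000L,
                    source = "gbs", support = "20",
                    stringsAsFactors = FALSE)
  plc <- data.frame(scaffold_id = "s1", start = 120000L, end = 160000L,
                    source = "placement", support = "chr1|chr2",
                    stringsAsFactors = FALSE)
  cons <- consensus_breakpoints(gbs, plc)
  expect_equal(c(cons$start, cons$end), c(120000L, 150000L))
  ## disjoint scaffolds pair nothing
  plc2 <- plc; plc2$scaffold_id <- "s2"
  expect_equal(nrow(consensus_breakpoints(gbs, plc2)), 0L)
  ## |consensus| <= min(|gbs|, |placement|), one use per breakpoint
  plc3 <- rbind(plc, plc)
  expect_equal(nrow(consensus_breakpoints(gbs, plc3)), 1L)
})

test_that("splitting conserves sequence and prefers N-gap midpoints", {
  set.seed(8)
  left <- random_dna_str(5000); right <- random_dna_str(4000)
  s <- paste0(left, strrep("N", 100), right)
  set <- scaffold_set(c(chim = s, clean = random_dna_str(2000)))
  ## no breakpoints: identity, empty log
  sp0 <- split_scaffolds(set, uplift:::breakpoint_table())
  expect_identical(sp0$set$seqs, set$seqs)
  expect_equal(nrow(sp0$edits), 0L)
  ## breakpoint interval containing the N-gap: split drops the gap
  bp <- uplift:::breakpoint_table("chim", 4000L, 6000L, "consensus", "x")
  sp <- split_scaffolds(set, bp)
  expect_identical(sp$set$seqs[["chim_1"]], left)
  expect_identical(sp$set$seqs[["chim_2"]], right)
  expect_identical(sp$set$seqs[["clean"]], set$seqs[["clean"]])
  ## non-N content conserved
  nn <- function(x) nchar(gsub("N", "", x))
  expect_equal(nn(sp$set$seqs[["chim_1"]]) + nn(sp$set$seqs[["chim_2"]]),
               nn(s))
  ## no gap inside the interval: midpoint split, exact conservation
  bp2 <- uplift:::breakpoint_table("chim", 1000L, 2000L, "consensus", "x")
  sp2 <- split_scaffolds(set, bp2)
  expect_equal(nchar(sp2$set$seqs[["chim_1"]]), 1500L)
  expect_equal(nchar(sp2$set$seqs[["chim_1"]]) +
                 nchar(sp2$set$seqs[["chim_2"]]), nchar(s))
  expect_error(
    split_scaffolds(set, uplift:::breakpoint_table("chim", 0L, 99999L,
                                                   "consensus", "x")),
    "outside")
})

test_that("injected chimeras are recovered end to end and clean scaffolds stay whole", {
  p <- simulation_params(n_chromosomes = 4L, chrom_length = 250000L,
                         markers_per_chrom = 50L,
                         scaffolds_per_chrom = 5L, chimera_rate = 0.25,
                         seed = 13L)
  truth <- simulate_truth(p)
  fr <- fragment_into_scaffolds(truth, p)
  g <- simulate_ril_genotypes(truth, p, fr$layout)
  gm <- filter_markers(call_genotypes(g$ref_depth, g$alt_depth,
                                      g$markers))$kept
  ev <- derive_evidence(truth, fr$layout, p)
  gbs <- gbs_breakpoints(gm)
  plc <- placement_breakpoints(ev$placements)
  cons <- consensus_breakpoints(gbs, plc)
  ## consensus on exactly the injected chimeras, no false splits
  expect_setequal(cons$scaffold_id, fr$chimeras$scaffold_id)
  expect_equal(nrow(cons), nrow(fr$chimeras))
  sp <- split_scaffolds(fr$set, cons)
  ## every child contains sequence from a single truth chromosome
  for (i in seq_len(nrow(fr$chimeras))) {
    cj <- fr$chimeras[i, ]
    c1 <- sp$set$seqs[[paste0(cj$scaffold_id, "_1")]]
    lay <- fr$layout[fr$layout$scaffold_id == cj$scaffold_id &
                       fr$layout$part == 1L, ]
    tr <- substr(truth$chromosomes$seqs[[lay$chrom]],
                 lay$chrom_start + 1L, lay$chrom_end)
    ## masked gaps aside, child 1 is the part-1 truth segment
    expect_equal(nchar(c1), nchar(tr))
    m <- strsplit(c1, "")[[1]] != "N"
    expect_identical(strsplit(c1, "")[[1]][m],
                     strsplit(tr, "")[[1]][m])
  }
})
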