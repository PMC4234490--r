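## constructed patching scenario: one contig with gaps of known truth
build_patch_case <- function(seed = 42) {
  set.seed(seed)
  truth <- random_dna_str(30000)
  gap <- function(seq, at, len) {
    paste0(substr(seq, 1, at), strrep("N", len),
           substr(seq, at + len + 1L, nchar(seq)))
  }
  list(truth = truth, gap = gap)
}

test_that("seeded alignment finds planted targets and scores identity correctly", {
  cs <- build_patch_case()
  legacy <- scaffold_set(c(leg = cs$truth))
  cfg <- pipeline_config()
  ## exact substring: identity 1, correct interval
  q <- substr(cs$truth, 2001, 4000)
  hit <- seeded_align(q, legacy, cfg)[1, ]
  expect_equal(hit$identity, 1)
  expect_equal(c(hit$t_start, hit$t_end), c(2000L, 4000L))
  expect_equal(hit$orientation, "+")
  ## two mismatches in 2000 bp: identity 0.999 passes the 0.99 floor
  qm <- q
  substr(qm, 100, 100) <- chartr("ACGT", "CGTA", substr(qm, 100, 100))
  substr(qm, 1900, 1900) <- chartr("ACGT", "CGTA", substr(qm, 1900, 1900))
  hit2 <- seeded_align(qm, legacy, cfg)[1, ]
  expect_equal(hit2$identity, 0.999)
  ## reverse strand is found
  hit3 <- seeded_align(rc_str(q), legacy, cfg)[1, ]
  expect_equal(hit3$orientation, "-")
  expect_equal(c(hit3$t_start, hit3$t_end), c(2000L, 4000L))
  expect_error(seeded_align("ACGT", legacy, cfg), "word_size")
})

test_that("seeded alignment agrees with an exhaustive alignment oracle on planted queries", {
  set.seed(71)
  cfg <- pipeline_config()
  targets <- scaffold_set(setNames(
    vapply(1:4, function(i) random_dna_str(4000), character(1)),
    sprintf("t%d", 1:4)))
  for (rep in 1:25) {
    tid <- sample(names(targets$seqs), 1)
    at <- sample(1000:2500, 1)
    q <- substr(targets$seqs[[tid]], at, at + 499)
    nmut <- sample(0:3, 1)
    for (k in seq_len(nmut)) {
      i <- sample(50:450, 1)
      substr(q, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(q, i, i)), 1)
    }
    hit <- seeded_align(q, targets, cfg)[1, ]
    ## oracle: best target by full dynamic-programming alignment
    scores <- vapply(names(targets$seqs), function(id) {
      pa <- Biostrings::pairwiseAlignment(q, targets$seqs[[id]],
                                          type = "global-local")
      Biostrings::score(pa)
    }, numeric(1))
    expect_equal(hit$target_id, names(which.max(scores)))
    expect_lte(abs(hit$t_start - (at - 1L)), 1L)
    expect_lte(abs(hit$t_end - (at + 499L)), 1L)
  }
})

test_that("gap closeability rules fire with the correct reason codes", {
  cs <- build_patch_case()
  cfg <- pipeline_config()
  gapped <- cs$gap(cs$truth, 10000, 300)
  asm <- scaffold_set(c(ctg = gapped))
  ## closeable: patched bases equal truth exactly
  r <- close_gaps(asm, scaffold_set(c(leg = cs$truth)), cfg)
  expect_equal(r$decisions$reason, "closed")
  expect_identical(r$set$seqs[["ctg"]], cs$truth)
  ## reverse-orientation legacy still closes, byte-identically
  r2 <- close_gaps(asm, scaffold_set(c(leg = rc_str(cs$truth))), cfg)
  expect_equal(r2$decisions$reason, "closed")
  expect_identical(r2$set$seqs[["ctg"]], cs$truth)
  ## equal N count: strictly-fewer rule rejects
  r3 <- close_gaps(asm, scaffold_set(c(leg = gapped)), cfg)
  expect_equal(r3$decisions$reason, "not-fewer-Ns")
  ## flanks on different legacy records
  r4 <- close_gaps(asm, scaffold_set(c(
    legA = substr(cs$truth, 1, 10000),
    legB = substr(cs$truth, 10301, 30000))), cfg)
  expect_equal(r4$decisions$reason, "different-records")
  ## opposite orientations of the two flank matches
  r5 <- close_gaps(asm, scaffold_set(c(leg = paste0(
    substr(cs$truth, 1, 10000), strrep("T", 50),
    rc_str(substr(cs$truth, 10301, 30000))))), cfg)
  expect_equal(r5$decisions$reason, "orientation-mismatch")
  ## span beyond 200 kb
  set.seed(3)
  r6 <- close_gaps(asm, scaffold_set(c(leg = paste0(
    substr(cs$truth, 1, 10000), random_dna_str(210000),
    substr(cs$truth, 10301, 30000)))), cfg)
  expect_equal(r6$decisions$reason, "span-exceeded")
  ## no-match side
  r7 <- close_gaps(asm, scaffold_set(c(leg = substr(cs$truth, 1, 10000))),
                   cfg)
  expect_equal(r7$decisions$reason, "no-right-match")
})

test_that("patching never increases N count, is idempotent and replayable", {
  cs <- build_patch_case(7)
  cfg <- pipeline_config()
  ## several gaps, one of them unclosable (legacy keeps it gapped)
  g1 <- cs$gap(cs$truth, 5000, 200)
  gapped <- cs$gap(g1, 15000, 150)
  asm <- scaffold_set(c(ctg = gapped))
  legacy <- scaffold_set(c(leg = cs$gap(cs$truth, 5000, 200)))
  r <- close_gaps(asm, legacy, cfg)
  rep <- patch_report(r$decisions)
  expect_equal(rep$examined, 2L)
  expect_equal(rep$closed, 1L)
  expect_equal(rep$examined, rep$closed + sum(rep$reasons))
  n_count <- function(set) sum(set$gaps$n_count)
  expect_lte(n_count(r$set), n_count(asm))
  ## a second pass closes nothing more
  r_again <- close_gaps(r$set, legacy, cfg)
  expect_equal(patch_report(r_again$decisions)$closed, 0L)
  ## edit replay reproduces the patched assembly byte-for-byte
  replay <- apply_edits(asm, r$edits, sources = list(legacy = legacy))
  expect_identical(replay$set$seqs[["ctg"]], r$set$seqs[["ctg"]])
})

test_that("BAC-style region replacement honours orientation and overlap rules", {
  cs <- build_patch_case(9)
  cfg <- pipeline_config()
  gapped <- cs$gap(cs$truth, 12000, 400)
  asm <- scaffold_set(c(ctg = gapped))
  ## identical segment: byte-wise no-op outside the gap it fills
  hq <- scaffold_set(c(bac = substr(cs$truth, 6001, 18000)))
  r <- replace_bac_regions(asm, hq, cfg)
  expect_equal(r$decisions$action, "replaced")
  expect_identical(r$set$seqs[["ctg"]], cs$truth)
  ## N accounting: the filled gap is gone
  expect_equal(sum(asm$gaps$n_count) - sum(r$set$gaps$n_count), 400L)
  ## reversed segment is inserted reverse-complemented
  hq_rc <- scaffold_set(c(bac = rc_str(substr(cs$truth, 6001, 18000))))
  r2 <- replace_bac_regions(asm, hq_rc, cfg)
  expect_equal(r2$decisions$action, "replaced")
  expect_identical(r2$set$seqs[["ctg"]], cs$truth)
  ## empty decision set
  expect_equal(patch_report(r$decisions[0, ])$examined, 0L)
})
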