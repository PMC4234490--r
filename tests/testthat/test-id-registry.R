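test_that("identifier parsing and rendering round-trip", {
  p <- parse_gene_id(c("Medtr1g009000", "Medtr8g465780", "contig999_1"))
  expect_equal(p$chrom, c("1", "8", NA))
  expect_equal(p$numeric, c(9000L, 465780L, NA))
  expect_equal(format_gene_id(p$chrom[1:2], p$numeric[1:2]),
               c("Medtr1g009000", "Medtr8g465780"))
})

test_that("stride selection reproduces both worked identifier examples", {
  a <- assign_new_ids("Medtr1g009000", "Medtr1g009050", 2)
  expect_equal(a$ids, c("Medtr1g009010", "Medtr1g009020"))
  expect_equal(a$stride, 10L)
  expect_false(a$overflow)
  b <- assign_new_ids("Medtr1g009000", "Medtr1g009010", 20)
  expect_true(b$overflow)
  expect_equal(b$ids[1:2], c("Medtr1g409010", "Medtr1g409020"))
  expect_equal(b$ids[[20]], "Medtr1g409200")
  expect_equal(assign_new_ids("Medtr1g009000", "Medtr1g009050", 0)$ids,
               character(0))
})

test_that("minted identifiers stay inside the range, increase, and respect the registry", {
  ## 4 ids into a range of 50: stride 10 (40 < 50)
  r <- assign_new_ids("Medtr3g100000", "Medtr3g100050", 4)
  expect_equal(r$stride, 10L)
  expect_true(all(diff(r$numerics) > 0))
  expect_true(all(r$numerics > 100000L & r$numerics < 100050L))
  ## 9 ids into a range of 50: 9*5=45 < 50 -> stride 5
  r2 <- assign_new_ids("Medtr3g100000", "Medtr3g100050", 9)
  expect_equal(r2$stride, 5L)
  ## 3 ids fit a range of 10 with stride 3 (9 < 10)
  r3 <- assign_new_ids("Medtr1g009000", "Medtr1g009010", 3)
  expect_equal(r3$stride, 3L)
  expect_equal(r3$numerics, c(9003L, 9006L, 9009L))
  ## registry collisions are skipped in overflow mode
  reg <- id_registry(c("Medtr1g409010", "Medtr1g409030"))
  o <- assign_new_ids("Medtr1g009000", "Medtr1g009010", 5,
                      registry = reg)
  expect_equal(o$ids,
               c("Medtr1g409020", "Medtr1g409040", "Medtr1g409050",
                 "Medtr1g409060", "Medtr1g409070"))
  ## everything minted is registered: re-minting collides
  expect_true(all(registry_has(reg, o$ids)))
  ## duplicate issue in stride mode is an error
  reg2 <- id_registry("Medtr1g009010")
  expect_error(assign_new_ids("Medtr1g009000", "Medtr1g009050", 2,
                              registry = reg2), "already issued")
})

test_that("merge conflicts resolve by alignment identity then coverage", {
  base <- paste(sample(Biostrings::AA_STANDARD, 120, TRUE),
                collapse = "")
  mutate_aa <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    i <- sample(seq_along(v), k)
    v[i] <- "W"
    paste(v, collapse = "")
  }
  set.seed(19)
  near <- mutate_aa(base, 2)   # ~0.98 identity
  far <- mutate_aa(base, 48)   # ~0.60 identity
  r <- resolve_merge_conflict(base, c(Medtr1g010100 = near,
                                      Medtr1g020200 = far))
  expect_equal(r$chosen, "Medtr1g010100")
  ## same identity, different coverage: truncated candidate loses
  half <- substr(base, 1, 60)
  r2 <- resolve_merge_conflict(base, c(Medtr1g030300 = half,
                                       Medtr1g040400 = base))
  expect_equal(r2$chosen, "Medtr1g040400")
  ## random substitution-mutants: winner has the fewest mutations,
  ## cross-checked by an independent dynamic-programming match count
  for (rep in 1:5) {
    ks <- sample(0:5, 3) * 8L # spaced so chance synonymy cannot tie
    cand <- setNames(vapply(ks, function(k) mutate_aa(base, k),
                            character(1)),
                     sprintf("Medtr5g%06d", sort(sample(1:999, 3)) * 100))
    got <- resolve_merge_conflict(base, cand)$chosen
    oracle_matches <- vapply(cand, nw_matches_oracle, numeric(1),
                             b = base)
    expect_equal(got, names(which.max(oracle_matches)))
  }
  expect_warning(
    resolve_merge_conflict(base, c(a = NA_character_, b = base)),
    "excluded")
})

test_that("structure-change classification recovers a known edit script", {
  loci <- function(ids, starts, ends, chrom = "c1", strand = "+",
                   cds = NA) {
    data.frame(locus_id = ids, chrom = chrom, start = starts,
               end = ends, strand = strand, cds = cds,
               stringsAsFactors = FALSE)
  }
  old <- loci(c("Medtr1g010100", "Medtr1g010200", "Medtr1g010300",
                "Medtr1g010400", "contig999_1"),
              c(100L, 1000L, 1500L, 5000L, 8000L),
              c(500L, 1400L, 1900L, 5500L, 8400L))
  ## new: g1 unchanged; g2+g3 merged into one; g4 split in two; one
  ## novel locus; contig gene unchanged
  new <- loci(c("L1", "L2", "L3a", "L3b", "L4", "L5"),
              c(100L, 1000L, 5000L, 5300L, 8000L, 9500L),
              c(500L, 1900L, 5250L, 5500L, 8400L, 9900L))
  ## identity chain over one 10 kb sequence
  oldset <- scaffold_set(c(c1 = strrep("A", 10000)))
  tmp <- tempfile()
  emit_chain(edit_log(), oldset, oldset, tmp)
  ch <- read_chain(tmp)
  rel <- classify_structure_changes(old, new, ch)
  get <- function(o) rel$relation[!is.na(rel$old_id) & rel$old_id == o]
  expect_equal(get("Medtr1g010100"), "unchanged")
  expect_equal(unique(get("Medtr1g010200")), "merge")
  expect_equal(unique(get("Medtr1g010300")), "merge")
  expect_equal(unique(get("Medtr1g010400")), c("split"))
  expect_equal(rel$relation[!is.na(rel$new_locus) & rel$new_locus == "L5"],
               "novel")

  ## carry-over: Medtr ids retained, contig ids never, merges pick one
  rel$score <- 1
  assigned <- carry_over_ids(rel)
  a <- setNames(assigned$assigned_id, assigned$new_locus)
  expect_equal(unname(a[["L1"]]), "Medtr1g010100")
  ## merge keeps exactly one of the two legacy ids
  expect_true(a[["L2"]] %in% c("Medtr1g010200", "Medtr1g010300"))
  ## split: only one fragment retains the id
  split_ids <- a[c("L3a", "L3b")]
  expect_equal(sum(split_ids == "Medtr1g010400", na.rm = TRUE), 1L)
  ## contig gene flagged for a new identifier
  expect_true(is.na(a[["L5"]]) ||
                assigned$status[assigned$new_locus == "L5"] != "carried")
  ## no identifier is used twice
  used <- assigned$assigned_id[!is.na(assigned$assigned_id)]
  expect_false(any(duplicated(used)))
  ## fixed point: re-running changes nothing
  again <- carry_over_ids(rel)
  expect_identical(again, assigned)
})
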