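simple_locus <- function(id, start, end, chrom = "c1", strand = "+",
                         source = "evm") {
  list(locus_id = id, chrom = chrom, strand = strand, source = source,
       exons = list(c(start, end)), cds = list(c(start, end)))
}

test_that("gene-set merging applies source precedence on CDS overlap", {
  evm <- gs_from_loci(list(simple_locus("e1", 100, 500),
                           simple_locus("e2", 1000, 1500)))
  maker <- gs_from_loci(list(
    simple_locus("m1", 400, 800, source = "maker"),    # overlaps e1
    simple_locus("m2", 2000, 2400, source = "maker"),  # desert: kept
    simple_locus("m3", 1100, 1300, chrom = "c1", strand = "-",
                 source = "maker")))                   # other strand: kept
  comm <- gs_from_loci(list(
    simple_locus("c1g", 1400, 1800, source = "community")))
  out <- merge_gene_sets(evm, maker, community = comm)
  ids <- out$genes$locus_id
  expect_true(all(c("e1", "m2", "m3", "c1g") %in% ids))
  expect_false("m1" %in% ids)      # computed model intersecting kept CDS
  expect_false("e2" %in% ids)      # overridden by the community model
  ## the merged set has no same-strand CDS overlaps among computed loci
  cds <- uplift:::locus_cds(out)
  comp <- cds[out$genes$source[match(cds$locus_id,
                                     out$genes$locus_id)] %in%
                c("evm", "maker"), ]
  for (key in unique(paste(comp$chrom, comp$strand))) {
    v <- comp[paste(comp$chrom, comp$strand) == key, ]
    v <- v[order(v$start), ]
    if (nrow(v) > 1)
      expect_true(all(v$start[-1] >= v$end[-nrow(v)]))
  }
  ## overlapping loci inside one input set are rejected
  bad <- gs_from_loci(list(simple_locus("x1", 1, 300),
                           simple_locus("x2", 200, 400)))
  expect_error(merge_gene_sets(bad, maker), "overlapping")
})

test_that("isoform deduplication keeps one transcript per distinct CDS chain", {
  ## a locus with many UTR-variant isoforms over few CDS chains
  mk_tr <- function(exon_start, cds) list(
    exons = list(c(exon_start, 2000)), cds = cds)
  chains <- list(list(c(500, 800), c(900, 1200)),
                 list(c(500, 800), c(950, 1200)),
                 list(c(500, 1200)),
                 list(c(600, 800), c(900, 1100)))
  trs <- list()
  for (i in 1:31) {
    trs[[i]] <- mk_tr(100 + i * 7, chains[[((i - 1) %% 4) + 1]])
  }
  gs <- gs_from_loci(list(list(locus_id = "big", chrom = "c1",
                               strand = "+", transcripts = trs)))
  out <- dedup_isoforms(gs)
  expect_equal(out$summary$n_in, 31L)
  expect_equal(out$summary$n_out, 4L)
  expect_equal(nrow(out$set$transcripts), 4L)
  ## a single isoform is retained unchanged
  one <- gs_from_loci(list(simple_locus("solo", 10, 400)))
  out1 <- dedup_isoforms(one)
  expect_equal(nrow(out1$set$transcripts), 1L)
  ## the longest transcript of each CDS group wins
  gs2 <- gs_from_loci(list(list(
    locus_id = "L", chrom = "c1", strand = "+",
    transcripts = list(mk_tr(300, chains[[1]]),
                       mk_tr(100, chains[[1]])))))
  out2 <- dedup_isoforms(gs2)
  expect_equal(out2$set$transcripts$transcript_id, "L.2")
  ## input order of transcripts does not change the group count
  gs2b <- gs_from_loci(list(list(
    locus_id = "L", chrom = "c1", strand = "+",
    transcripts = list(mk_tr(100, chains[[1]]),
                       mk_tr(300, chains[[1]])))))
  expect_equal(dedup_isoforms(gs2b)$summary$n_out,
               dedup_isoforms(gs2)$summary$n_out)
})

test_that("the length filter drops sub-50aa models except exempt sources", {
  ## CDS lengths: 147 bp = 49 aa, 150 bp = 50 aa
  gs <- gs_from_loci(list(
    simple_locus("short_evm", 0, 147),
    simple_locus("edge", 200, 350),
    simple_locus("short_spada", 500, 647, source = "spada")))
  out <- length_filter(gs)
  expect_setequal(out$genes$locus_id, c("edge", "short_spada"))
})

test_that("confidence classes partition the gene set and track the planted tiers", {
  loci <- list()
  for (i in 1:30) {
    ## HC loci built multi-exon, the rest single-exon
    if (i <= 10) {
      loci[[i]] <- list(locus_id = sprintf("g%02d", i), chrom = "c1",
                        strand = "+", transcripts = list(list(
                          exons = list(c(i * 1000, i * 1000 + 200),
                                       c(i * 1000 + 400, i * 1000 + 700)),
                          cds = list(c(i * 1000, i * 1000 + 200),
                                     c(i * 1000 + 400, i * 1000 + 700)))))
    } else {
      loci[[i]] <- simple_locus(sprintf("g%02d", i), i * 1000,
                                i * 1000 + 300)
    }
  }
  gs <- gs_from_loci(loci)
  ev <- data.frame(locus_id = sprintf("g%02d", 1:25),
                   transcript_cov = c(rep(0.98, 10), rep(0.40, 10),
                                      rep(0, 5)),
                   transcript_id = c(rep(0.99, 10), rep(0.99, 10),
                                     rep(0, 5)),
                   protein_cov = 0, protein_id = 0,
                   stringsAsFactors = FALSE)
  expect_warning(
    out <- classify_confidence(gs, ev, te_loci = "g26"),
    "zero support")
  tab <- table(out$calls$class)
  expect_equal(unname(tab[["HC"]]), 10L)
  expect_equal(unname(tab[["LC"]]), 10L)
  expect_equal(unname(tab[["TE"]]), 1L)
  expect_equal(unname(tab[["unsupported"]]), 9L)
  expect_equal(sum(tab), nrow(gs$genes))
  ## HC loci were built with more exons than LC loci
  s <- out$summary
  expect_gt(s$mean_exons[s$class == "HC"],
            s$mean_exons[s$class == "LC"])
})

test_that("GFF3 round-trip preserves the gene/mRNA/exon/CDS hierarchy", {
  gs <- gs_from_loci(list(
    list(locus_id = "gA", chrom = "c1", strand = "+",
         transcripts = list(list(exons = list(c(100, 300), c(400, 600)),
                                 cds = list(c(150, 300), c(400, 550))))),
    simple_locus("gB", 1000, 1400, strand = "-")))
  tmp <- tempfile(fileext = ".gff3")
  write_gff_genes(gs, tmp)
  back <- read_gff_genes(tmp)
  expect_setequal(back$genes$locus_id, gs$genes$locus_id)
  expect_equal(nrow(back$transcripts), nrow(gs$transcripts))
  fa <- back$features[back$features$transcript_id == "gA.1" &
                        back$features$type == "CDS", ]
  fa <- fa[order(fa$start), ]
  expect_equal(fa$start, c(150L, 400L))
  expect_equal(fa$end, c(300L, 550L))
})
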