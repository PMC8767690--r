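make_tx <- function(id, sample, chrom, starts, ends, strand) {
  data.frame(transcript_id = id, sample_id = sample, chrom = chrom,
             start = starts, end = ends, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("transcript TSS is the strand-aware 5' end", {
  plus <- make_tx("t1", "s1", "chr1", c(101, 301), c(200, 400), "+")
  minus <- make_tx("t2", "s1", "chr1", c(101, 301), c(200, 400), "-")
  mono <- make_tx("t3", "s1", "chr1", 51, 80, "+")
  tss <- transcript_tss(rbind(plus, minus, mono))
  expect_equal(tss$tss[tss$transcript_id == "t1"], 101)
  expect_equal(tss$tss[tss$transcript_id == "t2"], 400)
  expect_equal(tss$tss[tss$transcript_id == "t3"], 51)
})

ltr_cat <- te_catalog("chr1", 1001L, 2000L, "+", "LTR12C", "ERV9", "LTR",
                      locus_id = "L1")
gene_ex <- GRanges("chr1", IRanges(c(3001, 4001), c(3200, 4200)))
mcols(gene_ex)$gene_id <- c("GA", "GA")

test_that("TcGT calling enforces all three predicates", {
  # TSS inside the LTR, junction into the gene: called
  ok <- make_tx("ok", "s1", "chr1", c(1101, 3001), c(1250, 3200), "+")
  res <- call_tcgts(ok, ltr_cat, gene_ex)
  expect_equal(nrow(res), 1L)
  expect_equal(res$driver_locus_id, "L1")
  expect_equal(res$gene_id, "GA")
  expect_equal(res$tss, 1101)
  # mono-exonic transcript starting in the LTR: no junction, no call
  mono <- make_tx("mono", "s1", "chr1", 1101, 1300, "+")
  expect_equal(nrow(call_tcgts(mono, ltr_cat, gene_ex)), 0L)
  # TSS one base upstream of the LTR boundary: no call
  out <- make_tx("out", "s1", "chr1", c(1000, 3001), c(1150, 3200), "+")
  expect_equal(nrow(call_tcgts(out, ltr_cat, gene_ex)), 0L)
  # TSS exactly on the first LTR base: called
  edge <- make_tx("edge", "s1", "chr1", c(1001, 3001), c(1150, 3200), "+")
  expect_equal(nrow(call_tcgts(edge, ltr_cat, gene_ex)), 1L)
  # junction into intergenic space only: no call
  inter <- make_tx("inter", "s1", "chr1", c(1101, 2500), c(1250, 2700), "+")
  expect_equal(nrow(call_tcgts(inter, ltr_cat, gene_ex)), 0L)
})

test_that("cognate gene maximizes downstream overlap with id tie-break", {
  two <- GRanges("chr1", IRanges(c(3001, 3001, 3121), c(3100, 3120, 3200)))
  mcols(two)$gene_id <- c("GB", "GA", "GC")
  tx <- make_tx("t", "s1", "chr1", c(1101, 3001), c(1250, 3200), "+")
  # GA overlaps 120 bp, GB 100, GC 80
  expect_equal(call_tcgts(tx, ltr_cat, two)$gene_id, "GA")
  tie <- GRanges("chr1", IRanges(c(3001, 3001), c(3100, 3100)))
  mcols(tie)$gene_id <- c("GZ", "GM")
  expect_equal(call_tcgts(tx, ltr_cat, tie)$gene_id, "GM")
})

test_that("transcripts on chromosomes absent from the catalog are skipped", {
  tx <- rbind(make_tx("t", "s1", "chr1", c(1101, 3001), c(1250, 3200), "+"),
              make_tx("x", "s1", "chrZ", c(1101, 3001), c(1250, 3200), "+"))
  expect_warning(res <- call_tcgts(tx, ltr_cat, gene_ex), "chrZ")
  expect_equal(res$transcript_id, "t")
})

fake_tcgt <- function(gene, sub, tss, sample = "s1", locus = "L1",
                      strand = "+") {
  data.frame(transcript_id = paste0("t", tss, sample), sample_id = sample,
             chrom = "chr1", strand = strand, tss = tss,
             driver_locus_id = locus, driver_subfamily = sub,
             gene_id = gene, stringsAsFactors = FALSE)
}

test_that("TSS aggregation chains by single linkage within 100 bp", {
  # {100,150,260}: 150-260 exceeds the window -> two aggregates
  t1 <- rbind(fake_tcgt("G", "S", 100), fake_tcgt("G", "S", 150),
              fake_tcgt("G", "S", 260))
  a1 <- aggregate_tcgts(t1, window = 100)
  expect_equal(nrow(a1), 2L)
  expect_equal(sort(a1$representative_tss), c(100, 260))
  expect_equal(a1$n_members[a1$representative_tss == 100], 2L)
  # {100,190,260}: chained through 190 -> one aggregate
  t2 <- rbind(fake_tcgt("G", "S", 100), fake_tcgt("G", "S", 190),
              fake_tcgt("G", "S", 260))
  a2 <- aggregate_tcgts(t2, window = 100)
  expect_equal(nrow(a2), 1L)
  expect_equal(a2$representative_tss, 100)
  # minus strand: representative is the 5'-most, i.e. the largest position
  t3 <- rbind(fake_tcgt("G", "S", 100, strand = "-"),
              fake_tcgt("G", "S", 150, strand = "-"))
  expect_equal(aggregate_tcgts(t3)$representative_tss, 150)
  # one call -> one aggregate; different genes never chain
  expect_equal(nrow(aggregate_tcgts(fake_tcgt("G", "S", 5))), 1L)
  t4 <- rbind(fake_tcgt("G1", "S", 100), fake_tcgt("G2", "S", 150))
  expect_equal(nrow(aggregate_tcgts(t4)), 2L)
  # permutation invariance
  perm <- t1[c(3, 1, 2), ]
  expect_equal(aggregate_tcgts(perm, window = 100), a1)
})

test_that("driver enrichment ranks a planted subfamily first", {
  subs <- c(rep("S", 20), rep(sprintf("O%02d", 1:9), each = 20))
  cat <- toy_catalog(subs)
  loci <- split(mcols(cat)$locus_id, mcols(cat)$subfamily)
  calls <- do.call(rbind, c(
    lapply(1:8, function(i)
      fake_tcgt(paste0("G", i), "S", i * 1000, locus = loci$S[i])),
    lapply(1:2, function(i)
      fake_tcgt(paste0("H", i), "O01", 50000 + i * 1000,
                locus = loci$O01[i]))))
  agg <- aggregate_tcgts(calls)
  enr <- tcgt_enrichment_table(agg, cat, c(s1 = "grp"))
  expect_equal(enr$subfamily[1L], "S")
  expect_equal(enr$n_driver_loci[enr$subfamily == "S"], 8L)
  expect_equal(enr$p[enr$subfamily == "S"],
               hypergeom_sf(8, 20, 10, 200), tolerance = 1e-12)
  expect_true(all(enr$padj >= enr$p))
  # a group with no calls yields count-zero rows with p = 1
  enr0 <- tcgt_enrichment_table(agg, cat, c(s1 = "grp", s9 = "empty"))
  e <- enr0[enr0$group == "empty", ]
  expect_true(all(e$tcgt_count == 0L) && all(e$p == 1))
  # single-subfamily universe: k = n, K = N -> p = 1
  cat1 <- toy_catalog(rep("S", 20))
  calls1 <- fake_tcgt("G", "S", 1000, locus = mcols(cat1)$locus_id[1])
  enr1 <- tcgt_enrichment_table(aggregate_tcgts(calls1), cat1, c(s1 = "g"))
  expect_equal(enr1$p, 1)
})
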