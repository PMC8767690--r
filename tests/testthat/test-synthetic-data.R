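test_that("the generator is deterministic given a seed", {
  cfg <- small_cfg(3)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_equal(as.data.frame(s1$annotation$fragmented),
               as.data.frame(s2$annotation$fragmented))
  expect_identical(s1$transcriptomes$transcripts,
                   s2$transcriptomes$transcripts)
  expect_identical(s1$expression$counts, s2$expression$counts)
  expect_identical(s1$methylation$calls, s2$methylation$calls)
  expect_identical(s1$peaks$base, s2$peaks$base)
  # a different seed perturbs the data
  s3 <- simulate_dataset(small_cfg(4))
  expect_false(identical(s1$expression$counts, s3$expression$counts))
})

test_that("fragmentation probability zero leaves the records untouched", {
  cfg <- small_cfg(5)
  cfg$fragmentation_prob <- 0
  ann <- simulate_annotation(cfg)
  expect_equal(as.data.frame(ann$fragmented), as.data.frame(ann$records))
})

test_that("fragment reassembly inverts the planted fragmentation exactly", {
  cfg <- small_cfg(6)
  ann <- simulate_annotation(cfg)
  expect_gt(length(ann$fragmented), length(ann$records))
  merged <- merge_fragments(ann$fragmented, max_gap = 100)
  got <- as.data.frame(merged)[, c("seqnames", "start", "end", "strand",
                                   "subfamily", "locus_id")]
  want <- as.data.frame(ann$records)[, c("seqnames", "start", "end",
                                         "strand", "subfamily", "locus_id")]
  expect_equal(got[order(got$locus_id), ], want[order(want$locus_id), ],
               ignore_attr = TRUE)
})

test_that("curation of the fragmented catalog reproduces the ground truth", {
  cfg <- small_cfg(8)
  ann <- simulate_annotation(cfg)
  cur <- curate_repeats(ann$fragmented, cfg$ltr_int_pairs)
  got <- as.data.frame(cur)
  want <- as.data.frame(ann$curated_truth)
  cols <- c("seqnames", "start", "end", "strand", "subfamily", "class",
            "locus_id", "is_solo_ltr")
  expect_equal(got[order(got$locus_id), cols],
               want[order(want$locus_id), cols], ignore_attr = TRUE)
})

test_that("planted chimeras satisfy, and decoys each violate, one predicate", {
  cfg <- small_cfg(9)
  sim <- simulate_dataset(cfg)
  ann <- sim$annotation
  exon_gr <- GRanges(ann$gene_exons$chrom,
                     IRanges(ann$gene_exons$start, ann$gene_exons$end))
  mcols(exon_gr)$gene_id <- ann$gene_exons$gene_id
  ltr <- ann$curated_truth[mcols(ann$curated_truth)$class == "LTR"]
  tx <- sim$transcriptomes$transcripts
  calls <- call_tcgts(tx, ltr, exon_gr)
  # recall 1: every planted (gene, locus) pair is called in its samples
  truth <- sim$transcriptomes$truth
  for (i in seq_len(nrow(truth))) {
    hit <- calls$gene_id == truth$gene_id[i] &
      calls$driver_locus_id == truth$locus_id[i]
    expect_setequal(calls$sample_id[hit],
                    strsplit(truth$samples[i], ",")[[1]])
  }
  # precision 1: no decoy or background transcript is ever called
  expect_length(intersect(calls$transcript_id,
                          sim$transcriptomes$decoys$transcript_id), 0L)
  expect_false(any(grepl("^bg_", calls$transcript_id)))
  # a decoy-only transcriptome yields zero calls
  dtx <- tx[tx$transcript_id %in% sim$transcriptomes$decoys$transcript_id, ]
  expect_equal(nrow(call_tcgts(dtx, ltr, exon_gr)), 0L)
})

test_that("emitted files re-parse losslessly through the package readers", {
  cfg <- small_cfg(10)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  # catalog BED
  f1 <- file.path(dir, "catalog.bed")
  write_catalog_bed(sim$annotation$fragmented, f1)
  expect_equal(as.data.frame(read_catalog_bed(f1)),
               as.data.frame(sim$annotation$fragmented))
  # per-sample transcript GTF
  tx <- sim$transcriptomes$transcripts
  sid <- tx$sample_id[1]
  one <- tx[tx$sample_id == sid, ]
  f2 <- file.path(dir, "sample.gtf")
  write_transcripts_gtf(one, f2)
  back <- read_transcripts_gtf(f2, sample_id = sid)
  o1 <- one[order(one$transcript_id, one$start), ]
  o2 <- back[order(back$transcript_id, back$start), ]
  expect_equal(o2[, names(o1)], o1, ignore_attr = TRUE)
  # CpG calls
  f3 <- file.path(dir, "cpg.tsv")
  write_cpg_calls(sim$methylation$calls, f3)
  expect_equal(read_cpg_calls(f3), sim$methylation$calls,
               ignore_attr = TRUE)
  # counts
  f4 <- file.path(dir, "counts.tsv")
  write_count_matrix(sim$expression$counts, sim$expression$feature_kind, f4)
  rt <- read_count_matrix(f4)
  expect_equal(rt$counts, sim$expression$counts)
})

test_that("expression and methylation generators honor their plans", {
  cfg <- small_cfg(11)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(cfg, ann)
  expect_equal(sum(ex$feature_kind == "te_locus"), 12L)
  expect_equal(ncol(ex$counts), 12L)
  expect_setequal(unique(ex$truth_labels), c("maternal", "zga"))
  me <- simulate_methylation(cfg, ann)
  expect_length(me$truth$set_a, 8L)
  expect_length(intersect(me$truth$set_a, me$truth$set_b), 0L)
  # zero CpG density produces an empty call table
  cfg0 <- cfg
  cfg0$methyl_plan$set_size <- 0L
  expect_equal(nrow(simulate_methylation(cfg0, ann)$calls), 0L)
})
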