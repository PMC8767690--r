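rmsk_text <- c(
  "   SW   perc perc perc  query     position in query    matching  repeat         position in repeat",
  "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family   begin end (left)  ID",
  "",
  "  463   1.3  0.6  1.7   chr1      1001  1600  (100)  +  LTR12C   LTR/ERV9          1  600   (0)    1",
  "  239   2.0  0.0  0.0   chr1      5001  5300  (50)   C  THE1B    LTR/MaLR        (0)  300     1    2")

test_that("RepeatMasker .out records parse with 1-based inclusive coordinates", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(rmsk_text, f)
  cat <- parse_te_annotation(f, dialect = "rmsk_out")
  expect_length(cat, 2L)
  expect_equal(start(cat), c(1001L, 5001L))
  expect_equal(end(cat), c(1600L, 5300L))
  expect_equal(as.character(strand(cat)), c("+", "-"))
  expect_equal(mcols(cat)$subfamily, c("LTR12C", "THE1B"))
  expect_equal(mcols(cat)$class, c("LTR", "LTR"))
  expect_equal(mcols(cat)$family, c("ERV9", "MaLR"))
  expect_equal(mcols(cat)$linkage_id, c("1", "2"))
  # empty file yields an empty catalog
  f2 <- withr::local_tempfile(fileext = ".out")
  writeLines(rmsk_text[1:3], f2)
  expect_length(read_rmsk_out(f2), 0L)
  expect_error(parse_te_annotation(f, dialect = "gff"), "arg")
})

test_that("catalog BED starts convert from 0-based half-open and round-trip", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t1600\tA1\t0\t+\tLTR12C\tERV9\tLTR", f)
  cat <- parse_te_annotation(f, dialect = "bed")
  expect_equal(start(cat), 1000L)
  expect_equal(end(cat), 1600L)
  # write -> re-parse round trip is lossless
  cat2 <- te_catalog(c("chr1", "chr2"), c(1000L, 50L), c(1600L, 400L),
                     c("+", "-"), c("LTR12C", "AluY"), c("ERV9", "Alu"),
                     c("LTR", "SINE"), locus_id = c("a", "b"),
                     linkage_id = c("x", NA), is_solo_ltr = c(TRUE, FALSE))
  f3 <- withr::local_tempfile(fileext = ".bed")
  write_catalog_bed(cat2, f3)
  back <- read_catalog_bed(f3)
  expect_equal(as.data.frame(back), as.data.frame(cat2))
})

test_that("fragment reassembly merges by gap and linkage, and is idempotent", {
  # two LTR12C fragments, 50 bp apart (closed coords of [1000,1300)+[1350,1600))
  frag <- te_catalog(rep("chr1", 2), c(1001L, 1351L), c(1300L, 1600L), "+",
                     "LTR12C", "ERV9", "LTR", locus_id = c("f1", "f2"))
  m <- merge_fragments(frag, max_gap = 100)
  expect_length(m, 1L)
  expect_equal(c(start(m), end(m)), c(1001L, 1600L))
  expect_equal(mcols(m)$merged_from, "f1,f2")
  # gap 500 > max_gap: not merged
  far <- te_catalog(rep("chr1", 2), c(1001L, 1801L), c(1300L, 2100L), "+",
                    "LTR12C", "ERV9", "LTR")
  expect_length(merge_fragments(far, max_gap = 100), 2L)
  # a shared linkage id bridges distances beyond max_gap
  linked <- te_catalog(rep("chr1", 2), c(1001L, 3001L), c(1300L, 3400L), "+",
                       "LTR12C", "ERV9", "LTR", locus_id = c("p_f1", "p_f2"),
                       linkage_id = "p")
  ml <- merge_fragments(linked, max_gap = 100)
  expect_length(ml, 1L)
  expect_equal(mcols(ml)$locus_id, "p")
  # single record is unchanged; merging is idempotent
  single <- te_catalog("chr1", 10L, 200L, "+", "X", "F", "LTR")
  expect_equal(as.data.frame(merge_fragments(single)), as.data.frame(single))
  expect_equal(as.data.frame(merge_fragments(m, max_gap = 100)),
               as.data.frame(m))
  # different strands or subfamilies never merge
  mixed <- te_catalog(rep("chr1", 2), c(1001L, 1351L), c(1300L, 1600L),
                      c("+", "-"), "LTR12C", "ERV9", "LTR")
  expect_length(merge_fragments(mixed, max_gap = 100), 2L)
})

test_that("LTR-int-LTR runs assemble into full-length ERVs with solo flags", {
  pairs <- c(LTR12C = "HERV9-int")
  cat <- te_catalog(
    rep("chr1", 5),
    start = c(1001L, 1651L, 8051L, 20001L, 40001L),
    end = c(1600L, 8000L, 8600L, 20600L, 46000L),
    strand = "+",
    subfamily = c("LTR12C", "HERV9-int", "LTR12C", "LTR12C", "HERV9-int"),
    family = "ERV9", class = "LTR",
    locus_id = c("l5", "int", "l3", "solo", "int_alone"))
  out <- assemble_full_length_ervs(cat, pairs, max_gap = 500)
  df <- as.data.frame(mcols(out))
  expect_length(out, 3L)
  full <- out[df$locus_id == "int"]
  expect_equal(c(start(full), end(full)), c(1001L, 8600L))
  expect_equal(mcols(full)$subfamily, "HERV9-int")
  expect_false(mcols(full)$is_solo_ltr)
  expect_equal(mcols(full)$merged_from, "l5,int,l3")
  expect_true(df$is_solo_ltr[df$locus_id == "solo"])
  expect_false(df$is_solo_ltr[df$locus_id == "int_alone"])
  # an LTR next to an internal it is not paired with stays unmerged
  odd <- te_catalog(rep("chr1", 2), c(1001L, 1651L), c(1600L, 8000L), "+",
                    c("LTR7", "HERV9-int"), c("HERVH", "ERV9"), "LTR",
                    locus_id = c("ltr7", "int9"))
  expect_warning(out2 <- assemble_full_length_ervs(odd, pairs, max_gap = 500),
                 "not paired")
  expect_length(out2, 2L)
  expect_true(mcols(out2)$is_solo_ltr[mcols(out2)$locus_id == "ltr7"])
})

test_that("exon exclusion uses >= 1 bp overlap on consistent coordinates", {
  cat <- te_catalog(rep("chr1", 2), c(101L, 101L), c(200L, 200L), "+",
                    c("A", "B"), "F", "LTR", locus_id = c("ov", "ab"))
  # exon touching base 200 overlaps locus "ov"; abutting exon at 201 does not
  expect_length(
    suppressMessages(exclude_exon_overlaps(cat[1], GRanges("chr1", IRanges(200, 300)))), 0L)
  expect_length(
    exclude_exon_overlaps(cat[2], GRanges("chr1", IRanges(201, 300))), 1L)
  expect_equal(exclude_exon_overlaps(cat, GRanges()), cat)
})

test_that("subfamily sizes sum merged locus lengths once", {
  cat <- te_catalog(rep("chr1", 3), c(1L, 201L, 1001L),
                    c(100L, 400L, 1600L), "+",
                    c("S", "S", "T"), "F", "LTR")
  sz <- subfamily_sizes(cat)
  expect_equal(sz$n_loci[sz$subfamily == "S"], 2L)
  expect_equal(sz$total_bp[sz$subfamily == "S"], 300L)
  expect_equal(sz$total_bp[sz$subfamily == "T"], 600L)
  expect_equal(nrow(subfamily_sizes(cat[0])), 0L)
  # merged fragments count once with the merged length
  frag <- te_catalog(rep("chr1", 2), c(1001L, 1351L), c(1300L, 1600L), "+",
                     "S", "F", "LTR")
  szm <- subfamily_sizes(merge_fragments(frag, max_gap = 100))
  expect_equal(szm$n_loci, 1L)
  expect_equal(szm$total_bp, 600L)
})
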