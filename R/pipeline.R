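#' Rand index between two partitions
#'
#' Pair-counting agreement between two clusterings of the same items:
#' the fraction of item pairs on which the two partitions agree (both
#' together or both apart). 1 means identical partitions up to label
#' permutation.
#'
#' @param a,b Cluster label vectors of equal length (names ignored; order
#'   must correspond).
#' @return The Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  if (n < 2) return(1)
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

#' Curate a repeat catalog
#'
#' The standard curation chain: reassemble fragmented records, merge LTRs
#' with adjacent internal segments into full-length ERVs (flagging solo
#' LTRs), and drop loci overlapping exons.
#'
#' @param catalog Raw `GRanges` catalog (e.g. from [read_rmsk_out()]).
#' @param ltr_int_pairs Named vector pairing LTR subfamilies with internal
#'   subfamilies.
#' @param exons Optional `GRanges` of exons to exclude against.
#' @param fragment_gap Maximum gap for fragment reassembly (bp).
#' @param erv_gap Maximum LTR-internal gap for full-length assembly (bp).
#' @return The curated `GRanges` catalog.
#' @export
curate_repeats <- function(catalog, ltr_int_pairs, exons = NULL,
                           fragment_gap = 100, erv_gap = 500) {
  out <- merge_fragments(catalog, max_gap = fragment_gap)
  out <- assemble_full_length_ervs(out, ltr_int_pairs, max_gap = erv_gap)
  if (!is.null(exons)) out <- exclude_exon_overlaps(out, exons)
  out
}

#' Run the full demonstration pipeline on synthetic data
#'
#' Simulates the toy dataset, curates the fragmented repeat annotation,
#' calls and aggregates TcGTs, computes per-subfamily TcGT and peak
#' enrichments, builds consensus peaks, tests 50-kb gene proximity,
#' clusters TE-locus expression into temporal patterns and contrasts
#' methylation between the planted locus sets — then scores every stage
#' against the generator's ground truth.
#'
#' @param cfg A [sim_config()] (or a seed, promoted via `sim_config(seed)`).
#' @param out_dir Optional directory; when given, the main tables (catalog
#'   BED, TcGT and enrichment TSVs, consensus BED, counts and cluster TSVs,
#'   methylation TSV, JSON report) are written there.
#' @return A report list; see the fields returned.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  if (!inherits(cfg, "sim_config")) cfg <- sim_config(seed = cfg)
  sim <- simulate_dataset(cfg)
  ann <- sim$annotation
  exon_gr <- GRanges(ann$gene_exons$chrom,
                     IRanges(ann$gene_exons$start, ann$gene_exons$end))
  mcols(exon_gr)$gene_id <- ann$gene_exons$gene_id

  # --- repeat curation ---
  curated <- curate_repeats(ann$fragmented, cfg$ltr_int_pairs,
                            exons = exon_gr)
  truth_df <- .catalog_df(ann$curated_truth)
  cur_df <- .catalog_df(curated)
  m <- match(truth_df$locus_id, cur_df$locus_id)
  curation_exact <- !anyNA(m) && nrow(cur_df) == nrow(truth_df) &&
    all(cur_df$start[m] == truth_df$start) &&
    all(cur_df$end[m] == truth_df$end) &&
    all(cur_df$subfamily[m] == truth_df$subfamily)
  solo_accuracy <- mean(cur_df$is_solo_ltr[m] == truth_df$is_solo_ltr,
                        na.rm = TRUE)

  # --- TcGT calling, aggregation, enrichment ---
  ltr_cat <- curated[mcols(curated)$class == "LTR"]
  tcgts <- call_tcgts(sim$transcriptomes$transcripts, ltr_cat, exon_gr)
  agg <- aggregate_tcgts(tcgts, window = 100)
  enr <- tcgt_enrichment_table(agg, ltr_cat, sim$transcriptomes$groups)
  groups <- sim$transcriptomes$groups
  called <- unique(data.frame(group = unname(groups[tcgts$sample_id]),
                              gene_id = tcgts$gene_id,
                              locus_id = tcgts$driver_locus_id,
                              stringsAsFactors = FALSE))
  planted <- unique(sim$ground_truth$planted_tcgts[
    , c("group", "gene_id", "locus_id")])
  key <- function(d) paste(d$group, d$gene_id, d$locus_id)
  recall <- mean(key(planted) %in% key(called))
  precision <- if (nrow(called)) mean(key(called) %in% key(planted)) else NA
  top <- do.call(rbind, lapply(split(enr, enr$group),
                               function(d) d[1L, , drop = FALSE]))
  tcgt_top_correct <- all(top$subfamily == cfg$tcgt_subfamily)
  tcgt_top_max_padj <- max(top$padj)

  # --- peak enrichment, consensus, proximity ---
  assignments <- assign_peaks(sim$peaks$base, curated, min_frac = 0.5)
  sizes <- subfamily_sizes(curated)
  pe <- subfamily_peak_enrichment(assignments, length(sim$peaks$base),
                                  sizes, sum(cfg$genome))
  peak_top_correct <- pe$subfamily[1L] == sim$ground_truth$enriched_peak_subfamily
  cons <- consensus_peaks(sim$peaks$replicates, min_support = 2)
  prox <- proximity_enrichment(
    unique(planted$gene_id),
    ann$genes[, c("gene_id", "chrom", "tss")],
    curated[mcols(curated)$subfamily == cfg$tcgt_subfamily],
    window = 50000)

  # --- expression clustering ---
  ex <- sim$expression
  keep <- rowSums(ex$counts) >= ncol(ex$counts)
  norm <- tmm_normalize(ex$counts[keep, , drop = FALSE],
                        ex$feature_kind[keep])
  te_rows <- rownames(norm$matrix)[norm$feature_kind == "te_locus"]
  z <- suppressMessages(zscore_rows(log2(norm$matrix[te_rows, , drop = FALSE] + 1)))
  cl <- suppressMessages(cluster_loci(z, k = 2))
  lab <- ex$truth_labels[names(cl$clusters)]
  ri <- rand_index(cl$clusters[!is.na(lab)], lab[!is.na(lab)])

  # --- methylation contrast ---
  lm <- locus_methylation(sim$methylation$calls, curated)
  reps <- setNames(rep("pgc", length(sim$methylation$truth$replicates)),
                   sim$methylation$truth$replicates)
  avg <- average_replicates(lm, reps)
  set_a <- avg[avg$locus_id %in% sim$methylation$truth$set_a, , drop = FALSE]
  set_b <- avg[avg$locus_id %in% sim$methylation$truth$set_b, , drop = FALSE]
  meth <- compare_locus_sets(set_a, set_b)

  report <- list(
    seed = cfg$seed,
    n_te_records = length(ann$records),
    n_fragmented_records = length(ann$fragmented),
    n_curated_loci = length(curated),
    curation_exact = curation_exact,
    solo_ltr_flag_accuracy = solo_accuracy,
    n_tcgt_calls = nrow(tcgts),
    n_tcgt_aggregates = nrow(agg),
    n_planted_tcgts = nrow(planted),
    tcgt_recall = recall,
    tcgt_precision = precision,
    tcgt_top_subfamily_correct = tcgt_top_correct,
    tcgt_top_subfamily_max_padj = tcgt_top_max_padj,
    peak_top_subfamily = pe$subfamily[1L],
    peak_top_subfamily_correct = peak_top_correct,
    peak_top_padj = pe$padj[1L],
    n_consensus_peaks = length(cons),
    proximity_table = prox$table,
    proximity_p = prox$p.value,
    cluster_rand_index = ri,
    methylation_median_a = meth$median_a,
    methylation_median_b = meth$median_b,
    methylation_p = meth$p.value)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_catalog_bed(curated, file.path(out_dir, "curated_catalog.bed"))
    write.table(tcgts, file.path(out_dir, "tcgt_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(enr, file.path(out_dir, "tcgt_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pe, file.path(out_dir, "peak_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_peaks_bed(cons, file.path(out_dir, "consensus_peaks.bed"))
    write_count_matrix(ex$counts, ex$feature_kind,
                       file.path(out_dir, "counts.tsv"))
    write.table(data.frame(locus_id = names(cl$clusters),
                           cluster = unname(cl$clusters)),
                file.path(out_dir, "te_clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(avg, file.path(out_dir, "locus_methylation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report[!vapply(report, is.matrix, TRUE)],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
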