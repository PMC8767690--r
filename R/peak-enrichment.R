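#' Read ChIP peaks from BED/narrowPeak
#'
#' Reads a BED3+ or narrowPeak file (0-based half-open on disk) into a
#' `GRanges`. Column 5 (score) is kept when present; extra narrowPeak
#' columns are ignored.
#'
#' @param path Path to the peak file.
#' @param replicate_id Optional replicate label stored in `mcols`.
#' @return A `GRanges` of peaks.
#' @export
read_peaks_bed <- function(path, replicate_id = NULL) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE, quote = "",
                   comment.char = "#")
  if (ncol(df) < 3L) stop("peak BED needs at least 3 columns")
  gr <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]))
  if (ncol(df) >= 5L && is.numeric(df[[5L]])) mcols(gr)$score <- df[[5L]]
  if (!is.null(replicate_id)) mcols(gr)$replicate_id <- replicate_id
  gr
}

#' Write peaks to BED
#'
#' @param peaks A `GRanges` of peaks.
#' @param path Output path (BED: 0-based half-open starts).
#' @return Invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- if (!is.null(mcols(peaks)$score)) mcols(peaks)$score else 0
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = sprintf("peak_%05d", seq_along(peaks)),
                   score = score, strand = ".",
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes table
#'
#' @param path Two-column TSV: sequence name, length in bp.
#' @return A named numeric vector of sequence lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chrom.sizes needs two columns")
  setNames(as.numeric(df[[2L]]), df[[1L]])
}

#' Assign ChIP peaks to TE loci
#'
#' Each peak is assigned to the catalog locus it overlaps most, provided the
#' overlap exceeds `min_frac` of the peak length (strictly greater, matching
#' an "above 50%" inclusion rule at the default). Peaks not reaching the
#' threshold are reported unassigned with their best overlap.
#'
#' @param peaks A `GRanges` of peaks.
#' @param catalog A `GRanges` TE catalog.
#' @param min_frac Minimum overlap fraction of the peak length (strict).
#' @return A data.frame with one row per peak: `peak_id`, `chrom`, `start`,
#'   `end`, `locus_id`, `subfamily` (both `NA` when unassigned) and
#'   `overlap_bp`.
#' @export
assign_peaks <- function(peaks, catalog, min_frac = 0.5) {
  out <- data.frame(peak_id = sprintf("peak_%05d", seq_along(peaks)),
                    chrom = as.character(seqnames(peaks)),
                    start = start(peaks), end = end(peaks),
                    locus_id = NA_character_, subfamily = NA_character_,
                    overlap_bp = 0L, stringsAsFactors = FALSE)
  if (length(peaks) == 0 || length(catalog) == 0) return(out)
  hits <- findOverlaps(peaks, catalog, ignore.strand = TRUE)
  if (length(hits) == 0) return(out)
  ov <- width(pintersect(peaks[queryHits(hits)], catalog[subjectHits(hits)],
                         ignore.strand = TRUE))
  hdf <- data.frame(q = queryHits(hits), s = subjectHits(hits), ov = ov)
  hdf <- hdf[order(hdf$q, -hdf$ov, start(catalog)[hdf$s]), , drop = FALSE]
  hdf <- hdf[!duplicated(hdf$q), , drop = FALSE]
  out$overlap_bp[hdf$q] <- hdf$ov
  assigned <- hdf$ov > min_frac * width(peaks)[hdf$q]
  out$locus_id[hdf$q[assigned]] <- mcols(catalog)$locus_id[hdf$s[assigned]]
  out$subfamily[hdf$q[assigned]] <- mcols(catalog)$subfamily[hdf$s[assigned]]
  out
}

#' Genomic-size-corrected binomial enrichment of peaks per subfamily
#'
#' Compares the number of peaks assigned to each TE subfamily against a
#' uniform placement expectation: with `n` peaks in total and a subfamily
#' covering `total_bp` of a `genome_bp` genome, the one-sided p-value is
#' [binom_sf()]`(k, n, total_bp / genome_bp)`, BH-adjusted across
#' subfamilies.
#'
#' @param assignments Peak assignment table from [assign_peaks()].
#' @param n_peaks_total Total number of peaks tested (the binomial `n`).
#' @param sizes Subfamily size table from [subfamily_sizes()].
#' @param genome_bp Total genome length in bp.
#' @return A data.frame with `subfamily`, `n_peaks`, `expected`, `p`,
#'   `padj`, ordered by adjusted p-value.
#' @export
subfamily_peak_enrichment <- function(assignments, n_peaks_total, sizes,
                                      genome_bp) {
  if (genome_bp < max(c(0, sizes$total_bp))) {
    stop("genome_bp must be at least the largest subfamily total_bp")
  }
  zero <- sizes$total_bp == 0
  if (any(zero)) {
    warning("skipping subfamilies with zero genomic size: ",
            paste(sizes$subfamily[zero], collapse = ", "))
    sizes <- sizes[!zero, , drop = FALSE]
  }
  k <- vapply(sizes$subfamily, function(s)
    sum(!is.na(assignments$subfamily) & assignments$subfamily == s), 1L)
  p0 <- sizes$total_bp / genome_bp
  p <- vapply(seq_along(k), function(i)
    binom_sf(k[i], n_peaks_total, p0[i]), 1)
  out <- data.frame(subfamily = sizes$subfamily, n_peaks = unname(k),
                    expected = n_peaks_total * p0, p = p,
                    padj = unname(bh_adjust(p)), stringsAsFactors = FALSE)
  out <- out[order(out$padj, out$p, out$subfamily), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate-consensus peaks
#'
#' Keeps genomic regions covered by peaks from at least `min_support`
#' distinct replicates and merges the contributing peaks into their union
#' interval. Symmetric in replicate order.
#'
#' @param replicate_sets A list of `GRanges`, one per replicate.
#' @param min_support Minimum number of distinct replicates (default 2).
#' @return A `GRanges` of consensus peaks.
#' @export
consensus_peaks <- function(replicate_sets, min_support = 2) {
  if (!is.list(replicate_sets) || length(replicate_sets) < min_support) {
    stop(sprintf("need at least %d replicate peak sets, got %d",
                 min_support, length(replicate_sets)))
  }
  red <- lapply(replicate_sets, function(gr) reduce(granges(gr)))
  pooled <- suppressWarnings(do.call(c, unname(red)))
  if (length(pooled) == 0) return(GRanges())
  cov <- coverage(pooled)
  core <- as(cov >= min_support, "GRanges")
  core <- core[mcols(core)$score]
  mcols(core) <- NULL
  if (length(core) == 0) return(GRanges())
  contributing <- pooled[overlapsAny(pooled, core)]
  sort(reduce(contributing))
}

#' Fisher test for TE proximity of a gene set
#'
#' Classifies every gene by membership in `gene_set` and by whether its TSS
#' lies within `window` bp of any supplied TE locus (distance from the TSS
#' to the nearest locus edge; 0 when overlapping), then tests the resulting
#' 2x2 table with [fisher_exact_2x2()].
#'
#' @param gene_set Character vector of gene ids of interest (e.g.
#'   dysregulated genes); must be a non-empty subset of `all_genes`.
#' @param all_genes Gene TSS table: data.frame with `gene_id`, `chrom`,
#'   `tss`.
#' @param te_loci A `GRanges` of TE loci.
#' @param window Proximity window in bp (default 50000).
#' @return A list with `table` (2x2 matrix, rows = in set / not, columns =
#'   near / far) and `p.value`.
#' @export
proximity_enrichment <- function(gene_set, all_genes, te_loci,
                                 window = 50000) {
  if (length(gene_set) == 0) stop("gene_set must be non-empty")
  if (!all(gene_set %in% all_genes$gene_id)) {
    stop("gene_set contains ids absent from all_genes: ",
         paste(head(setdiff(gene_set, all_genes$gene_id), 5), collapse = ", "))
  }
  tss_gr <- GRanges(all_genes$chrom, IRanges(all_genes$tss, width = 1L))
  near <- rep(FALSE, nrow(all_genes))
  if (length(te_loci) > 0) {
    d <- distanceToNearest(tss_gr, te_loci, ignore.strand = TRUE)
    near[queryHits(d)] <- mcols(d)$distance <= window
  }
  in_set <- all_genes$gene_id %in% gene_set
  tab <- matrix(c(sum(in_set & near), sum(in_set & !near),
                  sum(!in_set & near), sum(!in_set & !near)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_set", "background"),
                                c("near_te", "far")))
  list(table = tab, p.value = fisher_exact_2x2(tab))
}
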