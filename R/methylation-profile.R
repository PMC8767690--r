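#' Read CpG methylation calls
#'
#' Reads a bedGraph-like TSV of CpG methylation calls. Two layouts are
#' accepted, identified by the header: `chrom`, `pos`, `meth_level`
#' (fraction in \[0, 1\]) or `chrom`, `pos`, `meth_count`, `total_count`
#' (ratio computed on the fly). An optional `sample_id` column is carried
#' through; `sample_id` passed as an argument overrides it. Positions are
#' 0-based on disk (the C of the CpG) and converted to 1-based internally.
#'
#' @param path Path to the TSV (with header).
#' @param sample_id Optional sample label applied to all calls.
#' @return A data.frame with `chrom`, `pos` (1-based), `meth_level`,
#'   `sample_id`.
#' @export
read_cpg_calls <- function(path, sample_id = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(df))) {
    stop("CpG table needs chrom and pos columns")
  }
  if ("meth_level" %in% names(df)) {
    lev <- df$meth_level
  } else if (all(c("meth_count", "total_count") %in% names(df))) {
    if (any(df$total_count <= 0)) stop("total_count must be positive")
    lev <- df$meth_count / df$total_count
  } else {
    stop("CpG table needs meth_level or meth_count/total_count columns")
  }
  sid <- if (!is.null(sample_id)) sample_id
         else if ("sample_id" %in% names(df)) df$sample_id
         else "sample1"
  out <- data.frame(chrom = df$chrom, pos = df$pos + 1L, meth_level = lev,
                    sample_id = sid, stringsAsFactors = FALSE)
  .validate_cpg(out)
}

#' Write CpG methylation calls
#'
#' @param calls CpG call table (1-based `pos`, written 0-based).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cpg_calls <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom, pos = calls$pos - 1L,
                    meth_level = calls$meth_level,
                    sample_id = calls$sample_id, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_cpg <- function(calls) {
  need <- c("chrom", "pos", "meth_level", "sample_id")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("CpG calls lack columns: ", paste(miss, collapse = ", "))
  if (any(calls$meth_level < 0 | calls$meth_level > 1)) {
    stop("meth_level values must lie in [0, 1]")
  }
  calls
}

#' Mean CpG methylation per TE locus
#'
#' Intersects CpG calls with the catalog (position containment, strand
#' ignored) and averages the methylation levels of the CpGs inside each
#' locus, per sample, with equal weight per CpG. Loci without any profiled
#' CpG are absent from the output.
#'
#' @param calls CpG call table (see [read_cpg_calls()]).
#' @param catalog A `GRanges` TE catalog.
#' @return A data.frame with `locus_id`, `sample_id`, `mean_meth`,
#'   `n_cpgs`.
#' @export
locus_methylation <- function(calls, catalog) {
  .validate_cpg(calls)
  empty <- data.frame(locus_id = character(), sample_id = character(),
                      mean_meth = numeric(), n_cpgs = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0 || length(catalog) == 0) return(empty)
  gr <- GRanges(calls$chrom, IRanges(calls$pos, width = 1L))
  hits <- findOverlaps(gr, catalog, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  df <- data.frame(locus_id = mcols(catalog)$locus_id[subjectHits(hits)],
                   sample_id = calls$sample_id[queryHits(hits)],
                   meth = calls$meth_level[queryHits(hits)],
                   stringsAsFactors = FALSE)
  key <- paste(df$locus_id, df$sample_id, sep = "\r")
  out <- do.call(rbind, lapply(split(df, key), function(d) {
    data.frame(locus_id = d$locus_id[1L], sample_id = d$sample_id[1L],
               mean_meth = mean(d$meth), n_cpgs = nrow(d),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$locus_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average locus methylation across replicates
#'
#' Averages per-locus methylation over the replicates of each group,
#' ignoring replicates that did not profile the locus. `n_cpgs` reports the
#' largest CpG count among contributing replicates.
#'
#' @param locus_meth Locus methylation table from [locus_methylation()].
#' @param replicate_groups Named character vector mapping `sample_id` to a
#'   replicate group label.
#' @return A locus methylation table with `sample_id` replaced by the group
#'   label.
#' @export
average_replicates <- function(locus_meth, replicate_groups) {
  unknown <- setdiff(unique(locus_meth$sample_id), names(replicate_groups))
  if (length(unknown)) {
    stop("samples without replicate group: ", paste(unknown, collapse = ", "))
  }
  grp <- unname(replicate_groups[locus_meth$sample_id])
  key <- paste(locus_meth$locus_id, grp, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(locus_meth)), key),
                               function(idx) {
    d <- locus_meth[idx, , drop = FALSE]
    data.frame(locus_id = d$locus_id[1L],
               sample_id = unname(replicate_groups[d$sample_id[1L]]),
               mean_meth = mean(d$mean_meth), n_cpgs = max(d$n_cpgs),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$locus_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean methylation per TE subfamily
#'
#' Averages the locus-level means of all detected member loci of each
#' subfamily, with equal weight per locus (not per CpG).
#'
#' @param locus_meth Locus methylation table.
#' @param catalog A `GRanges` TE catalog supplying locus-to-subfamily
#'   membership.
#' @return A data.frame with `subfamily`, `sample_id`, `mean_meth`,
#'   `n_loci`.
#' @export
subfamily_methylation <- function(locus_meth, catalog) {
  membership <- setNames(mcols(catalog)$subfamily, mcols(catalog)$locus_id)
  unknown <- setdiff(unique(locus_meth$locus_id), names(membership))
  if (length(unknown)) {
    stop("loci absent from the catalog: ",
         paste(head(unknown, 10), collapse = ", "))
  }
  sf <- unname(membership[locus_meth$locus_id])
  key <- paste(sf, locus_meth$sample_id, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(locus_meth)), key),
                               function(idx) {
    d <- locus_meth[idx, , drop = FALSE]
    data.frame(subfamily = unname(membership[d$locus_id[1L]]),
               sample_id = d$sample_id[1L],
               mean_meth = mean(d$mean_meth), n_loci = nrow(d),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$subfamily, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare methylation between two locus sets
#'
#' Two-sided Wilcoxon rank-sum comparison of per-locus methylation means
#' between two disjoint locus sets (e.g. maternal-cluster vs ZGA-cluster
#' LTR12C loci, or KZFP targets vs non-targets).
#'
#' @param set_a,set_b Locus methylation tables (columns `locus_id`,
#'   `mean_meth`) with no locus in common.
#' @return A list with `p.value`, `statistic`, `method`, `median_a`,
#'   `median_b`, `n_a`, `n_b`.
#' @export
compare_locus_sets <- function(set_a, set_b) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    stop("both locus sets must be non-empty")
  }
  shared <- intersect(set_a$locus_id, set_b$locus_id)
  if (length(shared)) {
    stop("locus sets must be disjoint; shared: ",
         paste(head(shared, 10), collapse = ", "))
  }
  rs <- ranksum_test(set_a$mean_meth, set_b$mean_meth)
  c(rs, list(median_a = median(set_a$mean_meth),
             median_b = median(set_b$mean_meth),
             n_a = nrow(set_a), n_b = nrow(set_b)))
}
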