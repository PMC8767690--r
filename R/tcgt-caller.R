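#' Read assembled transcript models from a GTF
#'
#' Imports exon records from a GTF and returns the flat exon table consumed
#' by [call_tcgts()] (one row per exon; 1-based closed coordinates).
#'
#' @param path Path to a GTF with `transcript_id` attributes on exon rows.
#' @param sample_id Sample identifier attached to every transcript; defaults
#'   to the file name without extension.
#' @return A data.frame with columns `transcript_id`, `sample_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_transcripts_gtf <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[mcols(gr)$type == "exon"]
  data.frame(transcript_id = as.character(mcols(gr)$transcript_id),
             sample_id = sample_id,
             chrom = as.character(seqnames(gr)),
             start = start(gr), end = end(gr),
             strand = as.character(strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write transcript models to a GTF
#'
#' @param transcripts Exon table as returned by [read_transcripts_gtf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  gr <- GRanges(transcripts$chrom,
                IRanges(transcripts$start, transcripts$end),
                strand = transcripts$strand)
  mcols(gr) <- DataFrame(type = "exon",
                         gene_id = transcripts$transcript_id,
                         transcript_id = transcripts$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

.validate_transcripts <- function(transcripts) {
  need <- c("transcript_id", "sample_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(transcripts))
  if (length(miss)) stop("transcripts table lacks columns: ",
                         paste(miss, collapse = ", "))
  invisible(transcripts)
}

#' Strand-aware transcription start sites
#'
#' The TSS of a transcript model is the 5'-most transcribed base: the start
#' of the leftmost exon on the plus strand, the end of the rightmost exon on
#' the minus strand.
#'
#' @param transcripts Exon table (see [read_transcripts_gtf()]).
#' @return A data.frame with one row per transcript: `transcript_id`,
#'   `sample_id`, `chrom`, `strand`, `tss`, `n_exons`.
#' @export
transcript_tss <- function(transcripts) {
  .validate_transcripts(transcripts)
  sp <- split(seq_len(nrow(transcripts)), transcripts$transcript_id)
  rows <- lapply(sp, function(idx) {
    ex <- transcripts[idx, , drop = FALSE]
    st <- ex$strand[1L]
    tss <- if (st == "-") max(ex$end) else min(ex$start)
    data.frame(transcript_id = ex$transcript_id[1L],
               sample_id = ex$sample_id[1L], chrom = ex$chrom[1L],
               strand = st, tss = tss, n_exons = nrow(ex),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call transpochimeric gene transcripts
#'
#' A transcript model is called as a TcGT when (a) its TSS base lies inside a
#' catalog locus, (b) it has at least one splice junction (>= 2 exons), and
#' (c) at least one exon downstream of a junction overlaps an annotated exon
#' of a gene. The cognate gene is the one with the largest total downstream
#' exonic overlap (ties broken by the lexicographically smallest `gene_id`).
#' When the TSS falls inside two overlapping loci the locus with the leftmost
#' start is taken. The catalog passed in should normally be restricted to
#' LTR-class loci.
#'
#' @param transcripts Exon table (see [read_transcripts_gtf()]).
#' @param catalog A `GRanges` TE catalog (typically `class == "LTR"`).
#' @param genes Gene exon annotation: a `GRanges` with a `gene_id` metadata
#'   column, or a data.frame with `chrom`, `start`, `end`, `gene_id`.
#' @return A data.frame of TcGT calls: `transcript_id`, `sample_id`,
#'   `chrom`, `strand`, `tss`, `driver_locus_id`, `driver_subfamily`,
#'   `gene_id`.
#' @export
call_tcgts <- function(transcripts, catalog, genes) {
  .validate_transcripts(transcripts)
  genes_gr <- .as_exon_granges(genes)
  tss <- transcript_tss(transcripts)
  empty <- data.frame(transcript_id = character(), sample_id = character(),
                      chrom = character(), strand = character(),
                      tss = integer(), driver_locus_id = character(),
                      driver_subfamily = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(tss) == 0) return(empty)
  cat_chroms <- unique(as.character(seqnames(catalog)))
  off <- !tss$chrom %in% cat_chroms
  if (any(off)) {
    warning(sprintf("skipping %d transcript(s) on chromosome(s) absent from the catalog: %s",
                    sum(off), paste(unique(tss$chrom[off]), collapse = ", ")))
    tss <- tss[!off, , drop = FALSE]
  }
  if (nrow(tss) == 0) return(empty)

  tss_gr <- GRanges(tss$chrom, IRanges(tss$tss, width = 1L))
  hits <- findOverlaps(tss_gr, catalog, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  hdf <- data.frame(q = queryHits(hits), s = subjectHits(hits))
  hdf <- hdf[order(hdf$q, start(catalog)[hdf$s]), , drop = FALSE]
  multi <- sum(duplicated(hdf$q))
  if (multi > 0) {
    message(sprintf("call_tcgts: %d TSS hit overlapping loci; assigned to the leftmost locus",
                    multi))
  }
  hdf <- hdf[!duplicated(hdf$q), , drop = FALSE]
  tss$driver_locus_id <- NA_character_
  tss$driver_subfamily <- NA_character_
  tss$driver_locus_id[hdf$q] <- mcols(catalog)$locus_id[hdf$s]
  tss$driver_subfamily[hdf$q] <- mcols(catalog)$subfamily[hdf$s]

  cand <- tss[!is.na(tss$driver_locus_id) & tss$n_exons >= 2L, ,
              drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  # downstream-of-junction exons: every exon except the 5'-most one
  ex <- transcripts[transcripts$transcript_id %in% cand$transcript_id, ,
                    drop = FALSE]
  sp <- split(seq_len(nrow(ex)), ex$transcript_id)
  dn_idx <- unlist(lapply(sp, function(idx) {
    e <- ex[idx, , drop = FALSE]
    if (e$strand[1L] == "-") idx[-which.max(e$end)] else idx[-which.min(e$start)]
  }), use.names = FALSE)
  dn <- ex[dn_idx, , drop = FALSE]
  dn_gr <- GRanges(dn$chrom, IRanges(dn$start, dn$end))
  gh <- findOverlaps(dn_gr, genes_gr, ignore.strand = TRUE)
  if (length(gh) == 0) return(empty)
  ov <- width(pintersect(dn_gr[queryHits(gh)], genes_gr[subjectHits(gh)],
                         ignore.strand = TRUE))
  odf <- data.frame(transcript_id = dn$transcript_id[queryHits(gh)],
                    gene_id = mcols(genes_gr)$gene_id[subjectHits(gh)],
                    ov = ov, stringsAsFactors = FALSE)
  agg <- aggregate(ov ~ transcript_id + gene_id, data = odf, FUN = sum)
  agg <- agg[order(agg$transcript_id, -agg$ov, agg$gene_id), , drop = FALSE]
  best <- agg[!duplicated(agg$transcript_id), , drop = FALSE]

  out <- merge(cand, best[, c("transcript_id", "gene_id")],
               by = "transcript_id")
  out <- out[, c("transcript_id", "sample_id", "chrom", "strand", "tss",
                 "driver_locus_id", "driver_subfamily", "gene_id")]
  out <- out[order(out$chrom, out$tss, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_exon_granges <- function(genes) {
  if (is(genes, "GRanges")) {
    if (is.null(mcols(genes)$gene_id)) stop("genes GRanges needs a gene_id column")
    return(genes)
  }
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% names(genes))) {
    stop("genes table needs columns chrom, start, end, gene_id")
  }
  gr <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                strand = if ("strand" %in% names(genes)) genes$strand else "*")
  mcols(gr)$gene_id <- as.character(genes$gene_id)
  gr
}

#' Aggregate TcGT calls by TSS proximity
#'
#' Within each (gene, driver subfamily) pair, TSS positions are chained by
#' single linkage: two calls belong to the same aggregate when their TSSs lie
#' within `window` bp of each other, directly or through intermediate calls.
#' The representative TSS is the 5'-most member (strand-aware).
#'
#' @param tcgts TcGT call table from [call_tcgts()].
#' @param window Chaining distance in bp (default 100).
#' @return A data.frame with one row per aggregate: `aggregate_id`,
#'   `gene_id`, `subfamily`, `strand`, `representative_tss`, `n_members`,
#'   and list columns `member_tss`, `member_samples`, `member_loci`.
#' @export
aggregate_tcgts <- function(tcgts, window = 100) {
  cols <- c("aggregate_id", "gene_id", "subfamily", "strand",
            "representative_tss", "n_members")
  if (nrow(tcgts) == 0) {
    out <- data.frame(aggregate_id = character(), gene_id = character(),
                      subfamily = character(), strand = character(),
                      representative_tss = integer(), n_members = integer(),
                      stringsAsFactors = FALSE)
    out$member_tss <- list(); out$member_samples <- list()
    out$member_loci <- list()
    return(out)
  }
  key <- paste(tcgts$gene_id, tcgts$driver_subfamily, sep = "\r")
  rows <- lapply(split(seq_len(nrow(tcgts)), key), function(idx) {
    sub <- tcgts[idx, , drop = FALSE]
    o <- order(sub$tss)
    sub <- sub[o, , drop = FALSE]
    chain <- cumsum(c(1L, as.integer(diff(sub$tss) > window)))
    lapply(split(seq_len(nrow(sub)), chain), function(m) {
      mem <- sub[m, , drop = FALSE]
      st <- mem$strand[1L]
      rep_tss <- if (st == "-") max(mem$tss) else min(mem$tss)
      df <- data.frame(aggregate_id = sprintf("%s|%s|%d", mem$gene_id[1L],
                                              mem$driver_subfamily[1L],
                                              rep_tss),
                       gene_id = mem$gene_id[1L],
                       subfamily = mem$driver_subfamily[1L],
                       strand = st, representative_tss = rep_tss,
                       n_members = nrow(mem), stringsAsFactors = FALSE)
      df$member_tss <- list(mem$tss)
      df$member_samples <- list(mem$sample_id)
      df$member_loci <- list(mem$driver_locus_id)
      df
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  out <- out[order(out$gene_id, out$subfamily, out$representative_tss), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-subfamily hypergeometric enrichment of TcGT drivers
#'
#' For each sample group and TE subfamily, tests whether the distinct driver
#' loci observed in that group over-represent the subfamily relative to the
#' catalog universe. With `k` distinct driver loci of the subfamily in the
#' group, `K` catalog loci of the subfamily, `n` distinct driver loci of any
#' subfamily in the group and `N` catalog loci in total, the p-value is
#' [hypergeom_sf()]`(k, K, n, N)`; adjustment is Benjamini-Hochberg across
#' subfamilies within each group.
#'
#' @param aggregates Aggregate table from [aggregate_tcgts()].
#' @param catalog The `GRanges` catalog defining the background universe
#'   (typically restricted to LTR-class loci).
#' @param groups Named character vector mapping `sample_id` to group, or a
#'   data.frame with columns `sample_id` and `group`.
#' @return A data.frame with `group`, `subfamily`, `tcgt_count` (aggregates
#'   with at least one member in the group), `n_driver_loci`, `p`, `padj`,
#'   ordered by group then adjusted p-value.
#' @export
tcgt_enrichment_table <- function(aggregates, catalog, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group),
                       as.character(groups$sample_id))
  }
  subfams <- sort(unique(mcols(catalog)$subfamily))
  K <- table(factor(mcols(catalog)$subfamily, levels = subfams))
  N <- length(catalog)
  mem <- if (nrow(aggregates) > 0) {
    data.frame(
      aggregate_id = rep(aggregates$aggregate_id,
                         lengths(aggregates$member_samples)),
      subfamily = rep(aggregates$subfamily,
                      lengths(aggregates$member_samples)),
      sample_id = unlist(aggregates$member_samples),
      locus = unlist(aggregates$member_loci),
      stringsAsFactors = FALSE)
  } else {
    data.frame(aggregate_id = character(), subfamily = character(),
               sample_id = character(), locus = character(),
               stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(mem$sample_id), names(groups))
  if (length(unknown)) {
    stop("samples without a group assignment: ",
         paste(unknown, collapse = ", "))
  }
  mem$group <- unname(groups[mem$sample_id])
  out <- do.call(rbind, lapply(sort(unique(unname(groups))), function(g) {
    mg <- mem[mem$group == g, , drop = FALSE]
    n <- length(unique(mg$locus))
    k <- vapply(subfams, function(s)
      length(unique(mg$locus[mg$subfamily == s])), 1L)
    cnt <- vapply(subfams, function(s)
      length(unique(mg$aggregate_id[mg$subfamily == s])), 1L)
    p <- vapply(seq_along(subfams), function(i)
      hypergeom_sf(k[i], as.integer(K[i]), n, N), 1)
    data.frame(group = g, subfamily = subfams, tcgt_count = cnt,
               n_driver_loci = k, p = p,
               padj = unname(bh_adjust(p)), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  out <- out[order(out$group, out$padj, out$subfamily), , drop = FALSE]
  rownames(out) <- NULL
  out
}
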