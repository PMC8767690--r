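#' Construct a TE catalog
#'
#' Builds the in-memory representation of a curated transposable-element
#' annotation: a [GenomicRanges::GRanges] (1-based, closed intervals, the
#' GRanges convention) with metadata columns `locus_id`, `subfamily`,
#' `family`, `class`, `linkage_id` (RepeatMasker integrant id, `NA` when
#' absent), `is_solo_ltr` and `merged_from` (comma-separated ids of the
#' source records a locus was merged from). Converters to and from the
#' 0-based half-open disk formats live in the readers/writers.
#'
#' @param chrom,start,end,strand Locus coordinates (1-based closed) and
#'   strand (`"+"`/`"-"`).
#' @param subfamily,family,class Repeat taxonomy labels (e.g. `LTR12C`,
#'   `ERV9`, `LTR`).
#' @param locus_id Unique locus identifiers; autogenerated when `NULL`.
#' @param linkage_id Optional integrant linkage ids tying fragments of one
#'   insertion together.
#' @param is_solo_ltr Logical solo-LTR flags.
#' @param merged_from Comma-separated source record ids; defaults to the
#'   locus id itself.
#' @return A `GRanges` catalog.
#' @export
te_catalog <- function(chrom, start, end, strand, subfamily, family, class,
                       locus_id = NULL, linkage_id = NA_character_,
                       is_solo_ltr = FALSE, merged_from = NULL) {
  n <- length(chrom)
  if (is.null(locus_id)) locus_id <- sprintf("te_%05d", seq_len(n))
  if (is.null(merged_from)) merged_from <- locus_id
  linkage_id <- rep(as.character(linkage_id), length.out = n)
  is_solo_ltr <- rep(as.logical(is_solo_ltr), length.out = n)
  if (any(start > end)) {
    bad <- which(start > end)[1L]
    stop(sprintf("locus %s has start > end (%d > %d)",
                 locus_id[bad], start[bad], end[bad]))
  }
  if (anyDuplicated(locus_id)) {
    stop("locus_id values must be unique within a catalog: ",
         paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "))
  }
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  mcols(gr) <- DataFrame(
    locus_id = as.character(locus_id),
    subfamily = as.character(subfamily),
    family = as.character(family),
    class = as.character(class),
    linkage_id = as.character(linkage_id),
    is_solo_ltr = as.logical(is_solo_ltr),
    merged_from = as.character(merged_from))
  sort(gr, ignore.strand = TRUE)
}

.catalog_df <- function(catalog) {
  data.frame(chrom = as.character(seqnames(catalog)),
             start = start(catalog), end = end(catalog),
             strand = as.character(strand(catalog)),
             as.data.frame(mcols(catalog)),
             stringsAsFactors = FALSE)
}

.catalog_from_df <- function(df) {
  te_catalog(df$chrom, df$start, df$end, df$strand, df$subfamily, df$family,
             df$class, df$locus_id, df$linkage_id, df$is_solo_ltr,
             df$merged_from)
}

#' Parse a TE annotation file
#'
#' Reads RepeatMasker `.out` text or a BED6+ table into a TE catalog.
#'
#' @param path Path to the annotation file.
#' @param dialect `"rmsk_out"` (15-column RepeatMasker output, 1-based
#'   inclusive coordinates) or `"bed"` (0-based half-open).
#' @return A `GRanges` catalog (see [te_catalog()]).
#' @export
parse_te_annotation <- function(path, dialect = c("rmsk_out", "bed")) {
  dialect <- match.arg(dialect)
  switch(dialect, rmsk_out = read_rmsk_out(path), bed = read_catalog_bed(path))
}

#' Read RepeatMasker .out annotation
#'
#' Parses the classic 15-column RepeatMasker output. Coordinates are 1-based
#' inclusive on disk and are kept as-is internally (GRanges convention).
#' Column 11 (`class/family`) is split into class and family; the integrant
#' id in column 15 is captured as `linkage_id`.
#'
#' @param path Path to the `.out` file.
#' @return A `GRanges` catalog.
#' @export
read_rmsk_out <- function(path) {
  lines <- readLines(path)
  # drop the two header lines plus separator blank line, tolerating files
  # without them, and any other blank lines
  is_blank <- !nzchar(trimws(lines))
  first_tok <- vapply(strsplit(trimws(lines), "\\s+"),
                      function(x) if (length(x)) x[[1L]] else "", "")
  keep <- !is_blank & grepl("^[0-9]+$", first_tok)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(te_catalog(character(), integer(), integer(), character(),
                      character(), character(), character(),
                      locus_id = character(), merged_from = character()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14L)) {
    bad <- which(nf < 14L)[1L]
    stop(sprintf("malformed RepeatMasker line %d: expected >= 14 fields, got %d",
                 lineno[bad], nf[bad]))
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  chrom <- get(5L)
  start <- suppressWarnings(as.integer(get(6L)))
  end <- suppressWarnings(as.integer(get(7L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("malformed RepeatMasker line %d: non-numeric coordinates",
                 lineno[bad]))
  }
  strand <- ifelse(get(9L) == "C", "-", "+")
  subfamily <- get(10L)
  clsfam <- strsplit(get(11L), "/", fixed = TRUE)
  class <- vapply(clsfam, `[[`, "", 1L)
  family <- vapply(clsfam, function(x) if (length(x) > 1L) x[[2L]] else x[[1L]],
                   "")
  linkage <- ifelse(nf >= 15L,
                    vapply(seq_along(fields), function(i)
                      if (nf[i] >= 15L) fields[[i]][[15L]] else NA_character_,
                      ""),
                    NA_character_)
  linkage[linkage %in% c("*", ".")] <- NA_character_
  te_catalog(chrom, start, end, strand, subfamily, family, class,
             locus_id = sprintf("rmsk_%05d", seq_along(chrom)),
             linkage_id = linkage)
}

#' Read a catalog BED/TSV
#'
#' Reads the catalog format written by [write_catalog_bed()]: a tab-separated
#' BED-style table (0-based half-open starts on disk) with columns `chrom`,
#' `start`, `end`, `locus_id`, `score`, `strand`, `subfamily`, `family`,
#' `class` and optionally `linkage_id`, `is_solo_ltr`, `merged_from`.
#' A plain header line starting with `chrom` is accepted and skipped.
#'
#' @param path Path to the file.
#' @return A `GRanges` catalog.
#' @export
read_catalog_bed <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L && grepl("^#?chrom\\b", first)
  df <- tryCatch(
    read.table(path, sep = "\t", header = has_header,
               stringsAsFactors = FALSE, quote = "", comment.char = ""),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 6L) {
    if (ncol(df) < 6L && nrow(df) > 0)
      stop("catalog BED needs at least 6 columns, got ", ncol(df))
    return(te_catalog(character(), integer(), integer(), character(),
                      character(), character(), character(),
                      locus_id = character(), merged_from = character()))
  }
  cn <- c("chrom", "start", "end", "locus_id", "score", "strand",
          "subfamily", "family", "class", "linkage_id", "is_solo_ltr",
          "merged_from")
  names(df) <- cn[seq_len(min(ncol(df), length(cn)))]
  if (ncol(df) < 9L) stop("catalog BED needs subfamily/family/class in columns 7-9")
  linkage <- if ("linkage_id" %in% names(df)) as.character(df$linkage_id)
             else NA_character_
  linkage[linkage %in% c(".", "")] <- NA_character_
  solo <- if ("is_solo_ltr" %in% names(df)) as.logical(df$is_solo_ltr) else FALSE
  merged <- if ("merged_from" %in% names(df)) as.character(df$merged_from)
            else NULL
  te_catalog(df$chrom, df$start + 1L, df$end, df$strand, df$subfamily,
             df$family, df$class, locus_id = as.character(df$locus_id),
             linkage_id = linkage, is_solo_ltr = solo, merged_from = merged)
}

#' Write a catalog BED/TSV
#'
#' Writes the catalog in the tab-separated BED-style layout read back by
#' [read_catalog_bed()] (starts converted to 0-based half-open on disk).
#'
#' @param catalog A `GRanges` catalog.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_catalog_bed <- function(catalog, path) {
  df <- .catalog_df(catalog)
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    locus_id = df$locus_id, score = 0L, strand = df$strand,
                    subfamily = df$subfamily, family = df$family,
                    class = df$class,
                    linkage_id = ifelse(is.na(df$linkage_id), ".",
                                        df$linkage_id),
                    is_solo_ltr = df$is_solo_ltr,
                    merged_from = df$merged_from,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  list(find = find, union = union,
       roots = function() vapply(seq_len(n), find, 1L))
}

#' Reassemble fragmented TE records
#'
#' Records that share a `linkage_id`, or that belong to the same chromosome,
#' strand and subfamily and lie within `max_gap` bp of each other, are merged
#' into a single locus spanning from the leftmost start to the rightmost end.
#' The merged locus lists all source ids in `merged_from`; when all members
#' share one linkage id the merged locus takes that id as its `locus_id`,
#' otherwise the leftmost member's id. Merging is idempotent.
#'
#' @param catalog A `GRanges` catalog.
#' @param max_gap Maximum gap (bp) bridged between same-subfamily fragments.
#' @return A merged `GRanges` catalog.
#' @export
merge_fragments <- function(catalog, max_gap = 100) {
  if (length(catalog) == 0) return(catalog)
  df <- .catalog_df(catalog)
  key <- paste(df$chrom, df$strand, df$subfamily, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    o <- order(sub$start, sub$end)
    sub <- sub[o, , drop = FALSE]
    n <- nrow(sub)
    if (n == 1L) return(sub)
    uf <- .union_find(n)
    gaps <- sub$start[-1L] - sub$end[-n] - 1L
    for (i in which(gaps <= max_gap)) uf$union(i, i + 1L)
    lk <- sub$linkage_id
    for (v in unique(lk[!is.na(lk)])) {
      members <- which(!is.na(lk) & lk == v)
      if (length(members) > 1L) {
        for (m in members[-1L]) uf$union(members[1L], m)
      }
    }
    comp <- uf$roots()
    do.call(rbind, lapply(split(seq_len(n), comp), function(m) {
      if (length(m) == 1L) return(sub[m, , drop = FALSE])
      mem <- sub[m, , drop = FALSE]
      lks <- unique(mem$linkage_id[!is.na(mem$linkage_id)])
      rec <- mem[1L, , drop = FALSE]
      rec$start <- min(mem$start)
      rec$end <- max(mem$end)
      rec$locus_id <- if (length(lks) == 1L) lks else mem$locus_id[1L]
      rec$linkage_id <- if (length(lks) == 1L) lks else NA_character_
      rec$merged_from <- paste(unlist(strsplit(mem$merged_from, ",")),
                               collapse = ",")
      rec
    }))
  })
  .catalog_from_df(do.call(rbind, pieces))
}

.is_internal_subfamily <- function(subfamily, ltr_int_pairs) {
  subfamily %in% unname(ltr_int_pairs) | grepl("-int$", subfamily)
}

#' Merge LTRs with adjacent internal segments into full-length ERVs
#'
#' Runs of LTR - internal (- LTR) records on the same chromosome and strand,
#' adjacent within `max_gap` bp and paired through `ltr_int_pairs`, are merged
#' into a single full-length feature labeled by the internal segment's
#' subfamily and family. Every LTR-class record not merged with an internal
#' segment is flagged as a solo LTR (`is_solo_ltr = TRUE`); internal
#' segments, full-length features and non-LTR classes are not. An LTR
#' adjacent only to an internal subfamily it is not paired with is left
#' unmerged with a warning.
#'
#' @param catalog A `GRanges` catalog (fragments already reassembled).
#' @param ltr_int_pairs Named character vector mapping LTR subfamily to its
#'   internal subfamily, e.g. `c(LTR12C = "HERV9-int")`.
#' @param max_gap Maximum gap (bp) between an LTR and its internal segment.
#' @return A `GRanges` catalog with full-length ERVs merged and solo-LTR
#'   flags set.
#' @export
assemble_full_length_ervs <- function(catalog, ltr_int_pairs, max_gap = 500) {
  if (length(catalog) == 0) return(catalog)
  df <- .catalog_df(catalog)
  df$.internal <- .is_internal_subfamily(df$subfamily, ltr_int_pairs)
  n_unpaired <- 0L
  key <- paste(df$chrom, df$strand, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    o <- order(sub$start, sub$end)
    sub <- sub[o, , drop = FALSE]
    n <- nrow(sub)
    uf <- .union_find(n)
    internal_at <- rep(NA_character_, n)  # internal subfamily of the merge
    for (i in which(sub$.internal)) {
      for (j in c(i - 1L, i + 1L)) {
        if (j < 1L || j > n) next
        if (sub$.internal[j] || sub$class[j] != "LTR") next
        gap <- if (j < i) sub$start[i] - sub$end[j] - 1L
               else sub$start[j] - sub$end[i] - 1L
        if (gap > max_gap) next
        paired_int <- ltr_int_pairs[sub$subfamily[j]]
        if (!is.na(paired_int) && paired_int == sub$subfamily[i]) {
          uf$union(i, j)
        } else {
          n_unpaired <<- n_unpaired + 1L
        }
      }
    }
    comp <- uf$roots()
    do.call(rbind, lapply(split(seq_len(n), comp), function(m) {
      if (length(m) == 1L) return(sub[m, , drop = FALSE])
      mem <- sub[m, , drop = FALSE]
      int <- mem[mem$.internal, , drop = FALSE][1L, , drop = FALSE]
      rec <- int
      rec$start <- min(mem$start)
      rec$end <- max(mem$end)
      rec$merged_from <- paste(unlist(strsplit(mem$merged_from, ",")),
                               collapse = ",")
      rec$linkage_id <- NA_character_
      rec
    }))
  })
  out <- do.call(rbind, pieces)
  if (n_unpaired > 0) {
    warning(sprintf(
      "%d LTR record(s) adjacent to an internal subfamily they are not paired with were left unmerged",
      n_unpaired))
  }
  out$is_solo_ltr <- out$class == "LTR" & !out$.internal
  out$.internal <- NULL
  .catalog_from_df(out)
}

#' Remove TE loci overlapping exons
#'
#' Drops every catalog locus overlapping any exon by at least one base and
#' reports the number removed.
#'
#' @param catalog A `GRanges` catalog.
#' @param exons A `GRanges` of exons (strand ignored).
#' @return The filtered catalog.
#' @export
exclude_exon_overlaps <- function(catalog, exons) {
  if (length(catalog) == 0 || length(exons) == 0) return(catalog)
  hit <- overlapsAny(catalog, exons, ignore.strand = TRUE)
  if (any(hit)) {
    message(sprintf("exclude_exon_overlaps: removed %d of %d TE loci",
                    sum(hit), length(catalog)))
  }
  catalog[!hit]
}

#' Per-subfamily locus counts and genomic size
#'
#' @param catalog A `GRanges` catalog.
#' @return A data.frame with `subfamily`, `n_loci` and `total_bp` (summed
#'   locus lengths).
#' @export
subfamily_sizes <- function(catalog) {
  if (length(catalog) == 0) {
    return(data.frame(subfamily = character(), n_loci = integer(),
                      total_bp = integer(), stringsAsFactors = FALSE))
  }
  sf <- mcols(catalog)$subfamily
  w <- width(catalog)
  tab <- tapply(w, sf, function(x) c(n = length(x), bp = sum(x)))
  subs <- sort(names(tab))
  data.frame(subfamily = subs,
             n_loci = vapply(tab[subs], `[[`, 1, "n"),
             total_bp = vapply(tab[subs], `[[`, 1, "bp"),
             row.names = NULL, stringsAsFactors = FALSE)
}
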