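#' Drop low-count features
#'
#' Keeps a feature (row) when its count sum across all samples is at least
#' the number of samples.
#'
#' @param counts Integer count matrix (features x samples).
#' @return The filtered matrix.
#' @export
filter_low_counts <- function(counts) {
  counts <- as.matrix(counts)
  counts[rowSums(counts) >= ncol(counts), , drop = FALSE]
}

#' TMM normalization with gene counts as library size
#'
#' Computes trimmed-mean-of-M-values scaling factors on the gene rows only
#' (log-ratio trim 30%, intensity trim 5%, inverse-variance weighting,
#' reference sample chosen by upper quartile closest to the mean upper
#' quartile; factors renormalized to unit geometric mean), with per-sample
#' library sizes taken as the gene count sums. All rows — genes and TE
#' loci — are then rescaled to counts per million of the effective
#' (factor-adjusted) gene library.
#'
#' @param counts Count matrix (features x samples), genes and TE loci mixed.
#' @param feature_kind Character vector parallel to rows, `"gene"` or
#'   `"te_locus"`.
#' @return A list with `matrix` (normalized CPM), `factors` (per-sample TMM
#'   factors), `lib_size` (gene-count library sizes) and `feature_kind`.
#' @export
tmm_normalize <- function(counts, feature_kind) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("tmm_normalize needs at least 2 samples")
  if (length(feature_kind) != nrow(counts)) {
    stop("feature_kind must parallel the rows of counts")
  }
  gene_rows <- feature_kind == "gene"
  if (!any(gene_rows)) stop("no gene rows present; TMM library sizes are gene count sums")
  g <- counts[gene_rows, , drop = FALSE]
  lib <- colSums(g)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero gene counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(g, lib.size = lib, method = "TMM")
  eff <- lib * f
  norm <- sweep(counts, 2, eff / 1e6, "/")
  list(matrix = norm, factors = setNames(f, colnames(counts)),
       lib_size = setNames(lib, colnames(counts)),
       feature_kind = feature_kind)
}

#' Row-wise z-scores
#'
#' Centers and scales each row by its mean and sample standard deviation
#' (n - 1 denominator). Constant rows become all-zero and are reported.
#'
#' @param m Numeric matrix.
#' @return Matrix of z-scores, with attribute `constant_rows` naming rows
#'   with zero variance.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("zscore_rows needs at least 2 samples")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  const <- s == 0 | is.na(s)
  s[const] <- 1
  z <- (m - mu) / s
  z[const, ] <- 0
  if (any(const)) {
    message(sprintf("zscore_rows: %d constant row(s) set to zero", sum(const)))
  }
  attr(z, "constant_rows") <- rownames(m)[const]
  z
}

#' Cluster TE loci by expression pattern
#'
#' Hierarchical agglomerative clustering of z-scored rows with distance
#' 1 - Pearson correlation and complete linkage, cut into `k` groups —
#' the standard temporal-pattern clustering that separates maternal-style
#' (high early, off after cleavage) from ZGA-style (off early, on from the
#' 8-cell stage) profiles at `k = 2`. Rows with zero variance cannot enter
#' the correlation distance; they are assigned after cutting to the cluster
#' with the nearest (Euclidean) centroid and reported in `flagged`.
#'
#' @param z Z-score matrix (loci x samples), e.g. from [zscore_rows()].
#' @param k Number of clusters (default 2).
#' @return A list with `clusters` (named integer vector of labels in
#'   `1..k`), `zscores` (the input), `tree` (the `hclust` object over the
#'   variable rows) and `flagged` (zero-variance row names).
#' @export
cluster_loci <- function(z, k = 2) {
  z <- as.matrix(z)
  if (nrow(z) < k) stop("need at least k rows to form k clusters")
  s <- apply(z, 1L, sd)
  variable <- s > 0 & !is.na(s)
  zv <- z[variable, , drop = FALSE]
  if (nrow(zv) < k) stop("fewer variable rows than clusters")
  d <- as.dist(1 - cor(t(zv)))
  tree <- hclust(d, method = "complete")
  cl <- cutree(tree, k = k)
  clusters <- setNames(rep(NA_integer_, nrow(z)), rownames(z))
  clusters[rownames(zv)] <- cl
  flagged <- rownames(z)[!variable]
  if (length(flagged)) {
    centroids <- vapply(seq_len(k), function(g)
      colMeans(zv[cl == g, , drop = FALSE]), numeric(ncol(z)))
    for (r in flagged) {
      dd <- colSums((centroids - z[r, ])^2)
      clusters[r] <- which.min(dd)
    }
    message(sprintf("cluster_loci: %d zero-variance row(s) assigned to nearest centroid",
                    length(flagged)))
  }
  list(clusters = clusters, zscores = z, tree = tree, flagged = flagged)
}

#' Sum locus counts per TE subfamily
#'
#' Sums the counts of all member loci of each subfamily, per sample, without
#' any filtering.
#'
#' @param counts Count matrix of TE loci (rows named by locus id).
#' @param membership Named character vector mapping locus id to subfamily.
#' @return A count matrix with one row per subfamily.
#' @export
sum_by_subfamily <- function(counts, membership) {
  counts <- as.matrix(counts)
  unmapped <- setdiff(rownames(counts), names(membership))
  if (length(unmapped)) {
    stop("loci without subfamily membership: ",
         paste(head(unmapped, 10), collapse = ", "))
  }
  rowsum(counts, group = unname(membership[rownames(counts)]))
}

#' Threshold a differential-expression table
#'
#' Generic fold-change / adjusted-p filter over an externally computed
#' statistics table: a feature passes when its absolute fold change exceeds
#' `fc_threshold` and its adjusted p-value is below `padj_threshold`.
#'
#' @param tab Data.frame with columns `log2fc` and `padj`.
#' @param fc_threshold Fold-change threshold on the linear scale (default 2).
#' @param padj_threshold Adjusted p-value threshold (default 0.05).
#' @return The rows of `tab` passing both thresholds.
#' @export
filter_differential <- function(tab, fc_threshold = 2, padj_threshold = 0.05) {
  if (!all(c("log2fc", "padj") %in% names(tab))) {
    stop("tab needs columns log2fc and padj")
  }
  tab[abs(tab$log2fc) > log2(fc_threshold) & tab$padj < padj_threshold, ,
      drop = FALSE]
}

#' Read a count matrix TSV
#'
#' Reads the layout written by [write_count_matrix()]: a header of sample
#' ids, a `feature_id` column and a `feature_kind` column.
#'
#' @param path Path to the TSV.
#' @return A list with `counts` (matrix) and `feature_kind`.
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(c("feature_id", "feature_kind") %in% names(df))) {
    stop("count matrix TSV needs feature_id and feature_kind columns")
  }
  m <- as.matrix(df[, setdiff(names(df), c("feature_id", "feature_kind")),
                    drop = FALSE])
  rownames(m) <- df$feature_id
  list(counts = m, feature_kind = df$feature_kind)
}

#' Write a count matrix TSV
#'
#' @param counts Count matrix with row and column names.
#' @param feature_kind Character vector parallel to rows.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(counts, feature_kind, path) {
  df <- data.frame(feature_id = rownames(counts),
                   feature_kind = feature_kind,
                   as.data.frame(counts, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
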