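#' Read a gapped FASTA alignment
#'
#' @param path Path to a FASTA of aligned (gapped) sequences.
#' @return A named character vector of equal-length gapped sequences.
#' @export
read_gapped_fasta <- function(path) {
  x <- readBStringSet(path)
  aln <- setNames(as.character(x), names(x))
  .validate_alignment(aln)
  aln
}

#' Write a gapped FASTA alignment
#'
#' @param aln Named character vector of gapped sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gapped_fasta <- function(aln, path) {
  writeXStringSet(BStringSet(aln), path)
  invisible(path)
}

.validate_alignment <- function(aln) {
  if (length(aln) == 0) stop("alignment has no rows")
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment rows differ in length")
  invisible(aln)
}

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
}

#' Trim gap-dense alignment columns
#'
#' Removes every column whose gap fraction strictly exceeds `max_gap_frac`
#' (so a column with exactly the threshold fraction of gaps is kept,
#' matching a "more than 85% gaps" trimming rule at the default).
#'
#' @param aln Named character vector of gapped sequences.
#' @param max_gap_frac Maximum tolerated gap fraction per column.
#' @return A list with `alignment` (trimmed) and `kept_columns` (original
#'   1-based positions of the retained columns).
#' @export
trim_gap_columns <- function(aln, max_gap_frac = 0.85) {
  .validate_alignment(aln)
  m <- .aln_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= max_gap_frac)
  trimmed <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  list(alignment = setNames(as.character(trimmed), names(aln)),
       kept_columns = keep)
}

#' Min-max scale a signal track to [0, 1]
#'
#' @param x Numeric signal values along the ungapped bases of one locus.
#' @return The scaled track; a constant track maps to all zeros and carries
#'   attribute `constant = TRUE`.
#' @export
scale_track <- function(x) {
  if (length(x) == 0) stop("track must be non-empty")
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    out <- rep(0, length(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Project a per-base track onto alignment columns
#'
#' The i-th non-gap column of the row carries the i-th track value; gap
#' columns carry `NA`.
#'
#' @param row A single gapped sequence.
#' @param track Numeric vector, one value per ungapped base of `row`.
#' @param locus_id Optional label used in error messages.
#' @return Numeric vector of length `nchar(row)` with `NA` at gaps.
#' @export
project_track <- function(row, track, locus_id = "<row>") {
  chars <- strsplit(row, "", fixed = TRUE)[[1L]]
  nongap <- chars != "-"
  if (sum(nongap) != length(track)) {
    stop(sprintf("track length (%d) does not match ungapped length (%d) for %s",
                 length(track), sum(nongap), locus_id))
  }
  out <- rep(NA_real_, length(chars))
  out[nongap] <- track
  out
}

#' Column-mean signal profile across projected tracks
#'
#' Averages projected tracks column by column over the non-missing values;
#' columns covered by no track report `NA`.
#'
#' @param tracks A list of equal-length numeric vectors (projected tracks)
#'   or a matrix with one track per row.
#' @return A data.frame with `column`, `mean` and `coverage` (number of
#'   non-missing values per column).
#' @export
mean_profile <- function(tracks) {
  m <- if (is.matrix(tracks)) tracks else {
    if (length(tracks) == 0) stop("need at least one track")
    L <- unique(lengths(tracks))
    if (length(L) != 1L) stop("projected tracks differ in length")
    do.call(rbind, tracks)
  }
  coverage <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  mu[coverage == 0] <- NA_real_
  data.frame(column = seq_len(ncol(m)), mean = mu, coverage = coverage,
             row.names = NULL)
}
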