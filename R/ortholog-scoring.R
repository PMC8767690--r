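#' Alignment-coverage similarity of a syntenic TE locus
#'
#' Similarity between a human TE locus and its syntenic counterpart in
#' another species: the number of human bases covered by the pairwise
#' alignment (point substitutions ignored) divided by the length of the
#' subfamily consensus, capped at 1. Normalizing by the consensus rather
#' than the locus keeps truncated integrants from scoring as fully
#' conserved.
#'
#' @param human_len Length of the human locus (bp).
#' @param aligned_bp Human bases covered by the alignment.
#' @param consensus_len Length of the subfamily consensus (bp).
#' @return Similarity fraction in \[0, 1\].
#' @export
alignment_coverage_score <- function(human_len, aligned_bp, consensus_len) {
  if (!is.numeric(consensus_len) || consensus_len <= 0) {
    stop("consensus_len must be positive, got ", format(consensus_len))
  }
  if (aligned_bp < 0 || aligned_bp > human_len) {
    stop(sprintf("aligned_bp (%s) must lie in [0, human_len = %s]",
                 format(aligned_bp), format(human_len)))
  }
  min(1, aligned_bp / consensus_len)
}

#' Classify a syntenic locus by annotation agreement
#'
#' @param lifted Whether a syntenic locus exists in the foreign genome.
#' @param annotation Foreign repeat label, or `NA`/empty when the syntenic
#'   sequence carries no repeat annotation.
#' @param human_subfamily Subfamily of the human locus.
#' @param family_map Named character vector mapping subfamily to family.
#' @return One of `"not_detected"`, `"detected_same_subfamily"`,
#'   `"detected_same_family"`, `"detected_unannotated"` (the last also
#'   covers annotations outside the human element's family).
#' @export
classify_ortholog <- function(lifted, annotation, human_subfamily,
                              family_map) {
  if (!human_subfamily %in% names(family_map)) {
    stop("human subfamily absent from family_map: ", human_subfamily)
  }
  if (!isTRUE(lifted)) return("not_detected")
  if (is.na(annotation) || !nzchar(annotation)) return("detected_unannotated")
  if (annotation == human_subfamily) return("detected_same_subfamily")
  if (annotation %in% names(family_map) &&
      family_map[[annotation]] == family_map[[human_subfamily]]) {
    return("detected_same_family")
  }
  "detected_unannotated"
}

#' Score a synteny table into ortholog hits
#'
#' Applies [classify_ortholog()] and [alignment_coverage_score()] row-wise
#' to a synteny table; undetected loci are forced to similarity 0.
#'
#' @param synteny Data.frame with `human_locus_id`, `species`, `lifted`
#'   (logical), `foreign_label`, `aligned_bp`, `human_len`, `subfamily`.
#' @param consensus_lengths Named numeric vector, consensus length per
#'   subfamily.
#' @param family_map Named character vector mapping subfamily to family.
#' @return The input with `status` and `similarity` columns appended.
#' @export
ortholog_hit_table <- function(synteny, consensus_lengths, family_map) {
  miss <- setdiff(unique(synteny$subfamily), names(consensus_lengths))
  if (length(miss)) {
    stop("subfamilies without a consensus length: ",
         paste(miss, collapse = ", "))
  }
  synteny$status <- vapply(seq_len(nrow(synteny)), function(i)
    classify_ortholog(synteny$lifted[i], synteny$foreign_label[i],
                      synteny$subfamily[i], family_map), "")
  synteny$similarity <- vapply(seq_len(nrow(synteny)), function(i) {
    if (synteny$status[i] == "not_detected") return(0)
    alignment_coverage_score(synteny$human_len[i], synteny$aligned_bp[i],
                             consensus_lengths[[synteny$subfamily[i]]])
  }, 1)
  synteny
}

.validate_fingerprint <- function(fp, what) {
  if (length(fp) == 0) stop(what, " must have at least one finger")
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]{4}$", fp)
  if (!all(ok)) {
    stop(sprintf("%s has malformed finger(s): %s (need exactly 4 amino-acid residues)",
                 what, paste(fp[!ok], collapse = ", ")))
  }
  invisible(fp)
}

#' Zinc-fingerprint similarity between two KZFPs
#'
#' Compares the ordered DNA-contacting residue quadruplets (positions -1, 2,
#' 3 and 6 of each zinc finger) of two KRAB zinc finger proteins. Fingers
#' are aligned globally by dynamic programming: aligning two fingers scores
#' the fraction of identical residues (0..1), skipping a finger costs
#' `gap_penalty`. The optimal alignment score is normalized by the larger
#' finger count and clamped to \[0, 1\]. This declared scoring rule is a
#' documented stand-in for proprietary fingerprint scorers and is
#' deterministic and symmetric.
#'
#' @param a,b Character vectors of 4-residue finger strings.
#' @param gap_penalty Cost of skipping one finger (default 0.25).
#' @return Similarity score in \[0, 1\]; 1 iff the fingerprints are
#'   identical.
#' @export
fingerprint_similarity <- function(a, b, gap_penalty = 0.25) {
  .validate_fingerprint(a, "a")
  .validate_fingerprint(b, "b")
  na <- length(a); nb <- length(b)
  ca <- strsplit(a, "", fixed = TRUE)
  cb <- strsplit(b, "", fixed = TRUE)
  m <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) m[i, j] <- mean(ca[[i]] == cb[[j]])
  }
  S <- matrix(0, na + 1L, nb + 1L)
  S[, 1L] <- -gap_penalty * (0:na)
  S[1L, ] <- -gap_penalty * (0:nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + m[i, j],
                               S[i, j + 1L] - gap_penalty,
                               S[i + 1L, j] - gap_penalty)
    }
  }
  min(1, max(0, S[na + 1L, nb + 1L] / max(na, nb)))
}

#' Most similar fingerprint among candidates
#'
#' Scores a query fingerprint against every candidate with
#' [fingerprint_similarity()] and returns the best, breaking ties by the
#' lexicographically smallest candidate id (flagged in the result).
#'
#' @param query Character vector of finger strings.
#' @param candidates Named list of candidate fingerprints.
#' @return A list with `id`, `score`, `tie` (logical) and `scores` (all
#'   candidate scores).
#' @export
best_ortholog <- function(query, candidates) {
  if (length(candidates) == 0) stop("candidate list must be non-empty")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    stop("candidates must be named")
  }
  scores <- vapply(candidates, function(cand)
    fingerprint_similarity(query, cand), 1)
  top <- max(scores)
  winners <- sort(names(scores)[scores == top])
  list(id = winners[1L], score = unname(top), tie = length(winners) > 1L,
       scores = scores)
}
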