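#' Upper-tail hypergeometric probability
#'
#' Exact probability \eqn{P(X \ge k)} of drawing at least `k` successes in a
#' sample of size `n` taken without replacement from a population of size `N`
#' containing `K` successes. This is the one-sided ("greater") enrichment
#' p-value used for TcGT subfamily enrichment.
#'
#' @param k Observed number of successes in the sample.
#' @param K Number of successes in the population.
#' @param n Sample size.
#' @param N Population size.
#' @return A single probability in \[0, 1\].
#' @examples
#' hypergeom_sf(3, 4, 3, 10)  # 4/120
#' @export
hypergeom_sf <- function(k, K, n, N) {
  .check_count(k, "k"); .check_count(K, "K")
  .check_count(n, "n"); .check_count(N, "N")
  if (K > N || n > N || k > min(K, n)) {
    stop(sprintf(
      "invalid hypergeometric parameters: k=%d, K=%d, n=%d, N=%d (need k <= min(K, n), n <= N, K <= N)",
      k, K, n, N))
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Upper-tail binomial probability
#'
#' One-sided \eqn{P(X \ge k)} for `k` successes in `n` Bernoulli trials with
#' success probability `p0`. Used for genomic-size-corrected TE subfamily
#' enrichment of ChIP peaks.
#'
#' @param k Observed successes.
#' @param n Number of trials.
#' @param p0 Null success probability in \[0, 1\].
#' @return A single probability.
#' @examples
#' binom_sf(5, 5, 0.5)  # 0.5^5
#' @export
binom_sf <- function(k, n, p0) {
  .check_count(k, "k"); .check_count(n, "n")
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 < 0 || p0 > 1) {
    stop(sprintf("p0 must be a probability in [0, 1], got %s", format(p0)))
  }
  if (k > n) stop(sprintf("k (%d) must not exceed n (%d)", k, n))
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value: the sum of the probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table.
#'
#' @param tab A 2x2 matrix of non-negative integer counts.
#' @return A single probability.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab) || !all(dim(tab) == c(2L, 2L))) {
    stop("tab must be a 2x2 matrix")
  }
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop(sprintf("all cells must be non-negative integers, got [%s]",
                 paste(tab, collapse = ", ")))
  }
  if (sum(tab) == 0) stop("at least one margin must be positive")
  fisher.test(tab)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1, with the input order
#' (and any labels) preserved.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @param labels Optional identifiers, used as names of the result.
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals, labels = NULL) {
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
      any(pvals < 0) || any(pvals > 1)) {
    stop("pvals must be probabilities in [0, 1] without NA")
  }
  if (!is.null(labels)) {
    if (length(labels) != length(pvals)) stop("labels must parallel pvals")
    if (anyDuplicated(labels)) stop("labels must be unique")
  }
  out <- p.adjust(pvals, method = "BH")
  if (!is.null(labels)) names(out) <- labels else names(out) <- names(pvals)
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney/Wilcoxon rank-sum comparison of two samples. The null
#' distribution is enumerated exactly when the pooled sample has at most 12
#' observations and no ties; otherwise the normal approximation with midranks,
#' tie correction and continuity correction is used. The branch taken is
#' reported in `method`.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A list with `statistic` (the Mann-Whitney U for `a`), `p.value`,
#'   and `method` (`"exact"` or `"normal_approximation"`).
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))
#' @export
ranksum_test <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) == 0 || length(b) == 0) {
    stop("a and b must be non-empty numeric vectors")
  }
  if (anyNA(a) || anyNA(b)) stop("a and b must not contain NA")
  ties <- anyDuplicated(c(a, b)) > 0L
  if (length(a) + length(b) <= 12L && !ties) {
    res <- wilcox.test(a, b, exact = TRUE)
    method <- "exact"
  } else {
    res <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    method <- "normal_approximation"
  }
  list(statistic = unname(res$statistic), p.value = res$p.value,
       method = method)
}

.check_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != round(x)) {
    stop(sprintf("%s must be a single non-negative integer, got %s",
                 what, format(x)))
  }
  invisible(TRUE)
}
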