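# Brute-force statistical oracles, kept independent of the package code
# paths they are used to check.

# P(X >= k) by exhaustive enumeration of all n-subsets of a 0/1 population
hyper_enum <- function(k, K, n, N) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  cmb <- utils::combn(N, n)
  succ <- colSums(matrix(pop[cmb], nrow = n))
  mean(succ >= k)
}

# two-sided Fisher p by enumerating all tables with the observed margins
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- sum(tab)
  a_range <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, a_range) * choose(r2, c1 - a_range) / choose(N, c1)
  p_obs <- prob[a_range == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# two-sided rank-sum p by enumerating all rank assignments (no ties)
ranksum_enum <- function(a, b) {
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  cmb <- utils::combn(N, m)
  u_null <- colSums(matrix(seq_len(N)[cmb], nrow = m)) - m * (m + 1) / 2
  ctr <- m * n / 2
  mean(abs(u_null - ctr) >= abs(u_obs - ctr))
}

# step-up BH by the hand formula
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# trimmed mean of M-values, evaluated from the published formula
tmm_oracle <- function(counts, lib) {
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]; rf <- counts[, ref]
    nO <- lib[i]; nR <- lib[ref]
    keep0 <- obs > 0 & rf > 0
    obs <- obs[keep0]; rf <- rf[keep0]
    M <- log2((obs / nO) / (rf / nR))
    A <- (log2(obs / nO) + log2(rf / nR)) / 2
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL &
      rank(A) >= loS & rank(A) <= hiS
    v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, 1)
  f / exp(mean(log(f)))
}

# quick non-overlapping toy catalog: one locus every `step` bp on one chrom
toy_catalog <- function(subfamilies, len = 500L, step = 5000L,
                        family = "FAM", class = "LTR", strand = "+") {
  n <- length(subfamilies)
  starts <- seq(10000L, by = step, length.out = n)
  te_catalog(chrom = rep("chr1", n), start = starts,
             end = starts + len - 1L, strand = strand,
             subfamily = subfamilies, family = family, class = class)
}
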