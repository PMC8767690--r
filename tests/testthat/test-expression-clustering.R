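test_that("low-count filter keeps rows with sum >= number of samples", {
  m <- matrix(c(1, 1, 0, 1, 1, 1, 2, 1, 1, 0, 0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("r", 1:4), paste0("s", 1:3)))
  kept <- filter_low_counts(m)
  expect_equal(rownames(kept), c("r2", "r3"))  # sums 2,3,4,0 vs 3 samples
  # single sample: a row with one read passes (1 >= 1)
  m1 <- matrix(1, 1, 1, dimnames = list("r", "s"))
  expect_equal(nrow(filter_low_counts(m1)), 1L)
})

test_that("TMM factors behave under library identity, scaling, and match the formula", {
  set.seed(5)
  g <- matrix(rnbinom(40, mu = 200, size = 10) + 1, ncol = 2,
              dimnames = list(paste0("g", 1:20), c("a", "b")))
  kind <- rep("gene", 20)
  # identical libraries
  ident <- tmm_normalize(cbind(a = g[, 1], b = g[, 1]), kind)
  expect_equal(unname(ident$factors), c(1, 1), tolerance = 1e-9)
  # doubled library: composition unchanged, depth absorbed by library size
  doub <- tmm_normalize(cbind(a = g[, 1], b = 2 * g[, 1]), kind)
  expect_equal(unname(doub$factors), c(1, 1), tolerance = 1e-9)
  expect_equal(doub$matrix[, "a"], doub$matrix[, "b"], tolerance = 1e-12)
  # factors are depth-compositional: rescaling one library moves them only
  # through the inverse-variance weights, i.e. marginally
  f1 <- tmm_normalize(g, kind)$factors
  f2 <- tmm_normalize(cbind(a = 3 * g[, 1], b = g[, 2]), kind)$factors
  expect_equal(unname(f1), unname(f2), tolerance = 0.01)
  # toy matrix vs an independent evaluation of the trimmed-mean formula
  toy <- matrix(c(100, 150, 220, 380, 500, 610, 700, 850,
                  400, 150, 230, 370, 520, 600, 720, 830),
                ncol = 2, dimnames = list(paste0("g", 1:8), c("a", "b")))
  norm <- tmm_normalize(toy, rep("gene", 8))
  expect_equal(unname(norm$factors),
               unname(tmm_oracle(toy, colSums(toy))), tolerance = 1e-6)
  # TE rows share the gene-derived scaling
  both <- rbind(toy, te1 = c(50, 50))
  nb <- tmm_normalize(both, c(rep("gene", 8), "te_locus"))
  expect_equal(unname(nb$factors), unname(norm$factors), tolerance = 1e-12)
  expect_error(tmm_normalize(cbind(a = c(0, 0), b = c(1, 2)),
                             rep("gene", 2)), "all-zero")
})

test_that("row z-scores use the sample sd and zero out constant rows", {
  z <- zscore_rows(matrix(c(2, 4, 6), 1, dimnames = list("r", NULL)))
  expect_equal(unname(z[1, ]), c(-1, 0, 1))  # sd with n-1 is 2
  zc <- suppressMessages(
    zscore_rows(matrix(5, 1, 3, dimnames = list("c", NULL))))
  expect_equal(unname(zc[1, ]), c(0, 0, 0))
  expect_equal(attr(zc, "constant_rows"), "c")
  # an already-standardized row is unchanged
  zz <- zscore_rows(matrix(c(-1, 0, 1), 1))
  expect_equal(unname(zz[1, ]), c(-1, 0, 1))
})

test_that("correlation-distance clustering recovers planted temporal patterns", {
  set.seed(21)
  tmpl_m <- c(1, 1, 0, 0, 0, 0)
  tmpl_z <- c(0, 0, 0, 0, 1, 1)
  z <- rbind(
    t(replicate(10, tmpl_m + rnorm(6, 0, 0.1))),
    t(replicate(10, tmpl_z + rnorm(6, 0, 0.1))))
  rownames(z) <- paste0("L", 1:20)
  cl <- cluster_loci(z, k = 2)
  truth <- rep(1:2, each = 10)
  expect_equal(rand_index(cl$clusters, truth), 1)
  # k equal to the number of rows yields singletons
  zs <- z[1:4, ] + matrix(rnorm(24, 0, 0.01), 4)
  expect_equal(sort(unname(cluster_loci(zs, k = 4)$clusters)), 1:4)
  # duplicated rows co-cluster (zero correlation distance)
  zd <- rbind(a = tmpl_m, b = tmpl_m, c = tmpl_z, d = tmpl_z)
  cld <- cluster_loci(zd, k = 2)$clusters
  expect_equal(cld[["a"]], cld[["b"]])
  expect_equal(cld[["c"]], cld[["d"]])
  expect_true(cld[["a"]] != cld[["c"]])
  # zero-variance rows are assigned to the nearest centroid and flagged
  zf <- rbind(z, flat = rep(0, 6))
  clf <- suppressMessages(cluster_loci(zf, k = 2))
  expect_equal(clf$flagged, "flat")
  expect_false(is.na(clf$clusters[["flat"]]))
  # invariance to row order
  perm <- sample(nrow(z))
  cl2 <- cluster_loci(z[perm, ], k = 2)
  expect_equal(rand_index(cl2$clusters[rownames(z)], cl$clusters), 1)
})

test_that("subfamily sums conserve per-sample totals", {
  m <- matrix(c(3, 5, 2, 0, 7, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("l1", "l2", "l3"), c("s1", "s2")))
  mem <- c(l1 = "S", l2 = "S", l3 = "T")
  s <- sum_by_subfamily(m, mem)
  expect_equal(s["S", ], c(s1 = 5, s2 = 5))
  expect_equal(s["T", ], c(s1 = 7, s2 = 1))
  expect_equal(colSums(s), colSums(m))
  # single-member subfamily row is identical
  expect_equal(unname(s["T", ]), unname(m["l3", ]))
  expect_error(sum_by_subfamily(m, mem[1:2]), "without subfamily")
})

test_that("differential-expression thresholding applies both cutoffs", {
  tab <- data.frame(log2fc = c(1.5, 0.9, -1.2, 2.0),
                    padj = c(0.01, 0.01, 0.2, 0.04),
                    row.names = c("up", "small_fc", "big_p", "up2"))
  expect_equal(rownames(filter_differential(tab)), c("up", "up2"))
})

test_that("count matrices round-trip through the TSV writer", {
  m <- matrix(1:6, 2, dimnames = list(c("g1", "te1"), c("a", "b", "c")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, c("gene", "te_locus"), f)
  back <- read_count_matrix(f)
  expect_equal(back$counts, m)
  expect_equal(back$feature_kind, c("gene", "te_locus"))
})
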