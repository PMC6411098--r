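test_that("quantile normalization maps permuted columns to a fixed point", {
  set.seed(5)
  base <- sort(rpois(30, 100))
  m <- cbind(s1 = base, s2 = sample(base), s3 = sample(base))
  rownames(m) <- sprintf("g%02d", 1:30)
  norm <- normalize_counts(expression_table(m, "raw_counts"))
  expect_equal(expr_state(norm), "log_quantile")
  sorted <- apply(norm, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2])
  expect_equal(sorted[, 1], sorted[, 3])
  # within-sample ranking preserved
  expect_equal(rank(norm[, 2]), rank(m[, 2]))
})

test_that("single-sample normalization reduces to log counts-per-million", {
  m <- matrix(c(10L, 90L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  norm <- normalize_counts(expression_table(m, "raw_counts"))
  lib <- 100
  expect_equal(unname(norm[, 1]),
               log2((c(10, 90) + 0.5) / (lib + 1) * 1e6))
})

test_that("normalization equals an independent rank/mean-distribution oracle", {
  m <- matrix(c(5L, 40L, 200L,
                12L, 3L, 91L,
                77L, 50L, 8L), 3, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  norm <- normalize_counts(expression_table(m, "raw_counts"))
  # oracle: voom-style logCPM then map each column's ranks onto the mean of
  # the sorted columns
  lib <- colSums(m)
  logcpm <- log2(t((t(m) + 0.5) / (lib + 1)) * 1e6)
  ref <- rowMeans(apply(logcpm, 2, sort))
  expected <- apply(logcpm, 2, function(col) ref[rank(col)])
  expect_equal(unclass(norm), expected, ignore_attr = TRUE)
})

test_that("normalization rejects bad inputs", {
  m <- matrix(c(0L, 0L, 5L, 3L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(normalize_counts(expression_table(m, "raw_counts")),
               "zero library size")
  tab <- tiny_counts()
  expect_error(normalize_counts(normalize_counts(tab)), "raw_counts")
})

test_that("median centering zeroes medians and ignores additive shifts", {
  m <- matrix(c(1, 2, 9,
                4, 4, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  ctr <- median_center(expression_table(m, "log_quantile"))
  expect_equal(expr_state(ctr), "median_centred")
  expect_equal(unname(ctr["g1", ]), c(-1, 0, 7))
  expect_equal(unname(ctr["g2", ]), c(0, 0, 0))
  # shift invariance for the shifted gene only
  m2 <- m; m2["g1", ] <- m2["g1", ] + 13.7
  ctr2 <- median_center(expression_table(m2, "log_quantile"))
  expect_equal(unclass(ctr2), unclass(ctr), ignore_attr = TRUE)
  # per-gene output median is zero
  expect_equal(unname(apply(ctr, 1, median)), c(0, 0))

  m3 <- m; m3["g1", ] <- NA_real_
  expect_error(median_center(expression_table(m3, "log_quantile")),
               "all values missing")
})

test_that("metagene scores sum centred expression over signature genes", {
  tab <- centred_table(c(0, 1, -2,
                         0, 0.5, 3), c("a", "b"), c("s1", "s2", "s3"))
  sig <- gene_signature("two", c("a", "b"))
  sc <- metagene_score(tab, sig)
  expect_equal(as.numeric(sc), c(0, 1.5, 1))
  expect_equal(attr(sc, "n_genes_used"), 2L)

  # sample at every gene's median scores zero; one-gene signature is the
  # centred value itself
  expect_equal(unname(metagene_score(tab, gene_signature("one", "a"))["s2"]), 1)

  # genes absent from the table are skipped with a warning, coverage recorded
  sig3 <- gene_signature("three", c("a", "b", "zzz"))
  expect_warning(sc3 <- metagene_score(tab, sig3), "zzz")
  expect_equal(attr(sc3, "n_genes_used"), 2L)
  expect_equal(unclass(sc3), unclass(sc), ignore_attr = TRUE)
  expect_error(metagene_score(tab, gene_signature("none", "nope")),
               "no gene")
})

test_that("scores are additive over disjoint signatures", {
  set.seed(7)
  tab <- centred_table(rnorm(24), sprintf("g%d", 1:6), sprintf("s%d", 1:4))
  a <- gene_signature("A", c("g1", "g2", "g3"))
  b <- gene_signature("B", c("g4", "g5"))
  ab <- gene_signature("AB", c(a$genes, b$genes))
  expect_equal(unclass(metagene_score(tab, ab)),
               unclass(metagene_score(tab, a)) +
                 unclass(metagene_score(tab, b)),
               ignore_attr = TRUE)
})

test_that("score is invariant to pre-centering additive gene offsets", {
  set.seed(8)
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:5)))
  sig <- gene_signature("sig", c("g1", "g3"))
  s1 <- metagene_score(median_center(expression_table(m, "log_quantile")), sig)
  m2 <- m + c(5, -3, 100, 0.2)  # per-gene constants, recycled by row
  s2 <- metagene_score(median_center(expression_table(m2, "log_quantile")), sig)
  expect_equal(unclass(s1), unclass(s2), ignore_attr = TRUE)
})

test_that("signature construction drops unmeasured then excluded genes", {
  candidates <- sprintf("H%02d", 1:99)
  measured <- setdiff(candidates, c("H10", "H20", "H30"))
  exclusions <- gene_signature("excl", "H40")
  sig <- build_signature("hypoxia", candidates, measured, exclusions)
  expect_equal(length(sig), 95L)
  expect_equal(attr(sig, "removed")$unmeasured, c("H10", "H20", "H30"))
  expect_equal(attr(sig, "removed")$excluded, "H40")
  # order preserved; no removals = identity
  expect_equal(build_signature("id", candidates, candidates)$genes, candidates)
  expect_error(build_signature("none", "A", character()), "no candidate")
})

test_that("arm alteration calls use strict thresholds", {
  m <- matrix(c(-1.5, -1, -0.99, 0, 0.99, 1, 1.2, NA), 2, 4,
              dimnames = list(c("a1", "a2"), sprintf("s%d", 1:4)))
  calls <- call_arm_alterations(m)
  expect_equal(as.vector(calls)[1:7], c(-1L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_true(is.na(calls[2, 4]))
  expect_error(call_arm_alterations(m, low = 1, high = -1), "less than")
})
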