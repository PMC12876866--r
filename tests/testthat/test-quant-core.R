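test_that("column normalization equalizes sums and preserves proportions", {
  a <- matrix(c(2, 8, 6, 24), nrow = 2)
  qm <- toyQuantMatrix(cbind(a, a))
  nm <- normalizeColumns(qm)
  cs <- colSums(abundances(nm))
  expect_equal(unname(cs), rep(mean(colSums(abundances(qm))), 4))
  # columns with sums 10 and 30 scaled by 2 and 2/3
  expect_equal(unname(abundances(nm)[, 1]), c(4, 16))
  expect_equal(unname(abundances(nm)[, 2]), c(4, 16))
  # already-equal columns unchanged
  b <- matrix(c(1, 3, 2, 2), nrow = 2)
  qb <- toyQuantMatrix(cbind(b, b))
  expect_equal(abundances(normalizeColumns(qb)), abundances(qb))
})

test_that("zero-sum columns are rejected by name", {
  a <- matrix(c(0, 0, 6, 24), nrow = 2)
  qm <- toyQuantMatrix(cbind(a, a + 1))
  expect_error(normalizeColumns(qm), colnames(abundances(qm))[1])
})

test_that("replicate CV uses the n-1 sample SD on the linear scale", {
  expect_equal(replicateCV(c(5, 5)), 0)
  expect_equal(replicateCV(c(2, 2, 2, 2)), 0)
  expect_equal(replicateCV(c(1, 3)), sqrt(2) / 2)
  expect_true(is.na(replicateCV(c(3))))
  expect_true(is.na(replicateCV(c(NA, 3))))
})

test_that("log2 fold change is the log ratio of replicate means", {
  expect_equal(log2FoldChange(c(4, 4), c(1, 1)), 2)
  expect_equal(log2FoldChange(c(3, 3.5), c(3, 3.5)), 0)
  # with the filter widened, the ratio-of-means arithmetic is exposed
  expect_equal(log2FoldChange(c(2, 4), c(1, 1), cv_max = 0.5), log2(3))
  # CV filter: treated CV of (1, 3) is 0.707 >= 0.3 -> unquantified
  expect_true(is.na(log2FoldChange(c(1, 3), c(1, 1))))
  expect_true(is.na(log2FoldChange(c(1, 1), c(1, 3))))
})

test_that("replicate correlation matches the hand Pearson value", {
  a <- 2^matrix(c(1, 2, 3, 1, 3, 2, 1, 2, 3, 1, 2, 3), nrow = 3)
  qm <- toyQuantMatrix(a)
  rc <- replicateCorrelation(qm)
  expect_equal(unname(rc$per_group["CL01_drugA"]), 0.5)
  expect_equal(unname(rc$per_group["CL01_DMSO"]), 1)
  # duplicated identical replicate columns give r = 1
  b <- 2^matrix(c(1, 2, 3, 1, 2, 3, 4, 5, 9, 4, 5, 9), nrow = 3)
  expect_equal(unname(replicateCorrelation(toyQuantMatrix(b))$median), 1)
  # anti-correlated in log around the feature mean gives r = -1
  d <- 2^matrix(c(1, 2, 3, 3, 2, 1, 1, 2, 3, 1, 2, 3), nrow = 3)
  expect_equal(
    unname(replicateCorrelation(toyQuantMatrix(d))$per_group["CL01_drugA"]),
    -1)
})

test_that("constant replicate vectors are skipped with a warning", {
  a <- 2^matrix(c(1, 1, 1, 2, 3, 4, 1, 2, 3, 1, 2, 3), nrow = 3)
  expect_warning(replicateCorrelation(toyQuantMatrix(a)), "constant")
})

test_that("fold-change table applies the CV filter per arm", {
  # feature 1: treated CV ~0.35 -> unquantified; feature 2 clean
  tr <- c(1, 1.65)                       # CV = 0.347
  a <- rbind(c(tr, 1, 1), c(4, 4, 1, 1))
  qm <- toyQuantMatrix(a)
  tab <- fcTable(buildFoldChangeTable(qm, cv_max = 0.3))
  expect_false(tab$quantified[tab$feature == "P001"])
  expect_true(is.na(tab$log2fc[tab$feature == "P001"]))
  expect_true(tab$quantified[tab$feature == "P002"])
  expect_equal(tab$log2fc[tab$feature == "P002"], 2)
})

test_that("missing replicate values make a feature unquantified (no imputation)", {
  a <- rbind(c(4, NA, 1, 1), c(4, 4, 1, 1))
  tab <- fcTable(buildFoldChangeTable(toyQuantMatrix(a)))
  expect_false(tab$quantified[tab$feature == "P001"])
  expect_true(tab$quantified[tab$feature == "P002"])
})

test_that("empty feature sets give an empty table without error", {
  a <- matrix(numeric(0), nrow = 0, ncol = 4)
  rownames(a) <- character(0)
  qm <- toyQuantMatrix(a)
  fct <- buildFoldChangeTable(qm)
  expect_s4_class(fct, "FoldChangeTable")
  expect_equal(nrow(fcTable(fct)), 0)
})

test_that("groups without matched vehicle are rejected", {
  a <- matrix(1:8, nrow = 2)
  colnames(a) <- sprintf("CL01_drugA_rep%d", c(1, 2, 3, 4))
  rownames(a) <- c("P1", "P2")
  si <- data.frame(cell_line = "CL01", drug = "drugA", replicate = 1:4)
  expect_error(QuantMatrix(a, si), "DMSO")
})

test_that("log2 fold changes are invariant to global rescaling after normalization", {
  set.seed(31)
  a <- matrix(2^rnorm(40, 10, 1), nrow = 10)
  qm1 <- toyQuantMatrix(a)
  qm2 <- toyQuantMatrix(a * 7.3)
  f1 <- fcMatrix(buildFoldChangeTable(normalizeColumns(qm1)))
  f2 <- fcMatrix(buildFoldChangeTable(normalizeColumns(qm2)))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("swapping treated and vehicle negates the fold change", {
  set.seed(32)
  a <- matrix(2^rnorm(24, 10, 0.05), nrow = 6)
  qm <- toyQuantMatrix(a)
  sw <- toyQuantMatrix(a[, c(3, 4, 1, 2)])
  expect_equal(fcMatrix(buildFoldChangeTable(qm)),
               -fcMatrix(buildFoldChangeTable(sw)), tolerance = 1e-12)
})

test_that("vectorized fold-change table matches a naive per-feature oracle", {
  set.seed(33)
  for (trial in 1:5) {
    nf <- sample(3:8, 1)
    a <- matrix(2^rnorm(nf * 8, 10, 0.3), nrow = nf)
    qm <- toyQuantMatrix(cbind(a[, 1:4], a[, 5:8]),
                         drugs = c("drugA", "drugA", "drugB", "drugB",
                                   "DMSO", "DMSO", "drugC", "drugC"))
    tab <- fcTable(buildFoldChangeTable(qm))
    oracle <- naiveFoldChanges(qm)
    merged <- merge(tab, oracle, by = c("feature", "group"),
                    suffixes = c("", "_o"))
    expect_equal(nrow(merged), nrow(tab))
    expect_identical(merged$quantified, merged$quantified_o)
    q <- merged$quantified
    expect_equal(merged$log2fc[q], merged$log2fc_o[q], tolerance = 1e-12)
  }
})
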