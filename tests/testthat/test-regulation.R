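test_that("regulation calls use a strict absolute threshold", {
  m <- matrix(c(1.2, -1.2, 1.0, 0.5, -1.0, 2.5), nrow = 6,
              dimnames = list(paste0("P", 1:6), "CL01_drugA"))
  calls <- callRegulated(makeFct(m), threshold = 1)
  dir <- setNames(calls$direction, calls$feature)
  expect_equal(unname(dir[c("P1", "P2", "P6")]), c("up", "down", "up"))
  # exactly at the threshold is not a call (strict >)
  expect_equal(unname(dir[c("P3", "P4", "P5")]), rep("none", 3))
})

test_that("unquantified entries receive no call", {
  m <- matrix(c(2, NA), nrow = 2,
              dimnames = list(c("P1", "P2"), "CL01_drugA"))
  calls <- callRegulated(makeFct(m))
  expect_equal(calls$feature, "P1")
})

test_that("waterfall counts add up and sort by total then name", {
  m <- matrix(c(2, 2, 2, -2, -2, 0,
                2, 0, 0, 0, 0, 0,
                0, 0, 0, 0, 0, 0), nrow = 6,
              dimnames = list(paste0("P", 1:6),
                              c("CL01_drugA", "CL01_drugB", "CL02_drugA")))
  wf <- waterfallCounts(callRegulated(makeFct(m)))
  expect_equal(wf$group, c("CL01_drugA", "CL01_drugB", "CL02_drugA"))
  expect_equal(wf$n_up[1], 3L)
  expect_equal(wf$n_down[1], 2L)
  expect_equal(wf$n_total, wf$n_up + wf$n_down)
})

test_that("raising the threshold never increases waterfall counts", {
  set.seed(51)
  m <- matrix(rnorm(200, 0, 1.2), nrow = 50,
              dimnames = list(sprintf("P%02d", 1:50),
                              paste0("CL01_drug", c("A", "B", "C", "D"))))
  fct <- makeFct(m)
  for (th in c(0.5, 1, 1.5)) {
    lo <- waterfallCounts(callRegulated(fct, threshold = th))
    hi <- waterfallCounts(callRegulated(fct, threshold = th + 0.5))
    lo <- lo[order(lo$group), ]; hi <- hi[order(hi$group), ]
    expect_true(all(hi$n_total <= lo$n_total))
  }
})

test_that("consistency classes follow the group-count rules", {
  gs <- sprintf("CL%02d_drug%02d", rep(1:5, each = 6), rep(1:6, 5))
  m <- matrix(0, 4, 30, dimnames = list(c("ALL", "THIRTEEN", "NONE",
                                          "FOURTEEN"), gs))
  m["ALL", ] <- 2
  m["THIRTEEN", 1:13] <- 2
  m["FOURTEEN", 1:14] <- 2
  calls <- callRegulated(makeFct(m))
  cons <- classifyConsistency(calls, gs, specific_cutoff = 14)
  cls <- setNames(cons$class, cons$feature)
  expect_equal(unname(cls["ALL"]), "universal")
  expect_equal(unname(cls["THIRTEEN"]), "specific")  # 13 < 14
  expect_equal(unname(cls["FOURTEEN"]), "shared")    # 14 not < 14, not all
  expect_equal(unname(cls["NONE"]), "unresponsive")
})

test_that("consistency classes partition the classified features", {
  set.seed(52)
  gs <- sprintf("CL%02d_drug%02d", rep(1:5, each = 6), rep(1:6, 5))
  m <- matrix(rnorm(100 * 30, 0, 1.1), 100, 30,
              dimnames = list(sprintf("P%03d", 1:100), gs))
  m[sample(length(m), 200)] <- NA
  cons <- classifyConsistency(callRegulated(makeFct(m)), gs)
  expect_true(all(cons$class %in%
                    c("universal", "shared", "specific", "unresponsive")))
  expect_equal(anyDuplicated(cons$feature), 0L)
  # definitions are mutually exclusive by construction; re-derive by hand
  byhand <- ifelse(cons$n_regulated == 0, "unresponsive",
            ifelse(cons$n_regulated == 30 & cons$n_quantified == 30,
                   "universal",
            ifelse(cons$n_regulated < 14, "specific", "shared")))
  expect_equal(cons$class, byhand)
})

test_that("unknown groups in the consistency request are rejected", {
  m <- matrix(2, 1, 1, dimnames = list("P1", "CL01_drugA"))
  calls <- callRegulated(makeFct(m))
  expect_error(classifyConsistency(calls, c("CL01_drugA", "CL99_drugZ")),
               "CL99_drugZ")
})

test_that("composite viability correlation matches the hand Pearson oracle", {
  # subset = all models gives exactly r = 1
  v <- matrix(c(0.1, 0.4, 0.7, 0.9, 0.2, 0.3, 0.8, 0.8), ncol = 2,
              dimnames = list(NULL, c("m1", "m2")))
  expect_equal(compositeViabilityCorrelation(v, c("m1", "m2")), 1)
  # positive affine transform of the global mean also gives r = 1
  v2 <- cbind(g = c(0.1, 0.4, 0.7, 0.9), h = 2 * c(0.1, 0.4, 0.7, 0.9) + 0.1)
  expect_equal(compositeViabilityCorrelation(v2, "g"), 1)
  # frozen from an independent product-moment computation of
  # cor((0.2, 0.3, 0.8, 0.8), (0.1, 0.4, 0.7, 0.9)) -- the global means of
  # a two-model matrix are recovered by duplicating the target columns
  v3 <- cbind(a = 2 * c(0.1, 0.4, 0.7, 0.9) - c(0.2, 0.3, 0.8, 0.8),
              b = c(0.2, 0.3, 0.8, 0.8))
  expect_equal(compositeViabilityCorrelation(v3, "b"), 0.9444794,
               tolerance = 1e-6)
  expect_error(compositeViabilityCorrelation(v[1:2, ], "m1"), "3 conditions")
  expect_error(compositeViabilityCorrelation(cbind(a = rep(1, 4)), "a"),
               "constant")
})
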