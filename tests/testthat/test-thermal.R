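# independent Welch oracle: hand-coded statistic and Satterthwaite df
welchOracle <- function(x, y) {
  m1 <- mean(x); m2 <- mean(y)
  v1 <- sum((x - m1)^2) / (length(x) - 1)
  v2 <- sum((y - m2)^2) / (length(y) - 1)
  se2 <- v1 / length(x) + v2 / length(y)
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / length(x))^2 / (length(x) - 1) +
                   (v2 / length(y))^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

test_that("pisaShift matches the printed toys and a Welch oracle", {
  expect_equal(unname(pisaShift(c(4, 4, 4), c(1, 1, 1))["log2fc"]), 2)
  same <- pisaShift(c(2, 3, 4), c(2, 3, 4))
  expect_equal(unname(same["log2fc"]), 0)
  tr <- c(2.0, 2.2, 1.9); ve <- c(1.0, 1.1, 0.95)
  res <- pisaShift(tr, ve)
  expect_equal(unname(res["log2fc"]), log2(mean(tr) / mean(ve)),
               tolerance = 1e-12)
  expect_equal(unname(res["log2fc"]), 1.0, tolerance = 0.02)
  expect_equal(unname(res["p"]), welchOracle(log2(tr), log2(ve)),
               tolerance = 1e-9)
  # zero variance in both arms with equal means: log2fc 0, p 1
  flat <- pisaShift(c(2, 2, 2), c(2, 2, 2))
  expect_equal(unname(flat), c(0, 1))
})

test_that("pisaShift is antisymmetric under arm swap", {
  set.seed(91)
  for (i in 1:10) {
    a <- 2^rnorm(3, 10, 0.1); b <- 2^rnorm(3, 10, 0.1)
    f <- pisaShift(a, b); g <- pisaShift(b, a)
    expect_equal(unname(f["log2fc"]), -unname(g["log2fc"]),
                 tolerance = 1e-12)
    expect_equal(unname(f["p"]), unname(g["p"]), tolerance = 1e-12)
  }
})

test_that("engagement classes are mutually exclusive and follow the rule", {
  cases <- data.frame(
    fc_c = c(0.5, -0.5, 0.5, 0.1, 0.5, 0.5),
    p_c  = c(0.01, 0.01, 0.01, 0.01, 0.5, 0.01),
    fc_l = c(0.5, -0.5, 0.1, 0.5, 0.5, -0.5),
    p_l  = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01))
  cls <- classifyEngagement(cases$fc_c, cases$p_c, cases$fc_l, cases$p_l)
  expect_equal(cls$engagement,
               c("direct", "direct", "cell-context", "lysate-only",
                 "lysate-only", "none"))
  expect_equal(cls$direction,
               c("stabilized", "destabilized", "stabilized", "stabilized",
                 "stabilized", "mixed"))
  expect_true(all(cls$engagement %in%
                    c("direct", "cell-context", "lysate-only", "none")))
})

test_that("the fold-change floor gates significance", {
  cls <- classifyEngagement(0.15, 0.001, 0.15, 0.001,
                            min_abs_log2fc = 0.2)
  expect_equal(cls$engagement, "none")
  cls2 <- classifyEngagement(0.25, 0.001, 0.25, 0.001,
                             min_abs_log2fc = 0.2)
  expect_equal(cls2$engagement, "direct")
})

test_that("melting simulation obeys the two-state model limits", {
  set.seed(92)
  # no shift: treated and vehicle expectations equal
  sm0 <- simulateMelting(53, shift = 0, cv = 1e-9)
  expect_equal(sm0$expected_treated, sm0$expected_vehicle)
  # midpoint far above the gradient: pooled fraction ~1, shift-insensitive
  smhi <- simulateMelting(80, shift = 2, cv = 1e-9)
  expect_gt(smhi$expected_vehicle, 0.999)
  expect_lt(abs(log2(smhi$expected_treated / smhi$expected_vehicle)), 1e-3)
  expect_error(simulateMelting(53, slope = 0), "slope")
})

test_that("pooled soluble fraction matches a quadrature oracle", {
  temps <- seq(48, 58, length.out = 10)
  # independent evaluation of the sigmoid average at a +2 degree shift
  oracle <- function(tm) {
    tot <- 0
    for (T in temps) tot <- tot + 1 / (1 + exp((T - tm) / 1))
    tot / length(temps)
  }
  sm <- simulateMelting(53, shift = 2, slope = 1, temps = temps, cv = 1e-9)
  expect_equal(sm$expected_vehicle, oracle(53), tolerance = 1e-12)
  expect_equal(sm$expected_treated, oracle(55), tolerance = 1e-12)
  expect_gt(log2(sm$expected_treated / sm$expected_vehicle), 0)
})

test_that("planted engagement classes are recovered from the simulation", {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (seed in 1:8) {
    sdat <- simulateExperiment(smallSimConfig(seed = 200 + seed))
    rec <- pisaAnalyze(sdat$pisa_cell, sdat$pisa_lysate)
    truth <- sdat$truth$pisa_truth
    pred <- rec$protein[rec$engagement == "direct"]
    tru <- truth$protein[truth$direct]
    tp <- tp + length(intersect(pred, tru))
    fp <- fp + length(setdiff(pred, tru))
    fn <- fn + length(setdiff(tru, pred))
  }
  expect_gte(tp / (tp + fp), 0.9)
  expect_gte(tp / (tp + fn), 0.9)
})

test_that("proteins missing an arm are reported unclassified", {
  cell <- data.frame(protein = rep("P1", 6), arm = "cell",
                     condition = rep(c("treated", "vehicle"), each = 3),
                     replicate = rep(1:3, 2),
                     abundance = c(4, 4.1, 3.9, 1, 1.05, 0.98))
  lysate <- cell[0, ]
  rec <- pisaAnalyze(cell, lysate)
  expect_equal(rec$engagement, "unclassified")
})
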