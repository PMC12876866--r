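test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simConfig(n_cell_lines = 0), "n_cell_lines")
  expect_error(simConfig(replicate_cv = 0), "replicate_cv")
  expect_error(simConfig(n_proteins = 10, n_universal = 8, n_divergent = 8),
               "n_proteins")
  expect_error(simConfig(n_outgroup = 7, n_drugs = 7), "n_outgroup")
  expect_error(simConfig(dropout_rate = 1.2), "dropout_rate")
})

test_that("identical config and seed give bit-identical experiments", {
  cfg <- smallSimConfig(seed = 42L)
  a <- simulateExperiment(cfg)
  b <- simulateExperiment(cfg)
  expect_identical(abundances(a$protein), abundances(b$protein))
  expect_identical(abundances(a$phospho), abundances(b$phospho))
  expect_identical(a$pisa_cell, b$pisa_cell)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$truth, b$truth)
  d <- simulateExperiment(smallSimConfig(seed = 43L))
  expect_false(identical(abundances(a$protein), abundances(d$protein)))
})

test_that("near-zero noise and all-null features give zero CV and zero fold change", {
  cfg <- simConfig(n_proteins = 50, n_universal = 0, n_divergent = 0,
                   anchor_module_size = 0, n_decoy_kinases = 0,
                   kinase_effect_log2 = 0, kinase_activity_sd = 0,
                   n_kinase_substrates = 0,
                   n_phosphosites = 20, n_pisa_proteins = 0,
                   n_concordance_genes = 9, replicate_cv = 1e-9, seed = 3)
  sd0 <- simulateExperiment(cfg)
  fct <- buildFoldChangeTable(sd0$protein)
  tab <- fcTable(fct)
  expect_true(all(tab$quantified))
  expect_lt(max(abs(tab$log2fc)), 1e-6)
  expect_lt(max(tab$cv_treated, tab$cv_vehicle), 1e-6)
})

test_that("vehicle columns carry no planted effect", {
  cfg <- smallSimConfig(seed = 5L, replicate_cv = 1e-9)
  sdat <- simulateExperiment(cfg)
  a <- log2(abundances(sdat$protein))
  cd <- sampleInfo(sdat$protein)
  veh <- a[, cd$drug == "DMSO", drop = FALSE]
  # within each cell line the vehicle replicates equal the feature baseline
  spread <- apply(veh, 1L, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
})

test_that("recovered fold change of universal effectors matches the planted effect", {
  # Monte-Carlo check against the generator's own parameters
  cfg <- smallSimConfig(seed = 11L)
  sdat <- simulateExperiment(cfg)
  fct <- buildFoldChangeTable(sdat$protein)
  m <- fcMatrix(fct, groups = sdat$hdaci_groups)
  tr <- sdat$truth
  uids <- names(tr$effector_class)[tr$effector_class == "universal"]
  signed <- m[uids, , drop = FALSE] * tr$universal_sign[uids]
  expect_lt(abs(mean(signed) - cfg$effect_size_log2), 0.2)
  # 3 Monte-Carlo standard errors, on per-feature means (group-level
  # fold changes of one feature share vehicle noise, so features are the
  # independent replication unit)
  feat_means <- rowMeans(signed)
  se <- sd(feat_means) / sqrt(length(feat_means))
  expect_lt(abs(mean(feat_means) - cfg$effect_size_log2), 3 * se)
})

test_that("null-only simulations rarely exceed the regulation threshold", {
  cfg <- simConfig(n_proteins = 2000, n_universal = 0, n_divergent = 0,
                   anchor_module_size = 0, n_kinase_substrates = 0,
                   kinase_effect_log2 = 0, n_phosphosites = 50,
                   n_pisa_proteins = 0, n_concordance_genes = 9,
                   replicate_cv = 0.05, seed = 21)
  sdat <- simulateExperiment(cfg)
  calls <- callRegulated(buildFoldChangeTable(sdat$protein))
  frac <- mean(calls$direction != "none")
  expect_lt(frac, 0.01)
})

test_that("divergent effectors shift only their assigned cell lines", {
  cfg <- smallSimConfig(seed = 9L, replicate_cv = 1e-9)
  sdat <- simulateExperiment(cfg)
  fct <- buildFoldChangeTable(sdat$protein)
  m <- fcMatrix(fct, groups = sdat$hdaci_groups)
  tr <- sdat$truth
  grp <- sdat$groups[sdat$groups$hdaci, ]
  div <- names(tr$effector_class)[tr$effector_class == "divergent"]
  for (id in div[1:5]) {
    hit <- grp$cell_line %in% tr$divergent_lines[[id]]
    expect_true(all(abs(m[id, hit]) > 1.9))
    expect_true(all(abs(m[id, !hit]) < 0.01))
  }
})

test_that("recovery report handles perfect, empty and hand-counted predictions", {
  cfg <- smallSimConfig(seed = 2L)
  tr <- simulateExperiment(cfg)$truth
  uni <- names(tr$effector_class)[tr$effector_class == "universal"]
  div <- names(tr$effector_class)[tr$effector_class == "divergent"]

  perfect <- truthRecoveryReport(list(universal = uni, divergent = div,
                                      anchor = tr$anchor_members),
                                 tr)
  expect_true(all(perfect$precision == 1))
  expect_true(all(perfect$recall == 1))

  empty <- truthRecoveryReport(list(universal = character(0)), tr)
  expect_equal(empty$recall, 0)
  expect_equal(empty$precision, 1)   # stated convention
  expect_true(empty$precision_undefined)

  # 1 false positive, 1 false negative on a 10-item truth set
  nulls <- names(tr$effector_class)[tr$effector_class == "null"]
  tr10 <- tr
  tr10$effector_class[div] <- "null"
  tr10$effector_class[div[1:10]] <- "divergent"
  pred <- c(div[1:9], nulls[1])
  rep10 <- truthRecoveryReport(list(divergent = pred), tr10)
  expect_equal(rep10$precision, 9 / 10)
  expect_equal(rep10$recall, 9 / 10)
})

test_that("recovery report rejects predictions outside the truth universe", {
  tr <- simulateExperiment(smallSimConfig(seed = 4L))$truth
  expect_error(
    truthRecoveryReport(list(universal = c("NOT_A_FEATURE")), tr),
    "NOT_A_FEATURE")
})
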