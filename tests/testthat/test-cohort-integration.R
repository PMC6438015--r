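test_that("the low-anchor subset applies the ceiling rule with stable ties", {
  cfg <- smallConfig(cohortNTumor = 423L, cohortNNormal = 35L)
  ko <- simulateKoExperiment(cfg)
  cohort <- simulateCohort(cfg, ko$truth, ko$genes)
  subset <- selectLowAnchorSubset(cohort, "TET2", 0.10)
  expect_equal(length(subset), 43L)   # ceiling(0.10 * 423)
  # the subset really is the lowest tail of TET2 expression
  v <- cohortExpr(cohort)["TET2", tissueSamples(cohort, "tumor")]
  expect_lte(max(v[subset]), min(v[setdiff(names(v), subset)]))
  expect_equal(length(selectLowAnchorSubset(cohort, "TET2", 1.0)), 423L)
  expect_error(selectLowAnchorSubset(cohort, "NOPE"), "anchor")
})

test_that("the ceiling rule holds at small n", {
  cfg <- smallConfig(cohortNTumor = 10L, cohortNNormal = 5L)
  ko <- simulateKoExperiment(cfg)
  cohort <- simulateCohort(cfg, ko$truth, ko$genes)
  expect_equal(length(selectLowAnchorSubset(cohort, quantile = 0.10)), 1L)
})

test_that("concordance testing gates on direction and Bonferroni", {
  cfg <- smallConfig()
  ko <- simulateKoExperiment(cfg)
  cohort <- simulateCohort(cfg, ko$truth, ko$genes)
  subset <- selectLowAnchorSubset(cohort)
  dr <- driverGenes(ko$truth)
  fam <- c(dr, "TET2")  # TET2 is also down in the subset by construction
  conc <- cohortExpressionConcordance(cohort, fam, subset)
  expect_equal(attr(conc, "threshold"), 0.05 / length(fam))
  expect_true(all(dr %in% conc$geneId[conc$pass]))
  # a gene UP in tumors is excluded despite a small p
  nd <- setdiff(ko$truth@effects$geneId, c(dr, "TET2"))[1]
  up <- cohort
  upExpr <- cohortExpr(cohort)
  upExpr[nd, seq_len(60)] <- upExpr[nd, seq_len(60)] * 100
  up@expr <- upExpr
  conc2 <- cohortExpressionConcordance(up, c(dr, nd), subset)
  g1 <- conc2[conc2$geneId == nd, ]
  expect_lt(g1$p.value, attr(conc2, "threshold"))
  expect_false(g1$pass)
  # empty family: empty result
  expect_equal(nrow(cohortExpressionConcordance(cohort, character(),
                                                subset)), 0)
})

test_that("panel assembly recovers planted drivers with clean provenance", {
  cfg <- smallConfig()
  ko <- simulateKoExperiment(cfg)
  cohort <- simulateCohort(cfg, ko$truth, ko$genes)
  prior <- simulatePriorList(cfg, ko$truth)
  res <- runPipeline(pipelineConfig(seed = 11), ko$methWindows,
                     ko$exprCounts, ko$genes, cohort, prior)
  panel <- res$panel
  tb <- as.data.frame(panelTable(panel))
  truth <- driverGenes(ko$truth)
  top <- panelGenes(panel)
  expect_gte(mean(truth %in% top), 0.8)
  expect_lte(mean(!top %in% truth), 0.1)
  # funnel is monotone non-increasing along the cascade
  funnel <- vapply(0:max(tb$tier), function(k) sum(tb$tier >= k), integer(1))
  expect_true(all(diff(funnel) <= 0))
  # provenance: top genes carry their DMR coordinates and probes
  expect_true(all(nzchar(tb$dmrCoords[tb$geneId %in% top])))
  expect_true(all(nzchar(tb$probeIds[tb$geneId %in% top])))
  expect_equal(panelMetadata(panel)$bonferroniCohort,
               0.05 / panelMetadata(panel)$nKoDown)
})

test_that("dropping the prior list leaves other flags unchanged", {
  cfg <- smallConfig()
  ko <- simulateKoExperiment(cfg)
  cohort <- simulateCohort(cfg, ko$truth, ko$genes)
  prior <- simulatePriorList(cfg, ko$truth)
  pcfg <- pipelineConfig(seed = 11)
  withPrior <- runPipeline(pcfg, ko$methWindows, ko$exprCounts, ko$genes,
                           cohort, prior)
  noPrior <- runPipeline(pcfg, ko$methWindows, ko$exprCounts, ko$genes,
                         cohort, NULL)
  a <- as.data.frame(panelTable(withPrior$panel))
  b <- as.data.frame(panelTable(noPrior$panel))
  for (col in c("koDownEither", "cohortExprDown",
                "koPromoterHypermethEither"))
    expect_identical(a[[col]], b[[col]])
  expect_true(all(is.na(b$priorListMember)))
})

test_that("panel assembly is deterministic and validates the universe", {
  cfg <- smallConfig()
  ko <- simulateKoExperiment(cfg)
  cohort <- simulateCohort(cfg, ko$truth, ko$genes)
  pcfg <- pipelineConfig(seed = 11)
  r1 <- runPipeline(pcfg, ko$methWindows, ko$exprCounts, ko$genes, cohort)
  r2 <- runPipeline(pcfg, ko$methWindows, ko$exprCounts, ko$genes, cohort)
  expect_identical(panelTable(r1$panel), panelTable(r2$panel))
  # mismatched gene universes across KO lines are rejected
  de <- r1$de
  de$KO2 <- de$KO2[-1, ]
  expect_error(assemblePanel(de, r1$dmrs, cohort), "universe")
})
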