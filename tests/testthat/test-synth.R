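test_that("cohort generation is reproducible and honours the requested dimensions", {
  cfg <- cohortConfig(nSamples = 40, nMirna = 6, nGenes = 150, nPathways = 3,
                      genesPerPathway = 12)
  c1 <- generateCohort(cfg, seed = 71)
  c2 <- generateCohort(cfg, seed = 71)
  expect_identical(exprValues(cohortMirna(c1)), exprValues(cohortMirna(c2)))
  expect_identical(exprValues(cohortMrna(c1)), exprValues(cohortMrna(c2)))
  expect_identical(cohortSurvival(c1), cohortSurvival(c2))
  expect_identical(cohortTruth(c1)$scores, cohortTruth(c2)$scores)

  expect_equal(dim(cohortMirna(c1)), c(6L, 40L))
  expect_equal(dim(cohortMrna(c1)), c(150L, 40L))
  expect_identical(length(cohortGeneSets(c1)), 3L)
  expect_true(all(lengths(cohortGeneSets(c1)) == 12L))
  expect_true(all(cohortPurity(c1) >= 0.3 & cohortPurity(c1) <= 0.9))
  # pathways are disjoint subsets of the gene universe
  members <- unlist(cohortGeneSets(c1))
  expect_false(anyDuplicated(members) > 0)
  expect_true(all(members %in% featureIds(cohortMrna(c1))))
  # different seeds give different data
  c3 <- generateCohort(cfg, seed = 72)
  expect_false(identical(exprValues(cohortMirna(c1)),
                         exprValues(cohortMirna(c3))))
  expect_error(generateCohort(cfg), "seed")
  expect_error(cohortConfig(nGenes = 50, nPathways = 5,
                            genesPerPathway = 20), "gene universe")
})

test_that("the planted miRNA correlates more with its targets than with other genes", {
  stronger <- vapply(1:20, function(s) {
    co <- generateCohort(cohortConfig(), seed = 700 + s)
    truth <- cohortTruth(co)
    lm2 <- exprValues(log2p1(rpmNormalize(cohortMirna(co))))
    lg2 <- exprValues(log2p1(rpmNormalize(cohortMrna(co))))
    tab <- mirnaGeneAssociations(lm2[truth$planted$mirna[1], ],
                                 ExpressionMatrix(lg2, "log2"),
                                 cohortPurity(co))
    targets <- truth$targetGenes[[1]]
    mean(abs(tab$pcc[tab$gene_id %in% targets])) >
      mean(abs(tab$pcc[!tab$gene_id %in% targets]))
  }, logical(1))
  expect_true(all(stronger))
})

test_that("purity confounding inflates plain correlations relative to adjusted ones", {
  wins <- vapply(1:20, function(s) {
    cfg <- cohortConfig(nSamples = 100, nMirna = 10, nGenes = 300,
                        nPathways = 2, genesPerPathway = 20, planted = NULL)
    co <- generateCohort(cfg, seed = 800 + s)
    M <- exprValues(log2p1(rpmNormalize(cohortMirna(co))))
    G <- exprValues(log2p1(rpmNormalize(cohortMrna(co))))
    plain <- cor(t(M), t(G))
    adj <- ImmuMiR:::.partialCorMatrix(M, G, cohortPurity(co))$pcc
    sum(abs(plain) > 0.3) > sum(abs(adj) > 0.3)
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("survival truth drives a hazard difference across the recorded cutpoint", {
  co <- generateCohort(cohortConfig(nSamples = 300), seed = 73)
  truth <- cohortTruth(co)
  sv <- cohortSurvival(co)
  high <- truth$scores > truth$cutpoint
  res <- logRankStatistic(sv$time, sv$event, ifelse(high, "high", "low"))
  expect_lt(res$p, 0.01)
  # the high-score group dies faster
  expect_lt(median(sv$time[high]), median(sv$time[!high]))
})

test_that("drug tables reduce to pure noise when nothing is planted", {
  scores <- setNames(rnorm(50), paste0("s", 1:50))
  d0 <- generateDrugTable(scores, nDrugs = 8, nPlanted = 0, seed = 74)
  expect_identical(d0$planted, character(0))
  rmax <- max(abs(cor(t(d0$ic50), scores)))
  expect_lt(rmax, 0.6)
  # planted drugs correlate strongly at small noise
  d1 <- generateDrugTable(scores, nDrugs = 8, nPlanted = 3, noiseSd = 0.2,
                          seed = 74)
  rs <- abs(cor(t(d1$ic50[d1$planted, ]), scores))
  expect_true(all(rs > 0.8))
  d2 <- generateDrugTable(scores, nDrugs = 8, nPlanted = 3, noiseSd = 0.2,
                          seed = 74)
  expect_identical(d1$ic50, d2$ic50)
})

test_that("written cohorts round-trip through the module readers", {
  co <- generateCohort(cohortConfig(nSamples = 20, nMirna = 4, nGenes = 60,
                                    nPathways = 2, genesPerPathway = 10),
                       seed = 75)
  dir <- withr::local_tempdir()
  paths <- writeCohort(co, dir)
  expect_true(all(file.exists(paths)))
  backM <- readExpressionTable(paths[["mirna"]], "counts")
  expect_equal(exprValues(backM), exprValues(cohortMirna(co)))
  expect_equal(readPurity(paths[["purity"]]), cohortPurity(co))
  expect_identical(readGMT(paths[["gene_sets"]]), cohortGeneSets(co))
  expect_equal(readSurvival(paths[["survival"]]), cohortSurvival(co))
})
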