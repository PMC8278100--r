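test_that("the packaged IAMIPS signature carries the published constants", {
  sig <- iamipsSignature()
  co <- signatureCoefficients(sig)
  expect_identical(length(co), 3L)
  expect_equal(unname(co[c("miR-216a-5p", "miR-194-3p", "miR-3677-3p")]),
               c(0.015, -0.035, -0.124))
  expect_equal(signatureCutoff(sig), 0.05)
})

test_that("signature files round-trip", {
  sig <- SignatureModel(c("miR-a", "miR-b"), c(0.25, -0.5), cutoff = 0.1,
                        name = "toy")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSignatureFile(sig, path)
  back <- readSignatureFile(path)
  expect_equal(signatureCoefficients(back), signatureCoefficients(sig))
  expect_equal(signatureCutoff(back), 0.1)
  expect_error(SignatureModel(c("a", "a"), c(1, 2), 0), "unique")
})

test_that("risk scores are the signature-weighted sums of standardized expression", {
  sig <- iamipsSignature()
  ids <- names(signatureCoefficients(sig))
  z0 <- ExpressionMatrix(
    matrix(0, 3, 2, dimnames = list(ids, c("s1", "s2"))), "zscore")
  expect_equal(riskScore(z0, sig)$score, c(0, 0))

  unit <- matrix(0, 3, 3, dimnames = list(ids, paste0("u", 1:3)))
  diag(unit) <- 1
  sc <- riskScore(ExpressionMatrix(unit, "zscore"), sig)
  expect_equal(sc$score, c(0.015, -0.035, -0.124))

  # linearity: score(aX) = a score(X), score(X + Y) = score(X) + score(Y)
  set.seed(51)
  X <- matrix(rnorm(9), 3, 3, dimnames = dimnames(unit))
  Y <- matrix(rnorm(9), 3, 3, dimnames = dimnames(unit))
  sX <- riskScore(ExpressionMatrix(X, "zscore"), sig)$score
  sY <- riskScore(ExpressionMatrix(Y, "zscore"), sig)$score
  expect_equal(riskScore(ExpressionMatrix(2.5 * X, "zscore"), sig)$score,
               2.5 * sX)
  expect_equal(riskScore(ExpressionMatrix(X + Y, "zscore"), sig)$score,
               sX + sY)

  sub <- ExpressionMatrix(unit[1:2, ], "zscore")
  expect_error(riskScore(sub, sig), "miR-3677-3p")
  expect_warning(riskScore(ExpressionMatrix(unit, "log2"), sig), "zscore")
})

test_that("log-rank statistic matches the hand-computed observed/expected sums", {
  time <- c(2, 4, 5, 7, 8, 10, 12, 15)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  grp <- rep(c("a", "b"), each = 4)
  res <- logRankStatistic(time, event, grp)
  expect_equal(res$chisq, handLogRank(time, event, grp == "a"),
               tolerance = 1e-10)
  expect_equal(res$p, pchisq(res$chisq, 1, lower.tail = FALSE))
  # label symmetry
  res2 <- logRankStatistic(time, event, rep(c("b", "a"), each = 4))
  expect_equal(res2$chisq, res$chisq, tolerance = 1e-12)
  # no events at all: statistic 0 with a warning
  expect_warning(r0 <- logRankStatistic(time, rep(0, 8), grp), "no events")
  expect_equal(r0$chisq, 0)
})

test_that("the cutpoint search agrees with an exhaustive scan and respects minprop", {
  sim <- simulateStepHazard(30, hr = 4, seed = 52)
  cut <- optimalCutpoint(sim$score, sim$time, sim$event, minprop = 0.1)
  # brute-force oracle: evaluate every admissible midpoint directly
  u <- sort(unique(sim$score))
  mids <- (u[-1] + u[-length(u)]) / 2
  nLow <- vapply(mids, function(cc) sum(sim$score <= cc), integer(1))
  mids <- mids[nLow >= 3 & (30 - nLow) >= 3]
  chis <- vapply(mids, function(cc) {
    handLogRank(sim$time, sim$event, sim$score <= cc)
  }, numeric(1))
  expect_equal(cut, mids[which.max(chis)])
  # the cutpoint always lies inside the admissible quantile band
  qs <- quantile(sim$score, c(0.1, 0.9))
  expect_gte(cut, qs[[1]])
  expect_lte(cut, qs[[2]])
  expect_error(optimalCutpoint(sim$score[1:5], sim$time[1:5], sim$event[1:5]),
               "10 subjects")
  expect_error(optimalCutpoint(sim$score, sim$time, sim$event, minprop = 0.6),
               "minprop")
})

test_that("the cutpoint is invariant in rank position under monotone score transforms", {
  sim <- simulateStepHazard(60, hr = 3, seed = 53)
  cut <- optimalCutpoint(sim$score, sim$time, sim$event)
  cutExp <- optimalCutpoint(exp(sim$score), sim$time, sim$event)
  # same partition of the subjects
  expect_identical(sim$score <= cut, exp(sim$score) <= cutExp)
})

test_that("group assignment dichotomizes strictly above the cutoff", {
  prof <- assignGroups(c(a = 0.06, b = 0.05, c = -0.2), cutoff = 0.05)
  expect_identical(as.character(prof$group), c("high", "low", "low"))
  expect_identical(prof$sample_id, c("a", "b", "c"))
  expect_identical(nrow(prof), 3L)
  # data.frame input from riskScore is accepted
  sig <- iamipsSignature()
  ids <- names(signatureCoefficients(sig))
  z <- ExpressionMatrix(matrix(rnorm(9), 3, 3,
                               dimnames = list(ids, paste0("s", 1:3))),
                        "zscore")
  prof2 <- assignGroups(riskScore(z, sig), signatureCutoff(sig))
  expect_identical(levels(prof2$group), c("low", "high"))
  expect_identical(as.character(prof2$group),
                   ifelse(prof2$score > 0.05, "high", "low"))
})
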