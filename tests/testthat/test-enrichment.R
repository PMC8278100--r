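test_that("enrichment score hits its extremes for single-member sets", {
  ranked <- makeRanked(10)
  # member at rank 1, unweighted: immediate full deviation
  expect_equal(enrichmentScore(ranked, ranked$gene_id[1], weightExponent = 0),
               1)
  # member at rank 10: the running sum bottoms out at -9/9 just before it
  expect_equal(enrichmentScore(ranked, ranked$gene_id[10], weightExponent = 0),
               -1)
  expect_error(enrichmentScore(ranked, "absent"), "no member")
  expect_error(enrichmentScore(ranked, ranked$gene_id), "whole ranked list")
})

test_that("enrichment score equals the naive running-sum oracle", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(12:80, 1)
    k <- sample(3:6, 1)
    ranked <- makeRanked(N, seed = 31 + i)
    hitIdx <- sort(sample(N, k))
    set <- ranked$gene_id[hitIdx]
    for (w in c(0, 1, 1.7)) {
      hit <- seq_len(N) %in% hitIdx
      expect_equal(enrichmentScore(ranked, set, weightExponent = w),
                   naiveEs(ranked$rs, hit, w), tolerance = 1e-12)
    }
  }
})

test_that("unweighted enrichment equals the classic KS statistic and the weighted score matches fgsea", {
  skip_if_not_installed("fgsea")
  set.seed(32)
  for (i in 1:50) {
    N <- sample(20:100, 1)
    k <- sample(3:8, 1)
    ranked <- makeRanked(N, seed = 320 + i)
    hitIdx <- sort(sample(N, k))
    set <- ranked$gene_id[hitIdx]
    # classic KS: max signed gap between hit ECDF and miss ECDF
    hitEcdf <- cumsum(seq_len(N) %in% hitIdx) / k
    missEcdf <- cumsum(!(seq_len(N) %in% hitIdx)) / (N - k)
    gaps <- hitEcdf - missEcdf
    ks <- if (max(gaps) >= -min(gaps)) max(gaps) else min(gaps)
    expect_equal(enrichmentScore(ranked, set, weightExponent = 0), ks,
                 tolerance = 1e-12)
    # independent implementation for the weighted statistic
    stats <- stats::setNames(ranked$rs, ranked$gene_id)
    expect_equal(enrichmentScore(ranked, set, weightExponent = 1),
                 fgsea::calcGseaStat(stats, hitIdx, gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("all-zero hit weights fall back to unweighted steps with a warning", {
  ranked <- data.frame(gene_id = sprintf("g%02d", 1:10),
                       rs = c(rep(2, 4), rep(0, 6)))
  expect_warning(es <- enrichmentScore(ranked, c("g05", "g06")),
                 "falling back")
  expect_equal(es, suppressWarnings(
    enrichmentScore(ranked, c("g05", "g06"), weightExponent = 0)))
})

test_that("permutation p-values respect the pseudocount bound and reproduce under a seed", {
  ranked <- makeRanked(40, seed = 33)
  set <- ranked$gene_id[c(2, 5, 9)]
  r1 <- permutationTest(ranked, set, nPerm = 300, seed = 99)
  r2 <- permutationTest(ranked, set, nPerm = 300, seed = 99)
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / 301)
  expect_lte(r1$p, 1)
  expect_error(permutationTest(ranked, set, nPerm = 50, seed = 1), "100")
  expect_error(permutationTest(ranked, ranked$gene_id, nPerm = 100, seed = 1),
               "smaller")
})

test_that("permutation estimate matches the exhaustive null on a 5-gene universe", {
  ranked <- makeRanked(5, seed = 34)
  sets <- utils::combn(5, 2)
  allEs <- apply(sets, 2, function(idx) {
    enrichmentScore(ranked, ranked$gene_id[idx])
  })
  obsIdx <- c(1, 4)
  obs <- enrichmentScore(ranked, ranked$gene_id[obsIdx])
  same <- sign(allEs) == sign(obs)
  exact <- sum(same & abs(allEs) >= abs(obs)) / sum(same)
  est <- permutationTest(ranked, ranked$gene_id[obsIdx], nPerm = 5000,
                         seed = 7)$p
  expect_lt(abs(est - exact), 0.03)
})

test_that("permutation p-values of random sets are uniform", {
  ranked <- makeRanked(50, seed = 35)
  set.seed(35)
  ps <- replicate(500, {
    set <- sample(ranked$gene_id, 5)
    permutationTest(ranked, set, nPerm = 100)$p
  })
  bins <- cut(ps, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE)
  gof <- suppressWarnings(chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.01)
})

test_that("miRES maps (sign, p) onto [-1, 1] as specified", {
  expect_equal(miRES(0.8, 1e-300), 1)
  expect_equal(miRES(-0.8, 1e-300), -1)
  expect_equal(miRES(0.3, 0.0025), 0.995)
  expect_equal(miRES(0.3, 0.5), 0)
  expect_equal(miRES(-0.3, 0.5), 0)
  expect_error(miRES(0, 0.5), "undefined")
  expect_error(miRES(0.5, 0), "\\(0, 1\\]")
  # strictly decreasing in p for positive ES, increasing for negative;
  # |miRES| never exceeds 1; sign matches ES whenever p < 0.5
  p <- sort(runif(50, 1e-6, 1))
  expect_true(all(diff(miRES(rep(1, 50), p)) < 0))
  expect_true(all(diff(miRES(rep(-1, 50), p)) > 0))
  expect_true(all(abs(miRES(rep(1, 50), p)) <= 1))
  small <- p[p < 0.5]
  expect_true(all(miRES(rep(1, length(small)), small) > 0))
  expect_true(all(miRES(rep(-1, length(small)), small) < 0))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(numeric(0)), numeric(0))
  # hand step-up: p * m / i = (.04, .04, .04, .04) after monotonicity
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # order preserved, q >= p, q <= 1
  set.seed(36)
  p <- runif(30)
  q <- bhAdjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  expect_equal(q[order(p)], sort(q))
})

test_that("the full scan is deterministic and flags nothing on an empty collection", {
  co <- generateCohort(cohortConfig(nSamples = 50, nMirna = 4, nGenes = 200,
                                    nPathways = 2, genesPerPathway = 15),
                       seed = 41)
  lm2 <- log2p1(rpmNormalize(cohortMirna(co)))
  lg2 <- log2p1(rpmNormalize(cohortMrna(co)))
  cfg <- scanConfig(nPerm = 100, seed = 5)
  r1 <- immuMiRNAScan(lm2, lg2, cohortPurity(co), cohortGeneSets(co), cfg)
  r2 <- immuMiRNAScan(lm2, lg2, cohortPurity(co), cohortGeneSets(co), cfg)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 8L)
  expect_true(all(abs(r1$es) <= 1))
  expect_true(all(r1$p > 0 & r1$p <= 1))
  empty <- immuMiRNAScan(lm2, lg2, cohortPurity(co), list(), cfg)
  expect_identical(nrow(empty), 0L)
})

test_that("ssGSEA ranks a sample's own top genes above random sets", {
  set.seed(42)
  expr <- makeExpr(matrix(rnorm(400, 6, 2), 100, 4), "log2")
  v <- exprValues(expr)
  topSet <- rownames(v)[order(-v[, 1])][1:10]
  topScore <- ssgseaScores(expr, list(top = topSet))["top", 1]
  randomScores <- replicate(100, {
    ssgseaScores(expr, list(r = sample(rownames(v), 10)))["r", 1]
  })
  expect_true(all(topScore > randomScores))
})

test_that("ssGSEA is deterministic per column and handles empty/missing sets", {
  set.seed(43)
  v <- matrix(rnorm(60, 5), 20, 3)
  v[, 3] <- v[, 1]  # duplicated sample column
  expr <- makeExpr(v, "log2")
  sets <- list(a = rownames(exprValues(expr))[c(2, 5, 9)])
  sc <- ssgseaScores(expr, sets)
  expect_equal(sc[, 3], sc[, 1])
  expect_warning(sc2 <- ssgseaScores(expr, list(gone = c("x1", "x2"))),
                 "gone")
  expect_equal(unname(sc2["gone", ]), c(0, 0, 0))
  # min-max rescaling maps each set's scores onto [0, 1]
  sc3 <- ssgseaScores(expr, sets, rescale = TRUE)
  expect_equal(unname(range(sc3)), c(0, 1))
})

test_that("ssGSEA matches a hand-computed weighted ECDF sum on a 5-gene sample", {
  v <- matrix(c(8, 5, 3, 2, 1), 5, 1,
              dimnames = list(paste0("g", 1:5), "s1"))
  expr <- ExpressionMatrix(v, "log2")
  alpha <- 0.25
  # genes already in descending order; set = {g2, g3};
  # ascending ranks: g1 -> 5, g2 -> 4, g3 -> 3, g4 -> 2, g5 -> 1
  win <- c(0, 4^alpha, 3^alpha, 0, 0)
  pin <- cumsum(win) / sum(win)
  pout <- cumsum(c(1, 0, 0, 1, 1)) / 3
  hand <- sum(pin - pout)
  expect_equal(ssgseaScores(expr, list(s = c("g2", "g3")), alpha = alpha)[1, 1],
               hand, tolerance = 1e-12)
})
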