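# ImmuMiR

Identify miRNA regulators of immune-associated pathways from matched bulk
miRNA/mRNA expression, and stratify patients with a packaged three-miRNA
prognostic risk score.

Bulk tumour expression mixes malignant and immune cells, so naive
miRNA–gene correlations are confounded by tumour purity. ImmuMiR scans
every miRNA × immune-pathway pair in four steps:

1. **Purity-adjusted association** — first-order partial correlation
   between miRNA *M* and gene *G*, controlling purity *P*:
   `PCC = (R_MG − R_MP·R_GP) / (√(1−R_MP²)·√(1−R_GP²))`, with a two-sided
   p-value from `t = PCC·√((n−3)/(1−PCC²))` on n−3 df.
2. **Rank score** — genes ordered by `RS = −log10(p)·sign(PCC)`.
3. **Enrichment** — weighted Kolmogorov–Smirnov enrichment score (ES) of
   each pathway on the ranked list, with a gene-set permutation p-value.
4. **miRES** — `miRES = 1−2p` (ES>0) or `2p−1` (ES<0), in [−1, 1];
   a pair is significant when `|miRES| > 0.995` and the BH FDR pooled over
   all pairs of the scan is `< 0.05`.

Also included: ssGSEA per-sample immune-infiltration scoring, the IAMIPS
risk score `0.015·z(miR-216a-5p) − 0.035·z(miR-194-3p) −
0.124·z(miR-3677-3p)` with a maximally selected log-rank cutpoint search,
a risk-associated drug screen for IC50 tables, a ground-truth synthetic
cohort generator, and an `immumir` command-line interface
(`system.file("scripts", "immumir", package = "ImmuMiR")`) with
subcommands `simulate`, `scan`, `score`, `cutpoint`, `ssgsea`,
`drugscreen`.

## Worked example

Simulate a cohort with one planted regulation (`mir001` → `pathway1`,
effect 0.8), preprocess, and scan:

```r
library(ImmuMiR)

cfg <- cohortConfig(nSamples = 120, nMirna = 10, nGenes = 500,
                    nPathways = 3, genesPerPathway = 30)
co    <- generateCohort(cfg, seed = 42)
mirna <- log2p1(rpmNormalize(filterZeroFraction(cohortMirna(co))))
mrna  <- log2p1(rpmNormalize(filterZeroFraction(cohortMrna(co))))

res <- immuMiRNAScan(mirna, mrna, cohortPurity(co), cohortGeneSets(co),
                     scanConfig(nPerm = 2000, seed = 1))
head(res[order(-abs(res$mires)), ], 5)
#>    mirna_id  pathway     es        p    fdr  mires significant
#> 1    mir001 pathway1  0.984 0.000669 0.0142  0.999        TRUE
#> 19   mir007 pathway1 -0.811 0.000973 0.0142 -0.998        TRUE
#> 22   mir008 pathway1 -0.642 0.001833 0.0142 -0.996        TRUE
#> 28   mir010 pathway1 -0.655 0.001896 0.0142 -0.996        TRUE
#> 21   mir007 pathway3  0.192 0.983573 0.9836 -0.967       FALSE
```

The planted pair tops the list: `mir001`'s ranked gene list concentrates
`pathway1`'s genes at its head (ES 0.98), fewer than 0.07% of random
same-size gene sets score as high (p 0.00067), and the pair passes both
the `|miRES| > 0.995` and `FDR < 0.05` filters. The additional `pathway1`
hits illustrate a property of gene-set permutation: a planted program
makes the pathway's genes mutually correlated, which can lift other
miRNAs' enrichment above the random-set null (see the methods vignette).

Risk scoring with the packaged signature, and a survival cutpoint on the
simulated truth:

```r
sig <- iamipsSignature()
z <- ExpressionMatrix(matrix(c(1, 0, 0), 3, 1,
       dimnames = list(names(signatureCoefficients(sig)), "patient1")),
     "zscore")
riskScore(z, sig)
#>   sample_id score
#> 1  patient1 0.015     # 1 sd above the mean on miR-216a-5p alone

sv    <- cohortSurvival(co)
truth <- cohortTruth(co)
cut   <- optimalCutpoint(truth$scores, sv$time, sv$event)
prof  <- assignGroups(truth$scores, cut)
logRankStatistic(sv$time, sv$event, prof$group)
#> estimated cutpoint: -0.043 (true cutpoint: 0)
#> log-rank chi-square 26.9, p = 2.15e-07
```

The cutpoint search recovers the hazard step near the true threshold 0,
and the induced groups separate survival sharply.

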