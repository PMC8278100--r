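#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions a simulated cohort emulates: cohort size,
#' feature-space dimensions, the purity confounding acting on both miRNA and
#' gene expression, the planted miRNA-pathway regulations, and the survival
#' model tied to a true risk score. Defaults follow the scale of the
#' recovery analyses (200 samples, 50 miRNAs, 2000 genes, 5 disjoint
#' 40-gene pathways, one planted positive regulator of effect 0.8).
#'
#' @param nSamples number of patients (default 200).
#' @param nMirna,nGenes numbers of miRNAs (50) and genes (2000).
#' @param nPathways,genesPerPathway number (5) and size (40) of the disjoint
#'   pathway gene sets.
#' @param planted data.frame with columns mirna, pathway, direction (+1 or
#'   -1), effect (the regression coefficient of the standardized miRNA on
#'   its target genes' log expression); NULL for a null cohort. Identifiers
#'   are `mirNNN` / `pathwayN` as generated. Default: `mir001` up-regulates
#'   `pathway1` with effect 0.8.
#' @param plantedFraction fraction of a pathway's genes receiving the
#'   planted effect (default 0.6).
#' @param mirnaPuritySd,genePuritySd standard deviations of the per-feature
#'   purity slopes (confounding strengths; default 1 each).
#' @param noiseSd residual standard deviation of the latent log expression
#'   (default 0.5).
#' @param survCoefficients named-by-index numeric vector: coefficients of
#'   the true risk score over the standardized latent expression of the
#'   first `length(survCoefficients)` miRNAs (default c(1, -1, 0.5)).
#' @param cutpoint true risk-score cutpoint driving the hazard (default 0).
#' @param hazardRatio hazard ratio of scores above vs below the cutpoint
#'   (default 3).
#' @param weibullShape,weibullScale Weibull event-time parameters for the
#'   low-risk group (default shape 1.2, scale 40 time units).
#' @param censRate rate of the independent exponential censoring times
#'   (default 1/60, i.e. mean censoring time 60).
#' @return A validated named list.
#' @export
cohortConfig <- function(nSamples = 200, nMirna = 50, nGenes = 2000,
                         nPathways = 5, genesPerPathway = 40,
                         planted = data.frame(
                           mirna = "mir001", pathway = "pathway1",
                           direction = 1, effect = 0.8,
                           stringsAsFactors = FALSE
                         ),
                         plantedFraction = 0.6,
                         mirnaPuritySd = 1, genePuritySd = 1,
                         noiseSd = 0.5,
                         survCoefficients = c(1, -1, 0.5),
                         cutpoint = 0, hazardRatio = 3,
                         weibullShape = 1.2, weibullScale = 40,
                         censRate = 1 / 60) {
  stopifnot(nSamples >= 10, nMirna >= 1, nGenes >= 10,
            nPathways >= 0, genesPerPathway >= 1,
            plantedFraction > 0, plantedFraction <= 1,
            noiseSd > 0, hazardRatio > 0,
            weibullShape > 0, weibullScale > 0, censRate > 0,
            length(survCoefficients) <= nMirna)
  if (nPathways * genesPerPathway > nGenes) {
    stop("pathways exceed the gene universe: need nPathways * genesPerPathway <= nGenes",
         call. = FALSE)
  }
  cfg <- list(nSamples = as.integer(nSamples), nMirna = as.integer(nMirna),
              nGenes = as.integer(nGenes), nPathways = as.integer(nPathways),
              genesPerPathway = as.integer(genesPerPathway),
              planted = planted, plantedFraction = plantedFraction,
              mirnaPuritySd = mirnaPuritySd, genePuritySd = genePuritySd,
              noiseSd = noiseSd, survCoefficients = survCoefficients,
              cutpoint = cutpoint, hazardRatio = hazardRatio,
              weibullShape = weibullShape, weibullScale = weibullScale,
              censRate = censRate)
  mirnaIds <- .synthIds("mir", cfg$nMirna)
  pathIds <- .synthIds("pathway", cfg$nPathways, pad = FALSE)
  if (!is.null(planted) && nrow(planted)) {
    stopifnot(all(c("mirna", "pathway", "direction", "effect") %in%
                    names(planted)))
    if (!all(planted$mirna %in% mirnaIds)) {
      stop("planted miRNA id(s) outside the generated universe", call. = FALSE)
    }
    if (!all(planted$pathway %in% pathIds)) {
      stop("planted pathway id(s) outside the generated universe", call. = FALSE)
    }
    if (!all(planted$direction %in% c(-1, 1))) {
      stop("planted direction must be -1 or +1", call. = FALSE)
    }
  }
  cfg
}

.synthIds <- function(prefix, n, pad = TRUE) {
  if (n == 0L) return(character(0))
  if (!pad) return(paste0(prefix, seq_len(n)))
  width <- max(3L, nchar(as.character(n)))
  sprintf("%s%0*d", prefix, width, seq_len(n))
}

#' Generate a synthetic cohort with recorded ground truth
#'
#' Simulates a bulk tumour cohort with the statistical structure the
#' pipeline assumes, so that every stage can be exercised and checked
#' against known truth without any external data:
#' \itemize{
#'   \item tumour purity ~ Uniform(0.3, 0.9);
#'   \item latent miRNA log expression = baseline + (purity slope) x purity
#'     + Gaussian noise — purity acts as a confounder on both sides;
#'   \item latent gene log expression likewise, plus, for each planted
#'     regulation, `direction * effect * z(miRNA)` added to a fraction of
#'     the target pathway's genes;
#'   \item observed counts ~ Poisson(exp(latent log expression)), so the
#'     count-level zero filter is exercised;
#'   \item survival: Weibull event times whose hazard is multiplied by
#'     `hazardRatio` when the true risk score (a linear combination of
#'     standardized latent miRNA expression) exceeds the true cutpoint,
#'     with independent exponential censoring.
#' }
#' All draws derive from the single `seed`; the same seed reproduces the
#' cohort bit for bit.
#'
#' @param config a [cohortConfig()] list.
#' @param seed integer seed (required).
#' @return A [SyntheticCohort-class]. Its `truth` slot records the planted
#'   regulations (with the affected target genes), the true per-sample
#'   scores, the cutpoint and the hazard ratio.
#' @examples
#' co <- generateCohort(cohortConfig(nSamples = 40, nMirna = 5, nGenes = 200,
#'                                   nPathways = 2, genesPerPathway = 15),
#'                      seed = 1)
#' co
#' @export
generateCohort <- function(config = cohortConfig(), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  old <- .saveSeed()
  on.exit(.restoreSeed(old), add = TRUE)
  set.seed(seed)

  n <- config$nSamples
  sampleIds <- .synthIds("sample", n)
  mirnaIds <- .synthIds("mir", config$nMirna)
  geneIds <- .synthIds("gene", config$nGenes)
  pathIds <- .synthIds("pathway", config$nPathways, pad = FALSE)

  purity <- stats::setNames(stats::runif(n, 0.3, 0.9), sampleIds)

  muM <- stats::runif(config$nMirna, 2, 4)
  deltaM <- stats::rnorm(config$nMirna, 0, config$mirnaPuritySd)
  latentM <- muM + outer(deltaM, purity) +
    matrix(stats::rnorm(config$nMirna * n, 0, config$noiseSd),
           config$nMirna, n)
  dimnames(latentM) <- list(mirnaIds, sampleIds)

  # disjoint pathway memberships drawn from the gene universe
  shuffled <- sample(geneIds)
  geneSets <- stats::setNames(lapply(seq_len(config$nPathways), function(k) {
    sort(shuffled[seq.int((k - 1L) * config$genesPerPathway + 1L,
                          k * config$genesPerPathway)])
  }), pathIds)

  muG <- stats::runif(config$nGenes, 2, 5)
  bG <- stats::rnorm(config$nGenes, 0, config$genePuritySd)
  latentG <- muG + outer(bG, purity)
  dimnames(latentG) <- list(geneIds, sampleIds)

  planted <- config$planted
  targetGenes <- list()
  if (!is.null(planted) && nrow(planted)) {
    for (r in seq_len(nrow(planted))) {
      members <- geneSets[[planted$pathway[r]]]
      nTarget <- max(1L, ceiling(config$plantedFraction * length(members)))
      targets <- members[seq_len(nTarget)]
      targetGenes[[r]] <- targets
      mz <- as.numeric(scale(latentM[planted$mirna[r], ]))
      latentG[targets, ] <- latentG[targets, ] +
        rep(planted$direction[r] * planted$effect[r] * mz,
            each = length(targets))
    }
    planted$fraction <- config$plantedFraction
  } else {
    planted <- data.frame(mirna = character(0), pathway = character(0),
                          direction = numeric(0), effect = numeric(0),
                          fraction = numeric(0), stringsAsFactors = FALSE)
  }
  latentG <- latentG + matrix(stats::rnorm(config$nGenes * n, 0,
                                           config$noiseSd),
                              config$nGenes, n)

  mirnaCounts <- matrix(stats::rpois(config$nMirna * n, exp(latentM)),
                        config$nMirna, n, dimnames = dimnames(latentM))
  mrnaCounts <- matrix(stats::rpois(config$nGenes * n, exp(latentG)),
                       config$nGenes, n, dimnames = dimnames(latentG))

  nsig <- length(config$survCoefficients)
  zM <- t(scale(t(latentM[seq_len(nsig), , drop = FALSE])))
  scores <- stats::setNames(
    as.numeric(crossprod(zM, config$survCoefficients)), sampleIds
  )
  mult <- ifelse(scores > config$cutpoint, config$hazardRatio, 1)
  # Weibull hazard scales as scale^(-shape); dividing the scale by
  # mult^(1/shape) multiplies the hazard by mult
  eventTime <- stats::rweibull(n, shape = config$weibullShape,
                               scale = config$weibullScale /
                                 mult^(1 / config$weibullShape))
  censTime <- stats::rexp(n, rate = config$censRate)
  survivalDf <- data.frame(
    sample_id = sampleIds,
    time = pmax(pmin(eventTime, censTime), 1e-3),
    event = as.integer(eventTime <= censTime),
    stringsAsFactors = FALSE
  )

  methods::new("SyntheticCohort",
    mirna = ExpressionMatrix(mirnaCounts, "counts"),
    mrna = ExpressionMatrix(mrnaCounts, "counts"),
    purity = purity, geneSets = geneSets, survival = survivalDf,
    truth = list(planted = planted, targetGenes = targetGenes,
                 scores = scores, cutpoint = config$cutpoint,
                 hazardRatio = config$hazardRatio,
                 survCoefficients = config$survCoefficients)
  )
}

#' Generate a synthetic drug-response (IC50) table
#'
#' The first `nPlanted` drugs are linear in the supplied risk score
#' (`slope * score + Gaussian noise`); the remaining drugs are independent
#' standard Gaussian noise. All values are interpreted as log2-scale IC50.
#'
#' @param scores named numeric risk scores (samples).
#' @param nDrugs total number of drugs (default 20).
#' @param nPlanted number of score-associated drugs (default 2; 0 gives a
#'   pure null table).
#' @param slope linear coefficient of the planted drugs (default 2).
#' @param noiseSd residual noise of the planted drugs (default 0.2).
#' @param seed integer seed (required).
#' @return A list with `ic50` (drugs x samples matrix) and `planted`
#'   (character vector of the planted drug ids).
#' @export
generateDrugTable <- function(scores, nDrugs = 20, nPlanted = 2, slope = 2,
                              noiseSd = 0.2, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(nPlanted >= 0, nPlanted <= nDrugs, !is.null(names(scores)))
  old <- .saveSeed()
  on.exit(.restoreSeed(old), add = TRUE)
  set.seed(seed)
  n <- length(scores)
  drugIds <- .synthIds("drug", nDrugs)
  ic50 <- matrix(stats::rnorm(nDrugs * n), nDrugs, n,
                 dimnames = list(drugIds, names(scores)))
  if (nPlanted > 0L) {
    for (i in seq_len(nPlanted)) {
      ic50[i, ] <- slope * as.numeric(scores) + stats::rnorm(n, 0, noiseSd)
    }
  }
  list(ic50 = ic50, planted = drugIds[seq_len(nPlanted)])
}

#' Write a synthetic cohort as the pipeline's standard input files
#'
#' Writes miRNA counts, mRNA counts, purity, gene sets (GMT), survival and
#' the planted ground truth into a directory, in the delimited formats the
#' readers of this package consume.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if absent).
#' @return Named character vector of the written file paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(methods::is(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    mirna = file.path(dir, "mirna_counts.tsv"),
    mrna = file.path(dir, "mrna_counts.tsv"),
    purity = file.path(dir, "purity.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "truth_planted.tsv"),
    scores = file.path(dir, "truth_scores.tsv")
  )
  writeExpressionTable(cohortMirna(cohort), paths["mirna"])
  writeExpressionTable(cohortMrna(cohort), paths["mrna"])
  utils::write.table(
    data.frame(sample_id = names(cohortPurity(cohort)),
               purity = as.numeric(cohortPurity(cohort))),
    paths["purity"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeGMT(cohortGeneSets(cohort), paths["gene_sets"])
  utils::write.table(cohortSurvival(cohort), paths["survival"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohortTruth(cohort)
  utils::write.table(truth$planted, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(truth$scores),
               score = as.numeric(truth$scores),
               cutpoint = truth$cutpoint),
    paths["scores"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
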