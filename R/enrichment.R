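#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Scores whether a gene set concentrates at the top or bottom of a ranked
#' gene list. Walking the list from top to bottom, the running sum advances
#' by `|rs|^w / sum(|rs_hit|^w)` at each set member ("hit") and retreats by
#' `1 / (N - N_hit)` at each non-member; the enrichment score (ES) is the
#' running-sum deviation of maximal absolute value, signed. ES lies in
#' \[-1, 1\]: +1 means all members sit at the very top, -1 at the very
#' bottom.
#'
#' With `weightExponent = 0` every hit advances uniformly and ES reduces to
#' the classic Kolmogorov-Smirnov statistic against the hit-position ECDF.
#' If every hit weight is zero while `weightExponent > 0` (all member
#' p-values exactly 1), the score falls back to unweighted steps with a
#' warning.
#'
#' @param ranked data.frame with columns `gene_id`, `rs`, ordered by
#'   descending rank score (see [rankGenes()]).
#' @param geneSet character vector of member gene ids.
#' @param weightExponent non-negative weight exponent (default 1).
#' @return Numeric enrichment score.
#' @export
enrichmentScore <- function(ranked, geneSet, weightExponent = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene_id", "rs") %in% names(ranked)))
  if (weightExponent < 0) stop("weightExponent must be >= 0", call. = FALSE)
  pos <- which(ranked$gene_id %in% geneSet)
  N <- nrow(ranked)
  if (length(pos) == 0L) {
    stop("gene set has no member in the ranked list", call. = FALSE)
  }
  if (length(pos) >= N) {
    stop("gene set covers the whole ranked list", call. = FALSE)
  }
  w <- abs(ranked$rs)^weightExponent
  if (weightExponent > 0 && all(w[pos] == 0)) {
    warning("all hit weights are zero; falling back to unweighted steps",
            call. = FALSE)
    w <- rep(1, N)
  }
  as.numeric(.cppEsSets(w, matrix(as.integer(pos), ncol = 1L)))
}

#' Gene-set permutation test for an enrichment score
#'
#' Builds the null distribution of the enrichment score by drawing `nPerm`
#' random gene sets of the same (effective) size from the ranked universe
#' and rescoring. The p-value conditions on the sign of the observed score
#' so that it composes coherently with the signed [miRES()] transform:
#' \deqn{p = (1 + \#\{|ES_0| \ge |ES|,\ \mathrm{sign}(ES_0) =
#'   \mathrm{sign}(ES)\}) / (1 + \#\{\mathrm{sign}(ES_0) =
#'   \mathrm{sign}(ES)\})}
#' The pseudocount keeps p in (0, 1]; the smallest attainable p is
#' 1/(1 + nPerm).
#'
#' @param ranked ranked data.frame (`gene_id`, `rs`), descending rs.
#' @param geneSet character vector of member gene ids.
#' @param nPerm number of random sets (>= 100; default 1000).
#' @param seed optional integer; when given, the RNG is seeded locally so
#'   repeated calls reproduce. When NULL the current RNG stream is used
#'   (as inside [immuMiRNAScan()], which seeds once).
#' @param weightExponent weight exponent passed to the score.
#' @return A list with `es` (observed score), `p`, and `nPerm`.
#' @export
permutationTest <- function(ranked, geneSet, nPerm = 1000, seed = NULL,
                            weightExponent = 1) {
  if (nPerm < 100) stop("nPerm must be >= 100", call. = FALSE)
  N <- nrow(ranked)
  k <- sum(ranked$gene_id %in% geneSet)
  if (k >= N) stop("set size must be smaller than the ranked universe",
                   call. = FALSE)
  es <- enrichmentScore(ranked, geneSet, weightExponent)
  if (!is.null(seed)) {
    old <- .saveSeed()
    on.exit(.restoreSeed(old), add = TRUE)
    set.seed(seed)
  }
  w <- abs(ranked$rs)^weightExponent
  nullEs <- .nullEs(w, N, k, nPerm)
  list(es = es, p = .permPvalue(es, nullEs), nPerm = nPerm)
}

# null ES for nPerm random size-k sets over a ranked universe of size N
.nullEs <- function(w, N, k, nPerm) {
  posMat <- vapply(seq_len(nPerm), function(i) sample.int(N, k),
                   integer(k))
  as.numeric(.cppEsSets(w, matrix(posMat, nrow = k)))
}

.permPvalue <- function(es, nullEs) {
  s <- sign(es)
  if (s == 0) {
    warning("observed ES is exactly 0; p set to 1", call. = FALSE)
    return(1)
  }
  same <- sign(nullEs) == s
  (1 + sum(same & abs(nullEs) >= abs(es))) / (1 + sum(same))
}

.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' miRES: combine enrichment sign and permutation p-value
#'
#' Maps a (signed enrichment score, permutation p-value) pair onto a single
#' score in \[-1, 1\]:
#' `miRES = 1 - 2p` when `es > 0`, `miRES = 2p - 1` when `es < 0`.
#' A strongly significant positive enrichment approaches +1, a strongly
#' significant negative enrichment approaches -1, and p = 0.5 maps to 0
#' either way. `es = 0` is rejected: the transform is undefined there.
#'
#' @param es enrichment score(s), non-zero.
#' @param p permutation p-value(s) in (0, 1], same length.
#' @return Numeric miRES score(s) in \[-1, 1\].
#' @examples
#' miRES(0.7, 0.0025)  # 0.995
#' miRES(-0.7, 0.0025) # -0.995
#' @export
miRES <- function(es, p) {
  if (any(es == 0)) stop("miRES is undefined at es = 0", call. = FALSE)
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  ifelse(es > 0, 1 - 2 * p, 2 * p - 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`); input order is preserved.
#'
#' @param p numeric p-values in (0, 1].
#' @return Adjusted p-values (q-values), same order; empty in, empty out.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Scan configuration for [immuMiRNAScan()]
#'
#' @param nPerm gene-set permutations per null distribution (default 1000).
#' @param seed integer seed controlling every random draw of the scan.
#' @param weightExponent hit-weight exponent of the enrichment score.
#' @param miresThreshold significance calls require |miRES| strictly above
#'   this (default 0.995).
#' @param fdrThreshold and BH FDR strictly below this (default 0.05).
#' @return A named list of validated settings.
#' @export
scanConfig <- function(nPerm = 1000, seed = 1, weightExponent = 1,
                       miresThreshold = 0.995, fdrThreshold = 0.05) {
  stopifnot(nPerm >= 100, weightExponent >= 0,
            miresThreshold >= 0, miresThreshold <= 1,
            fdrThreshold > 0, fdrThreshold <= 1)
  list(nPerm = as.integer(nPerm), seed = as.integer(seed),
       weightExponent = weightExponent,
       miresThreshold = miresThreshold, fdrThreshold = fdrThreshold)
}

#' Scan all miRNA x immune-pathway pairs for candidate regulators
#'
#' The full regulator scan: for every miRNA, purity-adjusted partial
#' correlations against all genes are turned into rank scores
#' ([rankScore()]), the genes are ranked, and every pathway is scored by the
#' weighted enrichment statistic with a gene-set permutation p-value
#' ([permutationTest()]). BH FDR is computed across all miRNA-pathway pairs
#' of the scan, miRES combines each pair's enrichment sign and raw
#' permutation p, and pairs with `|miRES| >` `miresThreshold` and
#' `fdr <` `fdrThreshold` are flagged significant.
#'
#' Pathways with the same number of genes in the ranked universe share one
#' permutation null per miRNA (random sets depend only on the list and the
#' set size). Given the same seed the scan is fully reproducible, including
#' record order.
#'
#' @param mirna,mrna [ExpressionMatrix-class] objects (log2 scale
#'   recommended) sharing at least 4 samples.
#' @param purity named numeric purity vector, or NULL (plain correlation
#'   fallback, with a warning).
#' @param geneSets named list of character gene-set vectors.
#' @param config a [scanConfig()] list.
#' @return data.frame with one row per miRNA-pathway pair: mirna_id,
#'   pathway, es, p, fdr, mires, significant.
#' @examples
#' co <- generateCohort(cohortConfig(nSamples = 60, nMirna = 5, nGenes = 300,
#'                                   nPathways = 2, genesPerPathway = 20),
#'                      seed = 7)
#' lm2 <- log2p1(rpmNormalize(cohortMirna(co)))
#' lg2 <- log2p1(rpmNormalize(cohortMrna(co)))
#' res <- immuMiRNAScan(lm2, lg2, cohortPurity(co), cohortGeneSets(co),
#'                      scanConfig(nPerm = 100, seed = 1))
#' head(res)
#' @export
immuMiRNAScan <- function(mirna, mrna, purity, geneSets,
                          config = scanConfig()) {
  emptyResult <- data.frame(
    mirna_id = character(0), pathway = character(0), es = numeric(0),
    p = numeric(0), fdr = numeric(0), mires = numeric(0),
    significant = logical(0), stringsAsFactors = FALSE
  )
  if (length(geneSets) == 0L) return(emptyResult)
  al <- alignSamples(mirna, mrna, purity)
  if (ncol(exprValues(al$mirna)) < 4L) {
    stop("matrices must share at least 4 samples", call. = FALSE)
  }
  M <- exprValues(al$mirna)
  G <- exprValues(al$mrna)
  if (is.null(al$purity)) {
    warning("no purity supplied; using plain Pearson correlations",
            call. = FALSE)
  }
  pc <- .partialCorMatrix(M, G, al$purity)
  rsMat <- rankScore(pc$p, pc$pcc)

  old <- .saveSeed()
  on.exit(.restoreSeed(old), add = TRUE)
  set.seed(config$seed)

  geneIds <- rownames(G)
  N <- length(geneIds)
  pathNames <- names(geneSets)
  sizes <- vapply(geneSets, function(s) sum(geneIds %in% s), integer(1L))
  if (any(sizes == 0L)) {
    stop("gene set(s) with no member in the expression matrix: ",
         paste(pathNames[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  if (any(sizes >= N)) {
    stop("gene set(s) covering the whole gene universe: ",
         paste(pathNames[sizes >= N], collapse = ", "), call. = FALSE)
  }

  nMirna <- nrow(M)
  rows <- vector("list", nMirna)
  for (i in seq_len(nMirna)) {
    rs <- rsMat[i, ]
    ord <- order(-rs, geneIds, method = "radix")
    rsSorted <- rs[ord]
    idSorted <- geneIds[ord]
    w <- abs(rsSorted)^config$weightExponent
    rankIndex <- match(geneIds, idSorted)

    esObs <- numeric(length(geneSets))
    pObs <- numeric(length(geneSets))
    for (k in sort(unique(sizes))) {
      nullEs <- .nullEs(w, N, k, config$nPerm)
      for (j in which(sizes == k)) {
        pos <- rankIndex[geneIds %in% geneSets[[j]]]
        esObs[j] <- as.numeric(
          .cppEsSets(w, matrix(as.integer(pos), ncol = 1L))
        )
        pObs[j] <- .permPvalue(esObs[j], nullEs)
      }
    }
    rows[[i]] <- data.frame(
      mirna_id = rownames(M)[i], pathway = pathNames,
      es = esObs, p = pObs, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- bhAdjust(res$p)
  if (any(res$es == 0)) {
    warning("pair(s) with ES exactly 0: miRES undefined, set to NA",
            call. = FALSE)
  }
  res$mires <- ifelse(res$es == 0, NA_real_,
                      ifelse(res$es > 0, 1 - 2 * res$p, 2 * res$p - 1))
  res$significant <- !is.na(res$mires) &
    abs(res$mires) > config$miresThreshold &
    res$fdr < config$fdrThreshold
  res
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Per-sample enrichment scoring used to quantify, e.g., the relative
#' abundance of immune cell types from their marker gene sets. For each
#' sample, genes are ranked by expression; the score of a set is the sum
#' over all list positions of the difference between the weighted in-set
#' ECDF (ascending-rank weights raised to `alpha`) and the uniform
#' out-of-set ECDF.
#'
#' @param expr an [ExpressionMatrix-class] (log2 or tpm scale recommended).
#' @param geneSets named list of character gene-set vectors.
#' @param alpha rank-weight exponent (default 0.25).
#' @param rescale if TRUE, min-max rescale each set's scores across samples
#'   to \[0, 1\] (raw scores by default).
#' @return Numeric matrix, gene sets x samples.
#' @export
ssgseaScores <- function(expr, geneSets, alpha = 0.25, rescale = FALSE) {
  stopifnot(methods::is(expr, "ExpressionMatrix"), alpha >= 0)
  v <- exprValues(expr)
  N <- nrow(v)
  out <- matrix(0, nrow = length(geneSets), ncol = ncol(v),
                dimnames = list(names(geneSets), colnames(v)))
  memberIdx <- lapply(geneSets, function(s) which(rownames(v) %in% s))
  empty <- lengths(memberIdx) == 0L
  if (any(empty)) {
    warning("gene set(s) with no gene in the matrix scored 0: ",
            paste(names(geneSets)[empty], collapse = ", "), call. = FALSE)
  }
  for (s in seq_len(ncol(v))) {
    ord <- order(-v[, s], rownames(v), method = "radix")
    # ascending rank: the most highly expressed gene gets rank N
    rankWeight <- (N - seq_len(N) + 1)^alpha
    inv <- integer(N)
    inv[ord] <- seq_len(N)
    for (g in seq_along(geneSets)) {
      idx <- memberIdx[[g]]
      if (length(idx) == 0L || length(idx) >= N) next
      hit <- logical(N)
      hit[inv[idx]] <- TRUE
      win <- ifelse(hit, rankWeight, 0)
      pin <- cumsum(win) / sum(win)
      pout <- cumsum(!hit) / (N - length(idx))
      out[g, s] <- sum(pin - pout)
    }
  }
  if (rescale) {
    rng <- apply(out, 1L, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1
    out <- (out - rng[1L, ]) / span
  }
  out
}
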