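#' Purity-adjusted partial correlation between two expression vectors
#'
#' First-order partial correlation between miRNA expression `x` and gene
#' expression `y`, controlling for tumour purity `z`:
#' \deqn{PCC = (R_{MG} - R_{MP} R_{GP}) /
#'   (\sqrt{1 - R_{MP}^2}\,\sqrt{1 - R_{GP}^2})}
#' where \eqn{R_{MG}}, \eqn{R_{MP}}, \eqn{R_{GP}} are the plain Pearson
#' correlations miRNA-gene, miRNA-purity and gene-purity. Bulk expression of
#' both species co-varies with the malignant-cell fraction, so the plain
#' miRNA-gene correlation is confounded by purity; partialling it out removes
#' that shared component.
#'
#' The two-sided p-value uses the standard first-order partial-correlation
#' test, `t = pcc * sqrt((n - 3) / (1 - pcc^2))` on `n - 3` degrees of
#' freedom (one covariate); `|pcc|` is clipped to `1 - 1e-12` before the
#' t transform so perfect correlations stay finite.
#'
#' If `z` is NULL the function falls back to the plain Pearson correlation
#' (equivalent to \eqn{R_{MP} = R_{GP} = 0}) with a warning, and the test
#' keeps `n - 3` degrees of freedom for comparability.
#'
#' @param x,y numeric sample vectors of equal length `n >= 4`, non-constant.
#' @param z numeric purity vector (same length), or NULL for no adjustment.
#' @return A list with elements `pcc`, `p`, `n`, and the component
#'   correlations `r_mg`, `r_mp`, `r_gp`.
#' @examples
#' set.seed(1)
#' x <- rnorm(20); z <- rnorm(20); y <- 0.5 * x + 0.5 * z + rnorm(20, sd = 0.3)
#' partialCorrelation(x, y, z)
#' @export
partialCorrelation <- function(x, y, z = NULL) {
  n <- length(x)
  if (length(y) != n || (!is.null(z) && length(z) != n)) {
    stop("x, y and z must have equal length", call. = FALSE)
  }
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("x and y must be non-constant", call. = FALSE)
  }
  if (is.null(z)) {
    warning("no purity supplied; falling back to plain Pearson correlation",
            call. = FALSE)
    r_mp <- r_gp <- 0
  } else {
    if (stats::sd(z) == 0) stop("purity vector is constant", call. = FALSE)
    r_mp <- stats::cor(x, z)
    r_gp <- stats::cor(y, z)
    if (abs(r_mp) >= 1 - 1e-10 || abs(r_gp) >= 1 - 1e-10) {
      stop("purity is perfectly collinear with x or y (|R| = 1)",
           call. = FALSE)
    }
  }
  r_mg <- stats::cor(x, y)
  pcc <- (r_mg - r_mp * r_gp) / (sqrt(1 - r_mp^2) * sqrt(1 - r_gp^2))
  pcc <- min(max(pcc, -1), 1)
  p <- .pccPvalue(pcc, n)
  list(pcc = pcc, p = p, n = n, r_mg = r_mg, r_mp = r_mp, r_gp = r_gp)
}

# two-sided p for a first-order partial correlation on n - 3 df; vectorized
.pccPvalue <- function(pcc, n) {
  r <- pmin(pmax(pcc, -1 + 1e-12), 1 - 1e-12)
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 3)
}

#' Rank score from a partial-correlation test
#'
#' The gene-ordering statistic fed into enrichment analysis:
#' `RS = -log10(p) * sign(pcc)`. Strong positive associations get large
#' positive scores, strong negative associations large negative scores, and
#' non-associations sit near zero. `p` is floored at 1e-300 so the score
#' stays finite; `sign(0) = 0`.
#'
#' @param p p-value(s) in (0, 1].
#' @param pcc partial correlation(s), same length.
#' @return Numeric rank score(s).
#' @examples
#' rankScore(0.01, 0.6)   #  2
#' rankScore(0.001, -0.4) # -3
#' @export
rankScore <- function(p, pcc) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  -log10(pmax(p, 1e-300)) * sign(pcc)
}

#' Purity-adjusted associations between one miRNA and all genes
#'
#' Computes, for a single miRNA, the purity-adjusted partial correlation,
#' two-sided p-value and rank score against every gene of an expression
#' matrix. This is the per-miRNA association table behind
#' [immuMiRNAScan()].
#'
#' @param mirnaExpr numeric vector of the miRNA's expression across samples
#'   (or a 1-row [ExpressionMatrix-class]).
#' @param mrna an [ExpressionMatrix-class] of gene expression over the same
#'   samples (same order).
#' @param purity named or plain numeric purity vector, or NULL.
#' @param mirnaId identifier recorded in the output.
#' @return data.frame with columns mirna_id, gene_id, r_mg, r_mp, r_gp,
#'   pcc, p, rs, n (one row per gene).
#' @export
mirnaGeneAssociations <- function(mirnaExpr, mrna, purity = NULL,
                                  mirnaId = "miRNA") {
  if (methods::is(mirnaExpr, "ExpressionMatrix")) {
    stopifnot(nrow(exprValues(mirnaExpr)) == 1L)
    mirnaId <- featureIds(mirnaExpr)
    mirnaExpr <- as.numeric(exprValues(mirnaExpr)[1L, ])
  }
  G <- exprValues(mrna)
  res <- .partialCorMatrix(matrix(mirnaExpr, nrow = 1L), G, purity)
  data.frame(
    mirna_id = mirnaId, gene_id = rownames(G),
    r_mg = as.numeric(res$r_mg), r_mp = res$r_mp[1L],
    r_gp = as.numeric(res$r_gp),
    pcc = as.numeric(res$pcc), p = as.numeric(res$p),
    rs = rankScore(as.numeric(res$p), as.numeric(res$pcc)),
    n = length(mirnaExpr), stringsAsFactors = FALSE
  )
}

# Vectorized partial correlations of every row of M against every row of G,
# adjusting for one covariate. Returns miRNA x gene matrices.
.partialCorMatrix <- function(M, G, purity = NULL) {
  n <- ncol(M)
  stopifnot(ncol(G) == n, n >= 4L)
  r_mg <- stats::cor(t(M), t(G))
  if (is.null(purity)) {
    r_mp <- rep(0, nrow(M))
    r_gp <- rep(0, nrow(G))
  } else {
    purity <- as.numeric(purity)
    if (stats::sd(purity) == 0) stop("purity vector is constant", call. = FALSE)
    r_mp <- as.numeric(stats::cor(t(M), purity))
    r_gp <- as.numeric(stats::cor(t(G), purity))
    if (any(abs(r_mp) >= 1 - 1e-10) || any(abs(r_gp) >= 1 - 1e-10)) {
      stop("a feature is perfectly collinear with purity (|R| = 1)",
           call. = FALSE)
    }
  }
  pcc <- (r_mg - outer(r_mp, r_gp)) /
    (sqrt(1 - r_mp^2) %o% sqrt(1 - r_gp^2))
  pcc <- pmin(pmax(pcc, -1), 1)
  p <- .pccPvalue(pcc, n)
  list(pcc = pcc, p = p, r_mg = r_mg, r_mp = r_mp, r_gp = r_gp)
}

#' Rank genes by rank score
#'
#' Orders an association table by descending rank score; ties are broken by
#' gene id (ascending) so the ordering is deterministic under input
#' permutation.
#'
#' @param records data.frame with columns `gene_id` and `rs` (one row per
#'   gene), e.g. from [mirnaGeneAssociations()].
#' @return The same data.frame, reordered; row names dropped.
#' @export
rankGenes <- function(records) {
  stopifnot(is.data.frame(records), all(c("gene_id", "rs") %in% names(records)))
  if (anyDuplicated(records$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(records$gene_id[duplicated(records$gene_id)]),
               collapse = ", "), call. = FALSE)
  }
  ord <- order(-records$rs, records$gene_id, method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
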