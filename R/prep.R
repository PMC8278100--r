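#' Library-size normalization to reads per million
#'
#' Scales every sample column of a count matrix so that it sums to 10^6
#' (reads per million, the convention for miRNA counts). For mRNA, use
#' [tpmNormalize()] which additionally corrects for transcript length.
#'
#' @param x an [ExpressionMatrix-class] in state `"counts"`.
#' @return An [ExpressionMatrix-class] in state `"rpm"`.
#' @export
rpmNormalize <- function(x) {
  .requireState(x, "counts")
  v <- exprValues(x)
  tot <- colSums(v)
  zero <- tot == 0
  if (any(zero)) {
    stop("all-zero sample column(s): ",
         paste(colnames(v)[zero], collapse = ", "), call. = FALSE)
  }
  ExpressionMatrix(sweep(v, 2L, tot, "/") * 1e6, state = "rpm")
}

#' Length-corrected normalization to transcripts per million
#'
#' Divides each feature's counts by its transcript length in kilobases, then
#' scales every sample column to sum 10^6 (transcripts per million).
#'
#' @param x an [ExpressionMatrix-class] in state `"counts"`.
#' @param lengthsKb named numeric vector of transcript lengths in kilobases;
#'   must cover every feature of `x`.
#' @return An [ExpressionMatrix-class] in state `"tpm"`.
#' @export
tpmNormalize <- function(x, lengthsKb) {
  .requireState(x, "counts")
  v <- exprValues(x)
  missing <- setdiff(rownames(v), names(lengthsKb))
  if (length(missing)) {
    stop("missing transcript length(s) for: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  len <- lengthsKb[rownames(v)]
  if (any(!is.finite(len) | len <= 0)) {
    stop("transcript lengths must be positive and finite", call. = FALSE)
  }
  rate <- v / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    stop("all-zero sample column(s): ",
         paste(colnames(v)[zero], collapse = ", "), call. = FALSE)
  }
  ExpressionMatrix(sweep(rate, 2L, tot, "/") * 1e6, state = "tpm")
}

#' log2(x + 1) transform
#'
#' RNA-seq abundances are heavily right-skewed on the linear scale; the
#' pipeline works on log2-transformed values. The +1 offset maps the exact
#' zeros that survive library-size normalization to zero.
#'
#' @param x an [ExpressionMatrix-class] in state `"rpm"` or `"tpm"`, all
#'   values non-negative.
#' @return An [ExpressionMatrix-class] in state `"log2"`.
#' @export
log2p1 <- function(x) {
  .requireState(x, c("rpm", "tpm"))
  v <- exprValues(x)
  if (any(v < 0)) stop("negative values cannot be log2-transformed",
                       call. = FALSE)
  ExpressionMatrix(log2(v + 1), state = "log2")
}

#' Standardize each feature across samples
#'
#' Transforms every feature row to mean 0, standard deviation 1 (sample
#' standard deviation, n - 1 denominator). Standardization is per cohort and
#' makes risk-score coefficients transferable between data sets. Constant
#' rows cannot be standardized; they become all-zero and their ids are
#' reported in a warning.
#'
#' @param x an [ExpressionMatrix-class], typically in state `"log2"`.
#' @param requireLog2 if TRUE (default) insist on log2 input state.
#' @return An [ExpressionMatrix-class] in state `"zscore"`.
#' @export
zscoreRows <- function(x, requireLog2 = TRUE) {
  if (requireLog2) .requireState(x, "log2")
  v <- exprValues(x)
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  z <- (v - mu) / ifelse(const, 1, sdv)
  if (any(const)) {
    z[const, ] <- 0
    warning("constant feature row(s) set to zero: ",
            paste(utils::head(rownames(v)[const], 5L), collapse = ", "),
            call. = FALSE)
  }
  ExpressionMatrix(z, state = "zscore")
}

#' Drop features with too many zero counts
#'
#' Removes every feature whose fraction of zero-count samples is strictly
#' greater than `maxZeroFrac` (default 0.5, i.e. zero reads in more than 50%
#' of samples). Feature order is preserved.
#'
#' @param x an [ExpressionMatrix-class] in state `"counts"`.
#' @param maxZeroFrac maximum tolerated zero fraction (strict inequality).
#' @return The filtered [ExpressionMatrix-class], still in state `"counts"`.
#' @export
filterZeroFraction <- function(x, maxZeroFrac = 0.5) {
  .requireState(x, "counts")
  v <- exprValues(x)
  frac <- rowMeans(v == 0)
  keep <- frac <= maxZeroFrac
  ExpressionMatrix(v[keep, , drop = FALSE], state = "counts")
}

#' Align data sets on their common samples
#'
#' Subsets miRNA expression, mRNA expression and the optional purity and
#' survival inputs to the intersection of their sample ids (in the miRNA
#' matrix's order) and reports how many samples were dropped.
#'
#' @param mirna,mrna [ExpressionMatrix-class] objects.
#' @param purity optional named numeric purity vector.
#' @param survival optional survival data.frame (sample_id, time, event).
#' @return A list with elements `mirna`, `mrna`, `purity`, `survival`
#'   (the latter two NULL if not supplied) and `dropped`, the number of
#'   sample ids not shared by all inputs.
#' @export
alignSamples <- function(mirna, mrna, purity = NULL, survival = NULL) {
  idSets <- list(sampleIds(mirna), sampleIds(mrna))
  if (!is.null(purity)) idSets <- c(idSets, list(names(purity)))
  if (!is.null(survival)) idSets <- c(idSets, list(survival$sample_id))
  common <- Reduce(intersect, idSets)
  if (length(common) == 0L) stop("no samples shared by all inputs",
                                 call. = FALSE)
  common <- sampleIds(mirna)[sampleIds(mirna) %in% common]
  dropped <- length(unique(unlist(idSets))) - length(common)
  if (dropped > 0L) {
    message(sprintf("alignSamples: dropped %d sample(s) not shared by all inputs",
                    dropped))
  }
  out <- list(
    mirna = ExpressionMatrix(exprValues(mirna)[, common, drop = FALSE],
                             state = exprState(mirna)),
    mrna = ExpressionMatrix(exprValues(mrna)[, common, drop = FALSE],
                            state = exprState(mrna)),
    purity = if (is.null(purity)) NULL else purity[common],
    survival = if (is.null(survival)) NULL else {
      sv <- survival[match(common, survival$sample_id), , drop = FALSE]
      rownames(sv) <- NULL
      sv
    },
    dropped = dropped
  )
  out
}

.requireState <- function(x, states) {
  stopifnot(methods::is(x, "ExpressionMatrix"))
  if (!exprState(x) %in% states) {
    stop(sprintf("expected expression state %s, got '%s'",
                 paste(sQuote(states), collapse = " or "), exprState(x)),
         call. = FALSE)
  }
  invisible(TRUE)
}
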