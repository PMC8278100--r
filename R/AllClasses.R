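#' ExpressionMatrix: a features x samples expression table with a
#' normalization-state tag
#'
#' Thin S4 container for a numeric matrix of expression values whose rows are
#' features (miRNAs or genes) and whose columns are samples, together with a
#' tag recording where the values sit in the normalization chain:
#' `"counts"` (raw reads), `"rpm"`/`"tpm"` (library-size normalized),
#' `"log2"` (log2(x+1) of rpm/tpm) or `"zscore"` (per-feature standardized).
#' Downstream operations check the tag so that, e.g., the risk score is only
#' applied to standardized expression.
#'
#' @slot values numeric matrix, features in rows, samples in columns; both
#'   dimensions carry unique names.
#' @slot state character(1), one of `"counts"`, `"rpm"`, `"tpm"`, `"log2"`,
#'   `"zscore"`.
#'
#' @seealso [ExpressionMatrix()] for the constructor, [exprValues()],
#'   [exprState()], [featureIds()], [sampleIds()] for accessors.
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", state = "character")
)

.EXPR_STATES <- c("counts", "rpm", "tpm", "log2", "zscore")

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (length(object@state) != 1L || !object@state %in% .EXPR_STATES) {
    msgs <- c(msgs, sprintf(
      "state must be one of: %s", paste(.EXPR_STATES, collapse = ", ")
    ))
  }
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    msgs <- c(msgs, "values must have feature (row) and sample (column) names")
  } else {
    if (anyDuplicated(rownames(v))) {
      dup <- unique(rownames(v)[duplicated(rownames(v))])
      msgs <- c(msgs, sprintf(
        "duplicate feature ids: %s", paste(utils::head(dup, 5L), collapse = ", ")
      ))
    }
    if (anyDuplicated(colnames(v))) {
      dup <- unique(colnames(v)[duplicated(colnames(v))])
      msgs <- c(msgs, sprintf(
        "duplicate sample ids: %s", paste(utils::head(dup, 5L), collapse = ", ")
      ))
    }
  }
  if (is.numeric(v) && any(!is.finite(v))) {
    msgs <- c(msgs, "values must be finite")
  }
  if (identical(object@state, "counts") && is.numeric(v) &&
      any(v < 0, na.rm = TRUE)) {
    msgs <- c(msgs, "counts must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (features x samples) with row and column names.
#' @param state normalization state tag; see [ExpressionMatrix-class].
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ExpressionMatrix(m, "counts")
#' @export
ExpressionMatrix <- function(values, state = c("counts", "rpm", "tpm",
                                               "log2", "zscore")) {
  state <- match.arg(state)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  methods::new("ExpressionMatrix", values = values, state = state)
}

#' @describeIn ExpressionMatrix-class number of features and samples
#' @param x an ExpressionMatrix
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf(
    "ExpressionMatrix: %d features x %d samples [state: %s]\n",
    nrow(object@values), ncol(object@values), object@state
  ))
  cat("  features:", .preview(rownames(object@values)), "\n")
  cat("  samples: ", .preview(colnames(object@values)), "\n")
})

.preview <- function(ids, k = 3L) {
  if (length(ids) <= k) return(paste(ids, collapse = ", "))
  paste0(paste(ids[seq_len(k)], collapse = ", "), ", ... (", length(ids), ")")
}

#' Accessors for ExpressionMatrix
#'
#' `exprValues` returns the numeric matrix, `exprState` the normalization
#' tag, `featureIds` the row (feature) identifiers and `sampleIds` the column
#' (sample) identifiers.
#'
#' @param x an [ExpressionMatrix-class]
#' @return `exprValues`: numeric matrix; `exprState`: character(1);
#'   `featureIds`, `sampleIds`: character vectors.
#' @name expression-accessors
NULL

#' @rdname expression-accessors
#' @export
exprValues <- function(x) {
  stopifnot(methods::is(x, "ExpressionMatrix"))
  x@values
}

#' @rdname expression-accessors
#' @export
exprState <- function(x) {
  stopifnot(methods::is(x, "ExpressionMatrix"))
  x@state
}

#' @rdname expression-accessors
#' @export
featureIds <- function(x) rownames(exprValues(x))

#' @rdname expression-accessors
#' @export
sampleIds <- function(x) colnames(exprValues(x))


#' SignatureModel: a linear miRNA risk-score signature
#'
#' Holds the per-miRNA weighting coefficients of a linear prognostic risk
#' score, Risk = sum_i Exp_i * Coef_i over standardized expression, together
#' with the risk-score cutoff that separates high-risk from low-risk
#' patients. The packaged immune-associated miRNA prognostic signature
#' (IAMIPS) is returned by [iamipsSignature()].
#'
#' @slot mirnaIds character, unique miRNA identifiers.
#' @slot coefficients numeric, one finite coefficient per miRNA.
#' @slot cutoff numeric(1), finite risk-score threshold (score strictly
#'   greater than the cutoff is called high risk).
#' @slot name character(1) label.
#' @seealso [riskScore()], [assignGroups()], [iamipsSignature()]
#' @export
setClass("SignatureModel",
  representation(mirnaIds = "character", coefficients = "numeric",
                 cutoff = "numeric", name = "character")
)

setValidity("SignatureModel", function(object) {
  msgs <- character(0)
  if (length(object@mirnaIds) != length(object@coefficients)) {
    msgs <- c(msgs, "one coefficient per miRNA id required")
  }
  if (anyDuplicated(object@mirnaIds)) msgs <- c(msgs, "miRNA ids must be unique")
  if (length(object@mirnaIds) == 0L) msgs <- c(msgs, "signature must be non-empty")
  if (any(!is.finite(object@coefficients))) {
    msgs <- c(msgs, "coefficients must be finite")
  }
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff)) {
    msgs <- c(msgs, "cutoff must be a single finite number")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignatureModel
#'
#' @param mirnaIds character vector of miRNA identifiers.
#' @param coefficients numeric vector of risk-score weights, same length.
#' @param cutoff risk-score threshold separating high from low risk.
#' @param name label for the signature.
#' @return A [SignatureModel-class] object.
#' @examples
#' SignatureModel(c("miR-a", "miR-b"), c(0.2, -0.1), cutoff = 0)
#' @export
SignatureModel <- function(mirnaIds, coefficients, cutoff, name = "signature") {
  methods::new("SignatureModel",
    mirnaIds = as.character(mirnaIds),
    coefficients = as.numeric(coefficients),
    cutoff = as.numeric(cutoff), name = as.character(name)[1L]
  )
}

setMethod("show", "SignatureModel", function(object) {
  cat(sprintf("SignatureModel '%s': %d miRNAs, cutoff %.4g\n",
              object@name, length(object@mirnaIds), object@cutoff))
  for (i in seq_along(object@mirnaIds)) {
    cat(sprintf("  %-16s % .4g\n", object@mirnaIds[i], object@coefficients[i]))
  }
})

#' @rdname SignatureModel
#' @param x a SignatureModel
#' @export
signatureCoefficients <- function(x) {
  stopifnot(methods::is(x, "SignatureModel"))
  stats::setNames(x@coefficients, x@mirnaIds)
}

#' @rdname SignatureModel
#' @export
signatureCutoff <- function(x) {
  stopifnot(methods::is(x, "SignatureModel"))
  x@cutoff
}


#' SyntheticCohort: a simulated cohort with recorded ground truth
#'
#' Bundles the matched inputs the pipeline consumes — miRNA and mRNA count
#' matrices, per-sample tumour purity, immune gene sets and survival — for a
#' simulated cohort, together with the planted ground truth (which
#' miRNA-pathway regulations were injected, and the true risk-score cutpoint
#' driving the survival hazard). See [generateCohort()].
#'
#' @slot mirna,mrna [ExpressionMatrix-class] count matrices sharing samples.
#' @slot purity named numeric in \[0,1\], one value per sample.
#' @slot geneSets named list of character vectors (pathway gene sets).
#' @slot survival data.frame with columns sample_id, time, event.
#' @slot truth list: `planted` (data.frame mirna, pathway, direction, effect,
#'   fraction), `scores` (true per-sample risk scores), `cutpoint`,
#'   `hazardRatio`.
#' @export
setClass("SyntheticCohort",
  representation(mirna = "ExpressionMatrix", mrna = "ExpressionMatrix",
                 purity = "numeric", geneSets = "list",
                 survival = "data.frame", truth = "list")
)

setValidity("SyntheticCohort", function(object) {
  msgs <- character(0)
  s <- sampleIds(object@mirna)
  if (!identical(s, sampleIds(object@mrna))) {
    msgs <- c(msgs, "miRNA and mRNA sample ids must be identical")
  }
  if (!identical(s, names(object@purity))) {
    msgs <- c(msgs, "purity must be named by the same sample ids")
  }
  if (!identical(s, object@survival$sample_id)) {
    msgs <- c(msgs, "survival rows must match the sample ids")
  }
  pl <- object@truth$planted
  if (!is.null(pl) && nrow(pl)) {
    if (!all(pl$mirna %in% featureIds(object@mirna))) {
      msgs <- c(msgs, "truth references unknown miRNA ids")
    }
    if (!all(pl$pathway %in% names(object@geneSets))) {
      msgs <- c(msgs, "truth references unknown pathways")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d samples, %d miRNAs, %d genes, %d pathways\n",
    ncol(object@mirna@values), nrow(object@mirna@values),
    nrow(object@mrna@values), length(object@geneSets)
  ))
  npl <- if (is.null(object@truth$planted)) 0L else nrow(object@truth$planted)
  cat(sprintf("  planted miRNA-pathway regulations: %d\n", npl))
  cat(sprintf("  events: %d / %d\n", sum(object@survival$event),
              nrow(object@survival)))
})

#' Accessors for SyntheticCohort
#'
#' @param x a [SyntheticCohort-class]
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
cohortMirna <- function(x) x@mirna

#' @rdname cohort-accessors
#' @export
cohortMrna <- function(x) x@mrna

#' @rdname cohort-accessors
#' @export
cohortPurity <- function(x) x@purity

#' @rdname cohort-accessors
#' @export
cohortGeneSets <- function(x) x@geneSets

#' @rdname cohort-accessors
#' @export
cohortSurvival <- function(x) x@survival

#' @rdname cohort-accessors
#' @export
cohortTruth <- function(x) x@truth
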