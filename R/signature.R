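#' Apply a linear miRNA risk signature
#'
#' Computes the per-patient risk score
#' \deqn{Risk_s = \sum_i Exp_{is} \times Coef_i}
#' over the signature miRNAs. Expression must be standardized per cohort
#' ([zscoreRows()]) so that the coefficients transfer between data sets;
#' a non-`zscore` input state triggers a warning.
#'
#' @param zExpr an [ExpressionMatrix-class] of miRNA expression, state
#'   `"zscore"`, containing every signature miRNA.
#' @param signature a [SignatureModel-class].
#' @return data.frame with columns sample_id, score (one row per sample,
#'   matrix column order).
#' @examples
#' z <- ExpressionMatrix(
#'   matrix(c(1, 0, 0, 0, 0, 0), 3,
#'          dimnames = list(c("miR-216a-5p", "miR-194-3p", "miR-3677-3p"),
#'                          c("s1", "s2"))), "zscore")
#' riskScore(z, iamipsSignature())
#' @export
riskScore <- function(zExpr, signature) {
  stopifnot(methods::is(signature, "SignatureModel"))
  if (exprState(zExpr) != "zscore") {
    warning("expression state is '", exprState(zExpr),
            "', not 'zscore'; coefficients assume standardized expression",
            call. = FALSE)
  }
  co <- signatureCoefficients(signature)
  v <- exprValues(zExpr)
  missing <- setdiff(names(co), rownames(v))
  if (length(missing)) {
    stop("signature miRNA(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scores <- as.numeric(crossprod(v[names(co), , drop = FALSE], co))
  data.frame(sample_id = colnames(v), score = scores,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square statistic (1 degree of freedom) comparing
#' the survival curves of two groups (via `survival::survdiff`).
#'
#' @param time positive follow-up times.
#' @param event event indicators (1 = death, 0 = censored).
#' @param groups two-level factor or vector, same length.
#' @return A list with `chisq` and `p`. If neither group has any event the
#'   curves are trivially equal: `chisq = 0`, `p = 1`, with a warning.
#' @export
logRankStatistic <- function(time, event, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("exactly two non-empty groups required",
                                  call. = FALSE)
  if (sum(event) == 0) {
    warning("no events in either group; log-rank statistic is 0",
            call. = FALSE)
    return(list(chisq = 0, p = 1))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ groups)
  chisq <- as.numeric(fit$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Maximally selected log-rank cutpoint
#'
#' Finds the risk-score threshold that best separates survival: every
#' candidate cutpoint (midpoints of adjacent sorted unique scores) whose
#' induced high/low groups each contain at least `minprop` of the subjects
#' is evaluated by the two-group log-rank chi-square, and the candidate with
#' the maximal statistic is returned (ties: the smaller cutpoint).
#'
#' The maximally selected statistic is optimistically biased as a test; here
#' it is used only to pick the operating threshold of a fixed signature.
#'
#' @param scores numeric risk scores.
#' @param time,event survival outcome, aligned with `scores`.
#' @param minprop minimum fraction of subjects on each side of the cutpoint
#'   (in (0, 0.5); default 0.1).
#' @return The selected cutpoint (numeric).
#' @export
optimalCutpoint <- function(scores, time, event, minprop = 0.1) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 10L) stop("need at least 10 subjects", call. = FALSE)
  if (minprop <= 0 || minprop >= 0.5) stop("minprop must lie in (0, 0.5)",
                                           call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("all scores identical; no candidate cutpoint",
                           call. = FALSE)
  candidates <- (u[-1L] + u[-length(u)]) / 2
  nLow <- vapply(candidates, function(cc) sum(scores <= cc), integer(1L))
  ok <- nLow >= minprop * n & (n - nLow) >= minprop * n
  if (!any(ok)) stop("no candidate cutpoint satisfies minprop = ", minprop,
                     call. = FALSE)
  candidates <- candidates[ok]
  chisq <- vapply(candidates, function(cc) {
    suppressWarnings(
      logRankStatistic(time, event, factor(scores > cc,
                                           levels = c(FALSE, TRUE)))$chisq
    )
  }, numeric(1L))
  candidates[which.max(chisq)]  # which.max takes the first = smaller cutpoint
}

#' Assign high/low risk groups
#'
#' Dichotomizes risk scores at a cutoff: strictly greater is `"high"`,
#' less than or equal is `"low"`.
#'
#' @param scores named numeric vector of risk scores, or the data.frame from
#'   [riskScore()].
#' @param cutoff risk-score threshold (e.g. [signatureCutoff()] of the
#'   packaged signature, or an [optimalCutpoint()]).
#' @return data.frame with columns sample_id, score, group (factor
#'   low/high).
#' @export
assignGroups <- function(scores, cutoff) {
  if (is.data.frame(scores)) {
    df <- scores[c("sample_id", "score")]
  } else {
    df <- data.frame(
      sample_id = if (is.null(names(scores))) as.character(seq_along(scores))
                  else names(scores),
      score = as.numeric(scores), stringsAsFactors = FALSE
    )
  }
  df$group <- factor(ifelse(df$score > cutoff, "high", "low"),
                     levels = c("low", "high"))
  rownames(df) <- NULL
  df
}
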