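#' Screen drugs for association with the risk score
#'
#' Selects risk-associated drugs from an IC50 table (drugs x samples,
#' log-scale; lower IC50 = more sensitive) by the intersection of two
#' criteria, each FDR-corrected across drugs:
#' \enumerate{
#'   \item Pearson correlation between the drug's IC50 and the risk score:
#'     `|r| > rMin` and BH FDR `< alpha`;
#'   \item Welch two-sample t-test of IC50 between high- and low-risk
#'     groups: `|log2FC| > fcMin` (mean high minus mean low, values assumed
#'     log2-scale) and BH FDR `< alpha`.
#' }
#'
#' @param ic50 numeric matrix, drugs in rows (unique names), samples in
#'   columns; values on a log2 scale.
#' @param profiles data.frame with columns sample_id, score, group (from
#'   [assignGroups()]); samples are matched by id against the IC50 columns.
#' @param rMin correlation magnitude threshold (default 0.3).
#' @param fcMin log2 fold-change magnitude threshold (default 0.5).
#' @param alpha FDR threshold for both criteria (default 0.05).
#' @return data.frame with columns drug_id, r, r_fdr, log2fc, t_fdr,
#'   selected, in the input drug order. Drugs with constant IC50 (undefined
#'   correlation) are dropped with a warning.
#' @export
drugScreen <- function(ic50, profiles, rMin = 0.3, fcMin = 0.5,
                       alpha = 0.05) {
  stopifnot(is.matrix(ic50), !is.null(rownames(ic50)),
            is.data.frame(profiles),
            all(c("sample_id", "score", "group") %in% names(profiles)))
  if (anyDuplicated(rownames(ic50))) stop("duplicate drug ids", call. = FALSE)
  common <- intersect(colnames(ic50), profiles$sample_id)
  if (length(common) < 6L) stop("need >= 6 shared samples", call. = FALSE)
  ic50 <- ic50[, common, drop = FALSE]
  prof <- profiles[match(common, profiles$sample_id), ]
  high <- prof$group == "high"
  if (sum(high) < 3L || sum(!high) < 3L) {
    stop("need >= 3 samples per risk group", call. = FALSE)
  }

  const <- apply(ic50, 1L, stats::sd) == 0
  if (any(const)) {
    warning("constant IC50 row(s) excluded: ",
            paste(rownames(ic50)[const], collapse = ", "), call. = FALSE)
    ic50 <- ic50[!const, , drop = FALSE]
  }
  nDrug <- nrow(ic50)
  if (nDrug == 0L) {
    return(data.frame(drug_id = character(0), r = numeric(0),
                      r_fdr = numeric(0), log2fc = numeric(0),
                      t_fdr = numeric(0), selected = logical(0)))
  }

  r <- as.numeric(stats::cor(t(ic50), prof$score))
  n <- length(common)
  tR <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  rP <- 2 * stats::pt(-abs(tR), df = n - 2)

  tRes <- vapply(seq_len(nDrug), function(i) {
    tt <- stats::t.test(ic50[i, high], ic50[i, !high])
    c(fc = mean(ic50[i, high]) - mean(ic50[i, !high]), p = tt$p.value)
  }, numeric(2L))

  rFdr <- bhAdjust(rP)
  tFdr <- bhAdjust(tRes["p", ])
  log2fc <- tRes["fc", ]
  selected <- abs(r) > rMin & rFdr < alpha & abs(log2fc) > fcMin &
    tFdr < alpha
  data.frame(drug_id = rownames(ic50), r = r, r_fdr = rFdr,
             log2fc = log2fc, t_fdr = tFdr, selected = selected,
             stringsAsFactors = FALSE, row.names = NULL)
}
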