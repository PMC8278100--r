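#' Read a delimited expression table
#'
#' Reads a features x samples expression table from tab- or comma-delimited
#' text. The first column holds feature identifiers, the header row sample
#' identifiers. The delimiter is taken from the header line (tab if it
#' contains a tab, comma otherwise).
#'
#' @param path file path.
#' @param state normalization state tag to attach; see
#'   [ExpressionMatrix-class].
#' @return An [ExpressionMatrix-class].
#' @seealso [writeExpressionTable()]
#' @export
readExpressionTable <- function(path, state = "counts") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("expression table needs a feature id column plus >=1 sample: ", path,
         call. = FALSE)
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s) in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, samples))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric value in %s at feature '%s', sample '%s'",
      path, ids[bad[1L]], samples[bad[2L]]
    ), call. = FALSE)
  }
  ExpressionMatrix(vals, state = state)
}

.sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Write an expression table
#'
#' Inverse of [readExpressionTable()]: writes the matrix as delimited text
#' with a `feature_id` first column and sample ids in the header.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output file path.
#' @param sep field delimiter (tab by default).
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(x, path, sep = "\t") {
  v <- exprValues(x)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. The description field
#' is ignored; duplicate members within a line are collapsed.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (one element per gene set).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(fields)), call. = FALSE)
    }
    nms[i] <- fields[1L]
    members <- unique(fields[-c(1L, 2L)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop(sprintf("GMT line %d (set '%s') has no members", i, nms[i]),
           call. = FALSE)
    }
    sets[[i]] <- members
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(sets, nms)
}

#' Write gene sets to a GMT file
#'
#' @param geneSets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(geneSets, path, description = "na") {
  lines <- vapply(names(geneSets), function(nm) {
    paste(c(nm, description, geneSets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample tumour purity table
#'
#' Expects delimited text with columns `sample_id` and `purity`
#' (fraction of malignant cells, in \[0,1\]).
#'
#' @param path file path.
#' @return Named numeric vector of purities.
#' @export
readPurity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  .requireColumns(df, c("sample_id", "purity"), path)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id(s) in purity table: ", path, call. = FALSE)
  }
  p <- as.numeric(df$purity)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("purity values must be numeric in [0, 1]: ", path, call. = FALSE)
  }
  stats::setNames(p, df$sample_id)
}

#' Read a survival table
#'
#' Expects delimited text with columns `sample_id`, `time` (positive
#' follow-up time) and `event` (1 = death, 0 = censored).
#'
#' @param path file path.
#' @return data.frame with columns sample_id, time, event.
#' @export
readSurvival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  .requireColumns(df, c("sample_id", "time", "event"), path)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  if (anyNA(df$time) || any(df$time <= 0)) {
    stop("survival times must be positive: ", path, call. = FALSE)
  }
  if (anyNA(df$event) || !all(df$event %in% c(0L, 1L))) {
    stop("event must be 0 (censored) or 1 (death): ", path, call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id(s) in survival table: ", path, call. = FALSE)
  }
  df[c("sample_id", "time", "event")]
}

.requireColumns <- function(df, cols, path) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing)) {
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read or write a signature file
#'
#' A signature file is delimited text whose first line is
#' `cutoff=<value>`, followed by a header `mirna_id<TAB>coefficient` and one
#' row per signature miRNA.
#'
#' @param path file path.
#' @param name label attached to the loaded signature (defaults to the file
#'   base name).
#' @return [readSignatureFile()]: a [SignatureModel-class].
#' @seealso [iamipsSignature()]
#' @export
readSignatureFile <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^cutoff=", lines, value = TRUE)
  if (length(meta) != 1L) {
    stop("signature file must contain exactly one 'cutoff=<value>' line: ",
         path, call. = FALSE)
  }
  cutoff <- as.numeric(sub("^cutoff=", "", meta))
  body <- lines[!grepl("^cutoff=", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .requireColumns(df, c("mirna_id", "coefficient"), path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  SignatureModel(df$mirna_id, as.numeric(df$coefficient), cutoff, name = name)
}

#' @rdname readSignatureFile
#' @param signature a [SignatureModel-class] to write.
#' @export
writeSignatureFile <- function(signature, path) {
  co <- signatureCoefficients(signature)
  lines <- c(
    sprintf("cutoff=%.15g", signatureCutoff(signature)),
    "mirna_id\tcoefficient",
    sprintf("%s\t%.15g", names(co), unname(co))
  )
  writeLines(lines, path)
  invisible(path)
}

#' The packaged IAMIPS prognostic signature
#'
#' Returns the immune-associated miRNA prognostic signature (IAMIPS): a
#' three-miRNA linear risk score
#' `0.015 * miR-216a-5p - 0.035 * miR-194-3p - 0.124 * miR-3677-3p`
#' over z-scored expression, with risk-group cutoff 0.05, as fitted by LASSO
#' Cox regression on the TCGA colorectal cohort. The constants ship as a
#' versioned signature file under `extdata/`; the LASSO fit itself is not
#' re-estimated here.
#'
#' @return A [SignatureModel-class] with three entries.
#' @examples
#' sig <- iamipsSignature()
#' signatureCoefficients(sig)
#' @export
iamipsSignature <- function() {
  path <- system.file("extdata", "iamips_tcga.tsv", package = "ImmuMiR",
                      mustWork = TRUE)
  readSignatureFile(path, name = "iamips_tcga")
}
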