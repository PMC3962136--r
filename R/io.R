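#' Read a labeled dataset from delimited text
#'
#' Canonical dialect: a TSV with a header row, sample identifiers in the
#' first column, and either the outcome as one column of the same file
#' (`outcomeColumn`) or a separate phenotype file joined on sample ID
#' (`phenotypeFile`, whose outcome column is also named by
#' `outcomeColumn`). A features-by-samples file (first column = feature
#' names, header = sample IDs) is transposed on reading.
#'
#' Rows containing any missing value are dropped with a warning stating the
#' count. Duplicate sample IDs, unknown class labels (against `classOrder`)
#' and non-numeric feature cells raise errors naming the offending
#' row/column.
#'
#' @param path matrix file.
#' @param outcomeColumn name of the outcome column.
#' @param outcomeKind `"nominal"` or `"ordinal"`.
#' @param delimiter field separator (default tab).
#' @param orientation `"samples_by_features"` (default) or
#'   `"features_by_samples"`.
#' @param phenotypeFile optional separate phenotype table (first column =
#'   sample ID).
#' @param classOrder class label order, required for ordinal outcomes.
#' @return a \linkS4class{MulticlassExperiment}.
#' @export
readLabeledDataset <- function(path, outcomeColumn,
                               outcomeKind = c("nominal", "ordinal"),
                               delimiter = "\t",
                               orientation = c("samples_by_features",
                                               "features_by_samples"),
                               phenotypeFile = NULL, classOrder = NULL) {
  outcomeKind <- match.arg(outcomeKind)
  orientation <- match.arg(orientation)
  raw <- read.delim(path, sep = delimiter, header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (orientation == "features_by_samples") {
    featNames <- as.character(raw[[1L]])
    sampleIds <- colnames(raw)[-1L]
    mat <- t(as.matrix(raw[, -1L, drop = FALSE]))
    colnames(mat) <- featNames
    tab <- data.frame(..sample = sampleIds, mat, check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    tab <- raw
    colnames(tab)[1L] <- "..sample"
  }
  ids <- as.character(tab$..sample)
  if (anyDuplicated(ids))
    stop("duplicate sample ID: ", ids[duplicated(ids)][1L])

  if (is.null(phenotypeFile)) {
    if (!outcomeColumn %in% colnames(tab))
      stop("outcome column '", outcomeColumn, "' not found")
    outcome <- as.character(tab[[outcomeColumn]])
    featTab <- tab[, setdiff(colnames(tab), c("..sample", outcomeColumn)),
                   drop = FALSE]
  } else {
    ph <- read.delim(phenotypeFile, sep = delimiter, header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE)
    phIds <- as.character(ph[[1L]])
    if (anyDuplicated(phIds))
      stop("duplicate sample ID in phenotype file: ",
           phIds[duplicated(phIds)][1L])
    if (!outcomeColumn %in% colnames(ph))
      stop("outcome column '", outcomeColumn,
           "' not found in phenotype file")
    j <- match(ids, phIds)
    if (anyNA(j))
      stop("sample ", ids[which(is.na(j))[1L]],
           " has no phenotype record")
    outcome <- as.character(ph[[outcomeColumn]][j])
    featTab <- tab[, setdiff(colnames(tab), "..sample"), drop = FALSE]
  }

  for (cn in colnames(featTab)) {
    v <- featTab[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad))
        stop("non-numeric value in column '", cn, "', row ",
             bad[1L], " (sample ", ids[bad[1L]], ")")
      featTab[[cn]] <- vn
    }
  }
  X <- as.matrix(featTab)
  rownames(X) <- ids

  miss <- rowSums(is.na(X)) > 0 | is.na(outcome) | outcome == ""
  if (any(miss)) {
    warning("dropped ", sum(miss), " sample(s) with missing values")
    X <- X[!miss, , drop = FALSE]
    outcome <- outcome[!miss]
  }
  if (outcomeKind == "ordinal" && is.null(classOrder))
    stop("ordinal outcomes require 'classOrder'")
  MulticlassExperiment(X, outcome, outcomeKind, classOrder = classOrder)
}

#' Write a labeled dataset as delimited text
#'
#' Inverse of [readLabeledDataset()] in the canonical samples-by-features
#' dialect: sample IDs in the first column, the outcome labels in an
#' `outcome` column, values at 12 significant digits so that read-write
#' round trips are lossless at that precision.
#'
#' @param data a \linkS4class{MulticlassExperiment}.
#' @param path output file.
#' @param delimiter field separator.
#' @param outcomeColumn name for the outcome column.
#' @return invisibly, `path`.
#' @export
writeLabeledDataset <- function(data, path, delimiter = "\t",
                                outcomeColumn = "outcome") {
  fm <- featureMatrix(data)
  ids <- rownames(fm)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(fm)))
  labs <- classLabels(data)[outcomeCodes(data) + 1L]
  out <- data.frame(sample = ids,
                    as.data.frame(apply(fm, 2L, function(v)
                      sprintf("%.12g", v))),
                    outcome = labs, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("sample", colnames(fm), outcomeColumn)
  write.table(out, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}
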