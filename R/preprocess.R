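#' Build a SummarizedExperiment expression container
#'
#' Expression data are carried as a [SummarizedExperiment::SummarizedExperiment]
#' with genes as rows, samples as columns, a single `"exprs"` assay on the
#' log2 scale, and an optional `group` column in `colData`.
#'
#' @param values numeric genes x samples matrix (log-scale expression).
#'   Row names are gene IDs, column names sample IDs; both required unless
#'   supplied through `geneIds` / `sampleIds`.
#' @param groups optional character/factor vector of group labels, one per
#'   sample (or a named vector keyed by sample ID).
#' @param geneIds,sampleIds optional dimension names overriding those of
#'   `values`.
#' @return a `SummarizedExperiment` with assay `"exprs"`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
#' se <- makeExpressionSE(m, groups = c("AD", "AD", "CON", "CON"))
#' groupLabels(se)
#' @export
makeExpressionSE <- function(values, groups = NULL, geneIds = NULL,
                             sampleIds = NULL) {
  values <- as.matrix(values)
  if (!is.null(geneIds)) rownames(values) <- geneIds
  if (!is.null(sampleIds)) colnames(values) <- sampleIds
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs are not allowed")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (ncol(values) < 2L) stop("need at least 2 samples")
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(groups)) {
    if (!is.null(names(groups))) {
      if (!all(colnames(values) %in% names(groups)))
        stop("group labels missing for sample(s): ",
             paste(setdiff(colnames(values), names(groups)), collapse = ", "))
      groups <- groups[colnames(values)]
    } else if (length(groups) != ncol(values)) {
      stop("'groups' must have one label per sample")
    }
    cd$group <- as.character(groups)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd)
}

#' @describeIn makeExpressionSE extract the expression matrix.
#' @param se a `SummarizedExperiment` produced by this package.
#' @export
exprsMatrix <- function(se) {
  SummarizedExperiment::assay(se, "exprs")
}

#' @describeIn makeExpressionSE extract the per-sample group labels
#'   (`NULL` when absent).
#' @export
groupLabels <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (!"group" %in% colnames(cd)) return(NULL)
  stats::setNames(as.character(cd$group), rownames(cd))
}

#' Restrict an expression matrix to a gene set
#'
#' Returns the rows for `geneIds`, in the requested order.  A requested
#' gene absent from the matrix is an error naming the gene.
#'
#' @param se expression `SummarizedExperiment`.
#' @param geneIds character vector of gene IDs to keep, in order.
#' @return the row-subset `SummarizedExperiment`.
#' @export
selectGenes <- function(se, geneIds) {
  missing <- setdiff(geneIds, rownames(se))
  if (length(missing))
    stop("gene(s) not found in expression matrix: ",
         paste(missing, collapse = ", "))
  se[geneIds, ]
}

#' Split an expression matrix by sample group
#'
#' @param se expression `SummarizedExperiment` whose `colData$group`
#'   labels every sample.
#' @return named list of column-disjoint `SummarizedExperiment`s, one per
#'   group (in sorted group order), whose columns partition the input.
#' @export
splitByGroup <- function(se) {
  labels <- groupLabels(se)
  if (is.null(labels))
    stop("no group labels present; add colData$group first")
  if (anyNA(labels) || any(labels == ""))
    stop("unlabeled sample(s): ",
         paste(colnames(se)[is.na(labels) | labels == ""], collapse = ", "))
  groups <- sort(unique(labels))
  out <- lapply(groups, function(g) se[, labels == g])
  names(out) <- groups
  out
}

#' Z-score standardize each gene across samples
#'
#' Centers every row to mean zero and scales it to standard deviation one.
#' The sd divisor is selectable because different conventions divide by
#' \eqn{m-1} (sample sd, the default) or \eqn{m}; normalized eigen-spectra
#' downstream are invariant to this choice, since it rescales the Gram
#' matrix by a constant that cancels in the normalization.
#'
#' @param x expression `SummarizedExperiment` or a plain numeric matrix
#'   (genes x samples).
#' @param sdDivisor `"m-1"` (default) or `"m"`.
#' @param dropConstant drop zero-variance genes instead of erroring.
#' @return object of the same kind with standardized rows.
#' @examples
#' zscoreRows(matrix(c(1, 2, 3), 1, 3, dimnames = list("g", NULL)))
#' @export
zscoreRows <- function(x, sdDivisor = c("m-1", "m"), dropConstant = FALSE) {
  sdDivisor <- match.arg(sdDivisor)
  isSE <- methods::is(x, "SummarizedExperiment")
  m <- if (isSE) exprsMatrix(x) else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least 2 samples to standardize")
  d <- if (sdDivisor == "m-1") ncol(m) - 1L else ncol(m)
  ctr <- m - rowMeans(m)
  sds <- sqrt(rowSums(ctr^2) / d)
  zero <- sds == 0
  if (any(zero)) {
    if (!dropConstant)
      stop("zero-variance gene(s): ",
           paste(rownames(m)[zero], collapse = ", "),
           " (use dropConstant = TRUE to drop them)")
    m <- m[!zero, , drop = FALSE]
    ctr <- ctr[!zero, , drop = FALSE]
    sds <- sds[!zero]
    if (isSE) x <- x[!zero, ]
  }
  z <- ctr / sds
  if (isSE) {
    SummarizedExperiment::assay(x, "exprs") <- z
    x
  } else {
    z
  }
}

#' Read / write the package's TSV dialects
#'
#' Expression matrices travel as TSV with gene IDs in the first column and
#' sample IDs in the header row; sample group labels as a two-column
#' `sample<TAB>group` TSV; edge lists as `nodeA<TAB>nodeB<TAB>score`.
#'
#' @param path file path.
#' @param labelsPath optional path of the sample-to-group label table.
#' @return `readExpressionTSV` returns an expression
#'   `SummarizedExperiment`; the writers return their paths invisibly.
#' @name expression-io
#' @export
readExpressionTSV <- function(path, labelsPath = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           row.names = 1L, check.names = FALSE)
  groups <- NULL
  if (!is.null(labelsPath)) {
    lab <- utils::read.table(labelsPath, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             colClasses = "character")
    groups <- stats::setNames(lab[[2L]], lab[[1L]])
  }
  makeExpressionSE(as.matrix(tab), groups = groups)
}

#' @rdname expression-io
#' @param se expression `SummarizedExperiment` to write.
#' @export
writeExpressionTSV <- function(se, path, labelsPath = NULL) {
  m <- exprsMatrix(se)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(labelsPath)) {
    labels <- groupLabels(se)
    if (is.null(labels)) stop("no group labels to write")
    utils::write.table(
      data.frame(sample = names(labels), group = unname(labels)),
      labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
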