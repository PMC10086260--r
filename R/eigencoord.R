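#' Inner-product (Gram) matrix of Z-scored expression rows
#'
#' For genes-by-samples matrix \eqn{X} with Z-scored rows, forms
#' \eqn{R = X X^\top}, the matrix of pairwise inner products
#' \eqn{a_i \cdot a_j = \sum_s x_{is} x_{js}}.  With rows standardized
#' under sd divisor \eqn{d}, \eqn{R = d \times} the sample correlation
#' matrix, so it is symmetric positive semi-definite and carries the full
#' pairwise coordination structure of the gene set.
#'
#' @param x expression `SummarizedExperiment` or numeric genes x samples
#'   matrix with Z-scored rows (row means below 1e-6 in magnitude).
#' @param check verify that rows are centered; set `FALSE` to skip for
#'   deliberately non-standardized input.
#' @return a [GramMatrix-class].
#' @examples
#' z <- zscoreRows(matrix(rnorm(30), 3, dimnames = list(letters[1:3], NULL)))
#' innerProductMatrix(z)
#' @export
innerProductMatrix <- function(x, check = TRUE) {
  m <- if (methods::is(x, "SummarizedExperiment")) exprsMatrix(x)
       else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 genes")
  if (is.null(rownames(m)))
    rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (check && max(abs(rowMeans(m))) >= 1e-6)
    stop("rows do not look Z-scored (|row mean| >= 1e-6); ",
         "standardize with zscoreRows() or pass check = FALSE")
  R <- m %*% t(m)
  R <- (R + t(R)) / 2  # kill rounding asymmetry
  methods::new("GramMatrix", values = R,
               sampleCount = ncol(m))
}

#' Normalized eigenvalue spectrum of a Gram matrix
#'
#' Eigendecomposes the symmetric PSD matrix \eqn{R = Q \Lambda Q^\top}
#' (for symmetric \eqn{R} the inverse of the eigenvector matrix is its
#' transpose), clamps eigenvalues in \eqn{[-10^{-8}\,\mathrm{tr}(R), 0)}
#' to zero — floating point routinely produces such tiny PSD violations —
#' and divides by the eigenvalue sum so the spectrum sums to one.  The
#' result is reported as fractions in [0, 1], sorted descending.
#'
#' @param R a [GramMatrix-class], or any symmetric numeric matrix (e.g. a
#'   correlation matrix).
#' @return an [EigenSpectrum-class].
#' @examples
#' normalizedEigenvalues(equicorrMatrix(4, 0.6))  # 0.7, 0.1, 0.1, 0.1
#' @export
normalizedEigenvalues <- function(R) {
  if (methods::is(R, "GramMatrix")) {
    v <- gramValues(R)
  } else {
    v <- as.matrix(R)
    if (nrow(v) != ncol(v) ||
        max(abs(v - t(v))) > 1e-8 * max(1, max(abs(v))))
      stop("'R' must be a symmetric square matrix")
    if (is.null(rownames(v)))
      dimnames(v) <- list(paste0("g", seq_len(nrow(v))),
                          paste0("g", seq_len(nrow(v))))
  }
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(sum(diag(v)), .Machine$double.eps)
  if (any(ev < -tol))
    stop(sprintf(
      "matrix is not positive semi-definite (eigenvalue %.3g < -%.3g)",
      min(ev), tol))
  ev[ev < 0] <- 0
  s <- sum(ev)
  if (s <= 0) stop("degenerate input: eigenvalue sum is not positive")
  lam <- sort(ev / s, decreasing = TRUE)
  methods::new("EigenSpectrum", values = lam, geneIds = rownames(v))
}

#' Compare the eigen-spectra of two groups
#'
#' Per-rank difference of two normalized spectra over the same gene set:
#' `perRankDelta[i]` is rank-i of `spectrumB` minus rank-i of
#' `spectrumA`.  Both spectra sum to one, so the deltas sum to zero; a
#' positive delta at rank 1 means the gene set is more tightly
#' coordinated in group B.
#'
#' @param spectrumA,spectrumB [EigenSpectrum-class] objects of equal
#'   length over the same gene set.
#' @param groupA,groupB display names for the two groups.
#' @return a [SpectrumComparison-class]; see [largestDelta()] and
#'   [smallestDelta()] for the deltas at the extreme ranks.
#' @export
compareSpectra <- function(spectrumA, spectrumB,
                           groupA = "A", groupB = "B") {
  if (length(spectrumValues(spectrumA)) != length(spectrumValues(spectrumB)))
    stop("spectra have different lengths")
  if (!setequal(geneIds(spectrumA), geneIds(spectrumB)))
    stop("spectra describe different gene sets")
  delta <- spectrumValues(spectrumB) - spectrumValues(spectrumA)
  methods::new("SpectrumComparison",
    groupA = groupA, groupB = groupB,
    spectrumA = spectrumA, spectrumB = spectrumB,
    perRankDelta = delta)
}

#' Full two-group coordination analysis of a gene set
#'
#' The complete eigen-coordination pipeline: restrict the expression
#' matrix to the gene set plus an optional anchor gene, split samples by
#' group (exactly two groups required), Z-score each gene within each
#' group, build each group's Gram matrix, take normalized eigen-spectra,
#' and compare them.  The anchor-gene idiom supports asking whether a hub
#' module's coordination with a pathway marker differs between case and
#' control groups.
#'
#' @param se expression `SummarizedExperiment` with `colData$group`
#'   defining exactly two groups.
#' @param geneSet character vector of gene IDs.
#' @param anchorGene optional single gene ID appended to `geneSet`.
#' @param refGroup reference group (spectrum A; deltas are other minus
#'   reference).  Default: alphabetically first group.
#' @param scope `"within"` (default) Z-scores each group separately;
#'   `"global"` standardizes across all samples before splitting, for
#'   sensitivity analysis.
#' @param sdDivisor passed to [zscoreRows()]; normalized spectra are
#'   invariant to it.
#' @return a [SpectrumComparison-class].
#' @examples
#' se <- simulateExpression(syntheticDesign(seed = 7))
#' coordinationAnalysis(se, c("hubA", "hubB", "hubC"),
#'                      anchorGene = "anchor", refGroup = "CON")
#' @export
coordinationAnalysis <- function(se, geneSet, anchorGene = NULL,
                                 refGroup = NULL,
                                 scope = c("within", "global"),
                                 sdDivisor = c("m-1", "m")) {
  scope <- match.arg(scope)
  sdDivisor <- match.arg(sdDivisor)
  genes <- unique(c(geneSet, anchorGene))
  sub <- selectGenes(se, genes)
  if (scope == "global") sub <- zscoreRows(sub, sdDivisor = sdDivisor)
  parts <- splitByGroup(sub)
  if (length(parts) != 2L)
    stop("coordination analysis needs exactly 2 groups, got ",
         length(parts))
  if (is.null(refGroup)) refGroup <- names(parts)[1L]
  if (!refGroup %in% names(parts))
    stop("'refGroup' is not one of the groups: ",
         paste(names(parts), collapse = ", "))
  otherGroup <- setdiff(names(parts), refGroup)
  spec <- lapply(parts, function(p) {
    z <- if (scope == "within") zscoreRows(p, sdDivisor = sdDivisor)
         else p
    normalizedEigenvalues(innerProductMatrix(z, check = (scope == "within")))
  })
  compareSpectra(spec[[refGroup]], spec[[otherGroup]],
                 groupA = refGroup, groupB = otherGroup)
}
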