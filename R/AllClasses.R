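#' @import methods
NULL

.SYM_TOL <- 1e-10

#' Gram (inner-product) matrix of a gene set
#'
#' An n x n symmetric matrix of pairwise inner products of gene expression
#' row-vectors.  When the rows have been Z-scored with standard-deviation
#' divisor \eqn{d} (either \eqn{m} or \eqn{m-1} for \eqn{m} samples), every
#' diagonal entry equals \eqn{d} and the matrix is \eqn{d} times the sample
#' correlation matrix of the genes, hence symmetric positive semi-definite.
#'
#' @slot values symmetric numeric matrix with gene IDs as dimnames.
#' @slot sampleCount integer, the number of samples \eqn{m} the inner
#'   products were taken over.
#'
#' @seealso [innerProductMatrix()], [normalizedEigenvalues()]
#' @export
setClass("GramMatrix",
  representation(values = "matrix", sampleCount = "integer"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v) || nrow(v) != ncol(v))
      return("'values' must be a square numeric matrix")
    if (anyNA(v)) return("'values' contains missing values")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
      return("'values' must carry identical row and column gene IDs")
    if (max(abs(v - t(v))) > .SYM_TOL * max(1, max(abs(v))))
      return("'values' is not symmetric within tolerance")
    if (length(object@sampleCount) != 1L || object@sampleCount < 1L)
      return("'sampleCount' must be a single positive integer")
    TRUE
  }
)

#' Normalized eigenvalue spectrum of a gene-set Gram matrix
#'
#' Eigenvalues of a symmetric positive semi-definite Gram matrix divided by
#' their sum, sorted in descending order.  The spectrum sums to one, every
#' entry lies in [0, 1], and the whole object is invariant to positive
#' rescaling of the underlying expression data.  A dominant first entry
#' indicates tightly coordinated (co-varying) genes; a flat spectrum
#' indicates independence.
#'
#' @slot values numeric vector of normalized eigenvalues, non-increasing.
#' @slot geneIds character vector naming the gene set the spectrum
#'   describes.
#'
#' @seealso [normalizedEigenvalues()], [compareSpectra()]
#' @export
setClass("EigenSpectrum",
  representation(values = "numeric", geneIds = "character"),
  validity = function(object) {
    v <- object@values
    if (length(v) == 0L) return("empty spectrum")
    if (anyNA(v)) return("spectrum contains missing values")
    if (abs(sum(v) - 1) > 1e-10) return("spectrum must sum to 1 within 1e-10")
    if (any(v < -1e-12) || any(v > 1 + 1e-12))
      return("spectrum entries must lie in [0, 1]")
    if (any(diff(v) > 1e-10))
      return("spectrum must be sorted in descending order")
    if (length(object@geneIds) != length(v))
      return("'geneIds' length must match the spectrum length")
    TRUE
  }
)

#' Between-group comparison of two eigen-spectra
#'
#' Holds the per-rank difference between the normalized spectra of the same
#' gene set computed in two sample groups: \code{perRankDelta[i]} is the
#' rank-i eigenvalue of group B minus that of group A.  Because both
#' spectra sum to one the deltas sum to zero.
#'
#' @slot groupA,groupB group names; deltas are B minus A.
#' @slot spectrumA,spectrumB the two [EigenSpectrum-class] objects.
#' @slot perRankDelta numeric vector of per-rank differences.
#'
#' @seealso [compareSpectra()], [coordinationAnalysis()]
#' @export
setClass("SpectrumComparison",
  representation(
    groupA = "character", groupB = "character",
    spectrumA = "EigenSpectrum", spectrumB = "EigenSpectrum",
    perRankDelta = "numeric"
  ),
  validity = function(object) {
    na <- length(object@spectrumA@values)
    if (length(object@spectrumB@values) != na)
      return("spectra must have equal length")
    if (length(object@perRankDelta) != na)
      return("'perRankDelta' length must match the spectra")
    if (abs(sum(object@perRankDelta)) > 1e-10)
      return("per-rank deltas must sum to 0 within 1e-10")
    if (!setequal(object@spectrumA@geneIds, object@spectrumB@geneIds))
      return("spectra must describe the same gene set")
    TRUE
  }
)

#' Design of a synthetic two-group expression study
#'
#' Describes a block-correlated multivariate normal generative model on the
#' log2-expression scale: genes are partitioned into modules, each module is
#' equicorrelated with a group-specific coefficient rho, a subset of genes
#' receives an additive mean shift in one designated group, and all genes
#' share a common standard deviation.  Genes in different modules are
#' independent.
#'
#' @slot modules named list of character vectors; each element is the gene
#'   IDs of one coordinated module.  Genes listed nowhere are independent.
#' @slot rho named list (one element per group) of named numeric vectors
#'   giving the equicorrelation coefficient of each module in that group.
#'   A k-gene module requires rho in (-1/(k-1), 1) so the implied
#'   correlation matrix is positive definite.
#' @slot meanShift named numeric vector of additive shifts (log2 units)
#'   applied to the named genes in \code{shiftGroup} only.
#' @slot shiftGroup the group receiving the mean shifts.
#' @slot groupSizes named integer vector of sample counts per group
#'   (each at least 2).
#' @slot noiseSd common per-gene standard deviation (scales the
#'   unit-variance correlation blocks).
#' @slot seed integer seed making the draw fully reproducible.
#'
#' @seealso [syntheticDesign()], [simulateExpression()]
#' @export
setClass("SyntheticDesign",
  representation(
    modules = "list", rho = "list", meanShift = "numeric",
    shiftGroup = "character", groupSizes = "integer",
    noiseSd = "numeric", seed = "integer"
  ),
  validity = function(object) {
    gs <- object@groupSizes
    if (length(gs) < 1L || is.null(names(gs)) || anyNA(gs))
      return("'groupSizes' must be a named integer vector")
    if (any(gs < 2L)) return("every group must have at least 2 samples")
    if (length(object@modules) > 0L) {
      genes <- unlist(object@modules, use.names = FALSE)
      if (anyDuplicated(genes))
        return("a gene may belong to at most one module")
      if (is.null(names(object@modules)))
        return("'modules' must be a named list")
    }
    for (g in names(object@rho)) {
      if (!g %in% names(gs))
        return(sprintf("rho given for unknown group '%s'", g))
      r <- object@rho[[g]]
      for (mod in names(r)) {
        if (!mod %in% names(object@modules))
          return(sprintf("rho given for unknown module '%s'", mod))
        k <- length(object@modules[[mod]])
        lo <- if (k > 1L) -1 / (k - 1) else -Inf
        if (r[[mod]] <= lo || r[[mod]] >= 1)
          return(sprintf(
            "rho = %g for %d-gene module '%s' is outside (%.4g, 1)",
            r[[mod]], k, mod, lo))
      }
    }
    if (length(object@shiftGroup) != 1L ||
        !object@shiftGroup %in% names(gs))
      return("'shiftGroup' must name one of the groups")
    if (length(object@meanShift) > 0L && is.null(names(object@meanShift)))
      return("'meanShift' must be a named numeric vector")
    if (length(object@noiseSd) != 1L || object@noiseSd <= 0)
      return("'noiseSd' must be a single positive number")
    TRUE
  }
)

setMethod("show", "GramMatrix", function(object) {
  cat(sprintf("GramMatrix: %d genes, %d samples\n",
              nrow(object@values), object@sampleCount))
  cat("genes:", paste(rownames(object@values), collapse = ", "), "\n")
})

setMethod("show", "EigenSpectrum", function(object) {
  cat(sprintf("EigenSpectrum over %d genes (%s)\n",
              length(object@values),
              paste(object@geneIds, collapse = ", ")))
  print(round(object@values, 4))
})

setMethod("show", "SpectrumComparison", function(object) {
  cat(sprintf("SpectrumComparison: %s vs %s over %d ranks\n",
              object@groupA, object@groupB, length(object@perRankDelta)))
  cat(sprintf("  largest-rank delta (B - A): %+0.4f\n",
              object@perRankDelta[1L]))
  cat(sprintf("  smallest-rank delta (B - A): %+0.4f\n",
              object@perRankDelta[length(object@perRankDelta)]))
})

setMethod("show", "SyntheticDesign", function(object) {
  cat("SyntheticDesign\n")
  cat("  groups:",
      paste(sprintf("%s (n=%d)", names(object@groupSizes),
                    object@groupSizes), collapse = ", "), "\n")
  cat(sprintf("  modules: %d; shifted genes: %d (in group %s)\n",
              length(object@modules), length(object@meanShift),
              object@shiftGroup))
  cat(sprintf("  noiseSd = %g, seed = %d\n", object@noiseSd, object@seed))
})
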