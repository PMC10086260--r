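#' Accessors for eigen-coordination objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a [GramMatrix-class], [EigenSpectrum-class] or
#'   [SpectrumComparison-class] object.
#' @return `gramValues` the symmetric inner-product matrix;
#'   `sampleCount` the number of samples it was built over;
#'   `spectrumValues` the normalized eigenvalues (descending, unit sum);
#'   `geneIds` the gene set; `perRankDelta` the per-rank spectrum
#'   differences (group B minus group A); `largestDelta` /
#'   `smallestDelta` the delta at the first / last rank.
#'
#' @examples
#' R <- innerProductMatrix(zscoreRows(matrix(rnorm(40), 4,
#'   dimnames = list(paste0("g", 1:4), NULL))))
#' s <- normalizedEigenvalues(R)
#' spectrumValues(s)
#' geneIds(s)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gramValues", function(x) standardGeneric("gramValues"))

#' @rdname accessors
#' @export
setGeneric("sampleCount", function(x) standardGeneric("sampleCount"))

#' @rdname accessors
#' @export
setGeneric("spectrumValues", function(x) standardGeneric("spectrumValues"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("perRankDelta", function(x) standardGeneric("perRankDelta"))

#' @rdname accessors
#' @export
setGeneric("largestDelta", function(x) standardGeneric("largestDelta"))

#' @rdname accessors
#' @export
setGeneric("smallestDelta", function(x) standardGeneric("smallestDelta"))

#' @rdname accessors
setMethod("gramValues", "GramMatrix", function(x) x@values)

#' @rdname accessors
setMethod("sampleCount", "GramMatrix", function(x) x@sampleCount)

#' @rdname accessors
setMethod("spectrumValues", "EigenSpectrum", function(x) x@values)

#' @rdname accessors
setMethod("geneIds", "EigenSpectrum", function(x) x@geneIds)

#' @rdname accessors
setMethod("geneIds", "GramMatrix", function(x) rownames(x@values))

#' @rdname accessors
setMethod("perRankDelta", "SpectrumComparison", function(x) x@perRankDelta)

#' @rdname accessors
setMethod("largestDelta", "SpectrumComparison",
          function(x) x@perRankDelta[1L])

#' @rdname accessors
setMethod("smallestDelta", "SpectrumComparison",
          function(x) x@perRankDelta[length(x@perRankDelta)])

#' @rdname accessors
#' @export
setGeneric("comparisonSpectra",
           function(x) standardGeneric("comparisonSpectra"))

#' @rdname accessors
setMethod("comparisonSpectra", "SpectrumComparison", function(x) {
  s <- list(x@spectrumA, x@spectrumB)
  names(s) <- c(x@groupA, x@groupB)
  s
})
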