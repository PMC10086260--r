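#' Equicorrelation matrix
#'
#' The n x n correlation matrix with unit diagonal and a common
#' off-diagonal value rho.  Its eigenvalues are known in closed form:
#' \eqn{1 + (n-1)\rho} once and \eqn{1 - \rho} with multiplicity
#' \eqn{n - 1}, which makes it the analytic oracle for the eigen-spectrum
#' machinery.  Positive semi-definiteness requires
#' \eqn{\rho \in (-1/(n-1), 1]}.
#'
#' @param n number of genes (>= 1).
#' @param rho common correlation coefficient.
#' @param geneIds optional gene IDs (defaults to `g1..gn`).
#' @return symmetric numeric matrix with unit diagonal.
#' @examples
#' eigen(equicorrMatrix(4, 0.6))$values  # 2.8, 0.4, 0.4, 0.4
#' @export
equicorrMatrix <- function(n, rho, geneIds = NULL) {
  if (n < 1L) stop("'n' must be at least 1")
  if (n > 1L) {
    lo <- -1 / (n - 1)
    if (rho <= lo || rho > 1)
      stop(sprintf(
        "rho = %g is outside the PSD range (%.4g, 1] for n = %d", rho, lo, n))
  }
  m <- matrix(rho, n, n)
  diag(m) <- 1
  if (is.null(geneIds)) geneIds <- paste0("g", seq_len(n))
  dimnames(m) <- list(geneIds, geneIds)
  m
}

#' Construct a synthetic two-group study design
#'
#' Convenience constructor for [SyntheticDesign-class].  The defaults
#' emulate a small two-group microarray study — 10 case ("AD") and 9
#' control ("CON") samples, one four-gene module whose coordination is
#' strong in the case group (rho = 0.9) and weak in controls (rho = 0.1) —
#' with unit noise on the log2 scale.
#'
#' @param modules named list of gene-ID character vectors.
#' @param rho named list per group of named per-module equicorrelation
#'   coefficients; a k-gene module needs rho in (-1/(k-1), 1).
#' @param meanShift named numeric vector of additive log2 shifts applied
#'   in `shiftGroup`.
#' @param shiftGroup group receiving the shifts (default: first group).
#' @param groupSizes named sample counts per group, each >= 2.
#' @param noiseSd common per-gene standard deviation.
#' @param seed integer seed.
#' @param extraGenes number of additional independent, unshifted genes to
#'   append beyond those named in `modules` and `meanShift`.
#' @return a validated [SyntheticDesign-class] object.
#' @examples
#' d <- syntheticDesign()
#' se <- simulateExpression(d)
#' dim(se)
#' @export
syntheticDesign <- function(
    modules = list(M1 = c("hubA", "hubB", "hubC", "anchor")),
    rho = list(AD = c(M1 = 0.9), CON = c(M1 = 0.1)),
    meanShift = numeric(0),
    shiftGroup = names(groupSizes)[1L],
    groupSizes = c(AD = 10L, CON = 9L),
    noiseSd = 1, seed = 1L, extraGenes = 0L) {
  methods::new("SyntheticDesign",
    modules = modules, rho = rho,
    meanShift = meanShift, shiftGroup = shiftGroup,
    groupSizes = stats::setNames(as.integer(groupSizes),
                                 names(groupSizes)),
    noiseSd = as.numeric(noiseSd), seed = as.integer(seed)) -> d
  if (extraGenes > 0L)
    attr(d, "extraGenes") <- as.integer(extraGenes)
  d
}

.designGenes <- function(design) {
  genes <- unique(c(unlist(design@modules, use.names = FALSE),
                    names(design@meanShift)))
  extra <- attr(design, "extraGenes")
  if (!is.null(extra) && extra > 0L)
    genes <- c(genes, sprintf("noise%03d", seq_len(extra)))
  if (length(genes) == 0L)
    stop("design describes no genes; give modules, meanShift or extraGenes")
  genes
}

.groupCorrelation <- function(design, group, genes) {
  n <- length(genes)
  R <- diag(n)
  dimnames(R) <- list(genes, genes)
  rho <- design@rho[[group]]
  for (mod in names(rho)) {
    ids <- design@modules[[mod]]
    R[ids, ids] <- equicorrMatrix(length(ids), rho[[mod]], ids)
  }
  R
}

#' Simulate a block-correlated two-group expression dataset
#'
#' Each group's samples are drawn from a multivariate normal whose
#' correlation matrix is block-diagonal over the design's modules (with
#' that group's rho per module, identity elsewhere), scaled by
#' `noiseSd^2`.  Means are zero except for the `meanShift` genes in the
#' designated group.  One global seed feeds a single generator stream;
#' groups are drawn sequentially in sorted order, so the whole dataset is
#' bit-for-bit reproducible from the design.
#'
#' @param design a [SyntheticDesign-class] (see [syntheticDesign()]).
#' @return expression `SummarizedExperiment` with `colData$group`.
#' @export
simulateExpression <- function(design) {
  stopifnot(methods::is(design, "SyntheticDesign"))
  methods::validObject(design)
  genes <- .designGenes(design)
  groups <- sort(names(design@groupSizes))
  set.seed(design@seed)
  mats <- lapply(groups, function(g) {
    R <- .groupCorrelation(design, g, genes)
    Sigma <- design@noiseSd^2 * R
    mu <- stats::setNames(numeric(length(genes)), genes)
    if (g == design@shiftGroup && length(design@meanShift))
      mu[names(design@meanShift)] <- mu[names(design@meanShift)] +
        design@meanShift
    n <- design@groupSizes[[g]]
    x <- tryCatch(
      MASS::mvrnorm(n = n, mu = mu, Sigma = Sigma),
      error = function(e) stop(
        "implied covariance for group '", g,
        "' is not positive semi-definite: ", conditionMessage(e)))
    t(x)  # genes x samples
  })
  counts <- design@groupSizes[groups]
  values <- do.call(cbind, mats)
  colnames(values) <- unlist(lapply(seq_along(groups), function(i)
    sprintf("%s_%02d", groups[i], seq_len(counts[i]))))
  rownames(values) <- genes
  makeExpressionSE(values, groups = rep(groups, counts))
}

#' Simulate an undirected PPI-style edge list with planted hubs
#'
#' Builds a simple undirected graph in which every planted hub ends with
#' exactly its requested degree while all other nodes stay at strictly
#' smaller degree, then attaches a uniform confidence score in [0.5, 1]
#' to each edge.  Hubs preferentially attach to the currently
#' least-connected nodes; a few background edges among non-hub nodes keep
#' the graph from being a pure union of stars.
#'
#' @param nNodes total node count.
#' @param plantedHubs named integer vector `c(node = degree, ...)`
#'   (empty for a background-only graph); every degree must be < nNodes.
#' @param seed integer seed.
#' @param nBackground number of random background edges to attempt among
#'   non-hub nodes (default `nNodes %/% 4`).
#' @return data.frame with columns `nodeA`, `nodeB`, `score`.
#' @examples
#' e <- simulateEdgeList(10, c(G1 = 9), seed = 1)
#' degreeRanking(e, k = 1)
#' @export
simulateEdgeList <- function(nNodes, plantedHubs = integer(0), seed = 1L,
                             nBackground = nNodes %/% 4L) {
  if (length(plantedHubs)) {
    if (is.null(names(plantedHubs)))
      stop("'plantedHubs' must be named by node ID")
    if (any(plantedHubs >= nNodes))
      stop("planted degree must be smaller than the node count")
    if (any(plantedHubs < 1L)) stop("planted degrees must be positive")
  }
  hubs <- names(plantedHubs)
  if (length(hubs) >= nNodes)
    stop("more hubs than nodes")
  others <- setdiff(sprintf("N%03d", seq_len(nNodes)), hubs)
  nodes <- c(hubs, others[seq_len(nNodes - length(hubs))])
  deg <- stats::setNames(integer(nNodes), nodes)
  # non-hub degrees must stay below the smallest planted degree
  cap <- if (length(plantedHubs)) min(plantedHubs) - 1L else nNodes - 2L
  set.seed(seed)
  edges <- character(0)
  edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  addEdge <- function(a, b) {
    edges <<- c(edges, edgeKey(a, b))
    deg[a] <<- deg[a] + 1L
    deg[b] <<- deg[b] + 1L
  }
  for (h in names(sort(plantedHubs, decreasing = TRUE))) {
    need <- plantedHubs[[h]] - deg[[h]]
    if (need <= 0L) next
    cand <- setdiff(nodes, h)
    cand <- cand[!edgeKey(h, cand) %in% edges]
    ok <- vapply(cand, function(c2) {
      if (c2 %in% hubs) deg[[c2]] < plantedHubs[[c2]]
      else deg[[c2]] < cap
    }, logical(1))
    cand <- cand[ok]
    if (length(cand) < need)
      stop(sprintf("cannot realize degree %d for hub '%s'",
                   plantedHubs[[h]], h))
    # least-connected first; random among ties
    cand <- cand[order(deg[cand], stats::runif(length(cand)))]
    for (c2 in cand[seq_len(need)]) addEdge(h, c2)
  }
  nonHubs <- setdiff(nodes, hubs)
  if (nBackground > 0L && length(nonHubs) >= 2L) {
    for (i in seq_len(nBackground)) {
      pair <- sample(nonHubs, 2L)
      if (edgeKey(pair[1L], pair[2L]) %in% edges) next
      if (deg[[pair[1L]]] >= cap || deg[[pair[2L]]] >= cap) next
      addEdge(pair[1L], pair[2L])
    }
  }
  parts <- do.call(rbind, strsplit(edges, "\r", fixed = TRUE))
  data.frame(
    nodeA = parts[, 1L], nodeB = parts[, 2L],
    score = stats::runif(length(edges), 0.5, 1.0))
}
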