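#' Read a protein-protein interaction edge list
#'
#' Reads a TSV edge list (`nodeA`, `nodeB`, optional `score`), removes
#' self-loops and duplicate undirected edges, and drops edges below a
#' confidence threshold.  Scores are accepted in either the [0, 1] or the
#' [0, 1000] dialect (any value above 1 switches the whole column to the
#' thousand scale and it is divided by 1000).
#'
#' @param path TSV file with at least two columns; a header row is
#'   detected automatically.
#' @param minScore drop edges with score strictly below this (ignored
#'   when no score column is present).
#' @return data.frame with columns `nodeA`, `nodeB` and, when present,
#'   `score` in [0, 1].
#' @export
readEdgeList <- function(path, minScore = 0) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("node|score|protein", tolower(first))
  tab <- tryCatch(
    utils::read.table(path, header = hasHeader, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed edge list '", path, "': ",
                             conditionMessage(e)))
  if (ncol(tab) < 2L) stop("edge list needs at least 2 columns")
  edges <- data.frame(nodeA = as.character(tab[[1L]]),
                      nodeB = as.character(tab[[2L]]))
  if (ncol(tab) >= 3L) {
    score <- suppressWarnings(as.numeric(tab[[3L]]))
    if (anyNA(score)) {
      bad <- which(is.na(score))[1L] + hasHeader
      stop("malformed score on line ", bad, " of '", path, "'")
    }
    if (any(score > 1)) score <- score / 1000
    if (any(score < 0 | score > 1))
      stop("edge scores must lie in [0, 1] (or [0, 1000])")
    edges$score <- score
  }
  filterEdges(edges, minScore)
}

#' @describeIn readEdgeList apply the same cleaning (self-loop removal,
#'   undirected dedupe, score threshold) to an in-memory edge data.frame.
#' @param edges data.frame with columns `nodeA`, `nodeB`, optional
#'   `score`.
#' @export
filterEdges <- function(edges, minScore = 0) {
  keep <- edges$nodeA != edges$nodeB
  edges <- edges[keep, , drop = FALSE]
  if (!is.null(edges$score)) edges <- edges[edges$score >= minScore, ,
                                            drop = FALSE]
  key <- paste(pmin(edges$nodeA, edges$nodeB),
               pmax(edges$nodeA, edges$nodeB), sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

.edgeGraph <- function(edges) {
  igraph::graph_from_data_frame(edges[, c("nodeA", "nodeB")],
                                directed = FALSE)
}

#' Drop nodes with no retained interaction
#'
#' Mirrors the usual "hide disconnected nodes" step of PPI network
#' construction: of a candidate node universe (e.g. every differentially
#' expressed gene submitted to the interaction database), keep only those
#' incident to at least one retained edge.
#'
#' @param edges cleaned edge data.frame (see [filterEdges()]).
#' @param nodeUniverse optional character vector of candidate nodes; when
#'   given, the result is its intersection with the connected nodes, in
#'   universe order.
#' @return character vector of connected node IDs.
#' @export
dropIsolatedNodes <- function(edges, nodeUniverse = NULL) {
  connected <- unique(c(edges$nodeA, edges$nodeB))
  if (is.null(nodeUniverse)) return(sort(connected))
  nodeUniverse[nodeUniverse %in% connected]
}

#' Rank hub genes by network degree
#'
#' Unweighted degree centrality: each node's count of incident retained
#' edges, the plain "Degree" hub criterion.  Ties are broken by
#' lexicographic node ID so the ranking is deterministic.
#'
#' @param edges cleaned edge data.frame.
#' @param k how many top nodes to return (capped at the node count).
#' @return data.frame with columns `node` and `degree`, degrees
#'   non-increasing.
#' @examples
#' e <- simulateEdgeList(30, c(A = 12, B = 9, C = 7), seed = 2)
#' degreeRanking(e, k = 3)
#' @export
degreeRanking <- function(edges, k = 10L) {
  if (k < 1L) stop("'k' must be at least 1")
  if (nrow(edges) == 0L)
    return(data.frame(node = character(0), degree = integer(0)))
  g <- .edgeGraph(edges)
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  top <- ord[seq_len(min(k, length(deg)))]
  data.frame(node = names(deg)[top], degree = as.integer(deg[top]),
             row.names = NULL)
}
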