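# Shared fixture builders; everything is generated in code.

# small labeled expression container with known values
fixtureSE <- function(values = matrix(rnorm(20), 5, 4,
                                      dimnames = list(paste0("g", 1:5),
                                                      paste0("s", 1:4))),
                      groups = c("AD", "AD", "CON", "CON")) {
  makeExpressionSE(values, groups = groups)
}

# brute-force BH step-up, independent of stats::p.adjust
bruteForceBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# pair-counting AUC oracle (Mann-Whitney with half-ties)
pairCountAUC <- function(scores, labels, posClass) {
  pos <- scores[labels == posClass]
  neg <- scores[labels != posClass]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# textbook Welch t-test returning the two-sided p-value
welchOracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# per-node degree by direct edge counting, independent of igraph
bruteForceDegrees <- function(edges) {
  nodes <- unique(c(edges$nodeA, edges$nodeB))
  sapply(nodes, function(n) sum(edges$nodeA == n) + sum(edges$nodeB == n))
}

# edge list emulating a sparse PPI network: 22 edges touching 30 of 40
# candidate nodes (eight disjoint paths of sizes 4x6 + 3x2: 22 edges,
# 30 nodes), leaving 10 candidates isolated
fixtureHubNetwork <- function() {
  nodes <- sprintf("P%02d", 1:40)
  sizes <- c(4, 4, 4, 4, 4, 4, 3, 3)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  edges <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    idx <- starts[i]:ends[i]
    data.frame(nodeA = nodes[head(idx, -1)], nodeB = nodes[idx[-1]])
  }))
  edges$score <- seq(0.991, 0.999, length.out = nrow(edges))
  list(edges = edges, universe = nodes)
}
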