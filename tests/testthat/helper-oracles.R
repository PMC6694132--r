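# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Brute-force Spearman: rank both vectors, then Pearson on the ranks.
bruteSpearman <- function(x, y) {
  cor(rank(x), rank(y))
}

# Full-vs-reduced-model F test for the interaction term, via explicit
# residual sums of squares.
anovaInteractionOracle <- function(gA, gB, y) {
  reduced <- lm(y ~ gA + gB)
  full <- lm(y ~ gA + gB + I(gA * gB))
  rssR <- sum(residuals(reduced)^2)
  rssF <- sum(residuals(full)^2)
  df <- length(y) - 4
  f <- (rssR - rssF) / (rssF / df)
  list(f = f, p = pf(f, 1, df, lower.tail = FALSE))
}

# Breadth-first search giving exact shortest-path hop distances from a node
# over an undirected edge list (two-column matrix of node names).
bfsDistances <- function(edges, nodes, from) {
  adj <- lapply(setNames(nodes, nodes), function(n) character())
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(adj[frontier])), names(dist)[is.finite(dist)])
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# Tiny fixed annotation shared by several tests.
smallAnnotation <- function(seed = 42, nGenes = 12, nPseudogenes = 2) {
  genGeneAnnotation(nGenes, nPseudogenes, overlapFraction = 0, seed = seed)
}
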