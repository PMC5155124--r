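# Fixture builders and independent oracles used across the suite.
# Oracles deliberately use different machinery than the implementation:
# igraph shortest paths / geodesic enumeration and direct set arithmetic.

# network from an explicit edge list; weights default to 0.5
mkNet <- function(edges, ids = NULL, weights = NULL, phase = "p") {
  if (is.null(ids)) ids <- sort(unique(unlist(edges)))
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(edges)) {
    if (is.null(weights)) weights <- rep(0.5, length(edges))
    for (e in seq_along(edges)) {
      a <- edges[[e]][1]; b <- edges[[e]][2]
      W[a, b] <- W[b, a] <- weights[e]
    }
  }
  CoexNetwork(W, ids, phase)
}

# random sparse symmetric weight matrix with zero diagonal
randW <- function(n, p = 0.3, wmin = 0.1, wmax = 0.95) {
  ids <- sprintf("v%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- which(upper.tri(W))
  on <- ut[stats::runif(length(ut)) < p]
  W[on] <- stats::runif(length(on), wmin, wmax)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

asIgraph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# BFS ball oracle: nodes at unweighted shortest-path distance <= k
oracleBall <- function(W, center, k) {
  d <- igraph::distances(asIgraph(W), v = center, weights = NA)[1, ]
  names(d)[d <= k]
}

# induced edge set over `nodes`, canonical sorted-pair keys
oracleEdges <- function(W, nodes) {
  keys <- character(0)
  nodes <- sort(nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j && W[nodes[i], nodes[j]] != 0)
      keys <- c(keys, paste(nodes[i], nodes[j], sep = "|"))
  }
  keys
}

# dcgnS oracle: direct set arithmetic over independently computed balls
oracleDcgnS <- function(WA, WB, gene, k) {
  ea <- oracleEdges(WA, oracleBall(WA, gene, k))
  eb <- oracleEdges(WB, oracleBall(WB, gene, k))
  if (length(ea) == 0 && length(eb) == 0) return(0)
  1 - length(intersect(ea, eb)) / length(union(ea, eb))
}

# exhaustive enumeration of minimal-hop walks center -> target inside the
# node set, maximising the product of transition probabilities along them
oracleMaxProb <- function(Wsub, M, center, target) {
  g <- asIgraph(Wsub)
  asp <- igraph::all_shortest_paths(g, from = center, to = target, weights = NA)
  paths <- if (!is.null(asp$vpaths)) asp$vpaths else asp$res
  stopifnot(length(paths) > 0)
  max(vapply(paths, function(p) {
    v <- names(p)
    prod(M[cbind(v[-length(v)], v[-1])])
  }, numeric(1)))
}

# independent star arithmetic: pmax via geodesic enumeration, then the
# normalise / invert / -p ln p chain written out explicitly
oracleStarInfo <- function(W, M, center, k) {
  nodes <- oracleBall(W, center, k)
  partners <- setdiff(nodes, center)
  if (!length(partners)) return(numeric(0))
  Wsub <- W[nodes, nodes, drop = FALSE]
  pmax <- vapply(partners, function(j) oracleMaxProb(Wsub, M, center, j),
                 numeric(1))
  p <- pmax / sum(pmax)
  q <- (1 / p) / sum(1 / p)
  ifelse(q >= 1, 0, -log(q) * q)
}

oracleDcgnI <- function(WA, WB, MA, MB, gene, k) {
  nA <- setdiff(oracleBall(WA, gene, k), gene)
  nB <- setdiff(oracleBall(WB, gene, k), gene)
  tot <- 0
  exA <- setdiff(nA, nB); exB <- setdiff(nB, nA)
  if (length(exA)) tot <- tot + sum(oracleStarInfo(WA, MA, gene, k)[exA])
  if (length(exB)) tot <- tot + sum(oracleStarInfo(WB, MB, gene, k)[exB])
  tot
}

# AUC as the normalised Mann-Whitney U statistic, by explicit double loop
oracleAUC <- function(orderedGenes, pos, neg) {
  posIdx <- match(pos, orderedGenes)
  negIdx <- match(neg, orderedGenes)
  u <- 0
  for (p in posIdx) for (q in negIdx)
    u <- u + (p < q) + 0.5 * (p == q)
  u / (length(pos) * length(neg))
}
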