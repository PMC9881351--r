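# Independent brute-force oracles used to validate the implementation on
# small instances.  Nothing here calls the code paths under test.

# all maximal cliques of a graph given as an adjacency matrix, by direct
# recursive extension (independent of igraph's Bron-Kerbosch)
bruteMaximalCliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  extend <- function(clique, candidates) {
    extendable <- FALSE
    for (v in candidates) {
      if (all(adj[clique, v] == 1)) {
        extendable <- TRUE
        if (v > max(clique)) extend(c(clique, v), candidates[candidates > v])
      }
    }
    if (!extendable) {
      # maximal iff no vertex outside is adjacent to every member
      maximal <- !any(vapply(setdiff(seq_len(n), clique), function(u)
        all(adj[clique, u] == 1), logical(1)))
      if (maximal) cliques[[length(cliques) + 1L]] <<- clique
    }
  }
  for (v in seq_len(n)) extend(v, setdiff(seq_len(n), seq_len(v)))
  cliques
}

# MCC by exhaustive maximal-clique enumeration with the degree fallback
bruteMCC <- function(adj) {
  n <- nrow(adj)
  cl <- bruteMaximalCliques(adj)
  scores <- numeric(n)
  inTri <- logical(n)
  for (c in cl) {
    if (length(c) < 2) next
    scores[c] <- scores[c] + factorial(length(c) - 1)
    if (length(c) >= 3) inTri[c] <- TRUE
  }
  deg <- rowSums(adj)
  scores[!inTri] <- deg[!inTri]
  scores
}

# two-sided Fisher exact p by exhaustive enumeration over the support of
# the fixed-margin 2x2 family
bruteFisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  kmin <- max(0, r1 + c1 - n); kmax <- min(r1, c1)
  ks <- kmin:kmax
  probs <- dhyper(ks, c1, n - c1, r1)
  pObs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# ORA upper-tail p by exhaustive enumeration of all query draws from a
# small universe
bruteOra <- function(N, setSize, querySize, overlap) {
  draws <- combn(N, querySize)
  inSet <- seq_len(setSize)            # wlog the set is 1..setSize
  mean(apply(draws, 2, function(q) sum(q %in% inSet) >= overlap))
}

# AUC by all-pairs counting with half-credit for ties
bruteAuc <- function(scores, labels) {
  cs <- scores[labels == "case"]; ks <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ks)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ks))
}

# random simple graph as igraph + adjacency, for oracle comparisons
randomGraph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(graph = g, adj = adj)
}
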