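# Interaction-network stage: score-filtered graph construction, MCODE-style
# dense-module detection (k-core-based vertex weighting, seed-and-grow,
# haircut), the five cytoHubba centralities, and the hub consensus.

#' Build a score-filtered interaction graph
#'
#' Edges with `combined_score > minScore` (strict) are retained; STRING-style
#' integer scores on the 0-1000 scale are auto-rescaled to [0, 1] (any score
#' above 1 triggers the rescale).  Duplicate edges collapse to their maximum
#' score; self-loops are dropped; isolated nodes do not appear.
#'
#' @param edgeList data.frame with columns node_a, node_b, combined_score
#'   (or the first three columns in that order).
#' @param minScore strict lower bound on the combined score (default 0.4).
#' @return an undirected igraph with edge attribute `combined_score`.
#' @examples
#' el <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
#'                  combined_score = c(0.39, 0.41))
#' buildGraph(el)   # keeps only B-C
#' @export
buildGraph <- function(edgeList, minScore = 0.4) {
  edgeList <- as.data.frame(edgeList)
  if (!all(c("node_a", "node_b", "combined_score") %in% names(edgeList))) {
    if (ncol(edgeList) < 3)
      stop("edge list needs columns node_a, node_b, combined_score")
    names(edgeList)[1:3] <- c("node_a", "node_b", "combined_score")
  }
  score <- suppressWarnings(as.numeric(edgeList$combined_score))
  if (anyNA(score))
    stop("malformed combined_score at row(s) ",
         paste(which(is.na(score)), collapse = ", "))
  if (any(score > 1)) score <- score / 1000   # STRING 0-1000 dialect
  if (any(score < 0 | score > 1))
    stop("combined scores must lie in [0, 1] after rescaling")
  a <- as.character(edgeList$node_a); b <- as.character(edgeList$node_b)
  keep <- score > minScore & a != b
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  # canonical order + dedup keeping the max score
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  ord <- order(key, -score)
  dup <- duplicated(key[ord])
  lo <- lo[ord][!dup]; hi <- hi[ord][!dup]; score <- score[ord][!dup]
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE)
  igraph::E(g)$combined_score <- score
  g
}

#' MCODE-style module score
#'
#' `score = density * V` with `density = E / (V * (V - 1))`, i.e. the score
#' reduces to `E / (V - 1)`.  This is the convention under which a module of
#' 14 nodes and 60 edges scores 60/13 = 4.615.
#'
#' @param graph an igraph module, or `NULL` when `nNodes`/`nEdges` given.
#' @param nNodes,nEdges explicit counts (used when `graph` is `NULL`).
#' @return numeric module score.
#' @examples
#' moduleScore(nNodes = 14, nEdges = 60)   # 4.615...
#' @export
moduleScore <- function(graph = NULL, nNodes = NULL, nEdges = NULL) {
  if (!is.null(graph)) {
    nNodes <- igraph::vcount(graph)
    nEdges <- igraph::ecount(graph)
  }
  if (nNodes < 2) return(0)
  nEdges / (nNodes * (nNodes - 1)) * nNodes
}

.graphDensityDir <- function(g) {
  v <- igraph::vcount(g)
  if (v < 2) return(0)
  igraph::ecount(g) / (v * (v - 1))
}

# MCODE vertex weighting: for each vertex, take the induced subgraph on the
# closed neighborhood, extract its highest k-core, and weight the vertex by
# core number x core density.  Vertices under the degree cutoff weigh 0.
.mcodeWeights <- function(g, degreeCutoff) {
  deg <- igraph::degree(g)
  vapply(seq_len(igraph::vcount(g)), function(i) {
    if (deg[i] < degreeCutoff) return(0)
    nb <- c(i, as.integer(igraph::neighbors(g, i)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0) return(0)
    kcore <- igraph::induced_subgraph(sub, which(core == k))
    k * .graphDensityDir(kcore)
  }, numeric(1))
}

#' Detect dense modules with an MCODE-style algorithm
#'
#' Vertices are weighted by the density of the highest k-core of their
#' closed neighborhood times its core number; complexes grow outward from
#' the highest-weight unvisited seed, including neighbors whose weight is at
#' least `seedWeight * (1 - nodeScoreCutoff)` up to `maxDepth`.  Complexes
#' are disjoint, must contain a `kCore`-core, are optionally haircut
#' (singly-connected nodes pruned), and are reported when they keep >= 3
#' nodes and a positive score, sorted by score descending.
#'
#' @param graph an igraph.
#' @param nodeScoreCutoff fraction of the seed weight a neighbor may fall
#'   short by (default 0.2).
#' @param degreeCutoff minimum degree to receive weight / seed (default 2).
#' @param kCore required core of a reported complex (default 2).
#' @param maxDepth growth radius from the seed (default 100).
#' @param haircut prune singly-connected nodes from complexes
#'   (default `TRUE`).
#' @param fluff unused placeholder for the classical fluff step
#'   (default `FALSE`).
#' @return data.frame(module, n_nodes, n_edges, score, members) with
#'   `members` a list-column of node-name vectors.
#' @export
mcodeCluster <- function(graph, nodeScoreCutoff = 0.2, degreeCutoff = 2,
                         kCore = 2, maxDepth = 100, haircut = TRUE,
                         fluff = FALSE) {
  stopifnot(igraph::vcount(graph) > 0, kCore >= 2)
  w <- .mcodeWeights(graph, degreeCutoff)
  visited <- rep(FALSE, igraph::vcount(graph))
  deg <- igraph::degree(graph)
  names_v <- igraph::V(graph)$name
  modules <- list()
  ord <- order(-w, names_v)
  for (seed in ord) {
    if (visited[seed] || w[seed] <= 0 || deg[seed] < degreeCutoff) next
    thr <- w[seed] * (1 - nodeScoreCutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < maxDepth) {
      nxt <- integer()
      for (v in frontier) {
        for (u in as.integer(igraph::neighbors(graph, v))) {
          if (!visited[u] && w[u] >= thr) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(graph, members)
    if (max(igraph::coreness(sub)) < kCore) next
    if (haircut) {
      repeat {
        d <- igraph::degree(sub)
        if (all(d >= 2) || igraph::vcount(sub) == 0) break
        sub <- igraph::induced_subgraph(sub, which(d >= 2))
      }
    }
    if (igraph::vcount(sub) < 3) next
    sc <- moduleScore(sub)
    if (sc <= 0) next
    modules[[length(modules) + 1L]] <- list(
      members = sort(igraph::V(sub)$name),
      n_nodes = igraph::vcount(sub), n_edges = igraph::ecount(sub),
      score = sc)
  }
  if (!length(modules))
    return(data.frame(module = integer(), n_nodes = integer(),
                      n_edges = integer(), score = numeric(),
                      members = I(list())))
  ordm <- order(-vapply(modules, `[[`, numeric(1), "score"))
  modules <- modules[ordm]
  data.frame(module = seq_along(modules),
             n_nodes = vapply(modules, `[[`, numeric(1), "n_nodes"),
             n_edges = vapply(modules, `[[`, numeric(1), "n_edges"),
             score = vapply(modules, `[[`, numeric(1), "score"),
             members = I(lapply(modules, `[[`, "members")),
             stringsAsFactors = FALSE)
}

.centralityMethods <- c("MCC", "Degree", "DMNC", "MNC",
                        "ClusteringCoefficient")

.mncComponent <- function(graph, v) {
  nb <- as.integer(igraph::neighbors(graph, v))
  if (!length(nb)) return(NULL)
  sub <- igraph::induced_subgraph(graph, nb)
  comp <- igraph::components(sub)
  big <- which.max(comp$csize)
  igraph::induced_subgraph(sub, which(comp$membership == big))
}

.mccScores <- function(graph) {
  n <- igraph::vcount(graph)
  if (n > 5000)
    stop("graph has more than 5000 nodes; maximal-clique enumeration is ",
         "exponential in the worst case — reduce the graph first")
  scores <- numeric(n)
  inTriangle <- logical(n)
  cliques <- igraph::max_cliques(graph, min = 2)
  for (cl in cliques) {
    idx <- as.integer(cl)
    scores[idx] <- scores[idx] + factorial(length(idx) - 1)
    if (length(idx) >= 3) inTriangle[idx] <- TRUE
  }
  deg <- igraph::degree(graph)
  scores[!inTriangle] <- deg[!inTriangle]   # cytoHubba fallback
  scores
}

#' Rank nodes by a cytoHubba-style centrality
#'
#' Methods: `MCC` (sum of (|C|-1)! over maximal cliques through the node,
#' falling back to degree for nodes in no triangle), `Degree`, `MNC` (size
#' of the largest connected component of the open neighborhood), `DMNC`
#' (edges of that component divided by its node count to the power 1.7),
#' and `ClusteringCoefficient` (local transitivity, 0 for degree < 2).
#' Ranking is score-descending with lexicographic tie-break; `topK` includes
#' every node tied with the k-th score so a tied gene is never dropped
#' arbitrarily.
#'
#' @param graph an igraph.
#' @param method one of `"MCC"`, `"Degree"`, `"DMNC"`, `"MNC"`,
#'   `"ClusteringCoefficient"`.
#' @param k size of the head list (default 14).
#' @return list with `method`, `scores` (data.frame node, score, sorted) and
#'   `topK` (character vector, tie-inclusive).
#' @export
centrality <- function(graph, method = "MCC", k = 14) {
  if (!method %in% .centralityMethods)
    stop("unknown method '", method, "'; valid methods: ",
         paste(.centralityMethods, collapse = ", "))
  nm <- igraph::V(graph)$name
  sc <- switch(method,
    Degree = as.numeric(igraph::degree(graph)),
    MCC = .mccScores(graph),
    MNC = vapply(seq_along(nm), function(v) {
      m <- .mncComponent(graph, v)
      if (is.null(m)) 0 else igraph::vcount(m)
    }, numeric(1)),
    DMNC = vapply(seq_along(nm), function(v) {
      m <- .mncComponent(graph, v)
      if (is.null(m) || igraph::vcount(m) == 0) return(0)
      igraph::ecount(m) / igraph::vcount(m)^1.7
    }, numeric(1)),
    ClusteringCoefficient = {
      cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
      cc[igraph::degree(graph) < 2] <- 0
      as.numeric(cc)
    })
  ord <- order(-sc, nm)
  scores <- data.frame(node = nm[ord], score = sc[ord],
                       stringsAsFactors = FALSE, row.names = NULL)
  kk <- min(k, nrow(scores))
  cutoffScore <- scores$score[kk]
  topK <- scores$node[scores$score >= cutoffScore]
  list(method = method, scores = scores, topK = topK)
}

#' Intersect top-k centrality lists into hub genes
#'
#' @param rankings list (>= 2) of results from [centrality()], or plain
#'   character vectors of top genes.
#' @param tissueSpecific optional gene set; `systemHubs` is its
#'   intersection with the hubs.
#' @return list with `hubs` (intersection of all top-k sets, sorted) and
#'   `systemHubs`.
#' @export
hubConsensus <- function(rankings, tissueSpecific = character()) {
  stopifnot(length(rankings) >= 2L)
  sets <- lapply(rankings, function(r) if (is.list(r)) r$topK else r)
  hubs <- sort(Reduce(intersect, sets))
  list(hubs = hubs, systemHubs = sort(intersect(hubs, tissueSpecific)))
}
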