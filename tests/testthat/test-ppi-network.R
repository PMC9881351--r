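# Graph construction, MCODE-style modules, the five centralities, and the
# hub consensus.

test_that("edge filtering is strict at the score threshold", {
  el <- data.frame(node_a = c("A", "B", "C"), node_b = c("B", "C", "D"),
                   combined_score = c(0.39, 0.40, 0.41))
  g <- buildGraph(el)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("C", "D"))
})

test_that("STRING 0-1000 scores are rescaled and duplicates keep the max", {
  el <- data.frame(node_a = c("A", "A", "B", "C"),
                   node_b = c("B", "B", "A", "C"),
                   combined_score = c(400, 900, 700, 999))
  g <- buildGraph(el)                    # self-loop C-C dropped
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$combined_score, 0.9)
  bad <- data.frame(node_a = "A", node_b = "B", combined_score = "oops")
  expect_error(buildGraph(bad), "row")
})

test_that("module score follows the density-times-nodes convention", {
  expect_equal(round(moduleScore(nNodes = 14, nEdges = 60), 3), 4.615)
  expect_equal(round(moduleScore(nNodes = 15, nEdges = 50), 3), 3.571)
  expect_equal(moduleScore(nNodes = 9, nEdges = 28), 3.5)
  expect_equal(moduleScore(igraph::make_full_graph(5)), 2.5)
})

test_that("a planted clique is recovered as the top module", {
  set.seed(42)
  k5 <- igraph::make_full_graph(5)
  bg <- igraph::sample_gnp(20, 0.05)
  g <- igraph::disjoint_union(k5, bg)
  igraph::V(g)$name <- paste0("v", 1:25)
  mods <- mcodeCluster(g)
  expect_gte(nrow(mods), 1)
  expect_setequal(mods$members[[1]], paste0("v", 1:5))
  expect_equal(mods$score[1], 2.5)
})

test_that("reported module scores match their induced subgraphs", {
  sim <- genPPI(synthConfig(seed = 21L))
  g <- buildGraph(sim$edges)
  mods <- mcodeCluster(g)
  for (i in seq_len(nrow(mods))) {
    sub <- igraph::induced_subgraph(g, mods$members[[i]])
    expect_equal(igraph::vcount(sub), mods$n_nodes[i])
    expect_equal(igraph::ecount(sub), mods$n_edges[i])
    expect_equal(moduleScore(sub), mods$score[i], tolerance = 1e-9)
    expect_equal(mods$score[i], mods$n_edges[i] / (mods$n_nodes[i] - 1),
                 tolerance = 1e-9)
  }
  expect_true(all(diff(mods$score) <= 1e-12))   # sorted descending
})

test_that("a tree yields no modules (no 2-core exists)", {
  tree <- igraph::make_tree(10, children = 2, mode = "undirected")
  igraph::V(tree)$name <- paste0("t", 1:10)
  expect_equal(nrow(mcodeCluster(tree)), 0)
})

test_that("centralities match closed forms on canonical graphs", {
  k3 <- igraph::make_full_graph(3); igraph::V(k3)$name <- c("a", "b", "c")
  expect_equal(centrality(k3, "MCC")$scores$score, rep(2, 3))
  expect_equal(centrality(k3, "ClusteringCoefficient")$scores$score,
               rep(1, 3))
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("l", 1:5))
  deg <- centrality(star, "Degree")
  expect_equal(deg$scores$score[deg$scores$node == "hub"], 5)
  mnc <- centrality(star, "MNC")
  expect_equal(mnc$scores$score[mnc$scores$node == "hub"], 1)
  dmnc <- centrality(star, "DMNC")
  expect_equal(dmnc$scores$score[dmnc$scores$node == "hub"], 0)
  path <- igraph::make_graph(~ a - b, b - c)
  cc <- centrality(path, "ClusteringCoefficient")
  expect_equal(cc$scores$score[cc$scores$node == "b"], 0)
  expect_error(centrality(k3, "Eigenvector"), "valid methods")
})

test_that("complete graphs give the textbook values for every method", {
  n <- 6
  kn <- igraph::make_full_graph(n)
  igraph::V(kn)$name <- paste0("k", 1:n)
  expect_equal(centrality(kn, "MCC")$scores$score, rep(factorial(n - 1), n))
  expect_equal(centrality(kn, "MNC")$scores$score, rep(n - 1, n))
  expect_equal(centrality(kn, "Degree")$topK,
               centrality(kn, "MNC")$topK)
})

test_that("MCC equals brute-force maximal-clique enumeration", {
  for (s in 1:12) {
    rg <- randomGraph(n = sample(6:12, 1), p = runif(1, 0.2, 0.6),
                      seed = 100 + s)
    got <- centrality(rg$graph, "MCC")$scores
    want <- bruteMCC(rg$adj)
    expect_equal(got$score[match(rownames(rg$adj), got$node)],
                 unname(want), info = paste("seed", 100 + s))
  }
})

test_that("relabeling nodes permutes but never changes scores", {
  rg <- randomGraph(10, 0.4, seed = 77)
  g2 <- rg$graph
  igraph::V(g2)$name <- rev(igraph::V(rg$graph)$name)
  for (m in c("MCC", "Degree", "DMNC", "MNC", "ClusteringCoefficient")) {
    a <- centrality(rg$graph, m)$scores
    b <- centrality(g2, m)$scores
    perm <- setNames(rev(igraph::V(rg$graph)$name),
                     igraph::V(rg$graph)$name)
    expect_equal(b$score[match(perm[a$node], b$node)], a$score,
                 info = m)
  }
})

test_that("top-k is tie-inclusive and deterministically ordered", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("l", 1:5))
  r <- centrality(star, "Degree", k = 3)
  expect_identical(r$topK, c("hub", paste0("l", 1:5)))   # leaves all tied
  expect_identical(r$scores$node[2:6], paste0("l", 1:5)) # lexicographic
})

test_that("hub consensus intersects top lists and the tissue set", {
  r <- hubConsensus(list(c("A", "B", "C"), c("B", "C", "D"),
                         c("B", "C", "E")),
                    tissueSpecific = c("B", "Z"))
  expect_identical(r$hubs, c("B", "C"))
  expect_identical(r$systemHubs, "B")
  same <- hubConsensus(list(c("A", "B"), c("A", "B")))
  expect_identical(same$hubs, c("A", "B"))
  none <- hubConsensus(list("A", "B"))
  expect_length(none$hubs, 0)
  expect_error(hubConsensus(list("A")), "2")
})

test_that("planted dense blocks are recovered with high overlap", {
  hits <- vapply(1:10, function(s) {
    sim <- genPPI(synthConfig(seed = s))
    mods <- mcodeCluster(buildGraph(sim$edges))
    if (!nrow(mods)) return(FALSE)
    truth <- sim$truth$module_1
    top <- mods$members[[1]]
    length(intersect(top, truth)) / length(union(top, truth)) > 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
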