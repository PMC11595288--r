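# logfc fixtures with controlled lineage series for network construction
series_tables <- function(mirna_series, cyt_series) {
  cols <- c("E_T1", "E_T2", "E_T3")
  mm <- do.call(rbind, mirna_series)
  dimnames(mm) <- list(names(mirna_series), cols)
  cm <- do.call(rbind, cyt_series)
  dimnames(cm) <- list(names(cyt_series), cols)
  list(mirna = logfc_table(mm, "miRNA", "logFC_vs_reference"),
       cytokine = logfc_table(cm, "cytokine", "log2_concentration"))
}

test_that("network construction enforces the four constraints", {
  # one anti-linear pair; a positively correlated pair; weakly related rest
  tabs <- series_tables(
    list(m1 = c(-1, -2, -3), m2 = c(0.1, -0.2, 0.1)),
    list(c1 = c(6, 7, 8),        # r(m1, c1) = -1 over the anchored series
         c2 = c(4.9, 3.8, 3.1),  # decreasing like m1, so r(m1, .) > 0
         c3 = c(5.2, 5.0, 5.2)))
  ref <- reference_profile(c(c1 = 2^5, c2 = 2^6, c3 = 2^5), "cytokine")
  g <- build_network(tabs$mirna, tabs$cytokine, c("m1", "m2"), "E",
                     cytokine_reference = ref, pseudocount = 0)
  expect_equal(igraph::ecount(g), 1)
  e <- igraph::ends(g, igraph::E(g)[1])
  expect_setequal(as.vector(e), c("m1", "c1"))
  expect_lte(igraph::E(g)$weight[1], -0.9)
  # bipartite: the two endpoint types differ
  type <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  expect_false(type[e[1, 1]] == type[e[1, 2]])
  # isolated nodes dropped by default, retained on request
  expect_equal(igraph::vcount(g), 2)
  g2 <- build_network(tabs$mirna, tabs$cytokine, c("m1", "m2"), "E",
                      cytokine_reference = ref, pseudocount = 0,
                      drop_isolated = FALSE)
  expect_equal(igraph::vcount(g2), 5)
})

test_that("a positive near-unity correlation is not an edge", {
  tabs <- series_tables(list(m1 = c(1, 2, 3)), list(c1 = c(6, 7, 8)))
  ref <- reference_profile(c(c1 = 2^5), "cytokine")
  g <- build_network(tabs$mirna, tabs$cytokine, "m1", "E",
                     cytokine_reference = ref, pseudocount = 0)
  expect_equal(igraph::ecount(g), 0)
})

test_that("a too-short series is refused", {
  mm <- matrix(c(-1, -2), 1, 2, dimnames = list("m1", c("E_T1", "E_T2")))
  cm <- matrix(c(5, 6), 1, 2, dimnames = list("c1", c("E_T1", "E_T2")))
  expect_error(
    build_network(logfc_table(mm, "miRNA"),
                  logfc_table(cm, "cytokine", "log2_concentration"),
                  "m1", "E", include_baseline = FALSE),
    "fewer than 3")
})

test_that("edge betweenness matches brute-force path enumeration", {
  # single edge
  g1 <- adj_to_graph(matrix(c(0, 1, 1, 0), 2))
  expect_equal(edge_betweenness_scores(g1), 1)

  # two triangles joined by one bridge: bridge strictly maximal
  adj <- matrix(0, 6, 6)
  tri <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4))
  adj[tri] <- 1; adj <- adj + t(adj)
  g <- adj_to_graph(adj)
  eb <- edge_betweenness_scores(g)
  oracle <- brute_betweenness(adj)$edge
  ends <- igraph::ends(g, igraph::E(g))
  key <- paste(pmin(as.integer(ends[, 1]), as.integer(ends[, 2])),
               pmax(as.integer(ends[, 1]), as.integer(ends[, 2])), sep = "-")
  expect_equal(eb, unname(oracle[key]), tolerance = 1e-10)
  bridge <- which(key == "3-4")
  expect_true(all(eb[bridge] > eb[-bridge]))

  # edge-transitive 4-cycle: all equal
  cyc <- adj_to_graph(rbind(c(0,1,0,1), c(1,0,1,0), c(0,1,0,1), c(1,0,1,0)))
  expect_equal(length(unique(edge_betweenness_scores(cyc))), 1)

  # random graphs against the oracle
  for (s in 1:5) {
    adj <- random_adj(7, 0.45, seed = s)
    g <- adj_to_graph(adj)
    if (igraph::ecount(g) == 0) next
    eb <- edge_betweenness_scores(g)
    oracle <- brute_betweenness(adj)$edge
    ends <- igraph::ends(g, igraph::E(g))
    key <- paste(pmin(as.integer(ends[, 1]), as.integer(ends[, 2])),
                 pmax(as.integer(ends[, 1]), as.integer(ends[, 2])), sep = "-")
    expect_equal(eb, unname(oracle[key]), tolerance = 1e-10)
  }
})

test_that("modularity matches direct edge counting", {
  # one community: Q = 0
  g <- adj_to_graph(random_adj(6, 0.5, seed = 9))
  expect_equal(modularity_q(g, rep(1, 6)), 0)

  # two equal disconnected cliques split apart: Q = 0.5
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
  g2 <- adj_to_graph(adj)
  expect_equal(modularity_q(g2, rep(1:2, each = 3)), 0.5)

  # edgeless graph: Q = 0 by convention
  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g0)$name <- letters[1:4]
  expect_equal(modularity_q(g0, setNames(1:4, letters[1:4])), 0)

  # random graphs and random partitions vs the oracle and igraph
  set.seed(61)
  for (s in 1:8) {
    adj <- random_adj(8, 0.4, seed = 100 + s)
    g <- adj_to_graph(adj)
    if (igraph::ecount(g) == 0) next
    memb <- sample(1:3, 8, replace = TRUE)
    expect_equal(modularity_q(g, memb), brute_modularity(adj, memb),
                 tolerance = 1e-12)
    expect_equal(modularity_q(g, memb),
                 igraph::modularity(g, memb), tolerance = 1e-12)
  }
})

test_that("Girvan-Newman recovers separable community structure", {
  # two disconnected triangles: partition = components at step 0
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
  p <- girvan_newman(adj_to_graph(adj))
  expect_equal(adjusted_rand_index(p$membership, rep(1:2, each = 3)), 1)
  expect_equal(p$q, 0.5)

  # two 4-cliques plus one bridge: split at the bridge
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1; diag(adj) <- 0
  adj[4, 5] <- adj[5, 4] <- 1
  g <- adj_to_graph(adj)
  p <- girvan_newman(g)
  expect_equal(adjusted_rand_index(p$membership, rep(1:2, each = 4)), 1)
  expect_equal(p$q, modularity_q(g, p$membership), tolerance = 1e-12)
  expect_equal(p$q, brute_max_modularity(adj)$q, tolerance = 1e-12)

  # edgeless graph: singletons, Q = 0
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  p0 <- girvan_newman(g0)
  expect_equal(length(unique(p0$membership)), 3)
  expect_equal(p0$q, 0)
})

test_that("Girvan-Newman is consistent, bounded, and matches the reference", {
  # The greedy edge-removal dendrogram need not contain the global max-Q
  # partition of an arbitrary graph, so on random graphs we check (a) the
  # returned Q equals the modularity of the returned partition, (b) it never
  # exceeds the exhaustive maximum, and (c) it coincides exactly with the
  # independent reference implementation of the same algorithm.
  for (s in 1:6) {
    adj <- random_adj(7, 0.35, seed = 200 + s)
    g <- adj_to_graph(adj)
    if (igraph::ecount(g) == 0) next
    p <- girvan_newman(g)
    expect_equal(p$q, modularity_q(g, p$membership), tolerance = 1e-12)
    expect_lte(p$q, brute_max_modularity(adj)$q + 1e-9)
    ref <- igraph::cluster_edge_betweenness(g, weights = NULL)
    expect_equal(p$q, max(c(0, ref$modularity)), tolerance = 1e-9)
  }
})

test_that("node roles follow the Z/P formulas", {
  # star inside one module: center has all links internal -> P = 0
  adj <- matrix(0, 5, 5); adj[1, 2:5] <- 1; adj <- adj + t(adj)
  g <- adj_to_graph(adj)
  roles <- node_roles(g, rep(1, 5))
  expect_equal(roles$p, rep(0, 5))

  # degree-regular module: all Z = 0
  cyc <- adj_to_graph(rbind(c(0,1,0,1), c(1,0,1,0), c(0,1,0,1), c(1,0,1,0)))
  expect_equal(node_roles(cyc, rep(1, 4))$z, rep(0, 4))

  # K = 2 split 1/1 across two modules -> P = 0.5
  path3 <- adj_to_graph(rbind(c(0,1,0), c(1,0,1), c(0,1,0)))
  roles3 <- node_roles(path3, c(1, 1, 2))
  expect_equal(roles3$p[2], 0.5)
  expect_equal(roles3$p[1], 0)

  # K_is sums to the degree; P in [0, 1)
  set.seed(62)
  adj <- random_adj(8, 0.5, seed = 63)
  g <- adj_to_graph(adj)
  memb <- sample(1:3, 8, TRUE)
  roles <- node_roles(g, memb)
  expect_equal(roles$degree, as.vector(igraph::degree(g)))
  expect_true(all(roles$p >= 0 & roles$p < 1))
  # recompute P by hand for node 1
  k1 <- sum(adj[1, ])
  kis <- tapply(adj[1, ], memb, sum)
  expect_equal(roles$p[1], 1 - sum((kis / k1)^2))
  # roles partition by thresholds
  r2 <- node_roles(g, memb, z_threshold = -10, p_threshold = 0)
  expect_true(all(r2$role == "hub_connector"))
})

test_that("graph descriptors match closed-form values on canonical graphs", {
  k5 <- adj_to_graph(matrix(1, 5, 5) - diag(5))
  d <- descriptors(k5)
  expect_equal(d$density, 1)
  expect_equal(d$diameter, 1L)
  expect_equal(d$centr_degree, 0)

  path5 <- adj_to_graph({a <- matrix(0, 5, 5); a[cbind(1:4, 2:5)] <- 1; a + t(a)})
  expect_equal(descriptors(path5)$diameter, 4L)

  star10 <- adj_to_graph({a <- matrix(0, 10, 10); a[1, 2:10] <- 1; a + t(a)})
  expect_equal(descriptors(star10)$centr_degree, 1)

  # diameter on a disconnected graph comes from the largest component
  adj <- matrix(0, 7, 7)     # path on 1..5 plus a separate edge 6-7
  adj[cbind(1:4, 2:5)] <- 1
  adj[6, 7] <- 1
  adj <- adj + t(adj)
  expect_equal(descriptors(adj_to_graph(adj))$diameter, 4L)

  single <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(single)$name <- "a"
  expect_true(is.na(descriptors(single)$density))
})

test_that("betweenness ranking orders hubs first with id tie-breaks", {
  star <- adj_to_graph({a <- matrix(0, 6, 6); a[1, 2:6] <- 1; a + t(a)})
  rk <- node_betweenness_ranking(star)
  expect_equal(rk$node[1], "1")

  cyc <- adj_to_graph(rbind(c(0,1,0,1), c(1,0,1,0), c(0,1,0,1), c(1,0,1,0)))
  rk2 <- node_betweenness_ranking(cyc)
  expect_equal(rk2$node, c("1", "2", "3", "4"))

  # barbell: bridge endpoints rank above clique-internal nodes
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1; diag(adj) <- 0
  adj[4, 5] <- adj[5, 4] <- 1
  rk3 <- node_betweenness_ranking(adj_to_graph(adj))
  expect_setequal(rk3$node[1:2], c("4", "5"))
  oracle <- brute_betweenness(adj)$node
  expect_equal(rk3$betweenness,
               sort(oracle, decreasing = TRUE), tolerance = 1e-10)
})

test_that("central cytokines are the highest-degree cytokine per community", {
  edges <- rbind(c("m1", "c1"), c("m2", "c1"), c("m3", "c2"),
                 c("m4", "c3"), c("m5", "c3"), c("m6", "c3"))
  type <- setNames(rep(c("miRNA", "cytokine"), c(6, 3)),
                   c(paste0("m", 1:6), paste0("c", 1:3)))
  g <- graph_fixture(edges, type = type)
  memb <- setNames(c(1, 1, 1, 2, 2, 2, 1, 1, 2),
                   c(paste0("m", 1:6), paste0("c", 1:3)))
  cc <- central_cytokines(g, memb)
  expect_equal(cc$cytokine[cc$module == 1], "c1")
  expect_equal(cc$cytokine[cc$module == 2], "c3")
})

test_that("a module-bridging miRNA attains the highest participation", {
  # two complete bipartite modules plus one miRNA wired into both
  edges <- rbind(
    as.matrix(expand.grid(paste0("mA", 1:3), paste0("cA", 1:3))),
    as.matrix(expand.grid(paste0("mB", 1:3), paste0("cB", 1:3))),
    cbind("m_bridge", c("cA1", "cA2", "cB1", "cB2")))
  type <- setNames(rep(c("miRNA", "cytokine", "miRNA"), c(6, 6, 1)),
                   c(paste0("mA", 1:3), paste0("mB", 1:3),
                     paste0("cA", 1:3), paste0("cB", 1:3), "m_bridge"))
  g <- graph_fixture(edges, type = type)
  part <- girvan_newman(g)
  roles <- node_roles(g, part)
  top_p <- roles$node[which.max(roles$p)]
  expect_equal(top_p, "m_bridge")
  expect_equal(roles$type[which.max(roles$p)], "miRNA")
  # nodes confined to one module have zero participation
  expect_true(all(roles$p[roles$node %in% c("mA1", "mB1")] == 0))
})
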