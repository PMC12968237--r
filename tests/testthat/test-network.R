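test_that("network construction enforces the simple-graph contract", {
  pairs <- data.frame(label_i = c("A", "A"), label_j = c("B", "B"),
                      lift = c(1.5, 1.6), observed = c(3L, 4L),
                      p_value = c(0.01, 0.02))
  expect_error(build_network(pairs), "duplicate pair")
  self <- data.frame(label_i = "A", label_j = "A", lift = 2,
                     observed = 1L, p_value = 0.1)
  expect_error(build_network(self), "self-pair")

  ok <- build_network(pairs[1, ], isolate_policy = "drop")
  expect_equal(sort(network_nodes(ok)), c("A", "B"))
  keep <- build_network(pairs[1, ], isolate_policy = "keep",
                        nodes = c("A", "B", "C"))
  expect_equal(sort(network_nodes(keep)), c("A", "B", "C"))

  none <- build_network(pairs[0, ], isolate_policy = "drop")
  expect_equal(length(network_nodes(none)), 0L)
})

test_that("complete and star graphs give the closed-form topology values", {
  k5 <- net_from_adj(matrix(1, 5, 5) - diag(5))
  topo <- network_topology(k5)
  expect_equal(topo$density, 1)
  expect_equal(topo$avg_clustering, 1)

  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star[2:5, 1] <- 1
  topo_s <- network_topology(net_from_adj(star))
  expect_equal(topo_s$density, 4 / 10)
  expect_equal(topo_s$avg_clustering, 0)
  expect_lt(topo_s$assortativity, 0)  # hubs connect to leaves
})

test_that("a 13-node 35-edge graph has density 35/78", {
  withr::with_seed(19, {
    adj <- matrix(0, 13, 13)
    idx <- which(upper.tri(adj))
    on <- sample(idx, 35)
    adj[on] <- 1; adj <- adj + t(adj)
  })
  topo <- network_topology(net_from_adj(adj))
  expect_equal(topo$n_nodes, 13L)
  expect_equal(topo$n_edges, 35L)
  expect_equal(topo$density, 35 / 78, tolerance = 1e-12)
  expect_equal(round(topo$density, 3), 0.449)
})

test_that("path-graph betweenness and clustering match closed forms", {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  net <- net_from_adj(path3)
  cent <- node_centralities(net)
  expect_equal(cent$betweenness[cent$node == "B"], 1)
  expect_equal(cent$degree[cent$node == "B"], 2L)
  expect_equal(cent$betweenness[cent$node == "A"], 0)

  # a node whose two neighbors are connected has local clustering 1
  tri <- matrix(1, 3, 3) - diag(3)
  cent_t <- node_centralities(net_from_adj(tri))
  expect_equal(cent_t$local_clustering, rep(1, 3))
})

test_that("uniform weights reproduce unweighted betweenness", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      adj <- rand_adj(7, 0.5, weighted = FALSE)
      net <- net_from_adj(adj)
      cent <- node_centralities(net)
      gr <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
      expect_equal(cent$betweenness,
                   as.numeric(igraph::betweenness(gr, normalized = TRUE)),
                   tolerance = 1e-12)
    }
  })
})

test_that("density, clustering and weighted betweenness match brute-force oracles", {
  withr::with_seed(47, {
    for (rep in 1:12) {
      n <- sample(4:8, 1)
      adj <- rand_adj(n, runif(1, 0.3, 0.8))
      if (sum(adj) == 0) next
      net <- net_from_adj(adj)
      topo <- network_topology(net)
      cent <- node_centralities(net)
      expect_equal(topo$density, oracle_density(adj), tolerance = 1e-9)
      lc <- oracle_local_clustering(adj)
      expect_equal(cent$local_clustering, lc, tolerance = 1e-9)
      expect_equal(topo$avg_clustering, mean(lc), tolerance = 1e-9)
      expect_equal(cent$betweenness, oracle_betweenness(adj), tolerance = 1e-9)
    }
  })
})

test_that("degree sums to twice the edge count", {
  withr::with_seed(61, {
    for (rep in 1:5) {
      adj <- rand_adj(8, 0.4)
      net <- net_from_adj(adj)
      cent <- node_centralities(net)
      expect_equal(sum(cent$degree), 2 * igraph::ecount(net$graph))
    }
  })
})

test_that("regular graphs report assortativity as missing, not NaN", {
  cyc <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; cyc[i, j] <- 1; cyc[j, i] <- 1 }
  topo <- network_topology(net_from_adj(cyc))
  expect_true(is.na(topo$assortativity))
  expect_false(is.nan(topo$assortativity))
})

test_that("hub ranking breaks ties by weighted degree then label", {
  pairs <- data.frame(
    label_i = c("a", "a", "a", "b", "b", "c"),
    label_j = c("b", "c", "d", "c", "e", "e"),
    lift = c(2, 2, 2, 5, 5, 1.1), observed = 1L, p_value = 0)
  net <- build_network(pairs)
  cent <- node_centralities(net)
  # degrees: a 3, b 3, c 3, d 1, e 2; weighted: a 6, b 12, c 8.1
  expect_equal(top_hubs(cent, 3), c("b", "c", "a"))
  expect_equal(top_hubs(cent, 99), c("b", "c", "a", "e", "d"))

  flat <- data.frame(label_i = c("x", "y"), label_j = c("y", "z"),
                     lift = c(1.5, 1.5), observed = 1L, p_value = 0)
  cent_f <- node_centralities(build_network(flat))
  expect_equal(top_hubs(cent_f, 2)[1], "y")
  # remaining degree-1 nodes tie on weighted degree: lexicographic
  expect_equal(top_hubs(cent_f, 3), c("y", "x", "z"))
})

test_that("adjacency matrices are symmetric with configurable convention", {
  pairs <- data.frame(label_i = "A", label_j = "C", lift = 1.7,
                      observed = 4L, p_value = 0.001)
  net <- build_network(pairs, isolate_policy = "keep", nodes = c("A", "B", "C"))
  a <- network_adjacency(net, nodes = c("A", "B", "C"))
  expect_equal(a["A", "C"], 1.7)
  expect_equal(a["C", "A"], 1.7)
  expect_equal(sum(a != 0), 2)
  b <- network_adjacency(net, nodes = c("A", "B", "C"), convention = "binary")
  expect_equal(b["A", "C"], 1)
})
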