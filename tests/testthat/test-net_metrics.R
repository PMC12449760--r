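test_that("connectance and mean degree follow their closed forms", {
  g <- igraph::make_full_graph(2)
  expect_equal(connectance(g), 1)
  ring <- igraph::make_ring(9)
  expect_equal(mean_degree(ring), 2)
  expect_equal(degree_skewness(ring), 0, ignore_attr = TRUE)
  expect_true(attr(degree_skewness(ring), "degenerate"))
  # identity 2L/S on arbitrary graphs, and monotonicity in L at fixed S
  set.seed(5)
  prev <- -1
  for (L in c(5, 10, 20)) {
    g <- igraph::sample_gnm(12, L)
    expect_equal(mean_degree(g), 2 * L / 12)
    expect_equal(connectance(g), L / choose(12, 2))
    expect_gt(connectance(g), prev)
    prev <- connectance(g)
  }
  expect_error(connectance(igraph::make_empty_graph(1, directed = FALSE)), "2 nodes")
})

test_that("degree skewness implements both the (S-1) and moment-ratio forms", {
  expect_equal(degree_skewness(c(1, 2, 3)), 0, ignore_attr = TRUE)
  # hand evaluation: degrees (0,0,6), mean 2, sample sd sqrt(12),
  # sum of cubes 48 -> 48 / (2 * 12^1.5)
  expect_equal(as.numeric(degree_skewness(c(0, 0, 6))), 48 / (2 * 12^1.5))
  # moment-ratio form agrees with the e1071 type-1 skewness
  set.seed(1)
  d <- rpois(15, 3)
  expect_equal(as.numeric(degree_skewness(d, method = "moment")),
               e1071::skewness(d, type = 1))
  expect_error(degree_skewness(c(1, 2)), "3 nodes")
})

test_that("modularity matches direct evaluation and the igraph cross-check", {
  g1 <- igraph::make_graph(~ a - b)
  expect_equal(net_modularity(g1, c(1, 2)), -0.5)
  expect_equal(net_modularity(g1, c(1, 1)), 0)
  # two disjoint m-cliques under the clique partition: Q = 0.5
  for (m in c(3, 4, 5)) {
    g <- two_cliques(m)
    part <- rep(1:2, each = m)
    expect_equal(net_modularity(g, part), 0.5)
    expect_equal(net_modularity(g, part),
                 igraph::modularity(g, part))
  }
  # trivial one-community partition has Q = 0 for any graph
  set.seed(7)
  for (i in 1:20) {
    g <- igraph::sample_gnp(sample(4:12, 1), runif(1, 0.2, 0.9))
    if (igraph::ecount(g) == 0) next
    expect_equal(net_modularity(g, rep(1, igraph::vcount(g))), 0)
  }
  # resolution parameter scales the null term
  g <- two_cliques(3)
  part <- rep(1:2, each = 3)
  expect_equal(net_modularity(g, part, gamma = 2), 1 - 2 * 0.5)
  expect_error(net_modularity(igraph::make_empty_graph(3, directed = FALSE),
                              rep(1, 3)), "edgeless")
})

test_that("Girvan-Newman separates planted structure and never merges components", {
  g <- two_cliques(3) # two disjoint triangles
  gn <- girvan_newman(g)
  expect_equal(gn$n_communities, 2)
  expect_equal(unname(gn$membership[1:3]), rep(gn$membership[[1]], 3))
  expect_equal(gn$modularity, 0.5)
  # a 2-node path stays one community (Q = 0 beats Q = -0.5)
  p2 <- igraph::make_graph(~ x - y)
  gn2 <- girvan_newman(p2)
  expect_equal(gn2$n_communities, 1)
  expect_equal(gn2$modularity, 0)
  expect_setequal(gn2$dendrogram$modularity, c(0, -0.5))
  # edgeless graph: singleton communities
  gn0 <- girvan_newman(igraph::make_empty_graph(4, directed = FALSE))
  expect_equal(gn0$n_communities, 4)
  # disconnected components never merge
  set.seed(11)
  g2 <- igraph::disjoint_union(igraph::sample_gnp(5, 0.8), igraph::sample_gnp(5, 0.8))
  memb <- girvan_newman(g2)$membership
  expect_equal(length(intersect(unique(memb[1:5]), unique(memb[6:10]))), 0)
})

test_that("returned Q is the maximum over dendrogram cuts on small graphs", {
  set.seed(13)
  for (i in 1:40) {
    g <- igraph::sample_gnp(sample(4:8, 1), runif(1, 0.3, 0.8))
    igraph::V(g)$name <- letters[seq_len(igraph::vcount(g))]
    if (igraph::ecount(g) == 0) next
    gn <- girvan_newman(g)
    # every recorded cut's Q, recomputed independently with igraph
    # (exhaustive enumeration of the dendrogram's cut levels)
    ceb <- igraph::cluster_edge_betweenness(g)
    q_ref <- vapply(seq_len(igraph::vcount(g)), function(k) {
      m <- tryCatch(suppressWarnings(igraph::cut_at(ceb, no = k)),
                    error = function(e) NULL)
      if (is.null(m)) return(-Inf)
      igraph::modularity(g, m)
    }, 0)
    expect_equal(gn$modularity, max(q_ref), tolerance = 1e-9)
    expect_equal(gn$modularity, igraph::modularity(g, gn$membership),
                 tolerance = 1e-12)
    expect_equal(gn$modularity, max(gn$dendrogram$modularity))
  }
})

test_that("detected communities recover planted modules on synthetic data", {
  # strong within-module correlation, 100 samples: adjusted Rand between the
  # communities of the positive-association subnetwork and the planted
  # modules (closure of the composition induces significant negative
  # between-module correlations, which are real features of the unsigned
  # topology, so module recovery is assessed on the positive links)
  ari <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sum_ij <- sum(choose(tab, 2))
    sum_a <- sum(choose(rowSums(tab), 2))
    sum_b <- sum(choose(colSums(tab), 2))
    expected <- sum_a * sum_b / choose(n, 2)
    (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
  }
  scores <- vapply(1:5, function(s) {
    sim <- generate_assemblage(synth_config(n_taxa = 45, n_samples = 100,
                                            n_modules = 3, rho_w = 0.7,
                                            prop_negative = 0,
                                            dominance_ratio = 0.92,
                                            seed = 200 + s))
    h <- hellinger_transform(to_relative_abundance(sim$counts))
    net <- build_network(spearman_matrix(h), alpha = 0.01)
    g <- net$graph
    gp <- igraph::subgraph_from_edges(g, igraph::E(g)[igraph::E(g)$sign == 1],
                                      delete.vertices = FALSE)
    gn <- girvan_newman(gp)
    ari(gn$membership[paste0("taxon_", sprintf("%02d", 1:45))],
        sim$truth$modules)
  }, 0)
  expect_gte(median(scores), 0.8)
})

test_that("network_summary assembles consistent metrics and flags degeneracy", {
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  s <- network_summary(empty)
  expect_equal(s$connectance, 0)
  expect_equal(s$mean_degree, 0)
  expect_true(is.na(s$modularity))
  expect_true(s$skewness_degenerate)
  # ring-regular graph: mean degree exactly 2, skewness 0
  ring <- igraph::make_ring(27)
  sr <- network_summary(ring)
  expect_equal(sr$mean_degree, 2)
  expect_equal(sr$skewness, 0)
  # S and L agree with the builder
  sim <- generate_assemblage(synth_config(n_taxa = 10, n_samples = 20, seed = 2))
  net <- build_network(spearman_matrix(
    hellinger_transform(to_relative_abundance(sim$counts))), 0.05)
  ss <- network_summary(net)
  expect_equal(ss$S, igraph::vcount(net$graph))
  expect_equal(ss$L, igraph::ecount(net$graph))
  expect_equal(ss, glance(net))
  # report rounding: 3 decimals for connectance, 2 elsewhere
  fm <- format_metrics(tibble::tibble(connectance = 0.08084, mean_degree = 3.39534))
  expect_equal(fm$connectance, 0.081)
  expect_equal(fm$mean_degree, 3.40)
})
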