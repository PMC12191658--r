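graph_from_edges <- function(edges, classes = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$gene_class <- if (is.null(classes))
    rep("protein_coding", igraph::vcount(g)) else classes
  g
}

test_that("topology summary matches closed-form values on canonical graphs", {
  tri <- graph_from_edges(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  ts <- summarize_topology(tri)
  expect_equal(ts$diameter, 1L)
  expect_equal(ts$mean_clustering, 1.0)
  expect_true(all(ts$nodes$degree == 2))
  expect_equal(sum(ts$nodes$degree), 2 * ts$n_edges)   # handshake

  path <- graph_from_edges(rbind(c("a", "b"), c("b", "c")))
  ts <- summarize_topology(path)
  expect_equal(ts$diameter, 2L)
  expect_equal(ts$mean_clustering, 0)
  expect_equal(as.vector(ts$degree_histogram[c("1", "2")]), c(2L, 1L))

  star <- graph_from_edges(cbind("hub", paste0("leaf", 1:4)))
  ts <- summarize_topology(star)
  btw <- setNames(ts$nodes$betweenness, ts$nodes$gene_id)
  expect_equal(btw[["hub"]], 6)              # C(4,2) shortest-path pairs
  expect_true(all(btw[paste0("leaf", 1:4)] == 0))
  expect_error(summarize_topology(igraph::make_empty_graph(0)), "empty")
})

test_that("degree comparison by class reports direction and significance", {
  edges <- rbind(c("L1", "P1"), c("L1", "P2"), c("L1", "P3"),
                 c("L2", "P1"), c("L2", "P2"))
  g <- graph_from_edges(edges,
                        classes = c("lincRNA", rep("protein_coding", 3),
                                    "lincRNA"))
  cc <- compare_degree_by_class(g)
  expect_gt(cc$mean_a, cc$mean_b)
  expect_equal(cc$n_a, 2L)
  # identical degree multisets -> statistic 0, p = 1
  g2 <- graph_from_edges(rbind(c("L1", "P1"), c("L2", "P2")),
                         classes = c("lincRNA", "protein_coding",
                                     "lincRNA", "protein_coding"))
  cc2 <- compare_degree_by_class(g2)
  expect_equal(cc2$statistic, 0)
  expect_equal(cc2$p_value, 1)
  # a single node in one class is refused
  g3 <- graph_from_edges(rbind(c("L1", "P1"), c("P1", "P2")),
                         classes = c("lincRNA", rep("protein_coding", 2)))
  expect_error(compare_degree_by_class(g3), "2 values")
})

test_that("sub-network extraction respects mode and induced edges", {
  star <- graph_from_edges(cbind("hub", paste0("leaf", 1:4)),
                           classes = c("lincRNA",
                                       rep("protein_coding", 4)))
  sub <- extract_subnetwork(star, "hub", mode = "neighbors")
  expect_equal(igraph::vcount(sub), 5L)
  expect_equal(igraph::ecount(sub), 4L)
  expect_error(extract_subnetwork(star, "absent_gene"), "absent_gene")
  # panel of 2 genes sharing one lincRNA partner -> 3-node sub-network
  g <- graph_from_edges(rbind(c("LINC1", "GPCR1"), c("LINC1", "GPCR2"),
                              c("GPCR1", "OTHER")),
                        classes = c("lincRNA", "protein_coding",
                                    "protein_coding", "protein_coding"))
  sub <- extract_subnetwork(g, c("GPCR1", "GPCR2"), mode = "induced_panel")
  expect_setequal(igraph::V(sub)$name, c("GPCR1", "GPCR2", "LINC1"))
  # induced edges only: no edge in the output that is absent from g
  ed <- igraph::as_edgelist(sub)
  for (r in seq_len(nrow(ed)))
    expect_true(igraph::are_adjacent(g, ed[r, 1], ed[r, 2]))
})

test_that("degree ranking is deterministic with documented tie-breaks", {
  star <- graph_from_edges(cbind("hub", paste0("leaf", 1:4)),
                           classes = c("lincRNA",
                                       rep("protein_coding", 4)))
  igraph::E(star)$weight <- 1
  expect_equal(rank_by_degree(star, top_k = 1)$gene_id, "hub")
  # all-equal degrees and weights -> lexicographic order
  ring <- graph_from_edges(rbind(c("b", "a"), c("a", "c"), c("c", "b")))
  igraph::E(ring)$weight <- 1
  expect_equal(rank_by_degree(ring, top_k = 3)$gene_id, c("a", "b", "c"))
  # class restriction
  rk <- rank_by_degree(star, restrict = "protein_coding", top_k = 10)
  expect_false("hub" %in% rk$gene_id)
})

test_that("planted hubs dominate the degree ranking in the synthetic
           scenario", {
  sc <- simulate_scenario(small_params())
  net <- build_scenario_network(sc)
  rk <- rank_by_degree(net$graph, top_k = 3)
  expect_gte(sum(rk$gene_id %in% sc$truth$hubs), 2)
  cc <- compare_degree_by_class(net$graph)
  expect_gt(cc$mean_a, cc$mean_b)
  expect_lt(cc$p_value, 0.01)
})
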