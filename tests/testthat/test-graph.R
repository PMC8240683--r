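test_that("edge-list loading removes self-loops, applies cutoffs, dedupes to max weight", {
  tmp <- withr::local_tempfile(lines = c("a b 1.0", "b c 0.5", "a a 9.0"))
  g <- load_graph(tmp)
  expect_setequal(g$nodes, c("a", "b", "c"))
  expect_equal(nrow(g$edges), 2)

  tmp2 <- withr::local_tempfile(lines = c("a b 0.001", "b c 0.5"))
  g2 <- load_graph(tmp2, weight_cutoff = 0.0025)
  expect_equal(nrow(g2$edges), 1)
  expect_setequal(g2$nodes, c("b", "c"))
  expect_false("a" %in% g2$nodes)

  tmp3 <- withr::local_tempfile(lines = c("a b 0.2", "b a 0.7"))
  g3 <- load_graph(tmp3)
  expect_equal(nrow(g3$edges), 1)
  expect_equal(g3$edges$weight, 0.7)
})

test_that("edge-list parsing skips headers, names malformed lines, rejects empty graphs", {
  tmp <- withr::local_tempfile(lines = c("protein_a\tprotein_b\tscore", "a\tb\t0.9"))
  expect_equal(nrow(read_edge_list(tmp)), 1)

  tmp2 <- withr::local_tempfile(lines = c("a b 0.5", "c d"))
  expect_error(read_edge_list(tmp2), "line 2")
  tmp3 <- withr::local_tempfile(lines = c("a b 0.5", "c d oops"))
  expect_error(read_edge_list(tmp3), "line 2")

  tmp4 <- withr::local_tempfile(lines = c("a a 1.0"))
  expect_error(load_graph(tmp4), "empty")
})

test_that("node store round-trips the edge multiset exactly and serves per-node lookups", {
  g <- graph_triangle()
  dir <- withr::local_tempdir()
  write_node_store(g, dir)
  expect_length(list.files(dir, pattern = "\\.tsv$"), 4)  # 3 nodes + manifest
  expect_equal(unname(store_neighbors(dir, "a")), c(1, 1))
  expect_setequal(names(store_neighbors(dir, "a")), c("b", "c"))

  star <- graph_star()
  dir2 <- withr::local_tempdir()
  write_node_store(star, dir2)
  expect_length(store_neighbors(dir2, "h"), 3)
  expect_length(store_neighbors(dir2, "x"), 1)

  back <- read_node_store(dir2)
  expect_equal(back$edges, star$edges)

  # weights survive at full precision
  gw <- weighted_graph(edge_tbl("a", "b", 1 / 3))
  dir3 <- withr::local_tempdir()
  write_node_store(gw, dir3)
  expect_equal(read_node_store(dir3)$edges$weight, 1 / 3)

  blocked <- withr::local_tempfile(lines = "not a directory")
  expect_error(write_node_store(g, file.path(blocked, "sub")), "store")
})

test_that("induced communities count induced edges and flag disconnection", {
  tri <- induced_community(graph_triangle(), c("a", "b", "c"))
  expect_equal(tri$size, 3)
  expect_equal(tri$n_edges, 3)
  expect_true(tri$connected)

  p <- induced_community(graph_path4(), c("a", "c"))
  expect_equal(p$size, 2)
  expect_equal(p$n_edges, 0)
  expect_false(p$connected)

  k4 <- graph_clique(as.character(1:4))
  expect_equal(induced_community(k4, as.character(1:3))$n_edges, 3)

  # nodes absent from the graph are silently dropped
  expect_equal(induced_community(k4, c("1", "2", "zz"))$size, 2)
  expect_error(induced_community(k4, "zz"), "no nodes")
})

test_that("neighbor_map enumerates the boundary with max weights and connecting edges", {
  pg <- weighted_graph(edge_tbl(c("a", "b"), c("b", "c"), c(0.4, 0.9)))
  nm <- neighbor_map(pg, "a")
  expect_equal(nm$neighbor, "b")
  expect_equal(nm$max_weight, 0.4)
  expect_equal(nm$links[[1]]$node, "a")

  k4 <- graph_clique(as.character(1:4), w = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  nm4 <- neighbor_map(k4, c("1", "2"))
  expect_setequal(nm4$neighbor, c("3", "4"))
  for (i in seq_len(nrow(nm4))) {
    expect_equal(nrow(nm4$links[[i]]), 2)
    expect_equal(nm4$max_weight[i], max(nm4$links[[i]]$weight))
  }

  # whole graph as the subgraph: no external neighbours
  expect_equal(nrow(neighbor_map(k4, as.character(1:4))), 0)

  # keys are disjoint from the community and within the node set
  expect_length(intersect(nm4$neighbor, c("1", "2")), 0)
  expect_true(all(nm4$neighbor %in% k4$nodes))
})

test_that("m_c never exceeds the complete-graph bound on random subsets", {
  ps <- planted_small()
  g <- ps$fx$graph
  withr::with_seed(11, {
    for (i in 1:25) {
      nodes <- sample(g$nodes, sample(2:10, 1))
      cm <- induced_community(g, nodes)
      expect_lte(cm$n_edges, cm$size * (cm$size - 1) / 2)
    }
  })
})
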