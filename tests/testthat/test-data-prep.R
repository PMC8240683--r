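test_that("cleaning drops undersized, disconnected and duplicate communities", {
  g <- graph_path4()  # a-b-c-d
  raw <- community_set(list(
    c("a", "b"),                 # too small
    c("a", "c", "d"),            # a-c not an edge, but c-d is: a disconnected from {c,d}
    c("a", "b", "c"),
    c("a", "b", "c"),            # duplicate
    c("a", "b", "c", "zz")       # zz absent from graph -> same set as above
  ))
  out <- clean_communities(raw, g)
  expect_equal(nrow(out), 1)
  expect_equal(out$nodes[[1]], c("a", "b", "c"))
  expect_equal(out$n_edges, 2)

  expect_error(clean_communities(community_set(list(c("a", "b"))), g),
               "filtered out")
})

test_that("merging collapses high-overlap pairs and leaves disjoint sets alone", {
  m <- merge_similar(community_set(list(c("1", "2", "3"), c("1", "2", "3", "4"))),
                     j = 0.5)
  expect_equal(nrow(m), 1)
  expect_equal(m$nodes[[1]], c("1", "2", "3", "4"))

  m2 <- merge_similar(community_set(list(c("1", "2", "3"), c("4", "5", "6"))),
                      j = 0.5)
  expect_equal(nrow(m2), 2)

  # chain: overlapping neighbours force repeated passes; assert the
  # postcondition rather than a particular composition
  chain <- community_set(list(as.character(1:4), as.character(3:6),
                              as.character(5:8)))
  m3 <- merge_similar(chain, j = 0.3)
  if (nrow(m3) > 1) {
    pairs <- utils::combn(nrow(m3), 2)
    for (k in seq_len(ncol(pairs))) {
      expect_lt(jaccard(m3$nodes[[pairs[1, k]]], m3$nodes[[pairs[2, k]]]), 0.3)
    }
  }
})

test_that("merging satisfies its postcondition on random sets with no more merges than a naive scheme", {
  naive_merge <- function(sets, j) {
    repeat {
      viol <- NULL
      for (i in seq_along(sets)) {
        for (k in seq_along(sets)) {
          if (i < k && jaccard(sets[[i]], sets[[k]]) >= j) {
            viol <- c(i, k); break
          }
        }
        if (!is.null(viol)) break
      }
      if (is.null(viol)) return(sets)
      sets <- c(sets[-viol], list(sort(union(sets[[viol[1]]], sets[[viol[2]]]))))
    }
  }
  for (cs in random_community_sets(40, seed = 7)) {
    out <- merge_similar(cs, j = 0.5)
    if (nrow(out) > 1) {
      pairs <- utils::combn(nrow(out), 2)
      jmax <- max(apply(pairs, 2, function(p) {
        jaccard(out$nodes[[p[1]]], out$nodes[[p[2]]])
      }))
      expect_lt(jmax, 0.5)
    }
    # fewer (or equal) merges than naive random-pair merging = more survivors
    expect_gte(nrow(out), length(naive_merge(cs$nodes, 0.5)))
  }
})

test_that("train/test splits are edge-independent with the requested balance", {
  toy <- make_clique_toy(10, 3:8)
  sp <- split_train_test(toy$truth, toy$graph, train_frac = 0.7, rng_seed = 2)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  tr_edges <- unlist(lapply(sp$train$nodes, function(ns)
    commfit:::induced_edge_keys(toy$graph, ns)))
  te_edges <- unlist(lapply(sp$test$nodes, function(ns)
    commfit:::induced_edge_keys(toy$graph, ns)))
  expect_length(intersect(tr_edges, te_edges), 0)
  expect_lte(abs(stats::median(sp$train$size) - stats::median(sp$test$size)), 2)

  # two cliques sharing an edge cannot be separated: when nothing else
  # remains to seed the other set, the split must fail loudly
  shared <- weighted_graph(edge_tbl(c("a", "a", "b", "a", "b", "c"),
                                    c("b", "c", "c", "d", "d", "d"),
                                    rep(1, 6)))
  comms <- community_set(list(c("a", "b", "c"), c("b", "c", "d")))
  expect_error(split_train_test(comms, shared, max_iters = 5, rng_seed = 1),
               "rng_seed")

  # with a third, edge-disjoint community the overlapping pair co-locates
  g3 <- weighted_graph(dplyr::bind_rows(
    shared$edges, edge_tbl(c("x", "x", "y"), c("y", "z", "z"), rep(1, 3))))
  comms3 <- community_set(list(c("a", "b", "c"), c("b", "c", "d"),
                               c("x", "y", "z")))
  # convergence depends on the initial random split; the documented recovery
  # is to retry with another seed
  sp3 <- NULL
  for (s in 1:10) {
    sp3 <- tryCatch(
      split_train_test(comms3, g3, train_frac = 0.7, max_iters = 10,
                       rng_seed = s),
      error = function(e) NULL)
    if (!is.null(sp3)) break
  }
  expect_false(is.null(sp3))
  in_train <- vapply(list(c("a", "b", "c"), c("b", "c", "d")), function(ns) {
    any(vapply(sp3$train$nodes, identical, TRUE, y = ns))
  }, TRUE)
  expect_true(all(in_train) || all(!in_train))
})

test_that("negative walks hit the requested count, size spread and determinism", {
  ps <- planted_small()
  g <- ps$fx$graph
  pos <- community_set(replicate(100, as.character(1:3), simplify = FALSE))
  pos$size <- rep(3:6, length.out = 100)  # size range 3..6 drives the targets
  neg <- suppressWarnings(
    sample_negatives(g, pos, scale_factor = 1.1, rng_seed = 9))
  expect_equal(nrow(neg), 110)
  counts <- table(neg$size)
  expect_true(all(counts %in% c(27, 28)))
  expect_lte(diff(range(counts)), 1)

  neg2 <- suppressWarnings(
    sample_negatives(g, pos, scale_factor = 1.1, rng_seed = 9))
  expect_identical(neg$nodes, neg2$nodes)

  # a triangle-only graph cannot support 5-node walks
  tri <- graph_triangle()
  pos5 <- community_set(list(c("a", "b", "c")))
  pos5$size <- 5L
  expect_warning(out <- sample_negatives(tri, pos5, scale_factor = 2,
                                         rng_seed = 1),
                 "capped")
  expect_true(all(out$size <= 3))

  # every walk is connected by construction
  conn <- vapply(neg$nodes[1:20], function(ns) {
    induced_community(g, ns)$connected
  }, TRUE)
  expect_true(all(conn))
})

test_that("negatives resembling positives are filtered at the Jaccard threshold", {
  pos <- community_set(list(c("1", "2", "3")))
  neg <- community_set(list(
    c("1", "2", "3"),        # identical -> removed
    c("7", "8", "9"),        # disjoint -> kept
    c("1", "2", "3", "9")    # Jaccard 0.75 -> removed at 0.5
  ), label = "negative")
  out <- suppressMessages(filter_negatives(neg, pos, j_neg = 0.5))
  expect_equal(nrow(out), 1)
  expect_equal(out$nodes[[1]], c("7", "8", "9"))
  expect_equal(attr(out, "n_removed"), 2)
})
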