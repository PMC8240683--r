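test_that("seed selection covers all four modes", {
  g <- graph_path4()  # 4 nodes
  expect_length(select_seeds(g, "all_nodes"), 4)

  two_tri <- weighted_graph(dplyr::bind_rows(
    edge_tbl(c("a", "a", "b"), c("b", "c", "c"), rep(1, 3)),
    edge_tbl(c("x", "x", "y"), c("y", "z", "z"), rep(1, 3))))
  cl <- select_seeds(two_tri, "maximal_cliques")
  expect_length(cl, 2)
  expect_setequal(lengths(cl), c(3, 3))

  r1 <- select_seeds(g, "random_n", n_random = 2, rng_seed = 3)
  r2 <- select_seeds(g, "random_n", n_random = 2, rng_seed = 3)
  expect_identical(r1, r2)
  expect_length(unique(unlist(r1)), 2)
  expect_error(select_seeds(g, "random_n", n_random = 99), "exceeds")

  known <- community_set(list(c("a", "b")))
  expect_length(select_seeds(g, "known_community_nodes", known = known), 2)
})

test_that("the growth-step budget ignores outlier community sizes", {
  expect_equal(max_steps_smart(c(3, 3, 4, 5, 20)), 5)  # fence Q3 + 1.5 IQR = 8
  expect_equal(max_steps_smart(c(3, 4, 5)), 5)
  expect_equal(max_steps_smart(rep(6, 4)), 6)
  expect_equal(max_steps_smart(community_set(list(c("a", "b", "c")))), 3)
})

test_that("the acceptance rule is exact for non-worsening moves and calibrated otherwise", {
  isa <- search_params(heuristic = "eps_greedy_isa", T0 = 1, alpha = 1)
  out <- accept_step(0.7, 0.7, iteration = 0, params = isa)
  expect_true(out$accept)
  expect_equal(out$T_next, 1)

  # temperature schedule: T = T0 * alpha^iteration
  isa2 <- search_params(heuristic = "eps_greedy_isa", T0 = 2, alpha = 0.5)
  expect_equal(accept_step(1, 1, 3, isa2)$T_next, 2 * 0.5^4)

  expect_error(accept_step(1, 0.5, 0, search_params(heuristic = "eps_greedy")),
               "ISA")

  # worsening moves: empirical acceptance matches exp(dS/T) and k
  n <- 4000
  acc_isa <- withr::with_seed(21, vapply(1:n, function(i) {
    accept_step(0.8, 0.7, 0, isa)$accept
  }, TRUE))
  p <- exp(-0.1)
  ci <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(acc_isa) - p), ci)

  pm <- search_params(heuristic = "eps_greedy_pseudo_metropolis", k_accept = 0.1)
  acc_pm <- withr::with_seed(22, vapply(1:n, function(i) {
    accept_step(0.8, 0.7, 0, pm)$accept
  }, TRUE))
  expect_lt(abs(mean(acc_pm) - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("seed growth recovers planted cliques and respects termination rules", {
  toy <- make_clique_toy(4, c(4, 5, 6, 4))
  dm <- density_model()
  sp <- search_params(heuristic = "eps_greedy", epsilon = 0, max_steps = 8)
  for (seed in c("c01_n01", "c02_n03", "c03_n06")) {
    grown <- grow_seed(toy$graph, dm, seed, sp)
    truth <- toy$truth$nodes[[as.integer(substr(seed, 2, 3))]]
    expect_equal(grown$nodes[[1]], truth)
    expect_gte(grown$score, 0.5)
  }

  # a seed spanning a whole component has no boundary: nothing to grow
  expect_null(grow_seed(toy$graph, dm, toy$truth$nodes[[1]], sp))
  expect_error(grow_seed(toy$graph, dm, "nope", sp), "not in graph")

  # max_steps caps growth
  sp2 <- search_params(heuristic = "eps_greedy", epsilon = 0, max_steps = 3)
  g6 <- grow_seed(toy$graph, dm, "c03_n01", sp2)
  expect_equal(g6$size, 4)  # seed + 3 additions
})

test_that("epsilon-0 growth equals an exhaustive greedy oracle on a small graph", {
  ps <- planted_small()
  g <- ps$fx$graph
  dm <- density_model()
  # independent oracle: full neighbour evaluation, best score, lexicographic
  # ties, stop on empty boundary / score < 0.5 / max_steps
  greedy_oracle <- function(graph, seed, max_steps) {
    nodes <- seed
    nbm <- neighbor_map(graph, nodes)
    if (nrow(nbm) == 0) return(NULL)
    first <- nbm$neighbor[order(-nbm$max_weight, nbm$neighbor)][1]
    sc <- min(1, max(0, density_fitness(graph, c(nodes, first))))
    if (sc < 0.5) return(NULL)
    nodes <- sort(c(nodes, first))
    steps <- 1
    while (steps < max_steps) {
      nbm <- neighbor_map(graph, nodes)
      if (nrow(nbm) == 0) break
      scores <- vapply(nbm$neighbor, function(cd) {
        min(1, max(0, density_fitness(graph, c(nodes, cd))))
      }, 0)
      pick <- order(-scores, nbm$neighbor)[1]
      steps <- steps + 1
      if (scores[pick] < 0.5) break
      nodes <- sort(c(nodes, nbm$neighbor[pick]))
    }
    nodes
  }
  sp <- search_params(heuristic = "eps_greedy", epsilon = 0,
                      t1 = 10000, t2 = 10000, max_steps = 6)
  withr::with_seed(31, {
    for (seed in sample(g$nodes, 12)) {
      mine <- grow_seed(g, dm, seed, sp)
      oracle <- greedy_oracle(g, seed, 6)
      if (is.null(oracle)) {
        expect_null(mine)
      } else {
        expect_equal(mine$nodes[[1]], oracle)
      }
    }
  })
})

test_that("annealed growth cools monotonically and windows out stalled walks", {
  isa <- search_params(heuristic = "eps_greedy_isa", T0 = 1.75, alpha = 0.5)
  temps <- vapply(0:5, function(i) accept_step(1, 1, i, isa)$T_next, 0)
  expect_true(all(diff(temps) < 0))

  # improvement window: a walk that stops improving terminates early
  toy <- make_clique_toy(3, c(6, 6, 6))
  sp <- search_params(heuristic = "eps_greedy_isa", epsilon = 0, T0 = 1,
                      alpha = 1, improvement_window = 2, max_steps = 50)
  grown <- grow_seed(toy$graph, density_model(), "c01_n01", sp)
  expect_false(is.null(grown))
  expect_lte(grown$size, 6)
})

test_that("search over many seeds dedupes, parallelises deterministically and reports failures", {
  toy <- make_clique_toy(6, c(3, 4, 5, 3, 4, 5))
  dm <- density_model()
  sp <- search_params(heuristic = "eps_greedy_isa", max_steps = 6, rng_seed = 11)
  seeds <- select_seeds(toy$graph, "all_nodes")
  r1 <- run_search(toy$graph, dm, seeds, sp, n_workers = 1)
  expect_equal(nrow(r1), 6)  # one candidate per planted clique after dedup
  keys <- vapply(r1$nodes, paste, "", collapse = ",")
  expect_false(any(duplicated(keys)))
  expect_true(all(r1$score >= 0.5))

  r2 <- run_search(toy$graph, dm, seeds, sp, n_workers = 2)
  expect_identical(r1$nodes, r2$nodes)
  expect_identical(r1$score, r2$score)

  # every returned community is connected
  conn <- vapply(r1$nodes, function(ns) {
    induced_community(toy$graph, ns)$connected
  }, TRUE)
  expect_true(all(conn))
})
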