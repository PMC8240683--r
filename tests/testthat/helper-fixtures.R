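# Shared fixtures, built in code once per test run.

edge_tbl <- function(a, b, w) tibble::tibble(node_a = a, node_b = b, weight = w)

# triangle a-b-c, unit weights
graph_triangle <- function() {
  weighted_graph(edge_tbl(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1)))
}

# path a-b-c-d
graph_path4 <- function(w = c(1, 1, 1)) {
  weighted_graph(edge_tbl(c("a", "b", "c"), c("b", "c", "d"), w))
}

# k-clique on given node names
graph_clique <- function(nodes, w = 1) {
  cmb <- utils::combn(nodes, 2)
  weighted_graph(edge_tbl(cmb[1, ], cmb[2, ], rep_len(w, ncol(cmb))))
}

# star with hub h and given leaves
graph_star <- function(hub = "h", leaves = c("x", "y", "z")) {
  weighted_graph(edge_tbl(rep(hub, length(leaves)), leaves,
                          rep(1, length(leaves))))
}

# random community sets over a small node universe, for merge/metric properties
random_community_sets <- function(n_sets, n_comms = 8, universe = 30,
                                  size_range = c(3, 8), seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      community_set(lapply(seq_len(n_comms), function(j) {
        as.character(sample.int(universe, sample(size_range[1]:size_range[2], 1)))
      }))
    })
  })
}

# brute-force optimum of a maximum-weight injective assignment (rows of M to
# distinct columns); the independent oracle for the matching-based measures
brute_force_matching <- function(M) {
  nk <- nrow(M); nl <- ncol(M)
  rec <- function(row, used) {
    if (row > nk) return(0)
    best <- rec(row + 1, used)  # leave this row unmatched
    for (cl in seq_len(nl)) {
      if (!used[cl]) {
        u <- used; u[cl] <- TRUE
        best <- max(best, M[row, cl] + rec(row + 1, u))
      }
    }
    best
  }
  rec(1, rep(FALSE, nl))
}

# pairwise F-similarity matrix computed here, independently of the package's
# similarity_matrix path
fsim_matrix <- function(K_sets, L_sets) {
  outer(seq_along(K_sets), seq_along(L_sets), Vectorize(function(i, j) {
    inter <- length(intersect(K_sets[[i]], L_sets[[j]]))
    p <- inter / length(L_sets[[j]])
    r <- inter / length(K_sets[[i]])
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }))
}

# one modest planted benchmark + trained model, reused across test files
planted_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- make_labeled_fixture(planted_spec(rng_seed = 5))
      model <- train_fitness(fx$train, rng_seed = 5)
      cache <<- list(fx = fx, model = model)
    }
    cache
  }
})
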