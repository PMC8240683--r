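#' Search heuristic parameters
#'
#' Bundles every knob of the candidate-community growth heuristics.
#' Defaults follow the best human-network configuration: epsilon-greedy
#' neighbour selection (`epsilon = 0.01`) combined with iterative simulated
#' annealing (`T0 = 1.75`, `alpha = 0.005`). `alpha > 1` is accepted and
#' heats rather than cools the annealing schedule (useful on noisier
#' networks). `t1` caps how many boundary neighbours are considered at all
#' (a uniform random sample is taken above it); `t2` caps how many of those
#' are evaluated with the fitness model in the greedy branch (the `t2` with
#' the largest maximum connecting edge weight are kept), so the per-step
#' cost is dominated by `t2` model evaluations and an `O(t1 log t1)` sort.
#'
#' @param heuristic one of `"greedy_edge_weight"`, `"eps_greedy"`,
#'   `"eps_greedy_isa"`, `"eps_greedy_pseudo_metropolis"`.
#' @param epsilon probability of adding a uniformly random neighbour
#'   instead of the best-scoring one.
#' @param T0,alpha initial temperature and geometric update factor of the
#'   annealing schedule (`T <- alpha * T` after every iteration).
#' @param k_accept constant acceptance probability for worsening moves under
#'   pseudo-metropolis.
#' @param t1,t2 neighbour-sampling and evaluation caps (`t2 <= t1`).
#' @param max_steps maximum number of growth steps per seed; in a pipeline
#'   this is usually set from the known-community sizes via
#'   [max_steps_smart()].
#' @param improvement_window under ISA/pseudo-metropolis, stop after this
#'   many iterations without a score improvement.
#' @param greedy_model_stop for `"greedy_edge_weight"` (which does not
#'   consult the model per step), whether the model is still used for the
#'   score-below-0.5 termination check.
#' @param rng_seed integer seed; every seed's walk draws from a substream
#'   keyed by (`rng_seed`, seed node set), so results are independent of
#'   worker count and scheduling.
#' @return a `search_params` list.
#' @export
search_params <- function(heuristic = c("eps_greedy_isa", "eps_greedy",
                                        "eps_greedy_pseudo_metropolis",
                                        "greedy_edge_weight"),
                          epsilon = 0.01, T0 = 1.75, alpha = 0.005,
                          k_accept = 0.1, t1 = 500, t2 = 50, max_steps = 20,
                          improvement_window = 10, greedy_model_stop = TRUE,
                          rng_seed = 1) {
  heuristic <- match.arg(heuristic)
  stopifnot(epsilon >= 0, epsilon <= 1, T0 > 0, alpha > 0,
            k_accept > 0, k_accept <= 1, t2 <= t1, max_steps >= 1,
            improvement_window >= 1)
  structure(
    list(heuristic = heuristic, epsilon = epsilon, T0 = T0, alpha = alpha,
         k_accept = k_accept, t1 = t1, t2 = t2, max_steps = max_steps,
         improvement_window = improvement_window,
         greedy_model_stop = greedy_model_stop, rng_seed = rng_seed),
    class = "search_params"
  )
}

#' Choose growth seeds
#'
#' @param graph a `weighted_graph`.
#' @param mode `"all_nodes"` (one singleton seed per node; recommended for
#'   best accuracy), `"known_community_nodes"` (singletons for nodes
#'   appearing in known communities), `"random_n"` (`n_random` distinct
#'   random singletons), or `"maximal_cliques"` (every maximal clique as a
#'   multi-node seed).
#' @param known community tibble (required for `"known_community_nodes"`).
#' @param n_random number of seeds for `"random_n"`.
#' @param rng_seed integer seed for `"random_n"`.
#' @return a list of character vectors (seed node sets).
#' @export
select_seeds <- function(graph, mode = c("all_nodes", "known_community_nodes",
                                         "random_n", "maximal_cliques"),
                         known = NULL, n_random = NULL, rng_seed = 1) {
  mode <- match.arg(mode)
  switch(mode,
    all_nodes = as.list(graph$nodes),
    known_community_nodes = {
      if (is.null(known)) abort("select_seeds: known communities required")
      nodes <- sort(intersect(unique(unlist(known$nodes)), graph$nodes))
      if (length(nodes) == 0) abort("select_seeds: no known-community node in graph")
      as.list(nodes)
    },
    random_n = {
      if (is.null(n_random)) abort("select_seeds: n_random required")
      if (n_random > graph$n) abort("select_seeds: n_random exceeds node count")
      as.list(with_seed(rng_seed, sample(graph$nodes, n_random)))
    },
    maximal_cliques = {
      lapply(igraph::max_cliques(graph$ig),
             function(v) sort(igraph::V(graph$ig)$name[v]))
    }
  )
}

#' Growth-step budget from known community sizes, ignoring outliers
#'
#' Returns the largest known-community size at or below the Tukey upper
#' fence (Q3 + 1.5 IQR, linear-interpolation quartiles) of the size
#' distribution, falling back to the plain maximum when no size exceeds the
#' fence. Keeps a few giant known communities from inflating every walk's
#' step budget.
#'
#' @param known a community tibble (or an integer vector of sizes).
#' @return an integer step budget.
#' @export
max_steps_smart <- function(known) {
  sizes <- if (is.data.frame(known)) known$size else as.integer(known)
  if (length(sizes) == 0) abort("max_steps_smart: no known communities")
  q <- stats::quantile(sizes, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  within <- sizes[sizes <= fence]
  as.integer(if (length(within) > 0) max(within) else max(sizes))
}

#' Accept or reject a worsening growth step
#'
#' Acceptance rule of the second heuristic stage. A non-worsening step
#' (`S_new >= S_old`) is always accepted. A worsening step is accepted with
#' probability `exp((S_new - S_old) / T)` under iterative simulated
#' annealing, where `T = T0 * alpha^iteration` (iteration 0 is the first
#' post-seed growth step and the temperature is updated every iteration
#' regardless of acceptance), or with constant probability `k_accept` under
#' pseudo-metropolis.
#'
#' @param S_old,S_new fitness scores before and after the candidate
#'   addition.
#' @param iteration zero-based iteration index.
#' @param params a [search_params()] with heuristic `"eps_greedy_isa"` or
#'   `"eps_greedy_pseudo_metropolis"`.
#' @return a list with `accept` (logical) and `T_next` (the temperature for
#'   the next iteration).
#' @export
accept_step <- function(S_old, S_new, iteration, params) {
  if (!params$heuristic %in% c("eps_greedy_isa", "eps_greedy_pseudo_metropolis")) {
    abort("accept_step applies only to the ISA / pseudo-metropolis heuristics")
  }
  temp <- params$T0 * params$alpha^iteration
  if (temp <= 0) abort("accept_step: temperature must be positive")
  accept <- if (S_new >= S_old) {
    TRUE
  } else if (params$heuristic == "eps_greedy_isa") {
    stats::runif(1) < exp((S_new - S_old) / temp)
  } else {
    stats::runif(1) < params$k_accept
  }
  list(accept = accept, T_next = params$T0 * params$alpha^(iteration + 1))
}

# fitness of nodes + each candidate, as one batch model call
score_with_candidates <- function(model, graph, nodes, cands) {
  if (model$type == "density") {
    vapply(cands, function(cd) {
      min(1, max(0, density_fitness(graph, c(nodes, cd))))
    }, 0)
  } else {
    x <- do.call(rbind, lapply(cands, function(cd) {
      community_embedding(graph, c(nodes, cd))
    }))
    score_embeddings(model, x)
  }
}

#' Grow one seed into a candidate community
#'
#' Two-stage stochastic growth. The first step always adds the neighbour
#' connected by the highest edge weight. Each later step proposes a
#' neighbour according to the base heuristic — greedy edge weight (highest
#' maximum connecting weight, no per-step model call) or epsilon-greedy
#' (random neighbour with probability epsilon, otherwise the highest-scoring
#' of up to `t2` candidates preselected by edge weight from a sample of at
#' most `t1` neighbours) — and, under ISA / pseudo-metropolis, passes a
#' score-worsening proposal through [accept_step()]. Growth stops when the
#' boundary is empty, when the score drops below 0.5 (the last-added node is
#' removed first), when `improvement_window` iterations pass without a score
#' improvement (ISA / pseudo-metropolis), or after `max_steps` steps.
#' Ties among equal proposals break toward the lexicographically smallest
#' node id, making epsilon = 0 growth fully deterministic.
#'
#' @param graph a `weighted_graph`.
#' @param model a `commfit_fitness` object.
#' @param seed character vector of starting nodes (singleton or clique).
#' @param params a [search_params()].
#' @return a one-row community tibble with the final score, or `NULL` when
#'   the walk ends below 2 nodes or below score 0.5.
#' @export
grow_seed <- function(graph, model, seed, params) {
  seed <- sort(unique(as.character(seed)))
  if (!all(seed %in% graph$nodes)) {
    abort(paste0("grow_seed: seed node(s) not in graph: ",
                 paste(setdiff(seed, graph$nodes), collapse = ", ")))
  }
  with_seed(substream_seed(params$rng_seed, seed), {
    grow_seed_impl(graph, model, seed, params)
  })
}

grow_seed_impl <- function(graph, model, seed, params) {
  anneal <- params$heuristic %in% c("eps_greedy_isa", "eps_greedy_pseudo_metropolis")
  uses_model_steps <- params$heuristic != "greedy_edge_weight"
  check_score <- uses_model_steps || params$greedy_model_stop

  nodes <- seed
  nbm <- neighbor_map(graph, nodes)
  if (nrow(nbm) == 0) return(NULL)
  # first step: highest connecting edge weight, ties to smallest node id;
  # the model is not consulted here by design, and the score-termination
  # check starts once the subgraph has >= 3 nodes (a 2-node subgraph has no
  # topological variation for the embedding to work with)
  first <- nbm$neighbor[order(-nbm$max_weight, nbm$neighbor)][1]
  cand_nodes <- sort(c(nodes, first))
  score <- if (check_score && length(cand_nodes) >= 3) {
    score_node_set(model, graph, cand_nodes)
  } else NA_real_
  if (!is.na(score) && score < 0.5) {
    return(finish_community(graph, model, nodes, check_score))
  }
  nodes <- cand_nodes
  steps <- 1
  iteration <- 0
  best_score <- score
  since_improve <- 0

  while (steps < params$max_steps) {
    nbm <- neighbor_map(graph, nodes)
    if (nrow(nbm) == 0) break
    if (nrow(nbm) > params$t1) {
      nbm <- nbm[sort(sample.int(nrow(nbm), params$t1)), ]
    }
    if (params$heuristic == "greedy_edge_weight") {
      cand <- nbm$neighbor[order(-nbm$max_weight, nbm$neighbor)][1]
      S_new <- if (check_score) {
        score_node_set(model, graph, sort(c(nodes, cand)))
      } else NA_real_
    } else if (stats::runif(1) < params$epsilon) {
      cand <- nbm$neighbor[sample.int(nrow(nbm), 1)]
      S_new <- score_node_set(model, graph, sort(c(nodes, cand)))
    } else {
      if (nrow(nbm) > params$t2) {
        nbm <- nbm[order(-nbm$max_weight, nbm$neighbor)[seq_len(params$t2)], ]
      }
      cand_scores <- score_with_candidates(model, graph, nodes, nbm$neighbor)
      pick <- order(-cand_scores, nbm$neighbor)[1]
      cand <- nbm$neighbor[pick]
      S_new <- cand_scores[pick]
    }
    steps <- steps + 1
    if (check_score && S_new < 0.5) break  # last added node not kept
    accepted <- TRUE
    if (anneal && check_score && !is.na(score)) {
      accepted <- accept_step(score, S_new, iteration, params)$accept
    }
    iteration <- iteration + 1
    if (accepted) {
      nodes <- sort(c(nodes, cand))
      score <- S_new
    }
    if (anneal) {
      if (accepted && is.finite(S_new) &&
          (is.na(best_score) || S_new > best_score)) {
        best_score <- S_new
        since_improve <- 0
      } else {
        since_improve <- since_improve + 1
      }
      if (since_improve >= params$improvement_window) break
    }
  }
  finish_community(graph, model, nodes, check_score, score)
}

finish_community <- function(graph, model, nodes, check_score, score = NA_real_) {
  if (length(nodes) < 2) return(NULL)
  if (is.na(score)) score <- score_node_set(model, graph, nodes)
  if (check_score && score < 0.5) return(NULL)
  out <- community_set(list(nodes), label = "learned", score = score)
  out
}

#' Grow many seeds and collect the candidate communities
#'
#' Seeds are grown independently (embarrassingly parallel); each walk uses
#' an RNG substream keyed by the global seed and the seed node set, so the
#' result is identical for any worker count. Failed seeds are reported and
#' skipped; grown communities with identical node sets are deduplicated
#' (overlap-aware merging is the post-processing stage's job).
#'
#' @param graph a `weighted_graph`.
#' @param model a `commfit_fitness` object.
#' @param seeds list of seed node sets from [select_seeds()].
#' @param params a [search_params()].
#' @param n_workers number of forked workers (1 = sequential).
#' @return a community tibble of candidate communities with scores.
#' @export
run_search <- function(graph, model, seeds, params, n_workers = 1) {
  if (length(seeds) == 0) abort("run_search: no seeds")
  one <- function(s) {
    tryCatch(grow_seed(graph, model, s, params),
             error = function(e) structure(conditionMessage(e), class = "seed_failure"))
  }
  results <- if (n_workers > 1) {
    parallel::mclapply(seeds, one, mc.cores = n_workers)
  } else {
    lapply(seeds, one)
  }
  failed <- vapply(results, inherits, TRUE, what = "seed_failure")
  if (any(failed)) {
    warn(paste0(sum(failed), " seed(s) failed during growth; first error: ",
                unclass(results[failed][[1]])))
  }
  grown <- results[!failed]
  grown <- grown[!vapply(grown, is.null, TRUE)]
  if (length(grown) == 0) {
    return(community_set(list(), label = "learned"))
  }
  out <- bind_rows(grown)
  keys <- vapply(out$nodes, paste, "", collapse = "\x01")
  out <- out[!duplicated(keys), ]
  out$id <- sprintf("lea_%04d", seq_len(nrow(out)))
  out
}
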