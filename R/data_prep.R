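#' Clean a raw set of known communities against a network
#'
#' Maps each community onto the network (members absent from the network are
#' dropped first), then removes communities with fewer than 3 remaining
#' nodes, communities whose induced subgraph is internally disconnected, and
#' duplicate node sets.
#'
#' @param comms a community tibble (see [community_set()]).
#' @param graph a `weighted_graph`.
#' @return the retained community tibble, with `size` and `n_edges` columns
#'   recomputed from the induced subgraphs.
#' @export
clean_communities <- function(comms, graph) {
  if (nrow(comms) == 0) abort("clean_communities: empty input")
  present <- lapply(comms$nodes, function(ns) sort(ns[ns %in% graph$nodes]))
  keep_size <- lengths(present) >= 3
  stats <- vector("list", nrow(comms))
  connected <- rep(FALSE, nrow(comms))
  for (i in which(keep_size)) {
    stats[[i]] <- community_stats(graph, present[[i]])
    connected[i] <- stats[[i]]$connected
  }
  key <- vapply(present, paste, "", collapse = "\x01")
  keep <- keep_size & connected & !duplicated(key)
  if (!any(keep)) abort("clean_communities: all communities were filtered out")
  out <- comms[keep, ]
  out$nodes <- present[keep]
  out$size <- lengths(out$nodes)
  out$n_edges <- vapply(which(keep), function(i) stats[[i]]$m_c, 0L)
  out
}

#' Merge highly overlapping communities
#'
#' Iteratively merges communities until no pair overlaps at or above the
#' Jaccard threshold `j`. In a single pass, each community in list order is
#' merged with the community it overlaps most (if that overlap is >= `j`):
#' both originals are removed, their union is appended to the end of the
#' list, and the updated list is used immediately for the next community.
#' Passes repeat until one completes with no merge. Designed to perform few
#' merges so that as many distinct communities as possible survive —
#' important when known communities are scarce.
#'
#' @param comms a community tibble.
#' @param j Jaccard threshold in (0, 1]; default 0.6, the value used for
#'   redundancy removal in curated human-complex sets.
#' @param max_passes safety guard on the number of full passes.
#' @return a community tibble in which no pair has Jaccard >= `j`.
#' @export
merge_similar <- function(comms, j = 0.6, max_passes = 100) {
  stopifnot(j > 0, j <= 1)
  sets <- as_node_sets(comms)
  sets <- merge_pass_loop(
    sets, threshold = j,
    overlap = jaccard,
    pick = function(a, b, union_nodes) union_nodes,
    max_passes = max_passes
  )
  community_set(sets, label = if (nrow(comms) > 0) comms$label[1] else "positive")
}

# Shared pass structure for merge_similar and merge_learned. `pick` chooses
# the surviving node set from the two originals and their union.
merge_pass_loop <- function(sets, threshold, overlap, pick, max_passes) {
  passes <- 0
  repeat {
    passes <- passes + 1
    if (passes > max_passes) {
      abort(paste0("merging did not converge within ", max_passes,
                   " passes (", length(sets), " communities remain)"))
    }
    merged_any <- FALSE
    i <- 1
    while (i <= length(sets)) {
      if (length(sets) == 1) break
      ov <- vapply(seq_along(sets), function(k) {
        if (k == i) -Inf else overlap(sets[[i]], sets[[k]])
      }, 0)
      best <- which.max(ov)  # ties: earliest in current list order
      if (ov[best] >= threshold) {
        survivor <- pick(sets[[i]], sets[[best]],
                         sort(union(sets[[i]], sets[[best]])))
        sets <- c(sets[-sort(c(i, best))], list(survivor))
        merged_any <- TRUE
        # the element at position i was removed; continue at the same index
      } else {
        i <- i + 1
      }
    }
    if (!merged_any) break
  }
  sets
}

#' Split communities into edge-independent train and test sets
#'
#' Makes a random split at the requested fraction, then iterates transfer
#' rounds until the two sets are independent at the edge level: a training
#' community that shares at least one induced network edge with any test
#' community is transferred to the test set (and vice versa in the return
#' direction), with the updated sets visible immediately within a pass.
#' After each two-direction round, end-of-list rebalancing restores the
#' requested split fraction. Communities sharing edges therefore co-locate,
#' keeping the held-out communities genuinely unseen.
#'
#' @param comms a cleaned community tibble (>= 2 rows).
#' @param graph a `weighted_graph`.
#' @param train_frac target train fraction (default 0.7).
#' @param max_iters transfer rounds before giving up.
#' @param rng_seed integer seed for the initial random split.
#' @return a list with `train` and `test` community tibbles and the realized
#'   `ratio`.
#' @export
split_train_test <- function(comms, graph, train_frac = 0.7, max_iters = 20,
                             rng_seed = 1) {
  if (nrow(comms) < 2) abort("split_train_test: need at least 2 communities")
  sets <- as_node_sets(comms)
  edge_keys <- lapply(sets, function(ns) induced_edge_keys(graph, ns))
  n <- length(sets)
  n_train <- max(1L, min(n - 1L, round(train_frac * n)))
  ord <- with_seed(rng_seed, sample.int(n))
  train <- ord[seq_len(n_train)]
  test <- ord[-seq_len(n_train)]

  shares_edge <- function(i, others) {
    if (length(edge_keys[[i]]) == 0 || length(others) == 0) return(FALSE)
    any(edge_keys[[i]] %in% unlist(edge_keys[others], use.names = FALSE))
  }
  independent <- function(train, test) {
    tr_edges <- unlist(edge_keys[train], use.names = FALSE)
    te_edges <- unlist(edge_keys[test], use.names = FALSE)
    length(intersect(tr_edges, te_edges)) == 0
  }

  for (iter in seq_len(max_iters)) {
    if (independent(train, test) && length(train) >= 1 && length(test) >= 1) break
    # train -> test pass
    k <- 1
    while (k <= length(train)) {
      if (shares_edge(train[k], test)) {
        test <- c(test, train[k])
        train <- train[-k]
      } else k <- k + 1
    }
    # test -> train pass
    k <- 1
    while (k <= length(test)) {
      if (shares_edge(test[k], train)) {
        train <- c(train, test[k])
        test <- test[-k]
      } else k <- k + 1
    }
    # rebalance from list ends toward the target counts
    while (length(train) > n_train && length(train) > 1) {
      test <- c(test, train[length(train)])
      train <- train[-length(train)]
    }
    while (length(train) < n_train && length(test) > 1) {
      train <- c(train, test[length(test)])
      test <- test[-length(test)]
    }
    if (iter == max_iters && !independent(train, test)) {
      abort(paste0(
        "no edge-independent split found in ", max_iters,
        " iterations; restart with a different rng_seed"))
    }
  }
  if (length(train) == 0 || length(test) == 0 || !independent(train, test)) {
    abort("no edge-independent split found; restart with a different rng_seed")
  }
  list(
    train = comms[sort(train), ],
    test = comms[sort(test), ],
    ratio = length(train) / n
  )
}

# canonical "u|v" keys of a community's induced edges
induced_edge_keys <- function(graph, nodes) {
  in_set <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  keys <- unlist(lapply(nodes, function(u) {
    nb <- names(graph$adj[[u]])
    nb <- nb[!is.na(in_set[nb])]
    nb <- nb[nb > u]
    if (length(nb) == 0) character() else paste(u, nb, sep = "|")
  }), use.names = FALSE)
  keys
}

#' Sample random-walk negative communities
#'
#' Non-communities are represented by connected random walks: a walk starts
#' from a random seed node and repeatedly absorbs a uniformly random
#' neighbour of the current subgraph until the target size is reached. The
#' number of walks is `scale_factor` times the number of positives, with
#' target sizes spread (almost) equally over the positive size range
#' (`distribution = "uniform"`) or matched to the positive size histogram
#' (`distribution = "matched"`). When a walk stalls below its target size
#' (e.g. it exhausts a small connected component), up to `max_retries` fresh
#' walks are attempted before the nearest achieved size is accepted with a
#' warning.
#'
#' @param graph a `weighted_graph`.
#' @param positives a community tibble of positive communities.
#' @param scale_factor multiple of `nrow(positives)` walks to sample (> 1).
#' @param distribution `"uniform"` or `"matched"` target-size distribution.
#' @param max_retries fresh attempts per walk to hit the exact target size.
#' @param rng_seed integer seed.
#' @return a community tibble with `label = "negative"`.
#' @export
sample_negatives <- function(graph, positives, scale_factor = 1.1,
                             distribution = c("uniform", "matched"),
                             max_retries = 10, rng_seed = 1) {
  stopifnot(scale_factor > 1)
  distribution <- match.arg(distribution)
  sizes_pos <- positives$size
  size_min <- max(3L, min(sizes_pos))
  size_max <- max(sizes_pos)
  n_walks <- round(scale_factor * nrow(positives))
  targets <- if (distribution == "uniform") {
    spread_uniform(n_walks, size_min:size_max)
  } else {
    with_seed(rng_seed, sample(sizes_pos, n_walks, replace = TRUE))
  }
  walks <- with_seed(rng_seed, {
    lapply(targets, function(target) random_walk_community(graph, target, max_retries))
  })
  short <- sum(lengths(walks) < targets)
  if (short > 0) {
    warn(paste0(short, " random walk(s) capped below their target size ",
                "(component too small)"))
  }
  community_set(walks, label = "negative")
}

# split n_total walks over the candidate sizes as evenly as possible
# (counts differ by at most 1; the remainder goes to the smallest sizes)
spread_uniform <- function(n_total, sizes) {
  k <- length(sizes)
  base <- n_total %/% k
  extra <- n_total %% k
  counts <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  rep(sizes, times = counts)
}

# one connected random walk aiming for `target` nodes; revisits permitted
# upstream by construction (the subgraph's neighbour set shrinks only when
# the component is exhausted)
random_walk_community <- function(graph, target, max_retries) {
  best <- character()
  for (attempt in seq_len(max_retries + 1)) {
    current <- sample(graph$nodes, 1)
    steps <- 0
    while (length(current) < target && steps < 2 * target) {
      steps <- steps + 1
      nbm <- neighbor_map(graph, current)
      if (nrow(nbm) == 0) break
      current <- c(current, sample(nbm$neighbor, 1))
    }
    if (length(current) > length(best)) best <- current
    if (length(best) >= target) break
  }
  sort(best)
}

#' Remove negatives that resemble positive communities
#'
#' Random walks occasionally land on genuine communities; any negative with
#' Jaccard >= `j_neg` against some positive is dropped before training.
#'
#' @param negatives,positives community tibbles.
#' @param j_neg Jaccard threshold (default 0.5, matching the match threshold
#'   used in binary-match evaluation).
#' @return the retained negatives; the number removed is reported via a
#'   message and the `"n_removed"` attribute.
#' @export
filter_negatives <- function(negatives, positives, j_neg = 0.5) {
  pos_sets <- as_node_sets(positives)
  resembles <- vapply(negatives$nodes, function(ns) {
    any(vapply(pos_sets, function(ps) jaccard(ns, ps) >= j_neg, TRUE))
  }, TRUE)
  out <- negatives[!resembles, ]
  message(sum(resembles), " negative(s) removed for resembling positives")
  attr(out, "n_removed") <- sum(resembles)
  out
}
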