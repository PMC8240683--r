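#' Toy network of disconnected cliques
#'
#' Each clique is one ground-truth community; all edge weights are 1. A
#' pipeline that cannot recover these exactly is broken, which makes this
#' the canonical end-to-end validation input.
#'
#' @param n_cliques number of cliques.
#' @param sizes integer vector of clique sizes (each >= 3), recycled to
#'   `n_cliques`.
#' @return a list with `graph` (a `weighted_graph`) and `truth` (a community
#'   tibble).
#' @export
make_clique_toy <- function(n_cliques = 10, sizes = 3:8) {
  sizes <- rep_len(as.integer(sizes), n_cliques)
  stopifnot(all(sizes >= 3))
  comms <- lapply(seq_len(n_cliques), function(i) {
    sprintf("c%02d_n%02d", i, seq_len(sizes[i]))
  })
  edges <- bind_rows(lapply(comms, function(nodes) {
    cmb <- utils::combn(nodes, 2)
    tibble(node_a = cmb[1, ], node_b = cmb[2, ], weight = 1)
  }))
  list(graph = weighted_graph(edges), truth = community_set(comms))
}

#' Specification of a planted-community benchmark network
#'
#' Describes a synthetic network of communities with heterogeneous
#' topologies — cliques, stars (hub-and-spoke), linear paths, and hybrids
#' (a path plus random chords at probability 0.5) — reflecting the range of
#' shapes real protein complexes exhibit, embedded in low-weight background
#' noise. Intra-community weights are drawn from a normal distribution
#' truncated to (0, 1] centred high (default mean 0.8, sd 0.1) and
#' background weights centred low (default mean 0.1, sd 0.05), mimicking the
#' separation of confidence scores in integrated interaction networks while
#' leaving the classes learnable rather than trivially separable by a single
#' edge.
#'
#' @param n_communities number of planted communities.
#' @param size_range inclusive (min, max) community size; min >= 3.
#' @param topology_mix named proportions over
#'   `c("clique", "star", "linear", "hybrid")`; must sum to 1.
#' @param intra_weight (mean, sd) of intra-community edge weights.
#' @param background_nodes number of extra noise nodes.
#' @param background_edge_prob probability of a noise edge for each pair
#'   involving a background node.
#' @param background_weight (mean, sd) of noise edge weights.
#' @param overlap_prob probability that a community shares one node with a
#'   previously planted community.
#' @param rng_seed integer seed.
#' @return a `planted_spec` list.
#' @export
planted_spec <- function(n_communities = 50, size_range = c(4, 10),
                         topology_mix = c(clique = 0.25, star = 0.25,
                                          linear = 0.25, hybrid = 0.25),
                         intra_weight = c(0.8, 0.1),
                         background_nodes = 100,
                         background_edge_prob = 0.01,
                         background_weight = c(0.1, 0.05),
                         overlap_prob = 0.05, rng_seed = 1) {
  stopifnot(size_range[1] >= 3,
            abs(sum(topology_mix) - 1) < 1e-8,
            setequal(names(topology_mix), c("clique", "star", "linear", "hybrid")))
  structure(
    list(n_communities = n_communities, size_range = size_range,
         topology_mix = topology_mix, intra_weight = intra_weight,
         background_nodes = background_nodes,
         background_edge_prob = background_edge_prob,
         background_weight = background_weight,
         overlap_prob = overlap_prob, rng_seed = rng_seed),
    class = "planted_spec"
  )
}

rtrunc_weight <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out <= 0 | out > 1
  tries <- 0
  while (any(bad) && tries < 50) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out <= 0 | out > 1
    tries <- tries + 1
  }
  pmin(pmax(out, 1e-4), 1)
}

topology_edges <- function(nodes, topology) {
  size <- length(nodes)
  pairs <- switch(topology,
    clique = utils::combn(nodes, 2),
    star = rbind(rep(nodes[1], size - 1), nodes[-1]),
    linear = rbind(nodes[-size], nodes[-1]),
    hybrid = {
      path <- rbind(nodes[-size], nodes[-1])
      extra <- utils::combn(nodes, 2)
      adjacent <- abs(match(extra[1, ], nodes) - match(extra[2, ], nodes)) == 1
      chords <- extra[, !adjacent & stats::runif(ncol(extra)) < 0.5, drop = FALSE]
      cbind(path, chords)
    }
  )
  tibble(node_a = pairs[1, ], node_b = pairs[2, ])
}

#' Generate a planted-community network
#'
#' Instantiates each community per its sampled topology with high
#' intra-community weights, adds background noise nodes and low-weight noise
#' edges, and optionally lets communities share single nodes. Every planted
#' community is connected by construction and the ground-truth set satisfies
#' the cleaning constraints (size >= 3, connected, unique).
#'
#' @param spec a [planted_spec()].
#' @return a list with `graph` and `truth` (community tibble carrying a
#'   `topology` column).
#' @export
make_planted_graph <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  with_seed(spec$rng_seed, {
    topo <- sample(names(spec$topology_mix), spec$n_communities,
                   replace = TRUE, prob = spec$topology_mix)
    sizes <- sample(seq(spec$size_range[1], spec$size_range[2]),
                    spec$n_communities, replace = TRUE)
    comms <- vector("list", spec$n_communities)
    for (i in seq_len(spec$n_communities)) {
      nodes <- sprintf("m%03d_%02d", i, seq_len(sizes[i]))
      if (i > 1 && stats::runif(1) < spec$overlap_prob) {
        donor <- sample(seq_len(i - 1), 1)
        nodes[sample(sizes[i], 1)] <- sample(comms[[donor]], 1)
        nodes <- unique(nodes)
      }
      comms[[i]] <- nodes
    }
    intra <- bind_rows(lapply(seq_along(comms), function(i) {
      topology_edges(comms[[i]], topo[i])
    }))
    intra$weight <- rtrunc_weight(nrow(intra), spec$intra_weight[1],
                                  spec$intra_weight[2])
    member_nodes <- unique(unlist(comms))
    bg_nodes <- if (spec$background_nodes > 0) {
      sprintf("bg%03d", seq_len(spec$background_nodes))
    } else character()
    noise <- NULL
    if (length(bg_nodes) > 0) {
      all_nodes <- c(member_nodes, bg_nodes)
      cand_a <- rep(bg_nodes, times = length(all_nodes))
      cand_b <- rep(all_nodes, each = length(bg_nodes))
      keep <- cand_a < cand_b  # dedupe and drop self-pairs
      cand_a <- cand_a[keep]; cand_b <- cand_b[keep]
      pick <- stats::runif(length(cand_a)) < spec$background_edge_prob
      if (any(pick)) {
        noise <- tibble(
          node_a = cand_a[pick], node_b = cand_b[pick],
          weight = rtrunc_weight(sum(pick), spec$background_weight[1],
                                 spec$background_weight[2])
        )
      }
    }
    edges <- bind_rows(intra, noise)
    truth <- community_set(comms)
    truth$topology <- topo
    list(graph = weighted_graph(edges), truth = truth)
  })
}

#' End-to-end labelled feature matrices from a planted benchmark
#'
#' Runs the full data-preparation chain — cleaning, redundancy merging,
#' edge-independent train/test split, random-walk negative sampling and
#' resemblance filtering — on a planted network and returns ready train and
#' test feature matrices for fitness-model work.
#'
#' @param spec a [planted_spec()].
#' @param merge_j Jaccard threshold for merging similar known communities.
#' @param train_frac train fraction of the split.
#' @param neg_scale negative over-sampling factor (> 1).
#' @param j_neg resemblance threshold for discarding negatives.
#' @return a list with `graph`, `truth`, `split` (train/test positives),
#'   `negatives` (list with train/test), and `train` / `test` feature
#'   tibbles.
#' @export
make_labeled_fixture <- function(spec, merge_j = 0.6, train_frac = 0.7,
                                 neg_scale = 1.1, j_neg = 0.5) {
  inst <- make_planted_graph(spec)
  cleaned <- clean_communities(inst$truth, inst$graph) |>
    merge_similar(j = merge_j)
  split <- split_train_test(cleaned, inst$graph, train_frac = train_frac,
                            rng_seed = spec$rng_seed)
  negatives <- sample_negatives(inst$graph, cleaned, scale_factor = neg_scale,
                                rng_seed = spec$rng_seed) |>
    filter_negatives(cleaned, j_neg = j_neg) |>
    suppressMessages()
  n_neg <- nrow(negatives)
  if (n_neg < 2) abort("make_labeled_fixture: too few negatives survived filtering")
  idx <- with_seed(spec$rng_seed, sample.int(n_neg))
  n_tr <- max(1L, min(n_neg - 1L, round(train_frac * n_neg)))
  neg_train <- negatives[sort(idx[seq_len(n_tr)]), ]
  neg_test <- negatives[sort(idx[-seq_len(n_tr)]), ]
  list(
    graph = inst$graph, truth = inst$truth, split = split,
    negatives = list(train = neg_train, test = neg_test),
    train = build_feature_matrix(split$train, neg_train, inst$graph),
    test = build_feature_matrix(split$test, neg_test, inst$graph)
  )
}

#' Write a synthetic instance to disk in the standard formats
#'
#' @param instance a list with `graph` and `truth` (from
#'   [make_clique_toy()] or [make_planted_graph()]).
#' @param dir output directory (created if missing); writes `edges.tsv` and
#'   `communities.txt`.
#' @return `dir`, invisibly.
#' @export
write_instance <- function(instance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(instance$graph$edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_communities(instance$truth, file.path(dir, "communities.txt"),
                    with_score = FALSE)
  invisible(dir)
}
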