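#' Density-based community fitness (baseline score)
#'
#' The classical density fitness of a subgraph `C`:
#' `f(C) = delta_int(C) - delta_ext(C)`, where the intra-cluster density is
#' `delta_int = m_c / (n_c (n_c - 1) / 2)` and the inter-cluster density is
#' `delta_ext = (# boundary edges) / (n_c (n - n_c))` (defined as 0 when the
#' community spans the whole graph). Retained as a model-free baseline
#' scoring option; the trained classifier replaces it in the full pipeline.
#'
#' @param graph a `weighted_graph`.
#' @param nodes character vector of community members (>= 2, present in the
#'   graph).
#' @return `delta_int - delta_ext`, a value in \[-1, 1\].
#' @export
density_fitness <- function(graph, nodes) {
  nodes <- unique(as.character(nodes))
  n_c <- length(nodes)
  if (n_c < 2) abort("density_fitness: community must have at least 2 nodes")
  st <- community_stats(graph, nodes)
  delta_int <- st$m_c / (n_c * (n_c - 1) / 2)
  n <- graph$n
  if (n_c >= n) {
    delta_ext <- 0
  } else {
    in_set <- stats::setNames(rep(TRUE, n_c), nodes)
    boundary <- sum(vapply(nodes, function(u) {
      nb <- names(graph$adj[[u]])
      sum(is.na(in_set[nb]))
    }, 0L))
    delta_ext <- boundary / (n_c * (n - n_c))
  }
  delta_int - delta_ext
}

# Fixed, versioned order of the 18 topological features. Changing this list
# (or its order) invalidates trained models; the version string is embedded
# in every model artifact.
FEATURE_VERSION <- "commfit-18-v1"

FEATURE_NAMES <- c(
  "n_nodes", "n_edges", "density", "total_weight", "mean_weight",
  "max_weight", "var_weight", "mean_wdegree", "max_degree", "median_degree",
  "var_degree", "clust_mean", "clust_max", "clust_var", "assortativity",
  "lead_eigenvalue", "diameter", "transitivity"
)

#' Names of the 18 topological features, in canonical order
#' @return character vector of length 18.
#' @export
feature_names <- function() FEATURE_NAMES

#' Topological embedding of a community
#'
#' Computes the 18-dimensional feature vector of a community's induced
#' weighted subgraph. The set spans the size, edge-weight, degree, cohesion
#' and spectral axes along which community topologies (cliques, stars,
#' paths, hybrids) differ: node and edge counts, unweighted density, total /
#' mean / max / variance of edge weights, mean weighted degree, max / median
#' / variance of degrees, mean / max / variance of local clustering
#' coefficients, degree assortativity, leading eigenvalue of the weighted
#' adjacency, unweighted diameter, and global transitivity. Degenerate
#' statistics (variance over a single value, assortativity of a regular
#' graph, clustering of degree-1 nodes) are defined as 0 so vectors are
#' always finite. Only the induced subgraph is consulted, so the embedding
#' is invariant to node relabeling and to everything outside the community.
#'
#' @param graph a `weighted_graph`.
#' @param nodes community members; at least 2 nodes, inducing a connected
#'   subgraph.
#' @return a named numeric vector of length 18.
#' @export
community_embedding <- function(graph, nodes) {
  nodes <- unique(as.character(nodes))
  n_c <- length(nodes)
  if (n_c < 2) abort("community_embedding: need at least 2 nodes")
  missing <- setdiff(nodes, graph$nodes)
  if (length(missing) > 0) {
    abort(paste0("community_embedding: node(s) absent from graph: ",
                 paste(utils::head(missing, 3), collapse = ", ")))
  }
  sub <- igraph::induced_subgraph(graph$ig, nodes)
  if (!igraph::is_connected(sub)) {
    abort("community_embedding: induced subgraph is disconnected (diameter undefined)")
  }
  w <- igraph::E(sub)$weight
  m_c <- length(w)
  deg <- igraph::degree(sub)
  wdeg <- igraph::strength(sub)
  lc <- igraph::transitivity(sub, type = "local", isolates = "zero")
  lc[is.na(lc)] <- 0
  assort <- igraph::assortativity_degree(sub)
  if (!is.finite(assort)) assort <- 0
  trans <- igraph::transitivity(sub, type = "global")
  if (!is.finite(trans)) trans <- 0
  adj <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
  lead_ev <- max(eigen(adj, symmetric = TRUE, only.values = TRUE)$values)
  var0 <- function(x) if (length(x) < 2) 0 else stats::var(x)
  out <- c(
    n_nodes = n_c,
    n_edges = m_c,
    density = m_c / (n_c * (n_c - 1) / 2),
    total_weight = sum(w),
    mean_weight = if (m_c > 0) mean(w) else 0,
    max_weight = if (m_c > 0) max(w) else 0,
    var_weight = var0(w),
    mean_wdegree = mean(wdeg),
    max_degree = max(deg),
    median_degree = stats::median(deg),
    var_degree = var0(deg),
    clust_mean = mean(lc),
    clust_max = max(lc),
    clust_var = var0(lc),
    assortativity = assort,
    lead_eigenvalue = lead_ev,
    diameter = igraph::diameter(sub, weights = NA),
    transitivity = trans
  )
  stopifnot(identical(names(out), FEATURE_NAMES), all(is.finite(out)))
  out
}

#' Build a labeled feature matrix from positive and negative communities
#'
#' One row per community, the 18 embedding features plus a `label` column
#' (1 = positive, 0 = negative) and the community `id`; row order follows
#' the inputs (positives first).
#'
#' @param pos,neg community tibbles (both nonempty).
#' @param graph a `weighted_graph`.
#' @return a tibble with 18 feature columns, `label` and `id`.
#' @export
build_feature_matrix <- function(pos, neg, graph) {
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    abort("build_feature_matrix: both classes must be nonempty")
  }
  embed_all <- function(comms, label) {
    rows <- lapply(seq_len(nrow(comms)), function(i) {
      tryCatch(
        community_embedding(graph, comms$nodes[[i]]),
        error = function(e) abort(paste0(
          "embedding failed for community ", comms$id[i], ": ",
          conditionMessage(e)))
      )
    })
    out <- as_tibble(do.call(rbind, rows))
    out$label <- label
    out$id <- comms$id
    out
  }
  bind_rows(embed_all(pos, 1L), embed_all(neg, 0L))
}

#' Write a feature matrix as TSV
#'
#' @param features a feature tibble from [build_feature_matrix()].
#' @param path output path; header = feature names + `label` (+ `id`).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
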