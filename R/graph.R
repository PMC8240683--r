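#' Read a weighted edge list from disk
#'
#' Parses a whitespace/TAB-separated file of `node_a node_b weight` records.
#' A single header line is skipped automatically when its third column does
#' not parse as a number. Node identifiers are opaque, case-sensitive
#' strings; no normalisation is applied.
#'
#' @param path path to the edge-list file.
#' @return a tibble with columns `node_a`, `node_b`, `weight` (one row per
#'   input record, uncleaned — see [weighted_graph()] for cleaning rules).
#' @seealso [weighted_graph()], [load_graph()]
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(paste0("edge list not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) abort("edge list is empty")
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  start <- 1L
  if (length(fields[[1]]) >= 3 && is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    start <- 2L  # header line
    if (length(keep) < 2) abort("edge list contains only a header")
  }
  rows <- seq(start, length(keep))
  bad_len <- rows[lengths(fields[rows]) < 3]
  if (length(bad_len) > 0) {
    abort(paste0("malformed edge list line ", keep[bad_len[1]],
                 ": expected at least 3 columns"))
  }
  w <- suppressWarnings(as.numeric(vapply(fields[rows], `[`, "", 3L)))
  if (anyNA(w)) {
    bad <- rows[which(is.na(w))[1]]
    abort(paste0("malformed edge list line ", keep[bad],
                 ": weight does not parse as a number"))
  }
  tibble(
    node_a = vapply(fields[rows], `[`, "", 1L),
    node_b = vapply(fields[rows], `[`, "", 2L),
    weight = w
  )
}

#' Build a weighted, undirected network from an edge table
#'
#' Cleans the edge table and constructs the in-memory network object used
#' by the rest of the package. Cleaning rules: self-loops are removed,
#' duplicate undirected edges are collapsed keeping the maximum weight
#' (conservative for confidence-weighted interaction edges), and edges with
#' weight below `weight_cutoff` are dropped. Nodes are the endpoints of the
#' surviving edges.
#'
#' @param edges data frame with columns `node_a`, `node_b`, `weight`.
#' @param weight_cutoff edges with weight strictly below this value are
#'   dropped (default 0, i.e. keep all positive weights).
#' @return an object of class `weighted_graph` with elements `edges`
#'   (canonical tibble, `node_a < node_b`), `nodes`, `n`, `adj` (per-node
#'   named weight vectors) and `ig` (an igraph handle for structural
#'   queries).
#' @export
weighted_graph <- function(edges, weight_cutoff = 0) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b", "weight") %in% names(edges)))
  if (any(edges$weight <= 0)) abort("edge weights must be strictly positive")
  ed <- tibble(
    node_a = pmin(as.character(edges$node_a), as.character(edges$node_b)),
    node_b = pmax(as.character(edges$node_a), as.character(edges$node_b)),
    weight = edges$weight
  )
  ed <- ed |>
    filter(.data$node_a != .data$node_b, .data$weight >= weight_cutoff)
  if (nrow(ed) == 0) abort("graph is empty after cleaning/cutoff")
  ed <- ed |>
    group_by(.data$node_a, .data$node_b) |>
    summarise(weight = max(.data$weight), .groups = "drop") |>
    arrange(.data$node_a, .data$node_b)
  nodes <- sort(unique(c(ed$node_a, ed$node_b)))
  adj <- build_adjacency(ed, nodes)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = ed$node_a, to = ed$node_b, weight = ed$weight),
    directed = FALSE, vertices = nodes
  )
  structure(
    list(edges = ed, nodes = nodes, n = length(nodes), adj = adj, ig = ig),
    class = "weighted_graph"
  )
}

build_adjacency <- function(edges, nodes) {
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  both_from <- c(edges$node_a, edges$node_b)
  both_to <- c(edges$node_b, edges$node_a)
  both_w <- c(edges$weight, edges$weight)
  split_idx <- split(seq_along(both_from), both_from)
  for (node in names(split_idx)) {
    i <- split_idx[[node]]
    adj[[node]] <- stats::setNames(both_w[i], both_to[i])
  }
  adj
}

#' Load, clean and index a weighted network in one step
#'
#' @inheritParams read_edge_list
#' @inheritParams weighted_graph
#' @return a `weighted_graph`.
#' @export
load_graph <- function(path, weight_cutoff = 0) {
  weighted_graph(read_edge_list(path), weight_cutoff = weight_cutoff)
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("<weighted_graph>", x$n, "nodes,", nrow(x$edges), "edges\n")
  if (!is.null(attr(x, "storage_dir"))) {
    cat("  node store:", attr(x, "storage_dir"), "\n")
  }
  invisible(x)
}

#' Persist the network as a per-node neighbour store
#'
#' Writes one text record per node (`<dir>/<encoded-node>.tsv`, lines of
#' `neighbor<TAB>weight`) plus a `nodes.tsv` manifest mapping node ids to
#' file names, so that any single node's neighbourhood can be read back
#' without loading the whole network.
#'
#' @param graph a `weighted_graph`.
#' @param dir directory to write into (created if missing).
#' @return `dir`, invisibly; the graph gains a `storage_dir` attribute.
#' @export
write_node_store <- function(graph, dir) {
  stopifnot(inherits(graph, "weighted_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(paste0("cannot create node store directory: ", dir))
  fnames <- paste0(utils::URLencode(graph$nodes, reserved = TRUE), ".tsv")
  ok <- tryCatch({
    for (i in seq_along(graph$nodes)) {
      nb <- graph$adj[[graph$nodes[i]]]
      writeLines(paste(names(nb), format(nb, digits = 17, trim = TRUE,
                                         scientific = FALSE), sep = "\t"),
                 file.path(dir, fnames[i]))
    }
    utils::write.table(
      data.frame(node = graph$nodes, file = fnames),
      file.path(dir, "nodes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(paste0("node store write failed: ", conditionMessage(ok)))
  invisible(dir)
}

#' Read one node's neighbours from a node store
#'
#' @param dir a node-store directory written by [write_node_store()].
#' @param node a node identifier.
#' @return a named numeric vector of neighbour weights.
#' @export
store_neighbors <- function(dir, node) {
  path <- file.path(dir, paste0(utils::URLencode(node, reserved = TRUE), ".tsv"))
  if (!file.exists(path)) abort(paste0("node not in store: ", node))
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                  vapply(parts, `[`, "", 1L))
}

#' Reconstruct a network from a node store
#'
#' @param dir a node-store directory written by [write_node_store()].
#' @return a `weighted_graph` with the identical edge multiset.
#' @export
read_node_store <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "nodes.tsv"), sep = "\t",
                                header = TRUE, colClasses = "character")
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    nb <- store_neighbors(dir, manifest$node[i])
    if (length(nb) == 0) return(NULL)
    tibble(node_a = manifest$node[i], node_b = names(nb), weight = unname(nb))
  })
  weighted_graph(bind_rows(recs))
}

# Number of induced edges and connectivity of a node set, via adjacency lists.
community_stats <- function(graph, nodes) {
  nodes <- unique(nodes)
  in_set <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  deg_in <- vapply(nodes, function(u) {
    nb <- names(graph$adj[[u]])
    sum(!is.na(in_set[nb]))
  }, 0L)
  m_c <- sum(deg_in) %/% 2L
  # BFS connectivity within the induced subgraph
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  queue <- nodes[1]
  visited[queue] <- TRUE
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    nb <- names(graph$adj[[u]])
    nb <- nb[!is.na(in_set[nb])]
    new <- nb[!visited[nb]]
    visited[new] <- TRUE
    queue <- c(queue, new)
  }
  list(n_c = length(nodes), m_c = m_c, connected = all(visited))
}

#' Induced subgraph of a node set as a community record
#'
#' Nodes absent from the network are silently dropped (community files often
#' reference proteins missing from the interaction network); edge counts are
#' taken from the induced subgraph.
#'
#' @param graph a `weighted_graph`.
#' @param nodes character vector of node ids.
#' @return a one-row tibble with columns `nodes` (list-column), `size`,
#'   `n_edges`, `connected`.
#' @export
induced_community <- function(graph, nodes) {
  nodes <- unique(as.character(nodes))
  nodes <- nodes[nodes %in% graph$nodes]
  if (length(nodes) == 0) abort("induced_community: no nodes present in graph")
  st <- community_stats(graph, nodes)
  tibble(nodes = list(sort(nodes)), size = st$n_c, n_edges = st$m_c,
         connected = st$connected)
}

#' Boundary neighbourhood of a subgraph
#'
#' Enumerates the nodes adjacent to (but outside) a community, with each
#' neighbour's best connecting edge weight and the full list of connecting
#' edges — the working structure consulted at every growth step.
#'
#' @param graph a `weighted_graph`.
#' @param nodes character vector of community member ids.
#' @return a tibble with columns `neighbor`, `max_weight`, and `links`
#'   (list-column of tibbles `node`, `weight`); zero rows if the community
#'   has no external neighbours.
#' @export
neighbor_map <- function(graph, nodes) {
  nodes <- unique(as.character(nodes))
  if (length(nodes) == 0) abort("neighbor_map: empty community")
  in_set <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  member <- rep(nodes, times = vapply(nodes, function(u) length(graph$adj[[u]]), 0L))
  nb <- unlist(lapply(nodes, function(u) names(graph$adj[[u]])), use.names = FALSE)
  w <- unlist(lapply(nodes, function(u) unname(graph$adj[[u]])), use.names = FALSE)
  outside <- is.na(in_set[nb])
  if (!any(outside)) {
    return(tibble(neighbor = character(), max_weight = numeric(), links = list()))
  }
  nb_out <- nb[outside]
  member_out <- member[outside]
  w_out <- w[outside]
  grp <- split(seq_along(nb_out), nb_out)  # split() sorts keys
  tibble(
    neighbor = names(grp),
    max_weight = unname(vapply(grp, function(i) max(w_out[i]), 0)),
    links = unname(lapply(grp, function(i) {
      tibble(node = member_out[i], weight = w_out[i])
    }))
  )
}
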