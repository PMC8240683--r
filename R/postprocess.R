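#' Drop 2-node candidate communities
#'
#' Pairs carry no topological variation, so candidates that never grew past
#' two nodes are removed before merging.
#'
#' @param comms a community tibble.
#' @return the rows with `size >= 3`; warns when nothing survives.
#' @export
remove_small <- function(comms) {
  out <- comms[comms$size >= 3, ]
  if (nrow(out) == 0 && nrow(comms) > 0) {
    warn("remove_small: all candidate communities had fewer than 3 nodes")
  }
  out
}

#' Merge-stage parameters for learned communities
#'
#' @param measure overlap measure: `"qi_overlap"` (neighbourhood affinity,
#'   `|A∩B|^2 / (|A||B|)`) or `"jaccard"`.
#' @param threshold overlap at or above which a pair is resolved (default
#'   0.375, the best-performing value on the human network).
#' @param max_passes convergence guard on full merge passes.
#' @return a `merge_params` list.
#' @export
merge_params <- function(measure = c("qi_overlap", "jaccard"),
                         threshold = 0.375, max_passes = 100) {
  measure <- match.arg(measure)
  stopifnot(threshold > 0, threshold <= 1)
  structure(list(measure = measure, threshold = threshold,
                 max_passes = max_passes),
            class = "merge_params")
}

#' Fitness-aware merging of overlapping learned communities
#'
#' Same iterative pass structure as [merge_similar()], but when a pair
#' overlaps at or above the threshold the two originals and their union are
#' all scored with the fitness model and only the single highest-scoring of
#' the three is retained (appended to the end of the working list). The
#' output therefore contains no pair overlapping at or above the threshold,
#' and with a threshold approaching 0 no two output communities could be
#' merged into a higher-scoring community.
#'
#' @param comms a community tibble of candidates.
#' @param model a `commfit_fitness` object.
#' @param graph a `weighted_graph`.
#' @param params a [merge_params()].
#' @return the merged community tibble, rescored.
#' @export
merge_learned <- function(comms, model, graph, params = merge_params()) {
  if (nrow(comms) == 0) return(comms)
  ov <- overlap_fun(params$measure)
  score_cache <- new.env(parent = emptyenv())
  score_of <- function(nodes) {
    key <- paste(nodes, collapse = "\x01")
    if (is.null(score_cache[[key]])) {
      score_cache[[key]] <- score_node_set(model, graph, nodes)
    }
    score_cache[[key]]
  }
  sets <- merge_pass_loop(
    as_node_sets(comms), threshold = params$threshold, overlap = ov,
    pick = function(a, b, union_nodes) {
      variants <- list(a, b, union_nodes)
      scores <- vapply(variants, score_of, 0)
      variants[[which.max(scores)]]
    },
    max_passes = params$max_passes
  )
  out <- community_set(sets, label = "learned")
  score_communities(out, model, graph)
}
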