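#' Node-level F-similarity between two communities
#'
#' For a known community `C_k` and a learned community `C_l`, the precision
#' `|C_k ∩ C_l| / |C_l|` (fraction of learned nodes that are correct), the
#' recall `|C_k ∩ C_l| / |C_k|` (fraction of known nodes recovered), and
#' their harmonic mean F. Equals 1 exactly when the node sets coincide.
#'
#' @param c_k,c_l nonempty character vectors (known and learned node sets).
#' @return a named list with `precision`, `recall`, `f`.
#' @export
f_similarity <- function(c_k, c_l) {
  if (length(c_k) == 0 || length(c_l) == 0) abort("f_similarity: empty node set")
  c_k <- unique(c_k); c_l <- unique(c_l)
  i <- length(intersect(c_k, c_l))
  p <- i / length(c_l)
  r <- i / length(c_k)
  list(precision = p, recall = r, f = harmonic_mean(p, r))
}

# |K| x |L| matrix of pairwise similarity values
similarity_matrix <- function(K, L, sim = function(a, b) f_similarity(a, b)$f) {
  Ks <- as_node_sets(K); Ls <- as_node_sets(L)
  if (length(Ks) == 0 || length(Ls) == 0) abort("empty community set")
  outer(seq_along(Ks), seq_along(Ls),
        Vectorize(function(i, j) sim(Ks[[i]], Ls[[j]])))
}

#' Binary-match precision/recall/F1 (Qi et al. style)
#'
#' A known and a learned community match at threshold `t` when both node
#' fractions clear it: `|C_k ∩ C_l| / |C_l| >= t` and
#' `|C_k ∩ C_l| / |C_k| >= t` (this package's match criterion). Recall is
#' the fraction of known communities with at least one match, precision the
#' fraction of learned communities with at least one match.
#'
#' @param K,L community tibbles (or lists of node sets): known and learned.
#' @param t match threshold (default 0.5).
#' @return a one-row tibble with `precision`, `recall`, `f1`.
#' @export
qi_prf <- function(K, L, t = 0.5) {
  Ks <- as_node_sets(K); Ls <- as_node_sets(L)
  if (length(Ks) == 0 || length(Ls) == 0) abort("qi_prf: empty community set")
  match_mat <- outer(seq_along(Ks), seq_along(Ls), Vectorize(function(i, j) {
    fs <- f_similarity(Ks[[i]], Ls[[j]])
    fs$precision >= t && fs$recall >= t
  }))
  r <- mean(apply(match_mat, 1, any))
  p <- mean(apply(match_mat, 2, any))
  tibble(precision = p, recall = r, f1 = harmonic_mean(p, r))
}

#' Similarity-weighted precision/recall/F1 framework
#'
#' The pluggable-similarity generalisation of binary matching: recall is the
#' mean over known communities of the best similarity against the learned
#' set, precision the mean over learned communities of the best similarity
#' against the known set, combined by harmonic mean.
#'
#' @param K,L community tibbles or lists of node sets.
#' @param sim a similarity function over two node sets returning a value in
#'   \[0, 1\] (default: the F component of [f_similarity()]).
#' @return a one-row tibble with `precision`, `recall`, `f1`.
#' @export
sensitive_prf <- function(K, L, sim = function(a, b) f_similarity(a, b)$f) {
  M <- similarity_matrix(K, L, sim)
  r <- mean(apply(M, 1, max))
  p <- mean(apply(M, 2, max))
  tibble(precision = p, recall = r, f1 = harmonic_mean(p, r))
}

#' Community-wise maximum F-similarity F-score (CMFF)
#'
#' [sensitive_prf()] instantiated with F-similarity: every community on each
#' side contributes its best F-similarity against the other side, so split
#' or partial matches are credited proportionally rather than counted as
#' binary hits.
#'
#' @inheritParams qi_prf
#' @return a one-row tibble with `precision`, `recall`, `f1`.
#' @export
cmff <- function(K, L) {
  sensitive_prf(K, L)
}

# exact maximum-weight one-to-one matching of the K x L similarity matrix;
# returns total weight and the matched pairs
max_weight_matching <- function(M) {
  nk <- nrow(M); nl <- ncol(M)
  pos <- which(M > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) {
    return(list(weight = 0, pairs = tibble(known = integer(), learned = integer(),
                                           weight = numeric())))
  }
  el <- cbind(pos[, 1], nk + pos[, 2])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nk + nl - igraph::vcount(g)))
  igraph::V(g)$type <- c(rep(FALSE, nk), rep(TRUE, nl))
  w <- M[pos]
  m <- igraph::max_bipartite_match(g, weights = w)
  matched_l <- m$matching[seq_len(nk)]
  keep <- !is.na(matched_l)
  pairs <- tibble(
    known = which(keep),
    learned = as.integer(matched_l[keep]) - nk,
    weight = M[cbind(which(keep), as.integer(matched_l[keep]) - nk)]
  ) |> arrange(.data$known)
  list(weight = m$matching_weight, pairs = pairs)
}

#' F-similarity maximal-matching F-score (FMMF)
#'
#' Builds the bipartite graph of known versus learned communities with
#' F-similarity edge weights, finds an exact maximum-weight one-to-one
#' matching of total weight `W`, and reports recall `W / |K|`, precision
#' `W / |L|` and their harmonic mean. Because the matching is one-to-one,
#' redundant learned duplicates and split fragments cannot double-count:
#' duplicating every learned community halves the precision, and splitting
#' an exact match credits only one fragment.
#'
#' @inheritParams qi_prf
#' @return a one-row tibble with `precision`, `recall`, `f1`, and a
#'   `matching` list-column (the matched index pairs with their weights).
#' @export
fmmf <- function(K, L) {
  M <- similarity_matrix(K, L)
  m <- max_weight_matching(M)
  p <- m$weight / ncol(M)
  r <- m$weight / nrow(M)
  tibble(precision = p, recall = r, f1 = harmonic_mean(p, r),
         matching = list(m$pairs))
}

#' Maximal matching ratio (MMR)
#'
#' The maximum-weight one-to-one matching sum divided by the number of known
#' communities — identical to the recall component of [fmmf()].
#'
#' @inheritParams qi_prf
#' @return a single number in \[0, 1\].
#' @export
mmr <- function(K, L) {
  M <- similarity_matrix(K, L)
  max_weight_matching(M)$weight / nrow(M)
}

#' Sensitivity / PPV accuracy and its unbiased variant
#'
#' With `t_kl = |C_k ∩ C_l|`: the classical node-level sensitivity
#' `Sn = sum_k max_l t_kl / sum_k |C_k|` (weighted toward large known
#' communities), positive predictive value
#' `PPV = sum_l max_k t_kl / sum_l sum_k t_kl` (insensitive to learned nodes
#' matching no known community), and their geometric mean SPA. The unbiased
#' variants average per community instead: `Sn_u = mean_k max_l t_kl /
#' |C_k|`, `PPV_u = mean_l max_k t_kl / |C_l|`, `UnSPA = sqrt(Sn_u PPV_u)`,
#' so every community counts equally and spurious learned nodes are
#' penalised.
#'
#' @inheritParams qi_prf
#' @return a one-row tibble with `sn`, `ppv`, `spa`, `sn_u`, `ppv_u`,
#'   `unspa`.
#' @export
spa_and_unspa <- function(K, L) {
  Ks <- as_node_sets(K); Ls <- as_node_sets(L)
  if (length(Ks) == 0 || length(Ls) == 0) abort("spa_and_unspa: empty community set")
  T_mat <- outer(seq_along(Ks), seq_along(Ls), Vectorize(function(i, j) {
    length(intersect(Ks[[i]], Ls[[j]]))
  }))
  size_k <- lengths(Ks)
  size_l <- lengths(Ls)
  sn <- sum(apply(T_mat, 1, max)) / sum(size_k)
  denom_ppv <- sum(T_mat)
  ppv <- if (denom_ppv > 0) sum(apply(T_mat, 2, max)) / denom_ppv else 0
  sn_u <- mean(apply(T_mat, 1, max) / size_k)
  ppv_u <- mean(apply(T_mat, 2, max) / size_l)
  tibble(sn = sn, ppv = ppv, spa = sqrt(sn * ppv),
         sn_u = sn_u, ppv_u = ppv_u, unspa = sqrt(sn_u * ppv_u))
}

#' Co-complex edge classification PR curve
#'
#' Treats unordered node pairs co-occurring in at least one known community
#' as the positive class; every pair co-occurring in a learned community is
#' predicted with the maximum score of a containing community, and the PR
#' curve is swept over descending scores.
#'
#' @param K known community tibble.
#' @param L learned community tibble with a populated `score` column.
#' @return a tibble of PR points (`threshold`, `precision`, `recall`).
#' @export
cocomplex_edge_pr <- function(K, L) {
  if (any(is.na(L$score))) abort("cocomplex_edge_pr: learned communities must carry scores")
  pair_keys <- function(nodes) {
    if (length(nodes) < 2) return(character())
    cmb <- utils::combn(sort(nodes), 2)
    paste(cmb[1, ], cmb[2, ], sep = "|")
  }
  known_pairs <- unique(unlist(lapply(as_node_sets(K), pair_keys)))
  pred <- lapply(seq_len(nrow(L)), function(i) {
    tibble(pair = pair_keys(L$nodes[[i]]), score = L$score[i])
  }) |>
    bind_rows() |>
    group_by(.data$pair) |>
    summarise(score = max(.data$score), .groups = "drop")
  if (nrow(pred) == 0) abort("cocomplex_edge_pr: learned set induces no pairs")
  ord <- order(pred$score, decreasing = TRUE)
  sc <- pred$score[ord]
  hit <- pred$pair[ord] %in% known_pairs
  tp <- cumsum(hit)
  npred <- seq_along(hit)
  last_of_score <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tibble(
    threshold = sc[last_of_score],
    precision = tp[last_of_score] / npred[last_of_score],
    recall = tp[last_of_score] / length(known_pairs)
  )
}

#' Full evaluation report of a learned community set
#'
#' Computes every measure against the known set: binary-match
#' precision/recall/F1, FMMF, CMFF, sensitivity/PPV (classical and
#' unbiased), MMR, and — when the learned set carries scores — the
#' co-complex edge PR curve.
#'
#' @param learned a community tibble (data-frame-first so reports pipe off
#'   the search/merge output).
#' @param known a community tibble of reference communities.
#' @param qi_t binary-match threshold.
#' @return a `commfit_report` object; see [tidy.commfit_report()] /
#'   [glance.commfit_report()].
#' @export
evaluate_communities <- function(learned, known, qi_t = 0.5) {
  qi <- qi_prf(known, learned, t = qi_t)
  fm <- fmmf(known, learned)
  cm <- cmff(known, learned)
  sp <- spa_and_unspa(known, learned)
  pr <- if (!any(is.na(learned$score))) cocomplex_edge_pr(known, learned)
  structure(
    list(
      qi_precision = qi$precision, qi_recall = qi$recall, qi_f1 = qi$f1,
      qi_t = qi_t,
      fmmf_p = fm$precision, fmmf_r = fm$recall, fmmf = fm$f1,
      matching = fm$matching[[1]],
      cmff_p = cm$precision, cmff_r = cm$recall, cmff = cm$f1,
      sn = sp$sn, ppv = sp$ppv, spa = sp$spa,
      sn_u = sp$sn_u, ppv_u = sp$ppv_u, unspa = sp$unspa,
      mmr = fm$recall,
      cocomplex_edge_pr = pr,
      n_known = nrow(as_tibble_comms(known)), n_learned = nrow(as_tibble_comms(learned))
    ),
    class = "commfit_report"
  )
}

as_tibble_comms <- function(x) {
  if (is.data.frame(x)) x else community_set(x)
}

#' @export
print.commfit_report <- function(x, ...) {
  cat(sprintf("<commfit_report> %d learned vs %d known communities\n",
              x$n_learned, x$n_known))
  cat(sprintf("  binary match (t=%.2f): P %.3f R %.3f F1 %.3f\n",
              x$qi_t, x$qi_precision, x$qi_recall, x$qi_f1))
  cat(sprintf("  FMMF %.3f (P %.3f R %.3f) | CMFF %.3f | MMR %.3f\n",
              x$fmmf, x$fmmf_p, x$fmmf_r, x$cmff, x$mmr))
  cat(sprintf("  SPA %.3f (Sn %.3f PPV %.3f) | UnSPA %.3f (Sn_u %.3f PPV_u %.3f)\n",
              x$spa, x$sn, x$ppv, x$unspa, x$sn_u, x$ppv_u))
  invisible(x)
}

#' All scalar measures of an evaluation report as a long tibble
#' @param x a `commfit_report`.
#' @param ... unused.
#' @return a tibble with `measure` and `value` columns.
#' @export
tidy.commfit_report <- function(x, ...) {
  vals <- x[c("qi_precision", "qi_recall", "qi_f1", "fmmf_p", "fmmf_r",
              "fmmf", "cmff_p", "cmff_r", "cmff", "sn", "ppv", "spa",
              "sn_u", "ppv_u", "unspa", "mmr")]
  tibble(measure = names(vals), value = as.numeric(unlist(vals)))
}

#' One-row summary of an evaluation report
#' @param x a `commfit_report`.
#' @param ... unused.
#' @return a one-row tibble of the headline measures.
#' @export
glance.commfit_report <- function(x, ...) {
  tibble(qi_f1 = x$qi_f1, fmmf = x$fmmf, cmff = x$cmff, unspa = x$unspa,
         spa = x$spa, mmr = x$mmr, n_known = x$n_known,
         n_learned = x$n_learned)
}

#' Write an evaluation report as TSV
#'
#' @param report a `commfit_report`.
#' @param path output TSV of scalar measures; the matching is written next
#'   to it as `<path>.matching.tsv` (`known_id`, `learned_id`, `weight`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(tidy(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$matching, paste0(path, ".matching.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sensitivity of all measures to the allowed learned-set overlap
#'
#' Re-evaluates candidate sets produced at different merge thresholds so the
#' response of each measure to learned-set redundancy can be compared.
#'
#' @param known a community tibble.
#' @param candidate_sets named list of community tibbles, one per merge
#'   threshold (>= 2 entries).
#' @param qi_t binary-match threshold.
#' @return a tibble with one row per threshold and one column per measure.
#' @export
overlap_sensitivity_sweep <- function(known, candidate_sets, qi_t = 0.5) {
  if (length(candidate_sets) < 2) {
    abort("overlap_sensitivity_sweep: need at least 2 threshold points")
  }
  purrr::imap(candidate_sets, function(L, nm) {
    glance(evaluate_communities(L, known, qi_t = qi_t)) |>
      mutate(threshold = nm, .before = 1)
  }) |> bind_rows()
}
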