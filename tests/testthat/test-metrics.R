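test_that("set similarities match their closed forms", {
  expect_equal(jaccard(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(jaccard(character(), "a"), "empty")

  expect_equal(qi_overlap(c("a", "b", "c"), c("a", "b", "c", "d")),
               9 / 12)

  fs <- f_similarity(as.character(1:4), as.character(1:6))
  expect_equal(fs$precision, 4 / 6)
  expect_equal(fs$recall, 1)
  expect_equal(fs$f, 0.8)
  expect_equal(f_similarity(c("a"), c("a"))$f, 1)
  expect_equal(f_similarity(c("a"), c("b"))$f, 0)
})

test_that("binary matching counts communities with a qualifying partner", {
  K <- list(as.character(1:3), as.character(4:6))
  expect_equal(qi_prf(K, K)$f1, 1)

  L <- c(K, list(c("x", "y", "z")))
  out <- qi_prf(K, L)
  expect_equal(out$recall, 1)
  expect_equal(out$precision, 2 / 3)

  expect_equal(qi_prf(K, list(c("p", "q", "r")))$f1, 0)
})

test_that("the similarity-weighted framework is pluggable and matches hand values", {
  K <- list(as.character(1:3))
  L <- list(as.character(1:3), as.character(7:9))
  out <- sensitive_prf(K, L)
  expect_equal(out$recall, 1)
  expect_equal(out$precision, 0.5)
  expect_equal(out$f1, 2 / 3)

  # swapping in Jaccard changes the value on asymmetric overlaps
  K2 <- list(as.character(1:4))
  L2 <- list(as.character(1:8))
  with_f <- sensitive_prf(K2, L2)$f1
  with_j <- sensitive_prf(K2, L2, sim = jaccard)$f1
  expect_false(isTRUE(all.equal(with_f, with_j)))

  # CMFF is exactly the F-similarity instantiation
  cm <- cmff(community_set(K), community_set(L))
  expect_equal(cm, sensitive_prf(K, L))
  expect_equal(cmff(list(as.character(1:4)), list(as.character(1:6)))$f1, 0.8)
})

test_that("splitting a known community lowers CMFF relative to an exact match", {
  K <- list(as.character(1:6))
  exact <- cmff(K, list(as.character(1:6)))$f1
  halves <- cmff(K, list(as.character(1:3), as.character(4:6)))$f1
  expect_equal(exact, 1)
  expect_lt(halves, exact)
})

test_that("the maximal matching agrees with brute force and penalises redundancy and splits", {
  K <- list(as.character(1:3), as.character(4:6))
  expect_equal(fmmf(K, K)$f1, 1)

  one <- fmmf(K, list(as.character(1:3)))
  expect_equal(one$precision, 1)
  expect_equal(one$recall, 0.5)
  expect_equal(one$f1, 2 / 3)

  # brute-force oracle on random small instances
  sets <- random_community_sets(30, n_comms = 6, universe = 20, seed = 23)
  for (i in seq(1, 29, by = 2)) {
    Kr <- sets[[i]]$nodes[1:sample(2:6, 1)]
    Lr <- sets[[i + 1]]$nodes[1:sample(2:6, 1)]
    got <- mmr(Kr, Lr) * length(Kr)
    want <- brute_force_matching(fsim_matrix(Kr, Lr))
    expect_equal(got, want, tolerance = 1e-12)
  }

  # duplicating every learned community halves precision, recall unchanged
  L <- list(as.character(1:3), c("4", "5", "9"))
  base <- fmmf(K, L)
  dup <- fmmf(K, c(L, L))
  expect_equal(dup$recall, base$recall)
  expect_equal(dup$precision, base$precision / 2)
  expect_lt(dup$f1, base$f1)

  # splitting an exact match keeps only one fragment in the matching
  split_f <- fmmf(list(as.character(1:6)),
                  list(as.character(1:3), as.character(4:6)))
  expect_lt(split_f$f1, 1)

  # MMR is the recall component of the matching
  expect_equal(mmr(K, L), base$recall)
})

test_that("Sn/PPV and their unbiased variants expose the documented biases", {
  # big community {1..6} and small {7,8,9}; detector recovers the two halves
  # of the big one only
  K <- list(as.character(1:6), as.character(7:9))
  halves <- list(as.character(1:3), as.character(4:6))
  s <- spa_and_unspa(K, halves)
  expect_equal(s$sn, 3 / 9)       # node-weighted: big community dominates
  expect_equal(s$sn_u, 0.25)      # community-weighted: (3/6 + 0/3) / 2
  expect_false(isTRUE(all.equal(s$sn, s$sn_u)))

  # detector that perfectly recovers only the small community scores higher
  # under the unbiased sensitivity
  small_only <- list(as.character(7:9))
  s2 <- spa_and_unspa(K, small_only)
  expect_equal(s2$sn, 3 / 9)
  expect_equal(s2$sn_u, 0.5)
  expect_gt(s2$sn_u, s2$sn)

  # spurious non-known nodes leave PPV untouched but depress PPV_u
  base <- spa_and_unspa(K, list(as.character(1:6)))
  spur <- spa_and_unspa(K, list(c(as.character(1:6), "s1", "s2", "s3")))
  expect_equal(spur$ppv, base$ppv)
  expect_lt(spur$ppv_u, base$ppv_u)

  # perfect detection on disjoint communities: all six measures are 1
  p <- spa_and_unspa(K, K)
  expect_equal(as.numeric(p), rep(1, 6))
})

test_that("co-complex edge PR sweeps pair predictions by score", {
  K <- community_set(list(as.character(1:3), as.character(4:6)))
  L <- K
  L$score <- 1
  L$label <- "learned"
  pr <- cocomplex_edge_pr(K, L)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  half <- community_set(list(as.character(1:3)), label = "learned", score = 1)
  pr2 <- cocomplex_edge_pr(K, half)
  expect_equal(max(pr2$recall), 0.5)

  spur <- community_set(list(as.character(1:3), c("x", "y", "z")),
                        label = "learned", score = c(0.9, 0.8))
  pr3 <- cocomplex_edge_pr(K, spur)
  expect_lt(pr3$precision[nrow(pr3)], 1)

  unscored <- community_set(list(as.character(1:3)), label = "learned")
  expect_error(cocomplex_edge_pr(K, unscored), "scores")
})

test_that("measures are relabeling-invariant and bounded", {
  sets <- random_community_sets(10, n_comms = 4, universe = 15, seed = 29)
  for (i in seq(1, 9, by = 2)) {
    K <- sets[[i]]; L <- sets[[i + 1]]
    relabel <- function(cs) {
      map <- stats::setNames(paste0("r", 1:15), as.character(1:15))
      community_set(lapply(cs$nodes, function(ns) unname(map[ns])))
    }
    for (fn in list(function(K, L) qi_prf(K, L)$f1,
                    function(K, L) fmmf(K, L)$f1,
                    function(K, L) cmff(K, L)$f1,
                    function(K, L) spa_and_unspa(K, L)$unspa)) {
      v <- fn(K, L)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(v, fn(relabel(K), relabel(L)))
    }
    # identity: every matching-based measure is 1 exactly on equal sets
    expect_equal(fmmf(K, K)$f1, 1)
    expect_equal(cmff(K, K)$f1, 1)
    expect_equal(spa_and_unspa(K, K)$unspa, 1)
  }
})

test_that("the report object aggregates all measures and sweeps thresholds", {
  K <- community_set(list(as.character(1:3), as.character(4:6)))
  L <- community_set(list(as.character(1:3), as.character(4:6), c("x", "y", "z")),
                     label = "learned", score = c(0.9, 0.8, 0.7))
  rep <- evaluate_communities(L, K)
  expect_s3_class(rep, "commfit_report")
  td <- tidy(rep)
  expect_true(all(td$value >= 0 & td$value <= 1))
  expect_equal(glance(rep)$qi_f1, rep$qi_f1)
  expect_equal(rep$mmr, rep$fmmf_r)

  # duplicated learned set: matching precision halves, binary precision doesn't
  Ldup <- dplyr::bind_rows(L, L)
  Ldup$id <- sprintf("lea_%02d", 1:6)
  sweep <- overlap_sensitivity_sweep(K, list(merged = L, raw = Ldup))
  expect_equal(nrow(sweep), 2)
  expect_equal(sweep$qi_f1[1] > 0, TRUE)
  raw <- evaluate_communities(Ldup, K)
  expect_equal(raw$fmmf_p, rep$fmmf_p / 2)
  expect_equal(raw$qi_precision, rep$qi_precision)

  expect_error(overlap_sensitivity_sweep(K, list(only = L)), "at least 2")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".matching.tsv")))
})
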